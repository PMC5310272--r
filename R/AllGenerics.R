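#' @describeIn AnnotatedGenome-class strain identifier
#' @param x an object
#' @export
setGeneric("strainID", function(x) standardGeneric("strainID"))

#' @describeIn AnnotatedGenome-class contig sequences as a \code{DNAStringSet}
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @describeIn AnnotatedGenome-class CDS features as a \code{GRanges}
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @describeIn AnnotatedGenome-class spliced CDS nucleotide sequences (minus
#'   strand genes reverse-complemented), named by \code{gene_id}
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))

#' @describeIn AnnotatedGenome-class translated proteins (bacterial code,
#'   translation table 11), named by \code{gene_id}
#' @export
setGeneric("proteinSeq", function(x) standardGeneric("proteinSeq"))

#' @describeIn StrainCohort-class genomes of the cohort as a named list
#' @param x an object
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @describeIn StrainCohort-class generating strain genealogy (\code{phylo})
#' @export
setGeneric("trueTree", function(x) standardGeneric("trueTree"))

#' @describeIn StrainCohort-class true gene-family presence/absence matrix
#' @export
setGeneric("truePAMatrix", function(x) standardGeneric("truePAMatrix"))

#' @describeIn StrainCohort-class true seven-locus allelic profiles
#' @export
setGeneric("trueProfiles", function(x) standardGeneric("trueProfiles"))

#' @describeIn StrainCohort-class planted variant truth per derived strain
#' @export
setGeneric("trueVariants", function(x) standardGeneric("trueVariants"))

#' @describeIn MLSTScheme-class ordered locus names of a scheme
#' @export
setGeneric("schemeLoci", function(x) standardGeneric("schemeLoci"))

#' @describeIn MLSTScheme-class per-locus reference sequences
#' @export
setGeneric("schemeRefs", function(x) standardGeneric("schemeRefs"))
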