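#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet DNAString
#' @importFrom GenomicRanges GRanges
NULL

#' AnnotatedGenome: contig sequences plus CDS features of one strain
#'
#' The unit consumed by every analysis stage: a set of contig sequences
#' (\linkS4class{DNAStringSet}) together with the strain's CDS features as a
#' \linkS4class{GRanges} (1-based inclusive coordinates, strand-aware), each
#' feature carrying a unique \code{gene_id} and a \code{product} description.
#'
#' @slot strainID single strain identifier.
#' @slot contigs named \code{DNAStringSet} of contig sequences.
#' @slot features \code{GRanges} of CDS features with metadata columns
#'   \code{gene_id} and \code{product}.
#'
#' @seealso [annotatedGenome()], [readGenome()], [writeGenome()]
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
  representation(
    strainID = "character",
    contigs = "DNAStringSet",
    features = "GRanges"
  )
)

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  if (length(object@strainID) != 1L || is.na(object@strainID) ||
      !nzchar(object@strainID)) {
    msg <- c(msg, "strainID must be a single non-empty string")
  }
  if (length(object@contigs) == 0L) {
    msg <- c(msg, "genome must contain at least one contig")
  }
  if (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs))) {
    msg <- c(msg, "contigs must have unique names")
  }
  ft <- object@features
  if (length(ft) > 0L) {
    gid <- ft$gene_id
    if (is.null(gid) || anyNA(gid)) {
      msg <- c(msg, "every feature needs a gene_id")
    } else if (anyDuplicated(gid)) {
      msg <- c(msg, paste0("duplicate gene_id: ",
                           paste(unique(gid[duplicated(gid)]), collapse = ", ")))
    }
    seqn <- as.character(GenomicRanges::seqnames(ft))
    bad <- !(seqn %in% names(object@contigs))
    if (any(bad)) {
      msg <- c(msg, paste0("feature on unknown contig: ",
                           paste(unique(seqn[bad]), collapse = ", ")))
    } else {
      cw <- BiocGenerics::width(object@contigs)[match(seqn, names(object@contigs))]
      oob <- GenomicRanges::start(ft) < 1L | GenomicRanges::end(ft) > cw
      if (any(oob)) {
        msg <- c(msg, paste0("feature out of contig bounds: ",
                             paste(gid[oob], collapse = ", ")))
      }
    }
    if (any(as.character(GenomicRanges::strand(ft)) == "*")) {
      msg <- c(msg, "CDS features must be stranded (+ or -)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PanGenomeModel: parameters of the synthetic species-cohort simulator
#'
#' Describes a pan-genome as a set of core gene families (present in every
#' strain) and dispensable families gained and lost along the branches of a
#' random strain genealogy, with nucleotide substitutions and in-frame indels
#' accumulating per branch.
#'
#' @slot nCore number of universally shared gene families (>= 1); always
#'   includes the seven MLST housekeeping loci.
#' @slot nDispensable number of variably present families.
#' @slot geneLengthRange two nt bounds for gene lengths; multiples of 3,
#'   minimum 33 (start + >= 9 codons + stop).
#' @slot gainProb,lossProb per-branch per-family gain/loss probabilities.
#' @slot snpRate substitutions per site per branch.
#' @slot indelRate in-frame indels per gene per branch.
#' @slot seed integer RNG seed; all randomness flows from it.
#'
#' @seealso [panGenomeModel()], [simulateCohort()]
#' @exportClass PanGenomeModel
setClass("PanGenomeModel",
  representation(
    nCore = "integer",
    nDispensable = "integer",
    geneLengthRange = "integer",
    gainProb = "numeric",
    lossProb = "numeric",
    snpRate = "numeric",
    indelRate = "numeric",
    seed = "integer"
  )
)

setValidity("PanGenomeModel", function(object) {
  msg <- character()
  if (object@nCore < 1L) msg <- c(msg, "nCore must be >= 1")
  if (object@nDispensable < 0L) msg <- c(msg, "nDispensable must be >= 0")
  glr <- object@geneLengthRange
  if (length(glr) != 2L || any(glr < 33L) || any(glr %% 3L != 0L) ||
      glr[1] > glr[2]) {
    msg <- c(msg, "geneLengthRange must be two nondecreasing multiples of 3, each >= 33")
  }
  for (p in c("gainProb", "lossProb")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      msg <- c(msg, paste(p, "must be in [0, 1]"))
    }
  }
  if (object@snpRate < 0 || object@snpRate > 1) {
    msg <- c(msg, "snpRate must be in [0, 1]")
  }
  if (object@indelRate < 0) msg <- c(msg, "indelRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MLSTScheme: seven-locus typing scheme with an allele registry
#'
#' Holds the ordered locus names, one reference sequence per locus used for
#' in-silico extraction, and a per-locus registry mapping observed allele
#' sequences to allele integers (>= 1, assigned in discovery order).
#'
#' @slot loci ordered character vector of the seven locus names.
#' @slot refSeqs \code{DNAStringSet} named by locus.
#' @slot registry list (one element per locus) of integer vectors whose names
#'   are allele sequences and whose values are allele numbers.
#'
#' @seealso [mlstScheme()], [assignAllele()], [extractLocus()]
#' @exportClass MLSTScheme
setClass("MLSTScheme",
  representation(
    loci = "character",
    refSeqs = "DNAStringSet",
    registry = "list"
  )
)

setValidity("MLSTScheme", function(object) {
  msg <- character()
  if (length(object@loci) != 7L) msg <- c(msg, "an MLST scheme has exactly 7 loci")
  if (anyDuplicated(object@loci)) msg <- c(msg, "locus names must be unique")
  if (!identical(names(object@refSeqs), object@loci)) {
    msg <- c(msg, "refSeqs must be named by the scheme loci, in order")
  }
  if (!identical(names(object@registry), object@loci)) {
    msg <- c(msg, "registry must be named by the scheme loci, in order")
  }
  for (loc in names(object@registry)) {
    reg <- object@registry[[loc]]
    if (length(reg)) {
      if (any(reg < 1L) || anyDuplicated(reg) || anyDuplicated(names(reg))) {
        msg <- c(msg, paste0("registry for ", loc,
                             " must map unique sequences to unique integers >= 1"))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' StrainCohort: simulated genomes plus their generating truth
#'
#' Container returned by [simulateCohort()]: the per-strain
#' \linkS4class{AnnotatedGenome} objects together with the truth channel used
#' by tests — the generating tree, the true gene-family presence/absence
#' matrix, the true seven-locus allelic profiles, and (for derived producer
#' strains) the planted variant calls relative to each strain's parent.
#'
#' @slot genomes named list of \linkS4class{AnnotatedGenome}.
#' @slot tree generating strain genealogy (\code{ape::phylo}).
#' @slot paMatrix logical matrix, gene families x strains.
#' @slot profiles integer matrix, strains x 7 MLST loci.
#' @slot variants named list: per derived strain, the data.frame of planted
#'   variant calls relative to its parent (with a \code{parent} attribute).
#' @slot model the \linkS4class{PanGenomeModel} that generated the cohort.
#'
#' @exportClass StrainCohort
setClass("StrainCohort",
  representation(
    genomes = "list",
    tree = "ANY",
    paMatrix = "matrix",
    profiles = "matrix",
    variants = "list",
    model = "PanGenomeModel"
  )
)

setValidity("StrainCohort", function(object) {
  msg <- character()
  ids <- names(object@genomes)
  if (is.null(ids) || anyDuplicated(ids)) {
    msg <- c(msg, "genomes must be a uniquely named list")
  }
  if (!all(vapply(object@genomes, is, logical(1), "AnnotatedGenome"))) {
    msg <- c(msg, "all genomes must be AnnotatedGenome objects")
  }
  if (!all(colnames(object@paMatrix) %in% c(ids, character(0)))) {
    msg <- c(msg, "paMatrix columns must be cohort strains")
  }
  if (!is.null(object@tree) && inherits(object@tree, "phylo")) {
    if (!all(object@tree$tip.label %in% ids)) {
      msg <- c(msg, "every tree tip must be a cohort strain")
    }
  }
  if (length(msg)) msg else TRUE
})
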