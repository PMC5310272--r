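#' Construct an AnnotatedGenome
#'
#' @param strainID single strain identifier.
#' @param contigs named [Biostrings::DNAStringSet] (or named character vector)
#'   of contig sequences.
#' @param features [GenomicRanges::GRanges] of CDS features with metadata
#'   columns \code{gene_id} (unique) and \code{product}; coordinates are
#'   1-based inclusive, strand must be \code{+} or \code{-}.
#' @return an \linkS4class{AnnotatedGenome}.
#' @examples
#' g <- annotatedGenome("s1",
#'   c(chr = "ATGAAATTTGGGTAA"),
#'   GenomicRanges::GRanges("chr", IRanges::IRanges(1, 15), "+",
#'                          gene_id = "g1", product = "demo"))
#' cdsSeq(g)
#' @export
annotatedGenome <- function(strainID, contigs, features) {
  if (is.character(contigs)) contigs <- DNAStringSet(contigs)
  if (is.null(features$product)) features$product <- "hypothetical protein"
  new("AnnotatedGenome", strainID = strainID, contigs = contigs,
      features = features)
}

#' @rdname AnnotatedGenome-class
#' @aliases strainID,AnnotatedGenome-method
setMethod("strainID", "AnnotatedGenome", function(x) x@strainID)

#' @rdname AnnotatedGenome-class
setMethod("contigs", "AnnotatedGenome", function(x) x@contigs)

#' @rdname AnnotatedGenome-class
setMethod("features", "AnnotatedGenome", function(x) x@features)

#' @rdname AnnotatedGenome-class
setMethod("cdsSeq", "AnnotatedGenome", function(x) {
  ft <- x@features
  if (length(ft) == 0L) return(DNAStringSet())
  seqn <- as.character(GenomicRanges::seqnames(ft))
  out <- vector("list", length(ft))
  for (ctg in unique(seqn)) {
    sel <- which(seqn == ctg)
    ext <- Biostrings::extractAt(
      x@contigs[[ctg]],
      IRanges::IRanges(GenomicRanges::start(ft)[sel],
                       GenomicRanges::end(ft)[sel]))
    out[sel] <- as.list(ext)
  }
  res <- DNAStringSet(out)
  minus <- as.character(GenomicRanges::strand(ft)) == "-"
  if (any(minus)) res[minus] <- Biostrings::reverseComplement(res[minus])
  names(res) <- ft$gene_id
  res
})

#' @rdname AnnotatedGenome-class
setMethod("proteinSeq", "AnnotatedGenome", function(x) {
  translateCDS(cdsSeq(x))
})

#' Translate CDS sequences with the bacterial genetic code
#'
#' Translation table 11; a trailing stop codon is trimmed from the protein.
#' Sequences whose length is not a multiple of 3 are an error.
#'
#' @param cds a [Biostrings::DNAStringSet].
#' @return an [Biostrings::AAStringSet]; internal stops are kept as \code{*}
#'   so that callers can quarantine untranslatable genes.
#' @export
translateCDS <- function(cds) {
  if (length(cds) == 0L) return(AAStringSet())
  w <- BiocGenerics::width(cds)
  cds <- Biostrings::subseq(cds, 1L, w - w %% 3L)  # drop partial codons
  aa <- Biostrings::translate(cds, genetic.code = Biostrings::getGeneticCode("11"),
                              if.fuzzy.codon = "X")
  aa <- AAStringSet(sub("\\*$", "", as.character(aa)))
  names(aa) <- names(cds)
  aa
}

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome of strain", object@strainID, "\n")
  cat(" ", length(object@contigs), "contig(s),",
      sum(BiocGenerics::width(object@contigs)), "bp;",
      length(object@features), "CDS feature(s)\n")
})

#' Read a genome from FASTA + GFF3
#'
#' GFF3 coordinates (1-based inclusive) are kept as-is in the returned
#' \code{GRanges}; CDS extraction reverse-complements minus-strand genes.
#' Only \code{CDS} features are retained; the \code{ID} attribute becomes
#' \code{gene_id}.
#'
#' @param fasta path to the genome FASTA.
#' @param gff path to the GFF3 annotation.
#' @param strainID strain identifier; defaults to the FASTA base name.
#' @return an \linkS4class{AnnotatedGenome}.
#' @export
readGenome <- function(fasta, gff, strainID = NULL) {
  if (!file.exists(fasta)) stop("no such FASTA: ", fasta)
  if (!file.exists(gff)) stop("no such GFF3: ", gff)
  ctg <- Biostrings::readDNAStringSet(fasta)
  names(ctg) <- sub("\\s.*$", "", names(ctg))
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr)) {
    if (is.null(gr$ID) || anyNA(gr$ID)) stop("GFF3 CDS features must carry ID=")
    gene_id <- as.character(gr$ID)
    product <- if (!is.null(gr$product)) as.character(gr$product) else
      rep("hypothetical protein", length(gr))
    product[is.na(product)] <- "hypothetical protein"
    ft <- GRanges(GenomicRanges::seqnames(gr),
                  IRanges::IRanges(GenomicRanges::start(gr),
                                   GenomicRanges::end(gr)),
                  strand = GenomicRanges::strand(gr),
                  gene_id = gene_id, product = product)
  } else {
    ft <- GRanges(gene_id = character(), product = character())
  }
  if (is.null(strainID)) {
    strainID <- sub("\\.(fa|fasta|fna)$", "", basename(fasta))
  }
  annotatedGenome(strainID, ctg, ft)
}

#' Write a genome as FASTA + GFF3
#'
#' The inverse of [readGenome()]: sequence lines wrapped at 70 columns, CDS
#' features written with \code{ID=} and \code{product=} attributes.
#'
#' @param x an \linkS4class{AnnotatedGenome}.
#' @param fasta,gff output paths.
#' @return invisibly, the two paths.
#' @export
writeGenome <- function(x, fasta, gff) {
  Biostrings::writeXStringSet(x@contigs, fasta, width = 70L)
  ft <- x@features
  gr <- GRanges(GenomicRanges::seqnames(ft),
                IRanges::IRanges(GenomicRanges::start(ft),
                                 GenomicRanges::end(ft)),
                strand = GenomicRanges::strand(ft))
  gr$source <- "strainTrace"
  gr$type <- "CDS"
  gr$phase <- if (length(ft)) 0L else integer(0)
  gr$ID <- ft$gene_id
  gr$product <- ft$product
  GenomeInfoDb::seqlengths(gr) <-
    stats::setNames(BiocGenerics::width(x@contigs), names(x@contigs))[
      GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}
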