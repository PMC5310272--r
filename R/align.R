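# Thin R wrappers over the seeded banded alignment engine in src/align.cpp.

#' Best seeded hit of a query sequence against a genome
#'
#' Exact-match k-mer seeds (both strands) locate the candidate diagonal; a
#' banded extension (affine gaps: open 10, extend 1; match +1, mismatch -1)
#' aligns the full query against the best-supported window.  Deterministic.
#'
#' @param query character or \code{DNAString} query sequence.
#' @param genome an \linkS4class{AnnotatedGenome} or named character vector of
#'   contig sequences.
#' @param k seed k-mer length.
#' @param band half-width of the alignment band.
#' @return one-row data.frame: identity (percent), coverage (fraction of the
#'   query aligned), contig, start, end (1-based on the forward strand),
#'   strand, score.  identity 0 / coverage 0 when no seed matches.
#' @export
bestGenomeHit <- function(query, genome, k = 15L, band = 32L) {
  res <- mapToGenome(as.character(query), genome, k = k, band = band)
  res[1L, , drop = FALSE]
}

# Batch mapping of queries against all contigs of a genome; the best-scoring
# contig wins per query.
mapToGenome <- function(queries, genome, k = 15L, band = 32L) {
  ctgs <- if (is(genome, "AnnotatedGenome")) {
    stats::setNames(as.character(genome@contigs), names(genome@contigs))
  } else if (is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  if (length(ctgs) == 0L || all(nchar(ctgs) == 0L)) stop("empty genome")
  best <- NULL
  for (ctg in names(ctgs)) {
    df <- cpp_map_queries(queries, ctgs[[ctg]], k = k, band = band)
    df$contig <- ctg
    if (is.null(best)) {
      best <- df
    } else {
      better <- !is.na(df$score) & (is.na(best$score) | df$score > best$score)
      best[better, ] <- df[better, ]
    }
  }
  data.frame(identity = best$identity, coverage = best$coverage,
             contig = ifelse(is.na(best$score), NA_character_, best$contig),
             start = best$ref_start, end = best$ref_end,
             strand = best$strand, score = best$score,
             stringsAsFactors = FALSE)
}

# Extract the genome subsequence matched by a mapToGenome row, in the
# query's orientation.
hitSequence <- function(genome, hit) {
  ctg <- contigs(genome)[[hit$contig]]
  s <- as.character(Biostrings::subseq(ctg, hit$start, hit$end))
  if (hit$strand == "-") cpp_revcomp(s) else s
}

#' Global pairwise alignment of two sequences
#'
#' Banded global alignment with affine gaps; returns the gapped strings plus
#' match statistics.  Used for gene-pair comparison and locus identity.
#'
#' @param a,b sequences (character).
#' @param bandPad extra band width beyond the length difference.
#' @return list with \code{a}, \code{b} (gapped), \code{score},
#'   \code{matches}, \code{columns}.
#' @export
pairAlign <- function(a, b, bandPad = 32L) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  cpp_pair_align(a, b, band_pad = bandPad)
}
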