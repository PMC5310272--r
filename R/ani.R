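#' Whole-genome average nucleotide identity (ANI)
#'
#' Fragment-based ANI: the query genome is cut into consecutive
#' non-overlapping 1020-nt fragments, each fragment is aligned to the
#' reference by seeded banded alignment on both strands, and ANI is the mean
#' identity over fragments passing the classical filters (identity >= 30
#' percent, fragment coverage >= 0.70).  Values above the 95-96 percent band
#' indicate conspecificity.
#'
#' @name ani-module
NULL

#' Cut a genome into consecutive non-overlapping fragments
#'
#' Fragments never span contig boundaries; a trailing remainder shorter than
#' \code{fragmentLength} is discarded.
#'
#' @param genome \linkS4class{AnnotatedGenome}, \code{DNAStringSet} or named
#'   character vector.
#' @param fragmentLength fragment size in nt (>= 100).
#' @return character vector of fragments (named contig:start).
#' @export
fragmentGenome <- function(genome, fragmentLength = 1020L) {
  fragmentLength <- as.integer(fragmentLength)
  if (is.na(fragmentLength) || fragmentLength < 100L) {
    stop("fragmentLength must be >= 100")
  }
  ctgs <- if (is(genome, "AnnotatedGenome")) {
    stats::setNames(as.character(genome@contigs), names(genome@contigs))
  } else if (is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  if (length(ctgs) == 0L || sum(nchar(ctgs)) == 0L) stop("empty genome")
  out <- character()
  for (ctg in names(ctgs)) {
    L <- nchar(ctgs[[ctg]])
    n <- L %/% fragmentLength
    if (n == 0L) next
    starts <- (seq_len(n) - 1L) * fragmentLength + 1L
    frs <- substring(ctgs[[ctg]], starts, starts + fragmentLength - 1L)
    names(frs) <- paste0(ctg, ":", starts)
    out <- c(out, frs)
  }
  out
}

#' Best local hit of one fragment against a reference genome
#'
#' @param fragment character fragment (from [fragmentGenome()]).
#' @param reference reference genome (any form accepted by [fragmentGenome()]).
#' @return named numeric: \code{identity} (percent, matches / alignment
#'   columns) and \code{coverage} (aligned fragment positions / fragment
#'   length); both 0 when nothing seeds.
#' @export
bestFragmentHit <- function(fragment, reference) {
  hit <- bestGenomeHit(fragment, reference)
  c(identity = hit$identity, coverage = hit$coverage)
}

#' Compute ANI between two genomes
#'
#' @param genomeA,genomeB genomes (query and reference).
#' @param minIdentity fragment filter: minimum percent identity.
#' @param minCoverage fragment filter: minimum aligned fraction.
#' @param fragmentLength fragment size (nt).
#' @param symmetric average the A->B and B->A directions (default TRUE).
#' @return an \code{ANIResult}: list with \code{query_id}, \code{reference_id},
#'   \code{ani_percent} (NA when no fragment passes the filters — an
#'   explicitly flagged undefined state, never silently 0),
#'   \code{n_fragments_total}, \code{n_fragments_used},
#'   \code{aligned_fraction}, \code{defined}.
#' @examples
#' \donttest{
#' cohort <- simulateCohort(panGenomeModel(nCore = 30, nDispensable = 0,
#'                                         seed = 7), 2)
#' computeANI(genomes(cohort)$S01, genomes(cohort)$S02)
#' }
#' @export
computeANI <- function(genomeA, genomeB, minIdentity = 30, minCoverage = 0.70,
                       fragmentLength = 1020L, symmetric = TRUE) {
  idA <- if (is(genomeA, "AnnotatedGenome")) genomeA@strainID else "query"
  idB <- if (is(genomeB, "AnnotatedGenome")) genomeB@strainID else "reference"
  dir1 <- aniOneDirection(genomeA, genomeB, minIdentity, minCoverage,
                          fragmentLength)
  if (!symmetric) {
    res <- dir1
  } else {
    dir2 <- aniOneDirection(genomeB, genomeA, minIdentity, minCoverage,
                            fragmentLength)
    anis <- c(dir1$ani, dir2$ani)
    res <- list(
      ani = if (all(is.na(anis))) NA_real_ else mean(anis, na.rm = TRUE),
      total = dir1$total + dir2$total,
      used = dir1$used + dir2$used,
      frac = mean(c(dir1$frac, dir2$frac)))
  }
  structure(list(query_id = idA, reference_id = idB,
                 ani_percent = res$ani,
                 n_fragments_total = res$total,
                 n_fragments_used = res$used,
                 aligned_fraction = res$frac,
                 defined = !is.na(res$ani)),
            class = "ANIResult")
}

aniOneDirection <- function(q, r, minIdentity, minCoverage, fragmentLength) {
  frs <- fragmentGenome(q, fragmentLength)
  if (length(frs) == 0L) return(list(ani = NA_real_, total = 0L, used = 0L,
                                     frac = 0))
  hits <- mapToGenome(unname(frs), r)
  pass <- hits$identity >= minIdentity & hits$coverage >= minCoverage
  used <- sum(pass)
  list(ani = if (used > 0L) mean(hits$identity[pass]) else NA_real_,
       total = length(frs), used = used,
       frac = used / length(frs))
}

#' @export
print.ANIResult <- function(x, ...) {
  cat(sprintf("ANI %s vs %s: %s%% (%d/%d fragments, aligned fraction %.2f)\n",
              x$query_id, x$reference_id,
              if (x$defined) sprintf("%.2f", x$ani_percent) else "undefined",
              x$n_fragments_used, x$n_fragments_total, x$aligned_fraction))
  invisible(x)
}

#' Species demarcation from an ANI value
#'
#' ANI above \code{high} is called \code{same_species}, below \code{low}
#' \code{different_species}, inside the band \code{borderline}.  The default
#' 95-96 percent band is the published demarcation range; conspecific strain
#' cohorts typically sit above 97 percent.
#'
#' @param ani an \code{ANIResult} from [computeANI()] (or a bare percent).
#' @param low,high demarcation band bounds (percent).
#' @return list with \code{ani_percent}, \code{threshold_low},
#'   \code{threshold_high}, \code{verdict}.
#' @export
classifySpecies <- function(ani, low = 95, high = 96) {
  if (low > high) stop("threshold_low must be <= threshold_high")
  pct <- if (inherits(ani, "ANIResult")) {
    if (!ani$defined) stop("ANI is undefined (no fragment passed the filters)")
    ani$ani_percent
  } else as.numeric(ani)
  if (is.na(pct)) stop("ANI is undefined")
  verdict <- if (pct > high) "same_species"
    else if (pct < low) "different_species"
    else "borderline"
  list(ani_percent = pct, threshold_low = low, threshold_high = high,
       verdict = verdict)
}

#' All-vs-all ANI matrix for a set of genomes
#'
#' @param genomeList named list of genomes.
#' @param ... passed to [computeANI()].
#' @return symmetric numeric matrix of ANI percentages (diagonal 100).
#' @export
aniMatrix <- function(genomeList, ...) {
  ids <- names(genomeList)
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids) < 2L) return(m)
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      a <- computeANI(genomeList[[i]], genomeList[[j]], ...)
      m[i, j] <- m[j, i] <- a$ani_percent
    }
  }
  m
}

#' Global-alignment identity between two homologous sequences
#'
#' Used for in-silico 16S rDNA checks on extracted loci: conspecific strains
#' show 16S identity above 99 percent.
#'
#' @param seqA,seqB homologous sequences (character or XString).
#' @return percent identity in [0, 100]: matches / alignment columns x 100.
#' @export
pairwiseLocusIdentity <- function(seqA, seqB) {
  seqA <- as.character(seqA); seqB <- as.character(seqB)
  if (nchar(seqA) == 0L || nchar(seqB) == 0L) stop("empty sequence")
  aln <- pairAlign(seqA, seqB, bandPad = max(64L, abs(nchar(seqA) - nchar(seqB)) + 16L))
  100 * aln$matches / aln$columns
}
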