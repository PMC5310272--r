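#' Seven-locus MLST typing, grouping and presumed-ancestor selection
#'
#' In-silico multilocus sequence typing over the seven housekeeping loci
#' atpA, dnaE, dnaK, fusA, leuA, odhA, rpoB (allelic-profile column order).
#' Distinct seven-integer profiles define sequence types (STs); profiles are
#' clustered into groups by single-linkage at Hamming distance <= 2; the
#' most closely related wild-type strain within a group is the presumed
#' ancestor used as the reference for variant discovery.
#'
#' @name mlst-module
NULL

#' Create an MLST scheme
#'
#' @param refSeqs named \code{DNAStringSet} (or character vector) with one
#'   reference sequence per locus; must cover exactly the seven scheme loci.
#'   Order is normalized to the allelic-profile column order
#'   (atpA, dnaE, dnaK, fusA, leuA, odhA, rpoB).
#' @return an \linkS4class{MLSTScheme} with an empty allele registry.
#' @export
mlstScheme <- function(refSeqs) {
  if (is.character(refSeqs)) refSeqs <- DNAStringSet(refSeqs)
  if (!setequal(names(refSeqs), MLST_LOCI)) {
    stop("scheme must provide exactly the loci: ",
         paste(MLST_LOCI, collapse = ", "))
  }
  refSeqs <- refSeqs[MLST_LOCI]
  new("MLSTScheme", loci = MLST_LOCI, refSeqs = refSeqs,
      registry = stats::setNames(rep(list(stats::setNames(integer(), character())),
                                     7L), MLST_LOCI))
}

#' Build a scheme from a cohort member's own locus sequences
#'
#' Convenience for simulated cohorts: uses one genome's seven housekeeping
#' genes as the locus references.
#'
#' @param genome an \linkS4class{AnnotatedGenome} containing genes named as
#'   the seven MLST loci.
#' @return an \linkS4class{MLSTScheme}.
#' @export
mlstSchemeFromGenome <- function(genome) {
  cds <- cdsSeq(genome)
  missing <- setdiff(MLST_LOCI, names(cds))
  if (length(missing)) stop("genome lacks MLST loci: ",
                            paste(missing, collapse = ", "))
  mlstScheme(cds[MLST_LOCI])
}

setMethod("schemeLoci", "MLSTScheme", function(x) x@loci)
setMethod("schemeRefs", "MLSTScheme", function(x) x@refSeqs)

setMethod("show", "MLSTScheme", function(object) {
  cat("MLSTScheme with loci:", paste(object@loci, collapse = ", "), "\n")
  nreg <- vapply(object@registry, length, integer(1))
  cat("  registered alleles:", paste(sprintf("%s=%d", object@loci, nreg),
                                     collapse = ", "), "\n")
})

#' Extract a locus sequence from a genome by homology
#'
#' Returns the best full-length hit of the locus reference on either strand
#' (reverse-strand hits are reverse-complemented into the reference
#' orientation).  Also serves for in-silico 16S rDNA extraction.
#'
#' @param genome an \linkS4class{AnnotatedGenome} (or contig sequences).
#' @param refSeq locus reference sequence.
#' @param minIdentity minimum percent identity of the hit.
#' @param minCoverage minimum full-length coverage (default 0.95).
#' @return the locus sequence (character), or \code{NA_character_} with a
#'   warning when no hit passes — a per-strain missing locus is reported,
#'   not fatal.
#' @export
extractLocus <- function(genome, refSeq, minIdentity = 90, minCoverage = 0.95) {
  refSeq <- as.character(refSeq)
  if (nchar(refSeq) == 0L) stop("empty locus reference")
  hit <- bestGenomeHit(refSeq, genome)
  if (is.na(hit$score) || hit$identity < minIdentity ||
      hit$coverage < minCoverage) {
    warning("locus not found (best identity ",
            sprintf("%.1f", hit$identity), "%)")
    return(NA_character_)
  }
  g <- if (is(genome, "AnnotatedGenome")) genome else
    annotatedGenome("tmp", if (is.character(genome)) genome else genome,
                    GRanges(gene_id = character(), product = character()))
  hitSequence(g, hit)
}

#' Assign (or register) an allele number for a locus sequence
#'
#' Exact registry match returns the registered number; a novel sequence is
#' registered under the next free integer.  Idempotent.
#'
#' @param scheme an \linkS4class{MLSTScheme}.
#' @param locus locus name.
#' @param sequence allele sequence (character).
#' @param rejectAmbiguous error on non-ACGT characters (default TRUE).
#' @return list with \code{allele} (integer) and the possibly updated
#'   \code{scheme}.
#' @export
assignAllele <- function(scheme, locus, sequence, rejectAmbiguous = TRUE) {
  stopifnot(is(scheme, "MLSTScheme"))
  if (!locus %in% scheme@loci) stop("unknown locus: ", locus)
  sequence <- toupper(as.character(sequence))
  if (rejectAmbiguous && grepl("[^ACGT]", sequence)) {
    stop("allele sequence contains ambiguity characters")
  }
  reg <- scheme@registry[[locus]]
  hit <- match(sequence, names(reg))
  if (!is.na(hit)) return(list(allele = unname(reg[hit]), scheme = scheme))
  allele <- if (length(reg)) max(reg) + 1L else 1L
  reg[sequence] <- allele
  scheme@registry[[locus]] <- reg
  list(allele = allele, scheme = scheme)
}

#' Type strains: extract loci, assign alleles, build allelic profiles
#'
#' @param genomeList named list of \linkS4class{AnnotatedGenome}.
#' @param scheme an \linkS4class{MLSTScheme}.
#' @param minIdentity,minCoverage passed to [extractLocus()].
#' @return list with \code{profiles} (data.frame: strain + seven allele
#'   columns; NA where a locus is missing), \code{scheme} (updated registry)
#'   and \code{missing} (data.frame of strain/locus extraction failures).
#' @export
typeStrains <- function(genomeList, scheme, minIdentity = 90,
                        minCoverage = 0.95) {
  stopifnot(is(scheme, "MLSTScheme"))
  rows <- list()
  missing <- list()
  for (id in names(genomeList)) {
    g <- genomeList[[id]]
    # one seed index per genome: map all seven locus references together
    hits <- mapToGenome(as.character(scheme@refSeqs), g)
    alle <- stats::setNames(rep(NA_integer_, 7L), scheme@loci)
    for (li in seq_along(scheme@loci)) {
      loc <- scheme@loci[li]
      hit <- hits[li, , drop = FALSE]
      if (is.na(hit$score) || hit$identity < minIdentity ||
          hit$coverage < minCoverage) {
        missing[[length(missing) + 1L]] <- data.frame(strain = id, locus = loc)
        next
      }
      a <- assignAllele(scheme, loc, hitSequence(g, hit))
      scheme <- a$scheme
      alle[loc] <- a$allele
    }
    rows[[id]] <- data.frame(strain = id, t(alle), stringsAsFactors = FALSE)
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  list(profiles = profiles,
       scheme = scheme,
       missing = if (length(missing)) do.call(rbind, missing) else
         data.frame(strain = character(), locus = character()))
}

profileMatrix <- function(profiles) {
  if (is.matrix(profiles)) {
    m <- profiles
  } else {
    cols <- intersect(MLST_LOCI, colnames(profiles))
    if (length(cols) != 7L) stop("profiles must contain the seven locus columns")
    m <- as.matrix(profiles[, cols])
    rownames(m) <- profiles$strain
  }
  storage.mode(m) <- "integer"
  if (ncol(m) != 7L) stop("allelic profiles must have 7 loci")
  m
}

#' Assign sequence types to allelic profiles
#'
#' STs are numbered in first-appearance order; strains share an ST iff their
#' seven-integer profiles are identical.
#'
#' @param profiles data.frame with \code{strain} plus the seven locus columns
#'   (or an integer matrix with strain rownames).
#' @return a \code{SequenceTypeTable}: list with \code{strains} (data.frame:
#'   strain, locus columns, ST) and \code{stProfiles} (matrix, one row per
#'   ST).
#' @export
assignSTs <- function(profiles) {
  m <- profileMatrix(profiles)
  if (nrow(m) < 1L) stop("need at least one profile")
  if (anyNA(m)) stop("profiles contain missing alleles; type strains first")
  key <- apply(m, 1L, paste, collapse = "-")
  st <- match(key, unique(key))
  stProfiles <- m[match(unique(key), key), , drop = FALSE]
  rownames(stProfiles) <- seq_len(nrow(stProfiles))
  structure(list(
    strains = data.frame(strain = rownames(m), m, ST = st,
                         row.names = NULL, check.names = FALSE),
    stProfiles = stProfiles), class = "SequenceTypeTable")
}

#' @export
print.SequenceTypeTable <- function(x, ...) {
  cat("SequenceTypeTable:", nrow(x$strains), "strains,",
      nrow(x$stProfiles), "sequence types")
  if (!is.null(x$strains$group)) {
    cat(",", length(unique(x$strains$group)), "groups")
  }
  cat("\n")
  print(utils::head(x$strains, 10L))
  invisible(x)
}

#' Hamming distance between two allelic profiles
#'
#' @param a,b length-7 integer vectors (or single rows of a profile table).
#' @return number of loci at which the profiles differ (0 iff same ST).
#' @export
profileHamming <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != 7L || length(b) != 7L) stop("profiles must have 7 loci")
  sum(a != b)
}

#' Cluster sequence types into groups
#'
#' Single-linkage connected components over profile Hamming distance
#' \code{<= maxDistance}.  Group labels are deterministic, ordered by the
#' smallest member ST.
#'
#' @param stTable a \code{SequenceTypeTable} from [assignSTs()].
#' @param maxDistance linkage threshold in differing loci (default 2, which
#'   reproduces the nine-group partition of the 26-strain reference cohort).
#' @return the table with a \code{group} column added to \code{strains}, plus
#'   \code{stGroups} (integer group per ST).
#' @export
clusterGroups <- function(stTable, maxDistance = 2L) {
  stopifnot(inherits(stTable, "SequenceTypeTable"))
  sp <- stTable$stProfiles
  nst <- nrow(sp)
  comp <- seq_len(nst)
  if (nst > 1L && maxDistance >= 0L) {
    for (i in seq_len(nst - 1L)) {
      for (j in (i + 1L):nst) {
        if (sum(sp[i, ] != sp[j, ]) <= maxDistance) {
          old <- comp[j]; new <- comp[i]
          comp[comp == old] <- new
        }
      }
    }
  }
  # label groups 1..k by smallest member ST
  first <- tapply(seq_len(nst), comp, min)
  stGroups <- match(unname(first[as.character(comp)]), sort(unname(first)))
  stTable$stGroups <- stGroups
  stTable$strains$group <- stGroups[stTable$strains$ST]
  stTable
}

#' Select the presumed ancestor of a strain
#'
#' The wild-type strain in the same MLST group with minimal profile Hamming
#' distance; ties are broken lexicographically (and reported).  A group
#' without any wild-type member yields an explicit no-ancestor result.
#'
#' @param strain strain id.
#' @param stTable grouped \code{SequenceTypeTable} (see [clusterGroups()]).
#' @param wildType named logical vector (or character vector of wild-type
#'   strain ids).
#' @return list with \code{ancestor} (strain id or NA), \code{distance},
#'   \code{tied} (other equally close wild types) and \code{reason}.
#' @export
presumedAncestor <- function(strain, stTable, wildType) {
  stopifnot(inherits(stTable, "SequenceTypeTable"))
  if (is.null(stTable$strains$group)) stop("call clusterGroups() first")
  df <- stTable$strains
  if (!strain %in% df$strain) stop("strain not typed: ", strain)
  if (is.character(wildType)) {
    wildType <- stats::setNames(df$strain %in% wildType, df$strain)
  }
  wt <- names(wildType)[wildType]
  if (length(wt) == 0L) stop("no wild-type strain flagged in cohort")
  me <- df[df$strain == strain, ]
  cand <- df[df$group == me$group & df$strain %in% wt, ]
  if (nrow(cand) == 0L) {
    return(list(ancestor = NA_character_, distance = NA_integer_,
                tied = character(),
                reason = "no wild-type strain in this MLST group"))
  }
  m <- profileMatrix(df)
  d <- apply(m[match(cand$strain, df$strain), , drop = FALSE], 1L,
             function(p) sum(p != m[match(strain, df$strain), ]))
  dmin <- min(d)
  best <- sort(cand$strain[d == dmin])
  list(ancestor = best[1L], distance = as.integer(dmin),
       tied = best[-1L], reason = "ok")
}

#' Reference 26-strain allelic profile table
#'
#' The packaged seven-locus allelic profiles of the 26 C. glutamicum strains
#' (type strain ATCC 13032 and derivatives, the classical "Brevibacterium"
#' isolates, and the industrial amino acid producers), with their published
#' group/ST labels, wild-type flags and recorded parent strains.
#'
#' @return data.frame with columns strain, published_group, published_st,
#'   the seven locus columns, wild_type, recorded_ancestor, description.
#' @export
cglutamicumProfiles <- function() {
  path <- system.file("extdata", "cglutamicum_mlst_profiles.tsv",
                      package = "strainTrace", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
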