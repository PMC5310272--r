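#' Synthetic pan-genome cohort simulator
#'
#' Generates species cohorts with known truth so that every downstream stage
#' (ANI, MLST, pan-genome rarefaction, SNP phylogeny, variant calling) can be
#' tested against a ground-truth channel without downloading genomes.
#'
#' @name simulate-module
NULL

MLST_LOCI <- c("atpA", "dnaE", "dnaK", "fusA", "leuA", "odhA", "rpoB")
MLST_LOCUS_LENGTH <- 450L
DNA_BASES <- c("A", "C", "G", "T")

#' Create a pan-genome simulation model
#'
#' Defaults describe a desk-scale bacterial species cohort: 2,500 gene
#' families (2,000 core including the seven housekeeping MLST loci, 500
#' dispensable), gene lengths 300-1500 nt, and per-branch substitution,
#' indel and gene gain/loss rates small enough that strains stay well within
#' the conspecific ANI band.
#'
#' @param nCore core gene families, present in every strain (>= 7; the seven
#'   MLST loci atpA, dnaE, dnaK, fusA, leuA, odhA, rpoB are always among them).
#' @param nDispensable variably present families.
#' @param geneLengthRange nt bounds for gene lengths; multiples of 3, >= 33.
#' @param gainProb,lossProb per-branch per-family gain/loss probabilities.
#' @param snpRate substitutions per site per branch.
#' @param indelRate in-frame (one-codon) indels per gene per branch.
#' @param seed integer seed; all randomness in [simulateCohort()] flows from it.
#' @return a \linkS4class{PanGenomeModel}.
#' @export
panGenomeModel <- function(nCore = 2000L, nDispensable = 500L,
                           geneLengthRange = c(300L, 1500L),
                           gainProb = 0.02, lossProb = 0.08,
                           snpRate = 0.002, indelRate = 0.02, seed = 1L) {
  new("PanGenomeModel",
      nCore = as.integer(nCore), nDispensable = as.integer(nDispensable),
      geneLengthRange = as.integer(geneLengthRange),
      gainProb = gainProb, lossProb = lossProb,
      snpRate = snpRate, indelRate = indelRate, seed = as.integer(seed))
}

randomCodingSeq <- function(L) {
  ncod <- L %/% 3L - 2L
  codons <- apply(matrix(sample(DNA_BASES, 3L * 64L, replace = TRUE), ncol = 3L),
                  1L, paste, collapse = "")
  nonstop <- setdiff(unique(codons), STOP_CODONS)
  # ensure a pool even if the random draw was unlucky
  if (length(nonstop) < 4L) nonstop <- c("GCT", "GAA", "AAA", "TTG")
  paste0("ATG", paste(sample(nonstop, ncod, replace = TRUE), collapse = ""), "TAA")
}

randomNonStopCodon <- function() {
  repeat {
    codon <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
    if (!(codon %in% STOP_CODONS)) return(codon)
  }
}

# Substitutions inside a CDS: interior positions only, never creating an
# in-frame stop (the pipeline expects translatable wild-type genes).
mutateCDS <- function(s, n) {
  L <- nchar(s)
  if (n <= 0L || L < 9L) return(s)
  v <- strsplit(s, "")[[1]]
  pos <- sample(4:(L - 3L), min(n, L - 6L))
  for (p in pos) {
    alts <- sample(setdiff(DNA_BASES, v[p]))
    cstart <- ((p - 1L) %/% 3L) * 3L + 1L
    for (a in alts) {
      old <- v[p]
      v[p] <- a
      if (!(paste(v[cstart:(cstart + 2L)], collapse = "") %in% STOP_CODONS)) break
      v[p] <- old
    }
  }
  paste(v, collapse = "")
}

mutateFree <- function(s, n) {
  L <- nchar(s)
  if (n <= 0L || L == 0L) return(s)
  v <- strsplit(s, "")[[1]]
  pos <- sample.int(L, min(n, L))
  for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
  paste(v, collapse = "")
}

# One-codon in-frame indels at interior codons.
mutateIndels <- function(s, n, minLen) {
  for (i in seq_len(n)) {
    ncod <- nchar(s) %/% 3L
    if (ncod < 5L) break
    ci <- sample(2:(ncod - 1L), 1L)
    at <- 3L * (ci - 1L) + 1L
    if (stats::runif(1) < 0.5 && nchar(s) - 3L >= minLen) {
      s <- paste0(substr(s, 1L, at - 1L), substr(s, at + 3L, nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, at - 1L), randomNonStopCodon(),
                  substr(s, at, nchar(s)))
    }
  }
  s
}

#' Simulate a species cohort with known truth
#'
#' Gene content evolves along a random coalescent genealogy: every branch
#' applies per-family gain/loss, per-site substitutions (uniform over the
#' three alternative bases, never creating an in-frame stop) and one-codon
#' in-frame indels.  Genes are non-overlapping, on random strands, separated
#' by >= 200 nt intergenic spacers so that 100-nt upstream windows never
#' collide with coding sequence.  The seven MLST housekeeping loci are
#' fixed-length (450 nt) core genes whose allele variants arise from the same
#' substitution process.
#'
#' @param model a \linkS4class{PanGenomeModel}.
#' @param nStrains number of strains (>= 2).
#' @return a \linkS4class{StrainCohort} holding one
#'   \linkS4class{AnnotatedGenome} per strain plus the truth channel (tree,
#'   presence/absence matrix, allelic profiles).
#' @examples
#' cohort <- simulateCohort(panGenomeModel(nCore = 10, nDispensable = 4,
#'                                         seed = 42), nStrains = 3)
#' truePAMatrix(cohort)[1:5, ]
#' @export
simulateCohort <- function(model, nStrains = 8L) {
  stopifnot(is(model, "PanGenomeModel"))
  validObject(model)
  nStrains <- as.integer(nStrains)
  if (is.na(nStrains) || nStrains < 2L) stop("nStrains must be >= 2")
  if (model@nCore < 7L) {
    stop("nCore must be >= 7 (the seven MLST loci are core genes)")
  }
  set.seed(model@seed)
  strains <- sprintf("S%02d", seq_len(nStrains))

  coreFams <- c(MLST_LOCI, if (model@nCore > 7L)
    sprintf("core%04d", seq_len(model@nCore - 7L)))
  dispFams <- if (model@nDispensable > 0L)
    sprintf("disp%04d", seq_len(model@nDispensable)) else character()
  fams <- c(coreFams, dispFams)
  nFam <- length(fams)

  lens <- stats::setNames(integer(nFam), fams)
  lens[MLST_LOCI] <- MLST_LOCUS_LENGTH
  other <- setdiff(fams, MLST_LOCI)
  pool <- seq(model@geneLengthRange[1L], model@geneLengthRange[2L], by = 3L)
  lens[other] <- sample(pool, length(other), replace = TRUE)

  rootSeq <- stats::setNames(vapply(lens, randomCodingSeq, character(1)), fams)
  ord <- sample(fams)
  strands <- stats::setNames(sample(c("+", "-"), nFam, replace = TRUE), ord)
  spacerLens <- sample(201:300, nFam + 1L, replace = TRUE)
  spacers <- vapply(spacerLens, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1))

  tree <- ape::rcoal(nStrains, tip.label = strains)
  nnode <- nStrains + tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- nStrains + 1L

  rootState <- list(seq = rootSeq,
                    present = stats::setNames(rep(TRUE, nFam), fams),
                    spacers = spacers)
  leafStates <- vector("list", nStrains)

  evolveBranch <- function(st) {
    if (length(dispFams)) {
      pres <- st$present[dispFams]
      lost <- pres & stats::runif(length(pres)) < model@lossProb
      gained <- !pres & stats::runif(length(pres)) < model@gainProb
      st$present[dispFams][lost] <- FALSE
      st$present[dispFams][gained] <- TRUE
    }
    for (f in fams) {
      s <- st$seq[[f]]
      n <- stats::rbinom(1L, max(nchar(s) - 6L, 0L), model@snpRate)
      if (n > 0L) s <- mutateCDS(s, n)
      nid <- stats::rpois(1L, model@indelRate)
      if (nid > 0L && !(f %in% MLST_LOCI)) {
        s <- mutateIndels(s, nid, max(33L, model@geneLengthRange[1L] - 30L))
      }
      st$seq[[f]] <- s
    }
    for (i in seq_along(st$spacers)) {
      n <- stats::rbinom(1L, nchar(st$spacers[i]), model@snpRate)
      if (n > 0L) st$spacers[i] <- mutateFree(st$spacers[i], n)
    }
    st
  }

  recurse <- function(node, st) {
    if (node <= nStrains) {
      leafStates[[node]] <<- st
      return(invisible())
    }
    for (ch in sort(kids[[as.character(node)]])) {
      recurse(ch, evolveBranch(st))
    }
  }
  recurse(root, rootState)

  # tip numbers carry labels in rcoal's own order; index states by strain
  tipIdx <- match(strains, tree$tip.label)
  pa <- matrix(FALSE, nFam, nStrains, dimnames = list(fams, strains))
  genomesList <- stats::setNames(vector("list", nStrains), strains)
  for (i in seq_len(nStrains)) {
    st <- leafStates[[tipIdx[i]]]
    pa[, i] <- st$present
    genomesList[[i]] <- assembleGenome(strains[i], ord, strands, st, spacers = st$spacers)
  }

  profiles <- matrix(NA_integer_, nStrains, 7L,
                     dimnames = list(strains, MLST_LOCI))
  for (loc in MLST_LOCI) {
    seen <- character()
    for (i in seq_len(nStrains)) {
      s <- leafStates[[tipIdx[i]]]$seq[[loc]]
      hit <- match(s, seen)
      if (is.na(hit)) {
        seen <- c(seen, s)
        hit <- length(seen)
      }
      profiles[i, loc] <- hit
    }
  }

  new("StrainCohort", genomes = genomesList, tree = tree, paMatrix = pa,
      profiles = profiles, variants = list(), model = model)
}

geneProduct <- function(fam) {
  ifelse(fam %in% MLST_LOCI, paste("housekeeping gene", fam),
         ifelse(startsWith(fam, "disp"), paste("dispensable protein", fam),
                paste("conserved protein", fam)))
}

assembleGenome <- function(strain, ord, strands, st, spacers) {
  parts <- character()
  starts <- integer()
  ends <- integer()
  strv <- character()
  gids <- character()
  pos <- 0L
  slot <- 1L
  for (f in ord) {
    parts <- c(parts, spacers[slot])
    pos <- pos + nchar(spacers[slot])
    slot <- slot + 1L
    if (!st$present[[f]]) next
    s <- st$seq[[f]]
    oriented <- if (strands[[f]] == "-") cpp_revcomp(s) else s
    parts <- c(parts, oriented)
    starts <- c(starts, pos + 1L)
    ends <- c(ends, pos + nchar(s))
    strv <- c(strv, strands[[f]])
    gids <- c(gids, f)
    pos <- pos + nchar(s)
  }
  parts <- c(parts, spacers[slot])
  contig <- paste(parts, collapse = "")
  ft <- GRanges("chr", IRanges::IRanges(starts, ends), strand = strv,
                gene_id = gids, product = geneProduct(gids))
  annotatedGenome(strain, stats::setNames(DNAStringSet(contig), "chr"), ft)
}

setMethod("genomes", "StrainCohort", function(x) x@genomes)
setMethod("trueTree", "StrainCohort", function(x) x@tree)
setMethod("truePAMatrix", "StrainCohort", function(x) x@paMatrix)
setMethod("trueProfiles", "StrainCohort", function(x) x@profiles)
setMethod("trueVariants", "StrainCohort", function(x) x@variants)

setMethod("show", "StrainCohort", function(object) {
  cat("StrainCohort:", length(object@genomes), "strains,",
      nrow(object@paMatrix), "gene families",
      sprintf("(%d core)\n", sum(rowSums(!object@paMatrix) == 0L)))
  if (length(object@variants)) {
    cat("  derived producer strains:",
        paste(names(object@variants), collapse = ", "), "\n")
  }
})

#' Specify a variant to plant in a genome
#'
#' @param gene_id target gene.
#' @param kind one of \code{missense}, \code{synonymous}, \code{stop_gained},
#'   \code{inframe_deletion}, \code{inframe_insertion}, \code{frameshift},
#'   \code{upstream}.
#' @param at 1-based codon index for coding kinds; negative nt offset from
#'   the start codon for \code{upstream} (e.g. \code{-9}).
#' @param payload kind-specific: replacement residue (one- or three-letter)
#'   for \code{missense}; codon count for \code{inframe_deletion}; inserted
#'   residue string for \code{inframe_insertion}; signed nt count for
#'   \code{frameshift} (default \code{-1}, a 1-nt deletion); replacement base
#'   or \code{"del"} for \code{upstream}.
#' @return a variant spec (list) consumed by [plantVariants()].
#' @export
variantSpec <- function(gene_id, kind, at, payload = NA) {
  kinds <- c("missense", "synonymous", "stop_gained", "inframe_deletion",
             "inframe_insertion", "frameshift", "upstream")
  if (!kind %in% kinds) stop("unknown variant kind: ", kind)
  structure(list(gene_id = gene_id, kind = kind, at = as.integer(at),
                 payload = payload), class = "variantSpec")
}

AA1 <- stats::setNames(names(Biostrings::AMINO_ACID_CODE),
                       Biostrings::AMINO_ACID_CODE)

normalizeResidue <- function(x) {
  x <- as.character(x)
  if (nchar(x) == 1L) return(toupper(x))
  r <- AA1[[paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))]]
  if (is.null(r)) stop("unknown residue: ", x)
  r
}

# Minimal-substitution codon encoding `aa`, relative to `codon`.
closestCodon <- function(codon, aa) {
  gc11 <- Biostrings::getGeneticCode("11")
  cands <- names(gc11)[gc11 == aa]
  if (length(cands) == 0L) stop("no codon encodes ", aa)
  d <- vapply(cands, function(cc)
    sum(strsplit(cc, "")[[1]] != strsplit(codon, "")[[1]]), integer(1))
  cands[order(d, cands)][1L]
}

# Build the nt-level events (gene-local coding coordinates) for one spec.
specToEvents <- function(spec, ancSeq, flank, upstreamWindow) {
  ncod <- nchar(ancSeq) %/% 3L
  chkCodon <- function(ci, lastOK = ncod - 1L) {
    if (ci < 2L || ci > lastOK) {
      stop("codon index out of range for gene ", spec$gene_id, ": ", ci)
    }
  }
  k <- spec$kind
  if (k == "upstream") {
    off <- spec$at
    if (off >= 0L || -off > upstreamWindow) {
      stop("upstream offset must be in [-", upstreamWindow, ", -1]")
    }
    fpos <- upstreamWindow + off + 1L
    ref <- substr(flank, fpos, fpos)
    if (identical(spec$payload, "del")) {
      return(list(region = "upstream",
                  events = list(list(type = "del", pos = fpos, ref = ref, alt = ""))))
    }
    alt <- if (is.na(spec$payload)) {
      DNA_BASES[match(ref, DNA_BASES) %% 4L + 1L]
    } else toupper(as.character(spec$payload))
    if (alt == ref) stop("upstream substitution equals the reference base")
    return(list(region = "upstream",
                events = list(list(type = "sub", pos = fpos, ref = ref, alt = alt))))
  }
  ci <- spec$at
  cstart <- 3L * (ci - 1L) + 1L
  codon <- substr(ancSeq, cstart, cstart + 2L)
  if (k %in% c("missense", "synonymous", "stop_gained")) {
    chkCodon(ci)
    target <- switch(k,
      missense = {
        aa <- normalizeResidue(spec$payload)
        if (aa == codon2aa(codon)) stop("missense payload equals ancestor residue")
        closestCodon(codon, aa)
      },
      synonymous = {
        cands <- setdiff(names(Biostrings::getGeneticCode("11"))[
          Biostrings::getGeneticCode("11") == codon2aa(codon)], codon)
        if (length(cands) == 0L) {
          stop("no synonymous change possible at ", spec$gene_id, " codon ", ci)
        }
        d <- vapply(cands, function(cc)
          sum(strsplit(cc, "")[[1]] != strsplit(codon, "")[[1]]), integer(1))
        cands[order(d, cands)][1L]
      },
      stop_gained = closestCodon(codon, "*"))
    difpos <- which(strsplit(target, "")[[1]] != strsplit(codon, "")[[1]])
    ev <- lapply(difpos, function(o)
      list(type = "sub", pos = cstart + o - 1L,
           ref = substr(codon, o, o), alt = substr(target, o, o)))
    return(list(region = "cds", events = ev))
  }
  if (k == "inframe_deletion") {
    nc <- if (is.na(spec$payload)) 1L else as.integer(spec$payload)
    chkCodon(ci, ncod - nc)
    ref <- substr(ancSeq, cstart, cstart + 3L * nc - 1L)
    return(list(region = "cds",
                events = list(list(type = "del", pos = cstart, ref = ref, alt = ""))))
  }
  if (k == "inframe_insertion") {
    chkCodon(ci)
    res <- toupper(as.character(spec$payload))
    res1 <- if (nchar(res) %% 3L == 0L && nchar(res) > 1L &&
                all(strsplit(res, "")[[1]] %in% LETTERS)) res else res
    residues <- vapply(strsplit(res1, "")[[1]], normalizeResidue, character(1))
    ins <- paste(vapply(residues, function(a) closestCodon("NNN", a), character(1)),
                 collapse = "")
    # insert after codon ci (before first base of codon ci + 1)
    return(list(region = "cds",
                events = list(list(type = "ins", pos = cstart + 3L, ref = "",
                                   alt = ins))))
  }
  if (k == "frameshift") {
    chkCodon(ci)
    nnt <- if (is.na(spec$payload)) -1L else as.integer(spec$payload)
    if (nnt %% 3L == 0L || nnt == 0L) stop("frameshift payload must not be a multiple of 3")
    if (nnt < 0L) {
      ref <- substr(ancSeq, cstart, cstart - nnt - 1L)
      return(list(region = "cds",
                  events = list(list(type = "del", pos = cstart, ref = ref, alt = ""))))
    }
    return(list(region = "cds",
                events = list(list(type = "ins", pos = cstart, ref = "",
                                   alt = paste(rep("A", nnt), collapse = "")))))
  }
  stop("unhandled kind ", k)
}

#' Plant variants into an annotated genome
#'
#' Applies a list of [variantSpec()] edits (point mutations, in-frame indels,
#' frameshifts, nonsense and upstream changes) to a genome and returns both
#' the edited genome and the expected variant calls — the calls the variant
#' caller must reproduce, with byte-identical HGVS-style notation.
#'
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @param specs list of [variantSpec()] objects; edits must not overlap.
#' @param upstreamWindow nt window before the start codon within which
#'   upstream variants are defined (default 100).
#' @return list with elements \code{genome} (edited) and \code{expected}
#'   (data.frame of expected calls: gene, effect, nt_change,
#'   protein_notation, upstream_offset).
#' @export
plantVariants <- function(genome, specs, upstreamWindow = 100L) {
  stopifnot(is(genome, "AnnotatedGenome"))
  if (length(specs) == 0L) {
    return(list(genome = genome,
                expected = emptyVariantTable()))
  }
  if (inherits(specs, "variantSpec")) specs <- list(specs)
  ft <- genome@features
  gids <- ft$gene_id
  cds <- cdsSeq(genome)
  expected <- list()
  contigEvents <- list()

  for (spec in specs) {
    gi <- match(spec$gene_id, gids)
    if (is.na(gi)) stop("no such gene: ", spec$gene_id)
    ancSeq <- as.character(cds[[gi]])
    flank <- upstreamFlank(genome, gi, upstreamWindow)
    pe <- specToEvents(spec, ancSeq, flank, upstreamWindow)
    allsub <- all(vapply(pe$events, function(e) e$type == "sub", logical(1)))
    if (pe$region == "cds" && allsub && length(pe$events) >= 1L) {
      # substitutions planted in one codon are annotated jointly
      cls <- classifyCodonSubs(ancSeq,
                               vapply(pe$events, `[[`, integer(1), "pos"),
                               vapply(pe$events, `[[`, character(1), "alt"))
      cls$upstream_offset <- NA_integer_
      expected[[length(expected) + 1L]] <- data.frame(
        gene = spec$gene_id, effect = cls$effect, nt_change = cls$nt_change,
        protein_notation = cls$protein_notation,
        upstream_offset = cls$upstream_offset, stringsAsFactors = FALSE)
      for (ev in pe$events) {
        contigEvents[[length(contigEvents) + 1L]] <-
          toContigEvent(ev, pe$region, ft[gi], upstreamWindow)
      }
      next
    }
    for (ev in pe$events) {
      if (pe$region == "cds") {
        cls <- classifyCDSEvent(ancSeq, ev)
        cls$upstream_offset <- NA_integer_
      } else {
        cls <- classifyUpstreamEvent(flank, ev, upstreamWindow)
      }
      expected[[length(expected) + 1L]] <- data.frame(
        gene = spec$gene_id, effect = cls$effect, nt_change = cls$nt_change,
        protein_notation = cls$protein_notation,
        upstream_offset = as.integer(cls$upstream_offset),
        stringsAsFactors = FALSE)
      contigEvents[[length(contigEvents) + 1L]] <-
        toContigEvent(ev, pe$region, ft[gi], upstreamWindow)
    }
  }
  expected <- do.call(rbind, expected)
  rownames(expected) <- NULL

  checkNoOverlap(contigEvents)
  genome2 <- applyContigEvents(genome, contigEvents)
  list(genome = genome2, expected = expected)
}

emptyVariantTable <- function() {
  data.frame(gene = character(), effect = character(), nt_change = character(),
             protein_notation = character(), upstream_offset = integer(),
             stringsAsFactors = FALSE)
}

upstreamFlank <- function(genome, gi, window) {
  ft <- genome@features[gi]
  ctg <- genome@contigs[[as.character(GenomicRanges::seqnames(ft))]]
  if (as.character(GenomicRanges::strand(ft)) == "+") {
    s <- GenomicRanges::start(ft)
    if (s - window < 1L) stop("upstream window extends past contig start")
    as.character(Biostrings::subseq(ctg, s - window, s - 1L))
  } else {
    e <- GenomicRanges::end(ft)
    if (e + window > length(ctg)) stop("upstream window extends past contig end")
    cpp_revcomp(as.character(Biostrings::subseq(ctg, e + 1L, e + window)))
  }
}

complementBase <- function(b) chartr("ACGT", "TGCA", b)

# Convert a gene-local (coding orientation) event to contig coordinates.
toContigEvent <- function(ev, region, feat, window) {
  plus <- as.character(GenomicRanges::strand(feat)) == "+"
  s <- GenomicRanges::start(feat)
  e <- GenomicRanges::end(feat)
  contig <- as.character(GenomicRanges::seqnames(feat))
  locpos <- ev$pos
  if (region == "upstream") {
    # flank position f (1..window): + strand contig pos = s - window + f - 1
    if (ev$type == "sub") {
      cp <- if (plus) s - window + locpos - 1L else e + window - locpos + 1L
      alt <- if (plus) ev$alt else complementBase(ev$alt)
      return(list(type = "sub", contig = contig, pos = cp, len = 1L, alt = alt,
                  delta = 0L))
    }
    if (ev$type == "del") {
      L <- nchar(ev$ref)
      cp <- if (plus) s - window + locpos - 1L else e + window - (locpos + L - 1L) + 1L
      return(list(type = "del", contig = contig, pos = cp, len = L, alt = "",
                  delta = -L))
    }
    L <- nchar(ev$alt)
    cp <- if (plus) s - window + locpos - 1L else e + window - locpos + 2L
    alt <- if (plus) ev$alt else cpp_revcomp(ev$alt)
    return(list(type = "ins", contig = contig, pos = cp, len = 0L, alt = alt,
                delta = L))
  }
  if (ev$type == "sub") {
    cp <- if (plus) s + locpos - 1L else e - locpos + 1L
    alt <- if (plus) ev$alt else complementBase(ev$alt)
    return(list(type = "sub", contig = contig, pos = cp, len = 1L, alt = alt,
                delta = 0L))
  }
  if (ev$type == "del") {
    L <- nchar(ev$ref)
    cp <- if (plus) s + locpos - 1L else e - (locpos + L - 1L) + 1L
    return(list(type = "del", contig = contig, pos = cp, len = L, alt = "",
                delta = -L))
  }
  L <- nchar(ev$alt)
  cp <- if (plus) s + locpos - 1L else e - locpos + 2L
  alt <- if (plus) ev$alt else cpp_revcomp(ev$alt)
  list(type = "ins", contig = contig, pos = cp, len = 0L, alt = alt, delta = L)
}

checkNoOverlap <- function(events) {
  if (length(events) < 2L) return(invisible())
  spans <- do.call(rbind, lapply(events, function(ev)
    data.frame(contig = ev$contig, from = ev$pos,
               to = ev$pos + max(ev$len - 1L, 0L))))
  spans <- spans[order(spans$contig, spans$from), ]
  for (i in seq_len(nrow(spans) - 1L)) {
    if (spans$contig[i] == spans$contig[i + 1L] &&
        spans$to[i] >= spans$from[i + 1L]) {
      stop("planted edits overlap")
    }
  }
  invisible()
}

applyContigEvents <- function(genome, events) {
  ctgs <- as.character(genome@contigs)
  ft <- genome@features
  for (ctg in unique(vapply(events, `[[`, character(1), "contig"))) {
    evs <- Filter(function(e) e$contig == ctg, events)
    ord <- order(vapply(evs, `[[`, integer(1), "pos"), decreasing = TRUE)
    s <- ctgs[[ctg]]
    for (ev in evs[ord]) {
      s <- switch(ev$type,
        sub = { substr(s, ev$pos, ev$pos) <- ev$alt; s },
        del = paste0(substr(s, 1L, ev$pos - 1L),
                     substr(s, ev$pos + ev$len, nchar(s))),
        ins = paste0(substr(s, 1L, ev$pos - 1L), ev$alt,
                     substr(s, ev$pos, nchar(s))))
    }
    ctgs[[ctg]] <- s
    # shift feature coordinates past indels
    sel <- as.character(GenomicRanges::seqnames(ft)) == ctg
    if (any(sel)) {
      starts <- GenomicRanges::start(ft)[sel]
      ends <- GenomicRanges::end(ft)[sel]
      for (ev in evs) {
        if (ev$delta == 0L) next
        starts <- starts + ifelse(ev$pos < starts, ev$delta, 0L)
        ends <- ends + ifelse(ev$pos <= ends, ev$delta, 0L)
      }
      ft <- c(ft[!sel], GRanges(ctg, IRanges::IRanges(starts, ends),
                                strand = GenomicRanges::strand(ft)[sel],
                                gene_id = ft$gene_id[sel],
                                product = ft$product[sel]))
      ft <- ft[order(match(ft$gene_id, genome@features$gene_id))]
    }
  }
  annotatedGenome(genome@strainID, DNAStringSet(ctgs), ft)
}

#' Derive a producer strain from a cohort member
#'
#' Plants the given variant specs into the parent genome and adds the result
#' to the cohort as a new strain; the expected calls are recorded in the
#' cohort's truth channel (with the parent as reference).
#'
#' @param cohort a \linkS4class{StrainCohort}.
#' @param parent id of the strain to derive from.
#' @param id id of the new strain.
#' @param specs list of [variantSpec()] objects.
#' @param upstreamWindow see [plantVariants()].
#' @return the extended cohort.
#' @export
deriveStrain <- function(cohort, parent, id, specs, upstreamWindow = 100L) {
  stopifnot(is(cohort, "StrainCohort"))
  if (!parent %in% names(cohort@genomes)) stop("no such parent strain: ", parent)
  if (id %in% names(cohort@genomes)) stop("strain id already used: ", id)
  res <- plantVariants(cohort@genomes[[parent]], specs, upstreamWindow)
  g <- res$genome
  g@strainID <- id
  cohort@genomes[[id]] <- g
  pa <- cbind(cohort@paMatrix, cohort@paMatrix[, parent])
  colnames(pa)[ncol(pa)] <- id
  cohort@paMatrix <- pa
  prof <- rbind(cohort@profiles, cohort@profiles[parent, ])
  rownames(prof)[nrow(prof)] <- id
  cohort@profiles <- prof
  tv <- res$expected
  attr(tv, "parent") <- parent
  cohort@variants[[id]] <- tv
  validObject(cohort)
  cohort
}

#' Write a cohort to disk
#'
#' Emits per-strain FASTA + GFF3, the truth tables as TSV (presence/absence
#' matrix, allelic profiles, strain table with parent attribution, planted
#' variants) and the genealogy as Newick.  Everything round-trips through
#' [readGenome()] losslessly.
#'
#' @param cohort a \linkS4class{StrainCohort}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
emitCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "StrainCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  written <- character()
  for (id in names(cohort@genomes)) {
    fa <- file.path(dir, paste0(id, ".fasta"))
    gf <- file.path(dir, paste0(id, ".gff3"))
    writeGenome(cohort@genomes[[id]], fa, gf)
    written <- c(written, fa, gf)
  }
  pa <- cohort@paMatrix
  paPath <- file.path(dir, "truth_pa_matrix.tsv")
  utils::write.table(data.frame(family = rownames(pa), pa + 0L,
                                check.names = FALSE),
                     paPath, sep = "\t", quote = FALSE, row.names = FALSE)
  profPath <- file.path(dir, "truth_profiles.tsv")
  utils::write.table(data.frame(strain = rownames(cohort@profiles),
                                cohort@profiles, check.names = FALSE),
                     profPath, sep = "\t", quote = FALSE, row.names = FALSE)
  strainPath <- file.path(dir, "strains.tsv")
  parents <- vapply(names(cohort@genomes), function(id) {
    v <- cohort@variants[[id]]
    if (is.null(v)) NA_character_ else attr(v, "parent")
  }, character(1))
  utils::write.table(data.frame(strain = names(cohort@genomes),
                                parent = parents,
                                wild_type = is.na(parents)),
                     strainPath, sep = "\t", quote = FALSE, row.names = FALSE)
  treePath <- file.path(dir, "truth_tree.nwk")
  ape::write.tree(cohort@tree, treePath)
  written <- c(written, paPath, profPath, strainPath, treePath)
  if (length(cohort@variants)) {
    tv <- do.call(rbind, lapply(names(cohort@variants), function(id) {
      cbind(strain = id, parent = attr(cohort@variants[[id]], "parent"),
            cohort@variants[[id]])
    }))
    tvPath <- file.path(dir, "truth_variants.tsv")
    utils::write.table(tv, tvPath, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tvPath)
  }
  invisible(written)
}

#' Read back a cohort directory written by [emitCohort()]
#'
#' @param dir directory produced by [emitCohort()].
#' @return named list of \linkS4class{AnnotatedGenome} plus the strain table
#'   (as attribute \code{strains}).
#' @export
readCohortDir <- function(dir) {
  st <- utils::read.delim(file.path(dir, "strains.tsv"))
  gl <- stats::setNames(lapply(st$strain, function(id) {
    readGenome(file.path(dir, paste0(id, ".fasta")),
               file.path(dir, paste0(id, ".gff3")), strainID = id)
  }), st$strain)
  attr(gl, "strains") <- st
  gl
}
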