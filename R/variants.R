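#' Ancestor-referenced variant calling and effect annotation
#'
#' Pairs the genes of a derived strain with its (presumed) ancestor by
#' two-strain ortholog clustering, aligns each single-copy shared pair
#' globally, and annotates every nucleotide difference with an HGVS-style
#' protein consequence (missense, synonymous, stop gained/lost, in-frame
#' indel, frameshift) or as an upstream / intergenic change.
#'
#' @name variants-module
NULL

#' Pair the genes of an ancestor and a derived strain
#'
#' Two-strain ortholog clustering at the nucleotide level (so that genes
#' with planted nonsense or frameshift changes still pair by DNA
#' similarity); clusters with exactly one gene in each strain become
#' alignment pairs, the rest are reported as presence/absence differences.
#'
#' @param ancestor,derived \linkS4class{AnnotatedGenome}.
#' @param minIdentity,minCoverage DNA-level pairing thresholds.
#' @return a \code{GenePairs}: list with \code{pairs} (data.frame: cluster,
#'   anc_gene, der_gene), \code{anc_only}, \code{der_only}, \code{multi}
#'   (cluster ids with copy-number differences) and the two genomes.
#' @export
pairGenes <- function(ancestor, derived, minIdentity = 70,
                      minCoverage = 0.8) {
  ancCds <- cdsSeq(ancestor)
  derCds <- cdsSeq(derived)
  seqs <- c(as.character(ancCds), as.character(derCds))
  side <- rep(c("anc", "der"), c(length(ancCds), length(derCds)))
  gene <- c(names(ancCds), names(derCds))
  memb <- if (length(seqs)) {
    clusterBySimilarity(seqs, minIdentity, minCoverage, protein = FALSE)
  } else integer()
  pairs <- list(); anc_only <- character(); der_only <- character()
  multi <- character()
  for (cl in unique(memb)) {
    sel <- memb == cl
    a <- gene[sel & side == "anc"]
    d <- gene[sel & side == "der"]
    if (length(a) == 1L && length(d) == 1L) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        cluster = sprintf("P%05d", length(pairs) + 1L),
        anc_gene = a, der_gene = d, stringsAsFactors = FALSE)
    } else if (length(d) == 0L) {
      anc_only <- c(anc_only, a)
    } else if (length(a) == 0L) {
      der_only <- c(der_only, d)
    } else {
      multi <- c(multi, paste(c(a, d), collapse = ","))
    }
  }
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(cluster = character(), anc_gene = character(),
                 der_gene = character()),
    anc_only = anc_only, der_only = der_only, multi = multi,
    ancestor = ancestor, derived = derived), class = "GenePairs")
}

# Parse a global alignment (ancestor vs derived) into nt-level events in
# ancestor-local coordinates; adjacent gap columns merge into single indels.
alignmentEvents <- function(aAln, bAln) {
  a <- strsplit(aAln, "")[[1L]]
  b <- strsplit(bAln, "")[[1L]]
  events <- list()
  apos <- 0L
  i <- 1L
  n <- length(a)
  while (i <= n) {
    if (a[i] != "-" && b[i] != "-") {
      apos <- apos + 1L
      if (a[i] != b[i]) {
        events[[length(events) + 1L]] <-
          list(type = "sub", pos = apos, ref = a[i], alt = b[i])
      }
      i <- i + 1L
    } else if (b[i] == "-") {        # deletion in derived
      j <- i
      while (j <= n && b[j] == "-") j <- j + 1L
      events[[length(events) + 1L]] <-
        list(type = "del", pos = apos + 1L,
             ref = paste(a[i:(j - 1L)], collapse = ""), alt = "")
      apos <- apos + (j - i)
      i <- j
    } else {                          # insertion in derived
      j <- i
      while (j <= n && a[j] == "-") j <- j + 1L
      events[[length(events) + 1L]] <-
        list(type = "ins", pos = apos + 1L, ref = "",
             alt = paste(b[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  events
}

# Classify CDS events of one gene pair; substitutions within one codon are
# annotated jointly.
classifyGeneEvents <- function(ancSeq, events, gene) {
  subs <- Filter(function(e) e$type == "sub", events)
  indels <- Filter(function(e) e$type != "sub", events)
  rows <- list()
  if (length(subs)) {
    codon <- vapply(subs, function(e) (e$pos - 1L) %/% 3L + 1L, integer(1))
    for (ci in unique(codon)) {
      grp <- subs[codon == ci]
      cls <- classifyCodonSubs(ancSeq,
                               vapply(grp, `[[`, integer(1), "pos"),
                               vapply(grp, `[[`, character(1), "alt"))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, effect = cls$effect, nt_change = cls$nt_change,
        protein_notation = cls$protein_notation,
        upstream_offset = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  for (ev in indels) {
    cls <- classifyCDSEvent(ancSeq, ev)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, effect = cls$effect, nt_change = cls$nt_change,
      protein_notation = cls$protein_notation,
      upstream_offset = NA_integer_, stringsAsFactors = FALSE)
  }
  rows
}

#' Call variants for all paired genes of an ancestor/derived pair
#'
#' @param genePairs a \code{GenePairs} from [pairGenes()].
#' @param upstreamWindow nt window before each start codon screened for
#'   upstream variants (default 100).
#' @return data.frame of variant calls: gene, cluster, effect, nt_change,
#'   protein_notation, upstream_offset.
#' @export
callVariants <- function(genePairs, upstreamWindow = 100L) {
  stopifnot(inherits(genePairs, "GenePairs"))
  anc <- genePairs$ancestor
  der <- genePairs$derived
  ancCds <- cdsSeq(anc)
  derCds <- cdsSeq(der)
  ancIdx <- stats::setNames(seq_along(anc@features), anc@features$gene_id)
  derIdx <- stats::setNames(seq_along(der@features), der@features$gene_id)
  rows <- list()
  for (r in seq_len(nrow(genePairs$pairs))) {
    p <- genePairs$pairs[r, ]
    ancSeq <- as.character(ancCds[[p$anc_gene]])
    derSeq <- as.character(derCds[[p$der_gene]])
    if (ancSeq != derSeq) {
      aln <- pairAlign(ancSeq, derSeq,
                       bandPad = abs(nchar(ancSeq) - nchar(derSeq)) + 32L)
      evs <- alignmentEvents(aln$a, aln$b)
      for (row in classifyGeneEvents(ancSeq, evs, p$anc_gene)) {
        row$cluster <- p$cluster
        rows[[length(rows) + 1L]] <- row
      }
    }
    ancFlank <- tryCatch(upstreamFlank(anc, unname(ancIdx[p$anc_gene]),
                                       upstreamWindow),
                         error = function(e) NULL)
    derFlank <- tryCatch(upstreamFlank(der, unname(derIdx[p$der_gene]),
                                       upstreamWindow),
                         error = function(e) NULL)
    if (!is.null(ancFlank) && !is.null(derFlank) && ancFlank != derFlank) {
      aln <- pairAlign(ancFlank, derFlank,
                       bandPad = abs(nchar(ancFlank) - nchar(derFlank)) + 16L)
      for (ev in alignmentEvents(aln$a, aln$b)) {
        cls <- classifyUpstreamEvent(ancFlank, ev, upstreamWindow)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = p$anc_gene, effect = cls$effect, nt_change = cls$nt_change,
          protein_notation = cls$protein_notation,
          upstream_offset = as.integer(cls$upstream_offset),
          cluster = p$cluster, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out[, c("gene", "cluster", "effect", "nt_change", "protein_notation",
            "upstream_offset")]
  } else {
    emptyCallTable()
  }
}

emptyCallTable <- function() {
  data.frame(gene = character(), cluster = character(), effect = character(),
             nt_change = character(), protein_notation = character(),
             upstream_offset = integer(), stringsAsFactors = FALSE)
}

#' Compare a derived strain against its ancestor
#'
#' Full genome comparison: per-gene CDS and upstream-window calls for every
#' paired gene, plus substitutions/indels in the intergenic blocks between
#' syntenic gene anchors.  Gene presence differences are reported
#' separately, not as variant rows.
#'
#' @param derived,ancestor \linkS4class{AnnotatedGenome}.
#' @param upstreamWindow nt upstream window (default 100).
#' @param includeIntergenic also scan intergenic blocks (default TRUE).
#' @return list with \code{variants} (data.frame, column \code{strain}
#'   first), \code{summary} (total_snps, total_indels, per-effect counts),
#'   \code{presence} (genes private to either strain) and \code{pairs}.
#' @export
compareStrainPair <- function(derived, ancestor, upstreamWindow = 100L,
                              includeIntergenic = TRUE) {
  gp <- pairGenes(ancestor, derived)
  vt <- callVariants(gp, upstreamWindow)
  if (includeIntergenic) {
    iv <- intergenicVariants(gp, upstreamWindow)
    if (nrow(iv)) vt <- rbind(vt, iv)
  }
  vt <- cbind(strain = rep(strainID(derived), nrow(vt)), vt)
  rownames(vt) <- NULL
  isIndel <- grepl("del|ins", vt$nt_change) & !grepl(">", vt$nt_change)
  summary <- c(list(total = nrow(vt),
                    total_snps = sum(!isIndel),
                    total_indels = sum(isIndel)),
               as.list(table(vt$effect)))
  presence <- rbind(
    if (length(gp$anc_only)) data.frame(gene = gp$anc_only,
                                        status = "absent_in_derived"),
    if (length(gp$der_only)) data.frame(gene = gp$der_only,
                                        status = "absent_in_ancestor"))
  if (is.null(presence)) presence <- data.frame(gene = character(),
                                                status = character())
  list(variants = vt, summary = summary, presence = presence, pairs = gp)
}

# Intergenic blocks between consecutive syntenic anchors (paired genes
# adjacent in both genomes, same contig); events falling in an adjacent
# gene's upstream window are skipped (already reported by the flank pass).
intergenicVariants <- function(gp, upstreamWindow) {
  anc <- gp$ancestor; der <- gp$derived
  if (nrow(gp$pairs) < 2L) return(emptyCallTable())
  aft <- anc@features; dft <- der@features
  aOrd <- order(as.character(GenomicRanges::seqnames(aft)),
                GenomicRanges::start(aft))
  pairedA <- gp$pairs$anc_gene
  a2d <- stats::setNames(gp$pairs$der_gene, gp$pairs$anc_gene)
  anchors <- aft$gene_id[aOrd]
  anchors <- anchors[anchors %in% pairedA]
  dStart <- stats::setNames(GenomicRanges::start(dft), dft$gene_id)
  dEnd <- stats::setNames(GenomicRanges::end(dft), dft$gene_id)
  dCtg <- stats::setNames(as.character(GenomicRanges::seqnames(dft)),
                          dft$gene_id)
  aStart <- stats::setNames(GenomicRanges::start(aft), aft$gene_id)
  aEnd <- stats::setNames(GenomicRanges::end(aft), aft$gene_id)
  aCtg <- stats::setNames(as.character(GenomicRanges::seqnames(aft)),
                          aft$gene_id)
  aStrand <- stats::setNames(as.character(GenomicRanges::strand(aft)),
                             aft$gene_id)
  rows <- list()
  for (i in seq_len(length(anchors) - 1L)) {
    g1 <- anchors[i]; g2 <- anchors[i + 1L]
    if (aCtg[[g1]] != aCtg[[g2]]) next
    d1 <- a2d[[g1]]; d2 <- a2d[[g2]]
    if (dCtg[[d1]] != dCtg[[d2]]) next
    if (dEnd[[d1]] >= dStart[[d2]]) next   # not syntenic/adjacent in derived
    aFrom <- aEnd[[g1]] + 1L; aTo <- aStart[[g2]] - 1L
    if (aTo < aFrom) next
    blockA <- as.character(Biostrings::subseq(anc@contigs[[aCtg[[g1]]]],
                                              aFrom, aTo))
    blockD <- as.character(Biostrings::subseq(der@contigs[[dCtg[[d1]]]],
                                              dEnd[[d1]] + 1L,
                                              dStart[[d2]] - 1L))
    if (blockA == blockD) next
    aln <- pairAlign(blockA, blockD,
                     bandPad = abs(nchar(blockA) - nchar(blockD)) + 32L)
    # upstream windows covered by the flank pass
    excl <- list()
    if (aStrand[[g2]] == "+") {
      excl[[1L]] <- c(max(aFrom, aStart[[g2]] - upstreamWindow), aTo)
    }
    if (aStrand[[g1]] == "-") {
      excl[[length(excl) + 1L]] <-
        c(aFrom, min(aTo, aEnd[[g1]] + upstreamWindow))
    }
    inExcl <- function(p) any(vapply(excl, function(e)
      p >= e[1L] && p <= e[2L], logical(1)))
    for (ev in alignmentEvents(aln$a, aln$b)) {
      gpos <- aFrom + ev$pos - 1L
      if (length(excl) && inExcl(gpos)) next
      nt <- switch(ev$type,
        sub = sprintf("g.%s:%d%s>%s", aCtg[[g1]], gpos, ev$ref, ev$alt),
        del = sprintf("g.%s:%ddel%s", aCtg[[g1]], gpos, ev$ref),
        ins = sprintf("g.%s:%dins%s", aCtg[[g1]], gpos, ev$alt))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = NA_character_, cluster = NA_character_, effect = "intergenic",
        nt_change = nt, protein_notation = NA_character_,
        upstream_offset = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    do.call(rbind, rows)[, c("gene", "cluster", "effect", "nt_change",
                             "protein_notation", "upstream_offset")]
  } else emptyCallTable()
}

#' Pathway-focused variant report
#'
#' Subsets a variant table to a list of genes of interest (e.g. amino acid
#' biosynthesis genes) and renders one row per gene with semicolon-joined
#' notations — the shape of a per-pathway mutation table.
#'
#' @param variantTable data.frame of calls (from [compareStrainPair()] or
#'   [callVariants()]).
#' @param geneList character vector of gene ids (genes without variants are
#'   omitted).
#' @return data.frame: gene, n_variants, notations.
#' @export
pathwayReport <- function(variantTable, geneList) {
  if (length(geneList) == 0L) stop("empty gene list")
  rows <- list()
  for (g in geneList) {
    sub <- variantTable[!is.na(variantTable$gene) & variantTable$gene == g, ]
    if (nrow(sub) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, n_variants = nrow(sub),
      notations = paste(sub$protein_notation, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), n_variants = integer(),
               notations = character(), stringsAsFactors = FALSE)
}
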