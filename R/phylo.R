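#' Composition-vector and core-SNP phylogenetics
#'
#' Two distance sources feed one neighbor-joining tree builder: alignment-free
#' whole-proteome composition vectors (k-peptide frequencies with a Markov
#' background subtracted) for cohort-wide trees, and core-gene SNP counts for
#' within-group trees of highly related strains.
#'
#' @name phylo-module
NULL

#' Whole-proteome composition vector
#'
#' For every observed peptide word of length \code{k}, the score is
#' \eqn{(f - f_0) / f_0}, where \eqn{f_0} is the Markov prediction from the
#' (k-1)- and (k-2)-word frequencies:
#' \eqn{f_0(a_1..a_k) = f(a_1..a_{k-1}) f(a_2..a_k) / f(a_2..a_{k-1})}.
#'
#' @param proteome \code{AAStringSet} or character vector of proteins.
#' @param k peptide word length (default 6; sensible range 5-7).
#' @param id optional strain id carried on the vector.
#' @return a \code{CompositionVector}: list with \code{id}, \code{k},
#'   \code{keys} (encoded words) and \code{scores}.
#' @export
compositionVector <- function(proteome, k = 6L, id = NA_character_) {
  seqs <- as.character(proteome)
  seqs <- seqs[nchar(seqs) > 0L]
  if (length(seqs) == 0L) stop("empty proteome")
  df <- cpp_cv_scores(seqs, k = as.integer(k))
  structure(list(id = id, k = as.integer(k), keys = df$key,
                 scores = df$score),
            class = "CompositionVector")
}

#' Distance between two composition vectors
#'
#' \eqn{d = (1 - C(u, v)) / 2} where \eqn{C} is the cosine similarity of the
#' score vectors over the union of observed words; bounded in [0, 1].
#'
#' @param u,v \code{CompositionVector}s built with the same \code{k}.
#' @return distance in [0, 1].
#' @export
cvDistance <- function(u, v) {
  stopifnot(inherits(u, "CompositionVector"), inherits(v, "CompositionVector"))
  if (u$k != v$k) stop("composition vectors have different k")
  nu <- sqrt(sum(u$scores^2))
  nv <- sqrt(sum(v$scores^2))
  if (nu == 0 && nv == 0) return(0)   # two flat vectors are indistinguishable
  if (nu == 0 || nv == 0) return(0.5) # orthogonal by convention
  idx <- match(u$keys, v$keys)
  dot <- sum(u$scores[!is.na(idx)] * v$scores[idx[!is.na(idx)]])
  (1 - dot / (nu * nv)) / 2
}

#' Composition-vector distance matrix for a strain set
#'
#' @param genomeList named list of \linkS4class{AnnotatedGenome}.
#' @param k peptide word length.
#' @return symmetric distance matrix.
#' @export
cvDistanceMatrix <- function(genomeList, k = 6L) {
  cvs <- lapply(names(genomeList), function(id)
    compositionVector(proteinSeq(genomeList[[id]]), k = k, id = id))
  n <- length(cvs)
  m <- matrix(0, n, n, dimnames = list(names(genomeList), names(genomeList)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- cvDistance(cvs[[i]], cvs[[j]])
      }
    }
  }
  m
}

#' Core-SNP sites across a set of closely related genomes
#'
#' Variable columns of per-cluster alignments of single-copy core genes
#' (clusters with exactly one member in every strain).  A site is reported
#' when it shows >= 2 states and no strain has a gap there (core sites
#' only); positions are 1-based within the reference strain's gene.
#'
#' @param genomeList named list of genomes (>= 2), typically one MLST group.
#' @param clusters optional precomputed \code{OrthologClusters} for these
#'   strains; computed if missing.
#' @return an \code{SNPMatrix}: list with \code{sites} (data.frame: cluster,
#'   gene, pos, then one base column per strain) and \code{strains}.
#' @export
coreSNPSites <- function(genomeList, clusters = NULL) {
  ids <- names(genomeList)
  if (length(ids) < 2L) stop("need >= 2 strains")
  if (is.null(clusters)) clusters <- clusterOrthologs(genomeList)
  mem <- clusters$members
  cnt <- table(mem$cluster, mem$strain)
  singleCore <- rownames(cnt)[apply(cnt == 1L, 1L, all) &
                                ncol(cnt) == length(ids)]
  if (ncol(cnt) < length(ids)) singleCore <- character()
  if (length(singleCore) == 0L) stop("no single-copy core genes found")
  cdsAll <- lapply(genomeList, cdsSeq)
  rows <- list()
  for (cl in singleCore) {
    sub <- mem[mem$cluster == cl, ]
    seqs <- vapply(ids, function(id)
      as.character(cdsAll[[id]][[sub$gene_id[sub$strain == id]]]), character(1))
    if (length(unique(seqs)) == 1L) next
    refGene <- sub$gene_id[sub$strain == ids[1L]]
    lens <- nchar(seqs)
    if (all(lens == lens[1L])) {
      chars <- do.call(rbind, strsplit(seqs, ""))
      nstates <- apply(chars, 2L, function(col) length(unique(col)))
      varPos <- which(nstates >= 2L)
      for (p in varPos) {
        rows[[length(rows) + 1L]] <-
          c(cluster = cl, gene = refGene, pos = p, chars[, p])
      }
    } else {
      # star alignment onto the first strain's gene
      ref <- seqs[1L]
      Lr <- nchar(ref)
      mat <- matrix(NA_character_, length(ids), Lr)
      mat[1L, ] <- strsplit(ref, "")[[1L]]
      for (i in 2L:length(ids)) {
        aln <- pairAlign(ref, seqs[i],
                         bandPad = abs(Lr - nchar(seqs[i])) + 32L)
        ra <- strsplit(aln$a, "")[[1L]]
        qa <- strsplit(aln$b, "")[[1L]]
        keep <- ra != "-"             # columns with a reference coordinate
        proj <- qa[keep]
        proj[proj == "-"] <- NA_character_
        mat[i, ] <- proj
      }
      ok <- colSums(is.na(mat)) == 0L
      nstates <- apply(mat, 2L, function(col) length(unique(col)))
      varPos <- which(ok & nstates >= 2L)
      for (p in varPos) {
        rows[[length(rows) + 1L]] <-
          c(cluster = cl, gene = sub$gene_id[sub$strain == ids[1L]],
            pos = p, mat[, p])
      }
    }
  }
  sites <- if (length(rows)) {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- c("cluster", "gene", "pos", ids)
    df$pos <- as.integer(df$pos)
    df
  } else {
    df <- data.frame(cluster = character(), gene = character(),
                     pos = integer())
    for (id in ids) df[[id]] <- character()
    df
  }
  structure(list(sites = sites, strains = ids), class = "SNPMatrix")
}

#' Pairwise SNP distance matrix
#'
#' @param m an \code{SNPMatrix} from [coreSNPSites()].
#' @return symmetric integer matrix: number of core-SNP sites at which each
#'   strain pair differs; zero diagonal.
#' @export
snpDistanceMatrix <- function(m) {
  stopifnot(inherits(m, "SNPMatrix"))
  ids <- m$strains
  d <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(m$sites) == 0L) return(d)
  bases <- as.matrix(m$sites[, ids, drop = FALSE])
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      d[i, j] <- d[j, i] <- sum(bases[, i] != bases[, j])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (exact on additive matrices); taxa are ordered by label
#' before joining so ties break deterministically.  Negative branch lengths
#' are clamped to zero with a warning, never hidden.  Two taxa yield a
#' trivial two-tip tree by a separate path.
#'
#' @param d symmetric distance matrix with zero diagonal (>= 2 taxa).
#' @param outgroup optional taxon to root on.
#' @return an \code{ape::phylo} tree.
#' @export
njTree <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(d))) stop("distance matrix must have taxon names")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  if (nrow(d) == 2L) {
    tr <- ape::read.tree(
      text = sprintf("(%s:%f,%s:%f);", rownames(d)[1L], d[1L, 2L] / 2,
                     rownames(d)[2L], d[1L, 2L] / 2))
    return(tr)
  }
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not among taxa")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}
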