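#' Pan-genome analysis: ortholog clustering, rarefaction and curve fits
#'
#' Gene families are single-linkage components of the protein-similarity
#' graph (>= 50 percent identity, >= 50 percent bidirectional coverage by
#' default).  Rarefaction over random genome orderings yields pan-, core-
#' and new-gene trajectories; asymptotic models are fitted to the per-x
#' medians: a Heaps-style power law \eqn{y = A x^\gamma + B} for the pan
#' genome (open iff \eqn{\gamma > 0}), an exponential decay
#' \eqn{y = C e^{-\delta x} + \Omega} for the core genome (\eqn{\Omega} is
#' the core-gene asymptote), and \eqn{y = K x^{-\alpha}} for new genes.
#'
#' @name pangenome-module
NULL

#' Cluster genes of a strain set into ortholog families
#'
#' All CDSs are translated (bacterial code, table 11); protein pairs meeting
#' the identity and bidirectional-coverage thresholds become edges and
#' single-linkage connected components become clusters.  Genes whose
#' translation carries an internal stop are quarantined and reported, not
#' clustered.
#'
#' @param genomeList named list of \linkS4class{AnnotatedGenome}.
#' @param minIdentity minimum percent protein identity for an edge.
#' @param minCoverage minimum aligned fraction of both proteins.
#' @return an \code{OrthologClusters}: list with \code{members} (data.frame:
#'   cluster, strain, gene_id), \code{params} and \code{quarantined}.
#' @export
clusterOrthologs <- function(genomeList, minIdentity = 50, minCoverage = 0.5) {
  stopifnot(length(genomeList) >= 1L, !is.null(names(genomeList)))
  prot <- list()
  strain_of <- character()
  gene_of <- character()
  quarantined <- list()
  for (id in names(genomeList)) {
    aa <- proteinSeq(genomeList[[id]])
    bad <- grepl("*", as.character(aa), fixed = TRUE)
    if (any(bad)) {
      quarantined[[id]] <- data.frame(strain = id, gene_id = names(aa)[bad],
                                      reason = "internal stop codon")
    }
    aa <- aa[!bad]
    prot <- c(prot, as.character(aa))
    strain_of <- c(strain_of, rep(id, length(aa)))
    gene_of <- c(gene_of, names(aa))
  }
  n <- length(prot)
  if (n == 0L) stop("no translatable genes")
  seqs <- unlist(prot, use.names = FALSE)
  memb <- clusterBySimilarity(seqs, minIdentity, minCoverage, protein = TRUE)
  clusterIds <- sprintf("CL%05d", match(memb, unique(memb)))
  structure(list(
    members = data.frame(cluster = clusterIds, strain = strain_of,
                         gene_id = gene_of, stringsAsFactors = FALSE),
    params = list(min_identity = minIdentity, min_coverage = minCoverage),
    quarantined = if (length(quarantined)) do.call(rbind, quarantined) else
      data.frame(strain = character(), gene_id = character(),
                 reason = character())),
    class = "OrthologClusters")
}

# Single-linkage components of the sequence-similarity graph.  Exact
# duplicates are joined without alignment; remaining candidate pairs come
# from shared k-mers and are verified by banded global alignment.
clusterBySimilarity <- function(seqs, minIdentity, minCoverage,
                                protein = TRUE) {
  n <- length(seqs)
  edges <- NULL
  # exact duplicates
  key <- match(seqs, seqs)
  dupEdges <- cbind(key[key != seq_len(n)], which(key != seq_len(n)))
  reps <- which(key == seq_len(n))
  if (length(reps) > 1L) {
    k <- if (protein) 5L else 12L
    cand <- cpp_candidate_pairs(seqs[reps], k = k,
                                min_shared = if (protein) 4L else 6L,
                                max_occ = 2L * as.integer(sqrt(n) + 64L))
    if (nrow(cand) > 0L) {
      st <- cpp_pair_stats(seqs[reps][cand[, 1L]], seqs[reps][cand[, 2L]],
                           band_pad = 48L)
      keep <- !is.na(st$score) & st$identity >= minIdentity &
        pmin(st$cov_a, st$cov_b) >= minCoverage
      edges <- cbind(reps[cand[keep, 1L]], reps[cand[keep, 2L]])
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  allEdges <- rbind(dupEdges, edges)
  if (!is.null(allEdges) && nrow(allEdges) > 0L) {
    g <- igraph::add_edges(g, t(allEdges))
  }
  igraph::components(g)$membership
}

#' Build the presence/absence matrix from ortholog clusters
#'
#' @param clusters an \code{OrthologClusters}.
#' @param strains strain ids (columns); defaults to the strains seen in the
#'   clustering.
#' @return logical matrix, clusters x strains; an entry is TRUE iff the
#'   strain has at least one member in the cluster.  Core genome = all-TRUE
#'   rows.
#' @export
buildPAMatrix <- function(clusters, strains = NULL) {
  stopifnot(inherits(clusters, "OrthologClusters"))
  mem <- clusters$members
  if (is.null(strains)) strains <- unique(mem$strain)
  if (!all(mem$strain %in% strains)) {
    stop("clustering contains strains not in `strains`: ",
         paste(setdiff(unique(mem$strain), strains), collapse = ", "))
  }
  cl <- unique(mem$cluster)
  m <- matrix(FALSE, length(cl), length(strains),
              dimnames = list(cl, strains))
  m[cbind(match(mem$cluster, cl), match(mem$strain, strains))] <- TRUE
  m
}

#' Rarefaction trajectories over random genome orderings
#'
#' For each permutation of the strain order, the cumulative pan-genome size,
#' core-genome size and the number of new gene families contributed by each
#' added genome.
#'
#' @param pa logical presence/absence matrix (families x strains).
#' @param nPermutations number of random orderings (>= 1).
#' @param seed RNG seed.
#' @return a \code{RarefactionTrajectories}: list with \code{x} (1..N),
#'   matrices \code{pan}, \code{core}, \code{new} (permutations x N),
#'   \code{n_permutations}, \code{seed}.
#' @export
rarefy <- function(pa, nPermutations = 100L, seed = 1L) {
  nPermutations <- as.integer(nPermutations)
  if (is.na(nPermutations) || nPermutations < 1L) {
    stop("nPermutations must be >= 1")
  }
  N <- ncol(pa)
  if (N < 2L) stop("need at least 2 strains")
  mode(pa) <- "integer"
  set.seed(seed)
  tri <- upper.tri(matrix(0L, N, N), diag = TRUE) + 0L
  pan <- core <- new <- matrix(0L, nPermutations, N)
  for (p in seq_len(nPermutations)) {
    ord <- sample.int(N)
    cum <- pa[, ord, drop = FALSE] %*% tri  # families x N cumulative counts
    pan[p, ] <- colSums(cum > 0L)
    core[p, ] <- colSums(cum == matrix(seq_len(N), nrow(pa), N, byrow = TRUE))
    new[p, ] <- diff(c(0L, pan[p, ]))
  }
  structure(list(x = seq_len(N), pan = pan, core = core, new = new,
                 n_permutations = nPermutations, seed = seed),
            class = "RarefactionTrajectories")
}

summariseTraj <- function(m, summary) {
  fn <- switch(summary, median = stats::median, mean = mean,
               stop("summary must be 'median' or 'mean'"))
  apply(m, 2L, fn)
}

fitOne <- function(formula, data, start) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("curve fit failed to converge: ", conditionMessage(fit),
         " (start: ", paste(sprintf("%s=%g", names(start), unlist(start)),
                            collapse = ", "), ")")
  }
  fit
}

#' Fit the three asymptotic pan-genome models
#'
#' Nonlinear least squares on the per-x summary (median by default) of the
#' rarefaction trajectories.  The new-gene power law is fitted excluding
#' x = 1, whose "new genes" are the whole first genome.  Constant
#' trajectories (e.g. identical genomes) take an explicit degenerate path
#' with a zero exponent rather than a spurious fit.
#'
#' @param traj a \code{RarefactionTrajectories}.
#' @param summary \code{"median"} (default) or \code{"mean"}.
#' @return list with \code{pan}, \code{core}, \code{new} (each a
#'   \code{CurveFit}: model, params, rss, degenerate flag), \code{openness}
#'   (\code{"open"} or \code{"closed"}), \code{gamma} and \code{gamma_se}.
#' @examples
#' # exact recovery on noiseless self-generated points
#' x <- 1:8; y <- 1161 * x^0.416 + 1821
#' traj <- structure(list(x = x, pan = rbind(y), core = rbind(rev(y)),
#'                        new = rbind(c(y[1], diff(y))),
#'                        n_permutations = 1, seed = 1),
#'                   class = "RarefactionTrajectories")
#' fitCurves(traj)$pan$params
#' @export
fitCurves <- function(traj, summary = "median") {
  stopifnot(inherits(traj, "RarefactionTrajectories"))
  x <- traj$x
  if (length(unique(x)) < 3L) stop("need >= 3 distinct x values")
  panY <- summariseTraj(traj$pan, summary)
  coreY <- summariseTraj(traj$core, summary)
  newY <- summariseTraj(traj$new, summary)

  out <- list()
  if (stats::sd(panY) < 1e-12) {
    out$pan <- curveFit("pan", c(A = 0, gamma = 0, B = panY[1L]), 0,
                        degenerate = TRUE)
    gamma_se <- NA_real_
  } else {
    fit <- fitOne(y ~ A * x^gamma + B, data.frame(x = x, y = panY),
                  list(A = panY[1L], gamma = 0.5, B = panY[1L]))
    cf <- stats::coef(fit)
    gamma_se <- tryCatch(summary(fit)$coefficients["gamma", "Std. Error"],
                         error = function(e) NA_real_)
    out$pan <- curveFit("pan", c(A = cf[["A"]], gamma = cf[["gamma"]],
                                 B = cf[["B"]]),
                        sum(stats::residuals(fit)^2))
  }
  if (stats::sd(coreY) < 1e-12) {
    out$core <- curveFit("core", c(C = 0, delta = 0, Omega = coreY[1L]), 0,
                         degenerate = TRUE)
  } else {
    N <- length(x)
    fit <- fitOne(y ~ C * exp(-delta * x) + Omega,
                  data.frame(x = x, y = coreY),
                  list(C = coreY[1L] - coreY[N], delta = 0.5,
                       Omega = coreY[N]))
    cf <- stats::coef(fit)
    out$core <- curveFit("core", c(C = cf[["C"]], delta = cf[["delta"]],
                                   Omega = cf[["Omega"]]),
                         sum(stats::residuals(fit)^2))
  }
  xn <- x[x > 1L]
  yn <- newY[x > 1L]
  if (all(yn == 0)) {
    out$new <- curveFit("new", c(K = 0, alpha = 0), 0, degenerate = TRUE)
  } else {
    pos <- yn > 0
    start <- if (sum(pos) >= 2L) {
      ll <- stats::lm(log(yn[pos]) ~ log(xn[pos]))
      list(K = exp(stats::coef(ll)[[1L]]), alpha = -stats::coef(ll)[[2L]])
    } else {
      list(K = max(yn), alpha = 1)
    }
    if (!all(is.finite(unlist(start)))) start <- list(K = max(yn), alpha = 1)
    fit <- fitOne(y ~ K * x^(-alpha), data.frame(x = xn, y = yn), start)
    cf <- stats::coef(fit)
    out$new <- curveFit("new", c(K = cf[["K"]], alpha = cf[["alpha"]]),
                        sum(stats::residuals(fit)^2))
  }
  gamma <- unname(out$pan$params["gamma"])
  out$openness <- if (!out$pan$degenerate && gamma > 0) "open" else "closed"
  out$gamma <- gamma
  out$gamma_se <- gamma_se
  out
}

curveFit <- function(model, params, rss, degenerate = FALSE) {
  structure(list(model = model, params = params, rss = rss,
                 degenerate = degenerate), class = "CurveFit")
}

#' @export
print.CurveFit <- function(x, ...) {
  form <- switch(x$model,
                 pan = "y = A*x^gamma + B",
                 core = "y = C*exp(-delta*x) + Omega",
                 new = "y = K*x^(-alpha)")
  cat(sprintf("CurveFit [%s] %s%s\n  ", x$model, form,
              if (x$degenerate) " (degenerate: constant data)" else ""))
  cat(paste(sprintf("%s = %.6g", names(x$params), x$params), collapse = ", "),
      sprintf("\n  RSS = %.4g\n", x$rss))
  invisible(x)
}

#' Screen strains for marker genes
#'
#' Presence/absence of marker sequences (e.g. the NAD+/NADP+ glutamate
#' dehydrogenase gene or the cspB S-layer gene) per strain, by the same
#' homology rule as [extractLocus()].
#'
#' @param genomeList named list of genomes.
#' @param markers named \code{DNAStringSet} or character vector of marker
#'   reference sequences.
#' @param minIdentity,minCoverage homology thresholds.
#' @return data.frame: strain, then one logical column per marker.
#' @export
screenMarkers <- function(genomeList, markers, minIdentity = 90,
                          minCoverage = 0.95) {
  if (length(markers) == 0L) stop("empty marker set")
  if (is.null(names(markers))) stop("markers must be named")
  res <- matrix(FALSE, length(genomeList), length(markers),
                dimnames = list(names(genomeList), names(markers)))
  for (id in names(genomeList)) {
    for (mk in names(markers)) {
      hit <- bestGenomeHit(as.character(markers[[mk]]), genomeList[[id]])
      res[id, mk] <- !is.na(hit$score) && hit$identity >= minIdentity &&
        hit$coverage >= minCoverage
    }
  }
  data.frame(strain = rownames(res), res, row.names = NULL,
             check.names = FALSE)
}
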