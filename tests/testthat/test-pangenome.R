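test_that("identical genomes form one full cluster per gene", {
  co <- frozenCohort(3)
  cl <- clusterOrthologs(genomes(co))
  tab <- table(cl$members$cluster)
  expect_identical(length(tab), 16L)      # 12 core (incl. 7 loci) + 4 dispensable
  expect_true(all(tab == 3L))
  pa <- buildPAMatrix(cl, names(genomes(co)))
  expect_true(all(pa))
})

test_that("unrelated gene sets stay as singleton clusters", {
  mk <- function(id, seed) {
    set.seed(seed)
    genes <- replicate(5, paste0("ATG", paste(
      sample(c("GCT","GAA","AAA","TTG","CAT","CGT"), 60, replace = TRUE),
      collapse = ""), "TAA"))
    ctg <- paste(genes, collapse = strrep("T", 60))
    starts <- cumsum(c(1, rep(nchar(genes[1]) + 60, 4)))
    annotatedGenome(id, c(chr = ctg),
      GenomicRanges::GRanges("chr",
        IRanges::IRanges(starts, starts + nchar(genes[1]) - 1), "+",
        gene_id = paste0(id, "_g", 1:5), product = "x"))
  }
  gl <- list(a = mk("a", 1), b = mk("b", 999))
  cl <- clusterOrthologs(gl)
  expect_true(all(table(cl$members$cluster) == 1L))
})

test_that("genes with internal stops are quarantined, not clustered", {
  g <- annotatedGenome("q", c(chr = paste0(strrep("A", 10),
                                           "ATGAAATAAGGGTAA",  # internal stop
                                           strrep("C", 10),
                                           "ATGAAATTTGGGTAA",
                                           strrep("G", 10))),
    GenomicRanges::GRanges("chr", IRanges::IRanges(c(11, 36), c(25, 50)),
                           "+", gene_id = c("bad", "good"),
                           product = c("x", "y")))
  cl <- clusterOrthologs(list(q = g))
  expect_identical(cl$quarantined$gene_id, "bad")
  expect_false("bad" %in% cl$members$gene_id)
})

test_that("recovered clustering reproduces the simulator's PA matrix", {
  co <- smallCohort()
  cl <- clusterOrthologs(genomes(co))
  pa <- buildPAMatrix(cl, names(genomes(co)))
  truth <- truePAMatrix(co)
  truth <- truth[rowSums(truth) > 0, , drop = FALSE]
  expect_identical(nrow(pa), nrow(truth))
  patterns <- function(m) sort(unname(apply(m + 0L, 1, paste, collapse = "")))
  expect_identical(patterns(pa), patterns(truth))
  # a strain-unique family appears as exactly one single-TRUE row
  uniq <- rowSums(truth) == 1L
  expect_identical(sum(rowSums(pa) == 1L), sum(uniq))
  expect_error(buildPAMatrix(cl, c("S01", "S02")), "not in")
})

test_that("rarefaction is seeded, exhaustive for two strains, constant for clones", {
  co <- frozenCohort(3)
  pa <- truePAMatrix(co)
  tr <- rarefy(pa, 10, seed = 3)
  expect_true(all(tr$pan == nrow(pa)))
  expect_true(all(tr$core == nrow(pa)))
  tr2 <- rarefy(pa, 10, seed = 3)
  expect_identical(tr, tr2)
  # 2-strain enumeration oracle: new genes at x=2 are the second strain's
  # private families, for both orderings
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
              4, 2, dimnames = list(paste0("f", 1:4), c("a", "b")))
  tr3 <- rarefy(m, 50, seed = 1)
  privB <- sum(m[, "b"] & !m[, "a"])  # 1
  privA <- sum(m[, "a"] & !m[, "b"])  # 2
  expect_setequal(unique(tr3$new[, 2]), c(privA, privB))
  expect_true(all(tr3$pan[, 2] == 3))
  expect_error(rarefy(m, 0), "nPermutations")
})

test_that("pan/core monotonicity and ordering invariants hold on real trajectories", {
  co <- smallCohort()
  pa <- buildPAMatrix(clusterOrthologs(genomes(co)), names(genomes(co)))
  tr <- rarefy(pa, 25, seed = 11)
  for (p in seq_len(nrow(tr$pan))) {
    expect_true(all(diff(tr$pan[p, ]) >= 0))
    expect_true(all(diff(tr$core[p, ]) <= 0))
    expect_true(all(tr$pan[p, ] >= tr$core[p, ]))
  }
  expect_true(all(tr$pan[, 1] == tr$core[, 1]))
  # conservation: cluster memberships sum to the translatable gene count
  cl <- clusterOrthologs(genomes(co))
  expect_identical(nrow(cl$members) + nrow(cl$quarantined),
                   sum(vapply(genomes(co), function(g)
                     length(features(g)), integer(1))))
})

test_that("curve fitting recovers noiseless parameters to 1e-6 relative", {
  x <- 1:8
  traj <- structure(list(
    x = x,
    pan = rbind(1161 * x^0.416 + 1821),
    core = rbind(1364 * exp(-0.802 * x) + 2359),
    new = rbind(c(0, 612 * (2:8)^-0.68)),
    n_permutations = 1, seed = 1), class = "RarefactionTrajectories")
  f <- fitCurves(traj)
  expect_equal(unname(f$pan$params), c(1161, 0.416, 1821), tolerance = 1e-6)
  expect_equal(unname(f$core$params), c(1364, 0.802, 2359), tolerance = 1e-6)
  expect_equal(unname(f$new$params), c(612, 0.68), tolerance = 1e-6)
  expect_identical(f$openness, "open")
  expect_lt(f$pan$rss, 1e-8)
})

test_that("constant trajectories give a degenerate closed verdict", {
  co <- frozenCohort(3)
  tr <- rarefy(truePAMatrix(co), 5, seed = 2)
  f <- fitCurves(tr)
  expect_identical(unname(f$pan$params["gamma"]), 0)
  expect_true(f$pan$degenerate)
  expect_identical(f$openness, "closed")
})

test_that("openness verdict does not depend on the permutation seed", {
  co <- smallCohort()
  pa <- buildPAMatrix(clusterOrthologs(genomes(co)), names(genomes(co)))
  v <- vapply(c(1, 99), function(s)
    fitCurves(rarefy(pa, 30, seed = s))$openness, character(1))
  expect_identical(v[1], v[2])
})

test_that("marker screening flags exactly the strains carrying the marker", {
  co <- smallCohort()
  pa <- truePAMatrix(co)
  disp <- rownames(pa)[grepl("^disp", rownames(pa)) &
                         rowSums(pa) > 0 & rowSums(pa) < ncol(pa)][1]
  carrier <- names(which(pa[disp, ]))[1]
  marker <- cdsSeq(genomes(co)[[carrier]])[disp]
  tab <- screenMarkers(genomes(co), marker)
  expect_identical(stats::setNames(tab[[disp]], tab$strain),
                   pa[disp, tab$strain])
  expect_error(screenMarkers(genomes(co), Biostrings::DNAStringSet()), "empty")
})
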