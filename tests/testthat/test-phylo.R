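# Brute-force composition-vector oracle over explicit word counts.
bruteCV <- function(proteins, k) {
  words <- function(len) {
    out <- character()
    for (p in proteins) {
      if (nchar(p) < len) next
      out <- c(out, substring(p, seq_len(nchar(p) - len + 1),
                              seq_len(nchar(p) - len + 1) + len - 1))
    }
    out
  }
  wk <- words(k); w1 <- words(k - 1); w2 <- words(k - 2)
  f <- function(w, pool) sum(pool == w) / length(pool)
  uk <- unique(wk)
  scores <- vapply(uk, function(w) {
    fp <- f(substr(w, 1, k - 1), w1) * f(substr(w, 2, k), w1) /
      f(substr(w, 2, k - 1), w2)
    (f(w, wk) - fp) / fp
  }, numeric(1))
  stats::setNames(scores, uk)
}

test_that("a homopolymer proteome has an exact Markov prediction (all scores 0)", {
  cv <- compositionVector(strrep("A", 30), k = 6)
  expect_true(all(abs(cv$scores) < 1e-12))
})

test_that("composition vectors match brute-force enumeration on a toy set", {
  prot <- c("MKLVAGGK", "MKLVMKGG")
  cv <- compositionVector(prot, k = 3)
  oracle <- bruteCV(prot, 3)
  got <- stats::setNames(cv$scores, strainTrace:::cpp_decode_words(cv$keys, 3))
  expect_setequal(names(got), names(oracle))
  expect_equal(unname(got[names(oracle)]), unname(oracle), tolerance = 1e-12)
})

test_that("cv distance is zero on identity, symmetric, bounded, 0.5 when orthogonal", {
  co <- smallCohort()
  p1 <- proteinSeq(genomes(co)$S01)
  p2 <- proteinSeq(genomes(co)$S02)
  u <- compositionVector(p1); v <- compositionVector(p2)
  expect_identical(cvDistance(u, u), 0)
  expect_identical(cvDistance(u, v), cvDistance(v, u))
  expect_gte(cvDistance(u, v), 0); expect_lte(cvDistance(u, v), 1)
  expect_identical(cvDistance(compositionVector(p1),
                              compositionVector(as.character(p1))), 0)
  # hand-built orthogonal vectors
  a <- structure(list(id = "a", k = 3, keys = c(1, 2), scores = c(1, 0)),
                 class = "CompositionVector")
  b <- structure(list(id = "b", k = 3, keys = c(1, 2), scores = c(0, 1)),
                 class = "CompositionVector")
  expect_identical(cvDistance(a, b), 0.5)
  expect_error(cvDistance(u, compositionVector(p1, k = 5)), "different k")
})

test_that("identical genomes produce an empty core-SNP matrix", {
  co <- frozenCohort(3)
  snp <- coreSNPSites(genomes(co))
  expect_identical(nrow(snp$sites), 0L)
  d <- snpDistanceMatrix(snp)
  expect_true(all(d == 0L))
})

test_that("planted substitutions appear as exactly that many core-SNP sites", {
  co <- frozenCohort(3)
  g <- genomes(co)$S01
  genesToHit <- c("core0001", "core0002", "core0003", "core0004", "core0005")
  specs <- lapply(genesToHit, function(gn)
    variantSpec(gn, "missense", 12, oneStepMissense(g, gn, 12)))
  co2 <- deriveStrain(co, "S01", "P1", specs)
  snp <- coreSNPSites(genomes(co2))
  expect_identical(nrow(snp$sites), 5L)
  d <- snpDistanceMatrix(snp)
  expect_identical(unname(d["P1", "S01"]), 5L)
  expect_identical(unname(d["S02", "S03"]), 0L)
})

test_that("a substitution inside another strain's deletion is excluded (gap rule)", {
  co <- frozenCohort(3)
  g <- genomes(co)$S01
  co2 <- deriveStrain(co, "S01", "PSUB", list(
    variantSpec("core0005", "missense", 30, oneStepMissense(g, "core0005", 30))))
  co2 <- deriveStrain(co2, "S02", "PDEL", list(
    variantSpec("core0005", "inframe_deletion", 29, 3)))
  snp <- coreSNPSites(genomes(co2)[c("S03", "PSUB", "PDEL")])
  expect_identical(nrow(snp$sites), 0L)
})

test_that("SNP distances match a brute-force recount and the triangle inequality", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 12; strains <- c("a", "b", "c", "d")
    bases <- matrix(sample(c("A", "C", "G", "T"), n * 4, replace = TRUE), n, 4,
                    dimnames = list(NULL, strains))
    sites <- data.frame(cluster = "cl1", gene = "g", pos = seq_len(n), bases,
                        stringsAsFactors = FALSE)
    m <- structure(list(sites = sites, strains = strains), class = "SNPMatrix")
    d <- snpDistanceMatrix(m)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_identical(d[i, j], sum(bases[, i] != bases[, j]))
    }
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      expect_lte(d[i, j], d[i, k] + d[k, j])
    }
  }
})

test_that("neighbor joining recovers a hand-built additive four-taxon tree", {
  # tree ((A:1,B:2):1.5,C:3,D:4): additive distances by path length
  D <- matrix(0, 4, 4, dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
  D["A","B"] <- D["B","A"] <- 3
  D["A","C"] <- D["C","A"] <- 5.5
  D["A","D"] <- D["D","A"] <- 6.5
  D["B","C"] <- D["C","B"] <- 6.5
  D["B","D"] <- D["D","B"] <- 7.5
  D["C","D"] <- D["D","C"] <- 7
  tr <- njTree(D)
  expect_equal(unname(as.matrix(stats::cophenetic(tr))[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-9)
})

test_that("neighbor joining is exact on random additive matrices (n <= 8)", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, tip.label = sprintf("t%02d", 1:n))
    true$edge.length <- stats::runif(nrow(true$edge), 0.5, 3)
    D <- as.matrix(stats::cophenetic(true))
    tr <- njTree(D)
    expect_equal(unname(as.matrix(stats::cophenetic(tr))[rownames(D), colnames(D)]),
                 unname(D), tolerance = 1e-8)
    expect_identical(phangorn::RF.dist(ape::unroot(tr), ape::unroot(true)), 0L)
  }
})

test_that("degenerate and invalid trees are handled explicitly", {
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr <- njTree(d2)
  expect_setequal(tr$tip.label, c("x", "y"))
  expect_equal(sum(tr$edge.length), 4)
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_identical(ape::Ntip(njTree(d3)), 3L)
  expect_error(njTree(d3[1, 1, drop = FALSE]), "2 taxa")
  bad <- d3; bad[1, 2] <- 9
  expect_error(njTree(bad), "symmetric")
})

test_that("within-lineage SNP distances are smaller than between-lineage ones", {
  co <- smallCohort()
  g1 <- genomes(co)$S01; g2 <- genomes(co)$S02
  co <- deriveStrain(co, "S01", "A1", list(
    variantSpec("core0001", "missense", 10, oneStepMissense(g1, "core0001", 10))))
  co <- deriveStrain(co, "S01", "A2", list(
    variantSpec("core0002", "missense", 11, oneStepMissense(g1, "core0002", 11))))
  co <- deriveStrain(co, "S02", "B2", list(
    variantSpec("core0003", "missense", 12, oneStepMissense(g2, "core0003", 12))))
  snp <- coreSNPSites(genomes(co)[c("A1", "A2", "B2")])
  d <- snpDistanceMatrix(snp)
  expect_lt(d["A1", "A2"], d["A1", "B2"])
  expect_lt(d["A1", "A2"], d["A2", "B2"])
})
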