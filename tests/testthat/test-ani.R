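randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("fragmentGenome follows the window, remainder and boundary rules", {
  expect_length(fragmentGenome(c(c1 = randomSeq(3060, 1)), 1020), 3L)
  expect_length(fragmentGenome(c(c1 = randomSeq(1100, 2)), 1020), 1L)
  frs <- fragmentGenome(c(c1 = randomSeq(1020, 3), c2 = randomSeq(1020, 4)),
                        1020)
  expect_length(frs, 2L)
  expect_named(frs, c("c1:1", "c2:1"))
  expect_error(fragmentGenome(character()), "empty genome")
  expect_error(fragmentGenome(c(c1 = "ACGT"), 50), ">= 100")
})

test_that("bestFragmentHit finds exact, reverse-complement and mutated placements", {
  ref <- randomSeq(5000, 10)
  frag <- substr(ref, 2001, 3020)
  hit <- bestFragmentHit(frag, c(chr = ref))
  expect_equal(unname(hit["identity"]), 100)
  expect_equal(unname(hit["coverage"]), 1)
  rcfrag <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  hit2 <- bestFragmentHit(rcfrag, c(chr = ref))
  expect_equal(unname(hit2["identity"]), 100)
  # 10 planted substitutions over 1020 nt, gap-free: identity 1010/1020
  set.seed(99)
  v <- strsplit(frag, "")[[1]]
  pos <- sample(seq_along(v), 10)
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  hit3 <- bestFragmentHit(paste(v, collapse = ""), c(chr = ref))
  expect_equal(unname(hit3["identity"]), 100 * 1010 / 1020, tolerance = 1e-6)
})

test_that("self-ANI is 100 and strand flipping leaves ANI unchanged", {
  g <- genomes(smallCohort())$S01
  a <- computeANI(g, g)
  expect_equal(a$ani_percent, 100)
  expect_gt(a$aligned_fraction, 0.99)
  rc <- annotatedGenome("rc",
    stats::setNames(as.character(Biostrings::reverseComplement(contigs(g))),
                    names(contigs(g))), features(g)[0])
  expect_equal(computeANI(g, rc)$ani_percent, 100, tolerance = 1e-4)
})

test_that("planted uniform substitutions give the analytic ANI", {
  g <- genomes(smallCohort())$S01
  for (rate in c(0.01, 0.02)) {
    mut <- plantedSubGenome(g, rate, seed = 1234)
    a <- computeANI(g, mut)
    expect_equal(a$ani_percent, 100 * (1 - rate), tolerance = 0.1 / 98)
  }
})

test_that("ANI degrades monotonically with substitution rate and is symmetric", {
  g <- genomes(smallCohort())$S02
  anis <- vapply(c(0, 0.01, 0.02, 0.05), function(rate) {
    mut <- plantedSubGenome(g, rate, seed = 77)
    computeANI(g, mut)$ani_percent
  }, numeric(1))
  expect_true(all(diff(anis) <= 0))
  h <- genomes(smallCohort())$S03
  expect_identical(computeANI(g, h)$ani_percent, computeANI(h, g)$ani_percent)
})

test_that("no passing fragment yields an explicit undefined state", {
  a <- computeANI(c(q = randomSeq(1100, 5)), c(r = randomSeq(1100, 600)))
  expect_false(a$defined)
  expect_true(is.na(a$ani_percent))
  expect_identical(a$n_fragments_used, 0L)
  expect_error(classifySpecies(a), "undefined")
})

test_that("species demarcation uses the 95-96 band", {
  expect_identical(classifySpecies(97.5)$verdict, "same_species")
  expect_identical(classifySpecies(90.0)$verdict, "different_species")
  expect_identical(classifySpecies(95.5)$verdict, "borderline")
  expect_error(classifySpecies(97, low = 96, high = 95), "threshold")
})

test_that("pairwise locus identity matches the substitution count oracle", {
  s <- randomSeq(1500, 42)
  expect_equal(pairwiseLocusIdentity(s, s), 100)
  set.seed(43)
  v <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(v), 15)
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  expect_equal(pairwiseLocusIdentity(s, paste(v, collapse = "")), 99.0,
               tolerance = 1e-6)
  expect_error(pairwiseLocusIdentity(s, ""), "empty")
})
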