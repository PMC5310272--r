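test_that("zero-mutation model yields identical strains and an all-true PA matrix", {
  co <- frozenCohort(3)
  gl <- genomes(co)
  s1 <- as.character(contigs(gl[[1]]))
  for (g in gl[-1]) expect_identical(as.character(contigs(g)), s1)
  expect_true(all(truePAMatrix(co)))
  expect_true(all(trueProfiles(co) == 1L))
})

test_that("same seed and model reproduce an identical cohort", {
  m <- panGenomeModel(nCore = 15, nDispensable = 6, seed = 33)
  a <- simulateCohort(m, 3)
  b <- simulateCohort(m, 3)
  expect_identical(lapply(genomes(a), function(g) as.character(contigs(g))),
                   lapply(genomes(b), function(g) as.character(contigs(g))))
  expect_identical(truePAMatrix(a), truePAMatrix(b))
  expect_identical(trueProfiles(a), trueProfiles(b))
  expect_identical(ape::write.tree(trueTree(a)), ape::write.tree(trueTree(b)))
})

test_that("argument and rate validation rejects bad models", {
  expect_error(simulateCohort(panGenomeModel(seed = 1), 1), "nStrains")
  expect_error(panGenomeModel(lossProb = 1.2), "lossProb")
  expect_error(panGenomeModel(geneLengthRange = c(100, 200)), "multiples of 3")
  expect_error(simulateCohort(panGenomeModel(nCore = 3), 2), "MLST")
})

test_that("per-strain dispensable counts follow the branch-path expectation", {
  m <- panGenomeModel(nCore = 10, nDispensable = 200, gainProb = 0,
                      lossProb = 0.3, snpRate = 0, indelRate = 0, seed = 55)
  co <- simulateCohort(m, 8)
  tr <- trueTree(co)
  # oracle: with gain 0 and all dispensable present at the root, presence
  # probability is (1 - loss)^(#branches root -> leaf)
  depth <- ape::node.depth.edgelength(ape::compute.brlen(tr, 1))[seq_along(tr$tip.label)]
  pa <- truePAMatrix(co)
  disp <- grepl("^disp", rownames(pa))
  for (i in seq_along(tr$tip.label)) {
    p <- (1 - 0.3)^depth[i]
    obs <- sum(pa[disp, tr$tip.label[i]])
    expect_lt(abs(obs - 200 * p), 3 * sqrt(200 * p * (1 - p)) + 1e-9,
              label = sprintf("strain %s count %d vs expectation %.1f",
                              tr$tip.label[i], obs, 200 * p))
  }
})

test_that("core families are present in every strain; MLST loci always exist", {
  co <- smallCohort()
  pa <- truePAMatrix(co)
  core <- !grepl("^disp", rownames(pa))
  expect_true(all(pa[core, ]))
  for (g in genomes(co)) {
    expect_true(all(c("atpA", "dnaE", "dnaK", "fusA", "leuA", "odhA", "rpoB")
                    %in% features(g)$gene_id))
  }
})

test_that("planted substitutions change exactly the edited positions", {
  co <- frozenCohort(2)
  g <- genomes(co)$S01
  # substitution-only specs: equal length, mismatches == planted sub widths
  res <- plantVariants(g, list(variantSpec("core0001", "synonymous", 10),
                               variantSpec("core0002", "stop_gained", 20),
                               variantSpec("atpA", "upstream", -5)))
  s0 <- as.character(contigs(g))[[1]]
  s1 <- as.character(contigs(res$genome))[[1]]
  expect_identical(nchar(s0), nchar(s1))
  nsub <- sum(lengths(strsplit(
    res$expected$nt_change[grepl(">", res$expected$nt_change)], ";")))
  expect_identical(sum(strsplit(s0, "")[[1]] != strsplit(s1, "")[[1]]),
                   as.integer(nsub))
  # indel specs: length change equals the summed signed edit widths
  res2 <- plantVariants(g, list(variantSpec("core0003", "inframe_deletion", 8, 2),
                                variantSpec("core0004", "frameshift", 12, -1),
                                variantSpec("core0005", "inframe_insertion", 9, "GK")))
  s2 <- as.character(contigs(res2$genome))[[1]]
  expect_identical(nchar(s2) - nchar(s0), -6L - 1L + 6L)
})

test_that("planting rejects overlapping edits and out-of-range codons", {
  g <- genomes(frozenCohort(2))$S01
  expect_error(plantVariants(g, list(
    variantSpec("core0001", "inframe_deletion", 10, 2),
    variantSpec("core0001", "synonymous", 11))), "overlap")
  expect_error(plantVariants(g, list(
    variantSpec("core0001", "missense", 10000, "K"))), "out of range")
  expect_error(plantVariants(g, list(
    variantSpec("nope", "missense", 5, "K"))), "no such gene")
})

test_that("empty spec list leaves the genome unchanged", {
  g <- genomes(frozenCohort(2))$S01
  res <- plantVariants(g, list())
  expect_identical(as.character(contigs(res$genome)), as.character(contigs(g)))
  expect_identical(nrow(res$expected), 0L)
})

test_that("emitCohort writes a complete file set that round-trips", {
  co <- frozenCohort(2)
  d <- withr::local_tempdir()
  emitCohort(co, d)
  expect_true(all(file.exists(file.path(
    d, c("S01.fasta", "S01.gff3", "S02.fasta", "S02.gff3",
         "truth_pa_matrix.tsv", "truth_profiles.tsv", "truth_tree.nwk")))))
  gl <- readCohortDir(d)
  expect_identical(as.character(contigs(gl$S01)),
                   as.character(contigs(genomes(co)$S01)))
  # PA truth matches a recount from the emitted GFF3 features
  pa <- utils::read.delim(file.path(d, "truth_pa_matrix.tsv"), row.names = 1)
  for (id in names(gl)) {
    expect_setequal(rownames(pa)[pa[[id]] == 1], features(gl[[id]])$gene_id)
  }
})
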