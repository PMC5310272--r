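LOCI <- c("atpA", "dnaE", "dnaK", "fusA", "leuA", "odhA", "rpoB")

test_that("the 26 reference profiles collapse to 13 sequence types", {
  st <- assignSTs(refProfiles())
  expect_identical(nrow(st$stProfiles), 13L)
  expect_identical(nrow(st$strains), 26L)
})

test_that("single-linkage at Hamming <= 2 reproduces the published nine groups", {
  prof <- refProfiles()
  st <- clusterGroups(assignSTs(prof), maxDistance = 2)
  expect_identical(length(unique(st$strains$group)), 9L)
  # the partition (and the smallest-ST labelling) matches the published groups
  expect_identical(st$strains$group, prof$published_group)
  # the three published ST merges, via the published ST labels
  pub <- stats::setNames(prof$published_st, prof$strain)
  grp <- stats::setNames(st$strains$group, st$strains$strain)
  groupOf <- function(publishedST)
    unique(grp[names(pub)[pub == publishedST]])
  expect_identical(groupOf(4), groupOf(5))
  expect_identical(groupOf(4), groupOf(11))
  expect_identical(groupOf(8), groupOf(13))
  expect_identical(groupOf(9), groupOf(10))
})

test_that("group count saturates with the linkage threshold", {
  st <- assignSTs(refProfiles())
  counts <- vapply(0:7, function(d)
    length(unique(clusterGroups(st, d)$strains$group)), integer(1))
  expect_identical(counts[1], 13L)  # one group per ST at distance 0
  expect_identical(counts[8], 1L)   # saturating threshold
  expect_true(all(diff(counts) <= 0L))
})

test_that("the two lysine/glutamate producer profiles differ at exactly one locus", {
  prof <- refProfiles()
  b253 <- unlist(prof[prof$strain == "B253", LOCI])
  b1 <- unlist(prof[prof$strain == "B1", LOCI])
  expect_identical(b253, stats::setNames(c(1L,2L,4L,7L,9L,3L,2L), LOCI))
  expect_identical(profileHamming(b253, b1), 1L)
  expect_identical(profileHamming(b1, b1), 0L)
  # positionwise count oracle for two maximally distant reference tuples
  st1 <- c(1L,1L,1L,1L,1L,1L,1L); st7 <- c(2L,5L,3L,5L,4L,3L,3L)
  expect_identical(profileHamming(st1, st7), sum(st1 != st7))
  expect_error(profileHamming(1:6, 1:7), "7 loci")
})

test_that("the presumed ancestor is the nearest wild type in the group", {
  prof <- refProfiles()
  st <- clusterGroups(assignSTs(prof), 2)
  wt <- stats::setNames(prof$wild_type, prof$strain)
  expect_identical(presumedAncestor("B253", st, wt)$ancestor, "B1")
  self <- presumedAncestor("B1", st, wt)
  expect_identical(self$ancestor, "B1")
  expect_identical(self$distance, 0L)
  # the arginine-producer group has no sequenced wild type
  noanc <- presumedAncestor("AR1", st, wt)
  expect_true(is.na(noanc$ancestor))
  expect_match(noanc$reason, "no wild-type")
})

test_that("allele registry numbering is discovery-ordered and idempotent", {
  sc <- mlstScheme(stats::setNames(
    Biostrings::DNAStringSet(rep("ATGAAACCCGGGTTTTAA", 7)), LOCI))
  a1 <- assignAllele(sc, "atpA", "ATGAAACCCGGGTTTTAA")
  expect_identical(a1$allele, 1L)
  a1b <- assignAllele(a1$scheme, "atpA", "ATGAAACCCGGGTTTTAA")
  expect_identical(a1b$allele, 1L)
  expect_identical(a1b$scheme@registry, a1$scheme@registry)
  a2 <- assignAllele(a1$scheme, "atpA", "ATGAAACCCGGGTTCTAA")
  expect_identical(a2$allele, 2L)
  expect_error(assignAllele(sc, "atpA", "ATGNNNTAA"), "ambiguity")
  expect_error(assignAllele(sc, "gyrB", "ATG"), "unknown locus")
})

test_that("locus extraction returns the strain's own allele on either strand", {
  co <- smallCohort()
  g <- genomes(co)$S02
  ref <- cdsSeq(genomes(co)$S01)[["atpA"]]   # reference from another strain
  own <- as.character(cdsSeq(g)[["atpA"]])
  expect_identical(extractLocus(g, ref), own)
  # a planted 3-substitution allele is returned verbatim with known identity
  res <- plantVariants(g, list(variantSpec("dnaK", "missense", 20, oneStepMissense(g, "dnaK", 20)),
                               variantSpec("dnaK", "synonymous", 40),
                               variantSpec("dnaK", "synonymous", 60)))
  refK <- as.character(cdsSeq(g)[["dnaK"]])
  gotK <- extractLocus(res$genome, refK)
  expect_identical(gotK, as.character(cdsSeq(res$genome)[["dnaK"]]))
  nsub <- sum(lengths(strsplit(res$expected$nt_change, ";")))
  hit <- bestGenomeHit(refK, res$genome)
  expect_equal(hit$identity, 100 * (450 - nsub) / 450, tolerance = 1e-6)
  expect_warning(out <- extractLocus(g, paste(rep("ACGTT", 100), collapse = "")),
                 "not found")
  expect_true(is.na(out))
})

test_that("ST equality is equivalent to zero Hamming distance", {
  set.seed(5)
  profs <- matrix(sample(1:3, 7 * 40, replace = TRUE), 40, 7,
                  dimnames = list(sprintf("s%02d", 1:40), LOCI))
  st <- assignSTs(profs)
  sts <- st$strains$ST
  for (i in 1:39) for (j in (i + 1):40) {
    expect_identical(sts[i] == sts[j],
                     profileHamming(profs[i, ], profs[j, ]) == 0L)
  }
})

test_that("simulated typing recovers the truth profiles and parent ancestry", {
  co <- smallCohort()
  co <- deriveStrain(co, "S04", "PX", list(
    variantSpec("core0002", "missense", 15, oneStepMissense(genomes(co)$S04, "core0002", 15))))
  sc <- mlstSchemeFromGenome(genomes(co)$S01)
  ty <- typeStrains(genomes(co), sc)
  got <- as.matrix(ty$profiles[, LOCI])
  rownames(got) <- ty$profiles$strain
  storage.mode(got) <- "integer"
  truth <- trueProfiles(co)
  # registry numbering is discovery-ordered in both; compare directly
  expect_identical(unname(got), unname(truth[rownames(got), ]))
  st <- clusterGroups(assignSTs(ty$profiles), 2)
  wt <- stats::setNames(grepl("^S", rownames(truth)), rownames(truth))
  anc <- presumedAncestor("PX", st, wt)
  expect_identical(anc$ancestor, "S04")
  expect_identical(anc$distance, 0L)
})
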