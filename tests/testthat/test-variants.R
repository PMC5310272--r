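test_that("gene pairing matches the simulator's correspondence", {
  co <- smallCohort()
  gp <- pairGenes(genomes(co)$S01, genomes(co)$S02)
  # simulated orthologs share family ids; pairing must agree
  expect_true(all(gp$pairs$anc_gene == gp$pairs$der_gene))
  shared <- intersect(features(genomes(co)$S01)$gene_id,
                      features(genomes(co)$S02)$gene_id)
  expect_setequal(gp$pairs$anc_gene, shared)
  expect_setequal(gp$anc_only,
                  setdiff(features(genomes(co)$S01)$gene_id, shared))
})

test_that("identical genomes yield zero variants; a dropped gene moves to the absence report", {
  co <- frozenCohort(2)
  res <- compareStrainPair(genomes(co)$S02, genomes(co)$S01)
  expect_identical(nrow(res$variants), 0L)
  expect_identical(res$summary$total, 0L)
  # drop one gene from the derived strain
  g2 <- genomes(co)$S02
  keep <- features(g2)$gene_id != "core0002"
  g2b <- annotatedGenome("S02b", as.character(contigs(g2)),
                         features(g2)[keep])
  res2 <- compareStrainPair(g2b, genomes(co)$S01, includeIntergenic = FALSE)
  expect_identical(res2$presence$gene, "core0002")
  expect_identical(res2$presence$status, "absent_in_derived")
  expect_false("core0002" %in% res2$pairs$pairs$anc_gene)
})

test_that("classical producer mutations are annotated with their exact notation", {
  co <- frozenCohort(3)
  g <- genomes(co)$S01
  cds <- cdsSeq(g)
  # engineer recognizable backgrounds, then plant the canonical changes:
  # Gln37* nonsense, Gly359Asp missense (via a long gene), a two-codon
  # in-frame deletion, a 1-nt frameshift deletion, and upstream-9 C->T
  longGene <- names(cds)[which(BiocGenerics::width(cds) >= 3 * 361)][1]
  skip_if(is.na(longGene), "no gene long enough in fixture")
  aaAt <- function(gene, ci) substr(as.character(translateCDS(cds[gene])[[1]]), ci, ci)
  specs <- list(
    variantSpec("core0001", "stop_gained", 37),
    variantSpec(longGene, "missense", 359,
                oneStepMissense(g, longGene, 359)),
    variantSpec("core0002", "inframe_deletion", 329 %% 90 + 10, 2),
    variantSpec("core0003", "frameshift", 191 %% 90 + 10, -1),
    variantSpec("core0004", "upstream", -9))
  res <- plantVariants(g, specs)
  exp <- res$expected
  expect_identical(exp$effect[1], "stop_gained")
  expect_identical(exp$protein_notation[1],
                   sprintf("p.%s37*", strainTrace:::aa3(aaAt("core0001", 37))))
  expect_identical(exp$effect[2], "missense")
  expect_match(exp$protein_notation[2], "^p\\.[A-Z][a-z]{2}359[A-Z][a-z]{2}$")
  expect_identical(exp$effect[3], "inframe_deletion")
  expect_match(exp$protein_notation[3], "del$")
  expect_identical(exp$effect[4], "frameshift")
  expect_match(exp$protein_notation[4], "fs$")
  expect_identical(exp$effect[5], "upstream")
  expect_identical(exp$upstream_offset[5], -9L)
  expect_match(exp$nt_change[5], "^upstream-9 [ACGT]->[ACGT]$")
  # and the caller reproduces every call byte-for-byte
  der <- res$genome; der@strainID <- "derived"
  got <- compareStrainPair(der, g)$variants
  keyf <- function(d) sort(paste(d$gene, d$effect, d$nt_change, d$protein_notation))
  expect_identical(keyf(got), keyf(exp2 <- cbind(exp)))
})

test_that("swapping the comparison direction preserves the variant count", {
  co <- frozenCohort(3)
  g <- genomes(co)$S01
  res <- plantVariants(g, list(
    variantSpec("core0001", "missense", 20, oneStepMissense(g, "core0001", 20)),
    variantSpec("core0002", "inframe_deletion", 30, 1),
    variantSpec("core0003", "frameshift", 40, 2)))
  der <- res$genome; der@strainID <- "der"
  fwd <- compareStrainPair(der, g)$variants
  rev <- compareStrainPair(g, der)$variants
  expect_identical(nrow(fwd), nrow(rev))
  # the substitution inverts ref/alt
  fsub <- fwd$nt_change[grepl(">", fwd$nt_change)]
  rsub <- rev$nt_change[grepl(">", rev$nt_change)]
  flip <- function(x) sub("^c\\.(\\d+)([ACGT])>([ACGT])$", "c.\\1\\3>\\2", x)
  expect_setequal(flip(fsub), rsub)
})

test_that("frameshift is called iff the coding indel width is not a multiple of 3", {
  co <- frozenCohort(2)
  g <- genomes(co)$S01
  for (w in c(-4L, -2L, -1L, 1L, 2L, 4L)) {
    res <- plantVariants(g, list(variantSpec("core0001", "frameshift", 25, w)))
    expect_identical(res$expected$effect, "frameshift", label = paste("width", w))
  }
  for (nc in 1:2) {
    res <- plantVariants(g, list(variantSpec("core0001", "inframe_deletion", 25, nc)))
    expect_identical(res$expected$effect, "inframe_deletion")
  }
  expect_error(plantVariants(g, list(variantSpec("core0001", "frameshift", 25, 3))),
               "multiple of 3")
})

test_that("randomized planted edits of all kinds round-trip byte-exactly", {
  co <- frozenCohort(2)
  g <- genomes(co)$S01
  set.seed(202)
  kinds <- c("missense", "synonymous", "stop_gained", "inframe_deletion",
             "inframe_insertion", "frameshift", "upstream")
  genesAvail <- setdiff(features(g)$gene_id, character())
  for (round in 1:6) {
    genesPick <- sample(genesAvail, 8)
    specs <- lapply(seq_along(genesPick), function(i) {
      gn <- genesPick[i]
      kind <- sample(kinds, 1)
      ncod <- nchar(as.character(cdsSeq(g)[[gn]])) %/% 3
      ci <- sample(5:(ncod - 5), 1)
      switch(kind,
        missense = variantSpec(gn, kind, ci, oneStepMissense(g, gn, ci)),
        synonymous = variantSpec(gn, kind, ci),
        stop_gained = variantSpec(gn, kind, ci),
        inframe_deletion = variantSpec(gn, kind, ci, sample(1:3, 1)),
        inframe_insertion = variantSpec(gn, kind, ci,
          paste(sample(c("G","K","A","L","S"), sample(1:2, 1)), collapse = "")),
        frameshift = variantSpec(gn, kind, ci, sample(c(-2L,-1L,1L,2L), 1)),
        upstream = variantSpec(gn, kind, -sample(1:100, 1)))
    })
    specs <- Filter(Negate(is.null), specs)
    res <- tryCatch(plantVariants(g, specs), error = function(e) NULL)
    if (is.null(res)) next  # rare: synonymous impossible at a Met/Trp codon
    der <- res$genome; der@strainID <- "der"
    got <- compareStrainPair(der, g)$variants
    keyf <- function(d) sort(paste(d$gene, d$effect, d$nt_change,
                                   d$protein_notation, d$upstream_offset))
    expect_identical(keyf(got), keyf(res$expected))
  }
})

test_that("pathway report joins notations per gene and omits quiet genes", {
  co <- frozenCohort(2)
  g <- genomes(co)$S01
  res <- plantVariants(g, list(
    variantSpec("core0001", "missense", 20, oneStepMissense(g, "core0001", 20)),
    variantSpec("core0001", "synonymous", 40),
    variantSpec("core0002", "stop_gained", 15)))
  der <- res$genome; der@strainID <- "der"
  vt <- compareStrainPair(der, g)$variants
  rep <- pathwayReport(vt, c("core0001", "core0002", "core0003"))
  expect_identical(rep$gene, c("core0001", "core0002"))
  expect_identical(rep$n_variants, c(2L, 1L))
  expect_match(rep$notations[1], "; ")
  # the report strings byte-match the planted expectations
  expect_true(all(unlist(strsplit(rep$notations, "; ")) %in%
                    res$expected$protein_notation))
  expect_error(pathwayReport(vt, character()), "empty gene list")
})
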