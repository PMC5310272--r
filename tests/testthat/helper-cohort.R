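# Shared fixtures: small simulated cohorts, memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small diverged cohort used across modules.
smallCohort <- function() {
  memo("small", simulateCohort(
    panGenomeModel(nCore = 40, nDispensable = 20, seed = 101,
                   lossProb = 0.15, gainProb = 0.05), nStrains = 5))
}

# Zero-mutation cohort: all strains byte-identical.
frozenCohort <- function(n = 3) {
  memo(paste0("frozen", n), simulateCohort(
    panGenomeModel(nCore = 12, nDispensable = 4, gainProb = 0, lossProb = 0,
                   snpRate = 0, indelRate = 0, seed = 7), nStrains = n))
}

# Uniform substitutions over a genome at an exact count (ANI oracles).
plantedSubGenome <- function(genome, rate, seed) {
  set.seed(seed)
  ctgs <- as.character(contigs(genome))
  for (nm in names(ctgs)) {
    s <- strsplit(ctgs[[nm]], "")[[1]]
    n <- round(length(s) * rate)
    if (n > 0) {
      pos <- sample.int(length(s), n)
      bases <- c("A", "C", "G", "T")
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1), "")
    }
    ctgs[[nm]] <- paste(s, collapse = "")
  }
  annotatedGenome(paste0(strainID(genome), "_mut"), ctgs, features(genome))
}

# Pick a residue reachable from the gene's codon `ci` by exactly one
# nucleotide substitution (guarantees a 1-nt missense edit).
oneStepMissense <- function(genome, gene, ci) {
  gc11 <- Biostrings::getGeneticCode("11")
  cds <- as.character(cdsSeq(genome)[[gene]])
  codon <- substr(cds, 3 * ci - 2, 3 * ci)
  ref <- unname(gc11[codon])
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      aa <- unname(gc11[alt])
      if (aa != ref && aa != "*") return(aa)
    }
  }
  stop("no one-step missense available")
}

# The packaged 26-strain reference profile table.
refProfiles <- function() memo("refProfiles", cglutamicumProfiles())
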