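---
title: "Methods: comparative genomics and ancestor attribution with strainTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics and ancestor attribution with strainTrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainTrace)
```

## The problem

Industrial amino-acid producers of *Corynebacterium glutamicum* (and the
strains historically filed under *Brevibacterium* or other *Corynebacterium*
species names) were bred by decades of random mutagenesis and selection, and
the breeding records are often lost. Understanding which mutations actually
matter for production requires comparing each producer against the right
reference: its own wild-type ancestor, not the distantly related type
strain. Compared against the type strain a producer shows tens of thousands
of differences, almost all of which are ordinary between-lineage divergence;
compared against its true ancestor the list shrinks to a few hundred, among
which the production-relevant changes stand out.

strainTrace implements that attribution workflow end to end:

1. **Species membership** — fragment-based average nucleotide identity
   (ANI) with the 95–96 % demarcation band; conspecific cohorts sit above
   97 %.
2. **Ancestor attribution** — seven-locus MLST (atpA, dnaE, dnaK, fusA,
   leuA, odhA, rpoB): distinct allelic profiles define sequence types
   (STs), profiles cluster into groups, and the nearest wild-type strain in
   a producer's group is its presumed ancestor.
3. **Breeding trajectory** — within-group phylogenies from core-gene SNP
   distances (and cohort-wide alignment-free composition-vector trees).
4. **Variant annotation** — global alignment of each ortholog pair between
   producer and ancestor, with HGVS-style protein consequences, upstream
   and intergenic records, and per-pathway report tables.
5. **Pan-genome context** — ortholog clustering, rarefaction and the three
   asymptotic fits that decide whether the species' pan-genome is open.

A seeded simulator generates whole cohorts with known truth so that every
stage is testable without downloading genomes.

## The cohort simulator

`simulateCohort()` evolves gene content along a random coalescent-style
bifurcating genealogy (`ape::rcoal`). The model treats all rates as
**per-branch** quantities: each branch applies per-family gene loss/gain
(Bernoulli with `lossProb`/`gainProb`), per-site substitutions (binomial at
`snpRate`, drawn uniformly over the three alternative bases), and one-codon
in-frame indels (Poisson at `indelRate`). The coalescent branch lengths on
the truth tree are therefore decorative; what matters for divergence is the
number of branches separating two strains. This is the simplest model
consistent with treating a "branch" as one mutational epoch, and it makes
the dispensable-gene expectation exactly enumerable from the tree
(presence probability $(1-p_\mathrm{loss})^{d}$ for a leaf $d$ branches
below the root when `gainProb = 0`), which the test suite exploits.

Structural choices:

* Genes are non-overlapping, on random strands, separated by intergenic
  spacers of 201–300 nt. With the default 100-nt upstream window this
  guarantees upstream windows never reach into a neighbouring gene, keeping
  effect classification unambiguous.
* Every gene is a well-formed CDS (ATG, no in-frame stop, one stop codon);
  substitutions that would create an internal stop are redrawn. The
  wild-type cohort therefore translates cleanly, and untranslatable genes
  found by the clustering stage are genuinely anomalous (they arise only
  from planted frameshifts/nonsense edits in producer strains).
* The seven MLST loci are fixed-length (450 nt) core genes; allele
  variation arises from the same substitution process, so typing a
  simulated cohort exercises the full extraction-plus-registry path.
* Defaults (2,000 core + 500 dispensable families, gene lengths
  300–1500 nt, `snpRate` 0.002, `lossProb` 0.08, `gainProb` 0.02) give
  eight-strain cohorts of realistic genome size (≈3 Mb) whose pairwise ANI
  stays in the conspecific range, mirroring an industrial species cohort.
  Eight strains is also the wild-type cohort size we consider the
  reference use case.

What the simulator does **not** emulate: prophages, transposons, plasmids,
rearrangements (gene order is conserved), horizontal transfer of divergent
sequence, assembly fragmentation and annotation error. Passing tests on
simulated cohorts therefore demonstrate correctness of the algorithms under
clean orthology and conserved synteny, not robustness to noisy draft
assemblies.

Producer strains are derived with `plantVariants()`/`deriveStrain()`, which
apply explicit variant specs (missense, synonymous, nonsense, in-frame
indel, frameshift, upstream) and return the expected calls — the byte-exact
HGVS strings the caller must reproduce. Expected and observed calls are
computed by the same normalization and formatting helpers; independence of
the check comes from the two sides taking entirely different routes to the
event list (direct spec expansion versus genome rebuild, re-alignment and
alignment parsing).

## ANI

`computeANI()` is the classical fragment formulation: 1020-nt
non-overlapping query fragments, best seeded hit per fragment against the
reference (exact 15-mer seeds on both strands, banded extension with band
32, affine gaps open 10 / extend 1, match +1 / mismatch −1), and the mean
identity over fragments passing ≥30 % identity and ≥70 % coverage.
Symmetric averaging of the two directions is on by default, since nothing
in the underlying question distinguishes query from reference. A pair with
no passing fragments yields an explicitly flagged undefined result rather
than a silent zero. Absolute values on real data may differ slightly (by
well under a percentage point) from MUMmer-based tools; the demarcation
logic is unaffected.

## MLST

Loci are extracted in silico by the same seeded-alignment engine
(full-length coverage ≥95 %, identity ≥90 %); alleles are integers assigned
in discovery order, with exact-sequence registry matching. STs are numbered
in first-appearance order. The packaged 26-strain reference table keeps the
published ST numbers in a separate `published_st` column because those
numbers come from an external registry's discovery order, not from the
table itself.

Grouping is single-linkage over profile Hamming distance with a threshold
of ≤2 differing loci. The reference dendrogram-derived partition of the 26
strains (13 STs, 9 groups) is reproduced exactly at this threshold — and at
no other small integer: distance 0 or 1 splits the known groups, distance 3
is still consistent but the test suite pins ≤2 as the operational rule. The
presumed ancestor of a strain is the wild-type group member with minimal
profile distance; ties break lexicographically and are reported, and a
group without any wild-type member returns an explicit no-ancestor result
(the pipeline then falls back to the nearest group member with a recorded
caveat).

## Pan-genome

Ortholog clustering is single-linkage over the protein-similarity graph:
translated CDSs (bacterial table 11), candidate pairs from shared amino
acid 5-mers, banded global alignment, and an edge when identity ≥50 % and
bidirectional coverage ≥50 %. Genes with internal stops are quarantined and
reported. Single-linkage at these permissive thresholds is a deliberate
stand-in for heavier pipelines; thresholds are exposed in the
configuration.

`rarefy()` draws random genome orderings (default 100 permutations) and
records cumulative pan size, core size and new-gene count. `fitCurves()`
fits, on the per-x **medians** (means are available; on monotone counts
over ≥25 permutations the two give practically identical fits):

* pan genome: $y = A\,x^{\gamma} + B$ (Heaps-style; open iff
  $\gamma > 0$),
* core genome: $y = C\,e^{-\delta x} + \Omega$ ($\Omega$ is the core-gene
  asymptote),
* new genes: $y = K\,x^{-\alpha}$, fitted excluding $x = 1$, whose "new
  genes" are the whole first genome.

Fitting is Levenberg–Marquardt (`minpack.lm::nlsLM`) with the documented
initializations ($A = B = $ pan(1), $\gamma = 0.5$; $\delta = 0.5$,
$\Omega = $ core(N); log–log regression for the power law). Noiseless
self-generated data are recovered to machine precision, which the
acceptance suite asserts at $10^{-6}$ relative. Constant trajectories
(e.g. identical genomes) take an explicit degenerate path with
$\gamma = 0$ and a "closed" verdict instead of a spurious fit;
non-convergence raises an error carrying the start values, never a silent
default.

## Phylogenies

Composition vectors score every observed amino acid $k$-word ($k = 6$ by
default, the CVTree convention; 5–7 supported) as $(f - f_0)/f_0$ against
the $(k-2)$-order Markov prediction
$f_0(a_1..a_k) = f(a_1..a_{k-1})\,f(a_2..a_k)/f(a_2..a_{k-1})$. Words that
are predicted but unobserved are omitted from the sparse vector (score 0
rather than −1); this keeps vectors proportional to proteome size and
changes distances negligibly for the close cohorts targeted here.
Distance is $(1 - \cos)/2$ over the union of words.

Core-SNP matrices come from per-cluster alignments of single-copy core
genes (reusing the ortholog clusters) projected onto the first strain's
gene coordinates: a site is kept when it shows ≥2 states and no strain has
a gap — the core-site rule, which also makes the star-projection exact,
since excluded columns are exactly those where projection could be
ambiguous. This is an annotation-aware substitute for whole-genome k-mer
anchoring tools and is documented as such.

Both distance sources feed the same neighbor-joining builder (`ape::nj`
behind `njTree()`): taxa are sorted by label first so ties break
deterministically, negative branch lengths are clamped to zero with a
warning, two taxa return a trivial tree by a separate path, and an
optional outgroup roots the tree. NJ is exact on additive matrices, which
the test suite verifies on random trees up to eight taxa. When both a CV
tree and a SNP tree are produced for the same strains the package reports
both and leaves adjudication to the analyst; `phangorn::RF.dist` is the
suggested comparison.

## Variant calling

`pairGenes()` clusters the two strains' genes at the **nucleotide** level
(identity ≥70 %, coverage ≥80 %), so genes carrying planted nonsense or
frameshift changes still pair even though their proteins truncate.
Single-copy shared clusters become alignment pairs; everything else is a
presence/absence record, not a variant row.

Per pair, a banded global alignment is parsed into events: adjacent gap
columns merge into single indels, and indels are left-aligned against the
ancestor sequence before notation, so that equivalent placements in repeat
runs collapse to one canonical call. Protein consequences:

* substitutions are annotated per codon (multiple substitutions in one
  codon jointly), as `p.Gly359Asp`, `p.Gln37*`, `p.Leu329=` and so on;
* in-frame indels are annotated by the longest-common-prefix/suffix diff of
  the two translations (`p.Leu329_Gln330del`, `p.Lys20_Arg21insGlyLys`,
  delins when the event is not codon-aligned);
* frameshifts are `p.Ala191fs` — the ancestor residue at the codon of the
  first (left-normalized) shifted nucleotide, without an extension length;
* changes in the 100-nt window before the start codon (strand-aware) are
  upstream records with a negative offset, rendered `upstream-9 C->T` /
  `upstream-1 delA`. The window width is a configuration choice: observed
  regulatory offsets in this literature are small (−1, −9), and 100 nt
  comfortably covers bacterial promoter elements without reaching the
  next gene under the simulator's spacer floor.

`compareStrainPair()` adds intergenic blocks between syntenic anchor pairs
(events already covered by an adjacent gene's upstream window are skipped
to avoid double counting) and returns the variant table plus summary
counts. One coordinate system is used throughout: ancestor protein/CDS
numbering.

## Pipeline, determinism and problem sizes

`runPipeline()` chains typing → grouping → ancestor selection → per-group
SNP trees → per-strain variant tables, records per-stage failures without
aborting the cohort, and stamps the report with a configuration hash that
covers every threshold, the seed and a digest of each input genome —
rerunning an identical configuration reproduces the report exactly. All
randomness (simulation, rarefaction permutations) flows from single
integer seeds.

The test and acceptance suites run at sizes chosen to exercise the
methods while staying desk-scale: unit fixtures use cohorts of 12–70 gene
families, the property suites use 40–230 families, and one acceptance
check runs the full reference condition — eight strains at 2,500 gene
families (≈3 Mb genomes) through simulation, typing, grouping, SNP trees
and producer-versus-ancestor variant calling — asserting completion within
ten minutes on a single CPU (it takes roughly two and a half).

## Known limitations

* Fragment ANI with k-mer seeding assumes the compared genomes share
  long near-identical stretches; below roughly 85 % identity seeds thin
  out and identities are dominated by the no-hit filter. This is the
  intended operating range (species demarcation), not a general aligner.
* Single-linkage ortholog clustering can chain paralog families through
  intermediate sequences at permissive thresholds; the simulator does not
  generate such chains, so this is untested territory inherited from the
  method choice, flagged rather than solved.
* The variant caller compares assemblies; it does not model read-level
  evidence, and large structural variants (inversions, island insertions)
  surface only as presence/absence or synteny breaks.
* Group labels, ST numbers and cluster ids are deterministic but
  registry-relative; they are stable within an analysis, not global
  nomenclature.
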