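---
title: "Read-depth copy-number genotyping, allele calling and gene profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth copy-number genotyping, allele calling and gene profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcnv)
```

# The problem

Short-read whole-genome sequencing panels carry copy-number information in
their depth of coverage: a segment present in four copies attracts roughly
twice the reads of a diploid segment. `rdcnv` turns per-window read depth in
a population panel into per-sample *integer copy-number confidence
intervals*, groups those intervals into population *copy-number alleles*,
classifies windows and regions as diploid, fixed duplication (FD — every
individual shares the same non-diploid copy number), copy-number variant
(CNV — more than one confidently distinguishable allele) or unclassified,
profiles protein-coding genes by their copy-number state, and tests
cross-species conservation and disease-gene enrichment by permutation.

Every stage is driven by plain containers (BED-style data frames, numeric
matrices) and the package ships a fully seeded synthetic-data generator, so
the entire pipeline can be exercised and validated without any external
sequencing data.

# Windowing and raw copy number

The reference is first masked: all 78-bp k-mers with more than 20 exact
placements (both strands) are masked, and masked intervals are widened by a
78-bp flank so windows bordering repeats do not leak repeat-attracted reads.
The remaining sequence is cut into non-overlapping windows of exactly 1,000
*unmasked* bases (`build_windows()`); a window may therefore span masked
gaps and be longer than 1 kbp on the reference. A trailing remainder under
1,000 unmasked bases emits no window, keeping the per-window read-depth
variance homogeneous. Coordinates are 0-based half-open throughout.

Per sample, depth is scaled to a continuous **raw copy number**:

1. *Control regions* — windows are trimmed iteratively (outside
   mean ± 3 sd, recomputed each round) until no window is removed or the
   index of dispersion (variance/mean) stabilizes below 1e-3; the retained,
   Poisson-like windows are taken as diploid. The rule assumes the
   non-diploid fraction of the genome is modest (real genomes: under ~10%);
   with much heavier contamination the first trimming round cannot separate
   the modes, and `select_control_regions()` aborts with a degenerate-sample
   error when over 90% of windows are shed.
2. *GC correction* — windows are binned by GC fraction (2% bins) and scaled
   by the ratio of the global control median to the bin's control median;
   bins with fewer than 20 control windows inherit the nearest populated
   bin's factor. Binned median scaling was chosen over loess because it is
   deterministic, cheap, and adequate at 1-kbp granularity.
3. *Scaling* — `raw = 2 * depth / mean(control depth)`, per sample, so each
   sample is normalized against its own coverage. The residual noise scale
   `sigma_CR = sd(raw in control windows)` calibrates everything downstream.

# The copy-number HMM

Hidden states are integer copy numbers 0–20 plus three high-copy interval
states (21–100, 101–500, 501–1000), where copy number and depth noise are
too entangled to resolve single integers. Emissions are Normal with mean
`N` and standard deviation `sigma_N = sigma_CR * N / 2`; state 0 uses the
floor `sigma_CR / 2`, the smallest nonzero width in the family, because the
formula degenerates at N = 0. Interval states emit a mixture of their
member integers' Normals, uniform-weighted by default (weights can be
supplied if a genome-wide raw-CN histogram is available to estimate them).

The transition matrix — and only the transition matrix — is trained by
Baum–Welch on a seeded random draw of held-out samples (default 5), which
are excluded from all downstream calls. The initial matrix is
diagonal-dominant (0.9 self-transition), the initial state distribution is
uniform, and training stops when the log-likelihood gain drops below the
tolerance; the likelihood trace is returned and is non-decreasing (EM
guarantee, asserted in the tests). Smoothing posteriors come from the exact
forward–backward recursion with per-step scaling; correctness is pinned
against brute-force path enumeration on all short tracks in the test suite.

Two refinements follow:

* **Population re-genotyping** — the prior for each window is the average
  posterior across all samples over five consecutive windows centered on
  the window (truncated at chromosome ends). Because decoding used a
  uniform state prior, the posterior is proportional to the likelihood, and
  the corrected probability is the renormalized product `posterior x
  prior`. When prior and posterior have disjoint support the uncorrected
  posterior is kept with a warning. When all samples agree, the correction
  never changes the call.
* **99% confidence intervals** — starting at the most probable state, the
  contiguous interval grows toward whichever adjacent state carries more
  probability (ties toward the lower copy number) until the cumulative
  probability reaches 0.99, e.g. (3) → (3–4) → (3–5). Keeping the set
  contiguous is what makes it expressible as an interval; a literal
  rank-all-states reading could produce non-contiguous sets. High-copy
  interval states absorb as their upper bound.

# Allele calling and window classification

At each window the per-sample intervals are grouped by an iterated majority
procedure (`call_alleles()`): seed on the most common integer (ties: the
lowest), assign the allele interval as the integers shared by ≥ 90% of the
seeded samples (the comparison is `count >= 0.9 * n`, so 18/20 qualifies),
absorb any unassigned sample whose interval overlaps the allele interval,
and repeat on the remainder. The procedure is deliberately conservative:
only samples whose 99% interval is cleanly separable from the major allele
found their own allele.

Windows with more than one allele are CNV (gain / loss / gain–loss by
whether some allele interval lies entirely above and/or below 2; alleles
containing 2 count as reference-like). Single-allele windows containing 2
are diploid; otherwise they are FD when no individual interval spans more
than three copy numbers — read here as *containing more than three
integers*, so [3,5] is acceptable and [3,6] is not; the range-difference
reading is available via `span_rule = "range"` — and unclassified when the
intervals are too wide to trust. A single allele fixed *below* 2 is
reported as FD with a `loss` subtype annotation. Consecutive same-category
windows merge into regions within chromosomes (`merge_regions()`).

# Gene profiles

Genes enter as exon tables of the main isoform. A gene overlapping a
non-diploid region by at least 1 coding bp is *partial*; at ≥ 90% of its
coding length it is *within*; within genes whose copy number is constant
along the gene in at least half the samples — constant meaning the
sample's window intervals share at least one integer, i.e. their
intersection is non-empty — get a gene-level allele call on those
intersections: one gene allele makes a *complete FD* gene, more than one a
*complete CNV* gene; within genes failing the constancy rule are
*composite*. Only windows overlapping exonic sequence count as covering
the gene. When a gene crosses both FD and CNV regions the larger coding
fraction decides its type, ties to CNV (the more conservative choice for
claims of fixation). Non-constant samples are excluded from the gene-level
allele call and cannot veto completeness once the half-samples rule is met.

# Cross-species comparison and permutation tests

Gene profiles of two species are crossed over one-to-one ortholog pairs
(`crosstab_profiles()`). Conservation of non-diploidy is tested by
excluding diploid–diploid pairs, counting pairs whose members match at the
FD/CNV class level, and shuffling one species' categories across the
retained genes (default 10,000 rounds); disease enrichment shuffles the
scope label (non-diploid, or profile-changed between species) across the
gene universe and counts disease-annotated qualifying genes. DisGeNET-style
score-bearing annotations are filtered at score ≥ 0.06 (curated sources);
GWAS-style entries (no score) pass through, with reported and mapped gene
columns unioned upstream. P-values use the add-one estimator
`(1 + #[null ≥ observed]) / (N + 1)` and can never be zero.

One property worth knowing: when both species contain diploid genes, the
diploid–diploid exclusion makes the retained pairs' categories dependent,
and the shuffle null is then stochastically *larger* than an
independence-generated observed statistic — the test is conservative under
that null. The calibration suite therefore checks type-I error on a focal
gene set without diploid genes, where the shuffle null is exact; there the
rejection rate at α = 0.05 sits inside 0.05 ± 0.01.

# Sample quality control

`qc_stats()` reports, per sample, the control-region standard deviation,
the one-sample Kolmogorov–Smirnov statistic against a Normal fitted to the
control raw CN, the Pearson correlation of neighboring windows (within
chromosomes), and mean raw coverage. The exclusion thresholds are sd > 0.5,
KS < 0.03, correlation > 0.15, coverage < 11.7x. The KS direction — *low*
statistics excluded — is kept exactly as published, with
`ks_direction = "high"` to invert it. Note its scale-dependence: the KS
statistic of a genuinely Gaussian control set decays as ~0.8/sqrt(n), so at
genome-scale control sets (tens of thousands of windows) every clean sample
falls below 0.03 and the printed rule only makes sense where real data
deviate measurably from normality; the package's null QC checks use
control sets of ~120 windows, where clean samples clear the bar. PCA
outlier screening replaces the published visual inspection with a
deterministic surrogate: at most two rounds of flagging samples beyond
median + 6 MAD of the PC1–PC2 distance from the component-wise median;
flags are returned, exclusion stays a user decision.

# The synthetic-data generator

`sim_spec()` fixes the study conditions: by default 30x mean coverage and
`sigma_CR = 0.3`, matching a high-coverage short-read panel. Loci carry
1–3 copy-number alleles at stated frequencies; an individual's copy number
at a locus is drawn directly from the allele distribution (alleles are
window copy-number states, not haplotypes, so no haplotype-sum model is
imposed) and is constant across the locus's windows. Depth per window is
`offset_s * coverage * CN/2 * gc_factor + Gaussian noise`, with the noise
scaled so the recovered raw CN in diploid windows has standard deviation
`sigma_CR`; the within-sample noise family is not dictated by the data
model and Gaussian was chosen to match the HMM's emission assumption — a
flagged assumption, not a fact about real libraries. GC bias is a smooth
multiplicative quadratic peaking at GC 0.5 with configurable amplitude.
Synthetic genomes keep the non-diploid fraction near 8%, comparable to
real genome-wide maps; this matters because mean ± 3 sd control trimming
(like any global outlier rule) degrades when non-diploid windows dominate.

What the generator does *not* emulate: read-level artifacts (mappability
gradients, insert-size effects, PCR duplicates), population structure and
relatedness, sex chromosomes, and CN-dependent noise inflation (simulated
noise is flat in CN while the HMM allows width growing with N — a
conservative mismatch that widens, never narrows, high-CN intervals).
Passing the calibration suite therefore demonstrates correctness of the
inference machinery under its own model, not robustness to everything real
libraries do.

The calibration experiments in the test suite use two 2.5-Mbp chromosomes,
ten {2,4}-at-0.5 CNV loci and ten fixed CN-4 loci of twenty windows each
(200 replicate windows per type), 100 samples at 30x with
`sigma_CR = 0.3`, five of them consumed by Baum–Welch training. Under
those conditions the truth copy number falls inside the 99% interval in
over 98% of sample-windows, locus windows classify correctly in over 95%
of replicates, and fixture genes recover their construction-expected
profiles in over 95% of cases.

# Worked example

```{r example, eval = FALSE}
library(rdcnv)

loci <- list(
  list(chrom = "chr1", start = 100000, end = 110000,
       cn = c(2L, 4L), freq = c(0.5, 0.5)),
  list(chrom = "chr2", start = 100000, end = 110000, cn = 4L, freq = 1))
spec <- sim_spec(n_chromosomes = 2, chrom_length = 250000, loci = loci,
                 n_samples = 30, mean_coverage = 30, sigma_cr = 0.3,
                 seed = 42)

ref   <- generate_reference(spec)
grid  <- build_windows(ref$sequences)
truth <- generate_population_truth(grid, spec)
depth <- simulate_depth_matrix(truth, grid, spec)

fit   <- genotype_panel(depth, grid, train_n = 3, seed = 1)
calls <- call_regions(fit)
table(calls$categories)
calls$regions
```

The worked 30-sample allele-calling example ships as `fixture_s28()`:

```{r s28}
print(call_alleles(fixture_s28()))
```

# Numerical choices and limitations

* Forward–backward runs in the scaled linear domain after per-window
  rescaling of emissions by their row maximum; posteriors are invariant to
  both rescalings and the log-likelihood is reassembled from the scaling
  constants. Equality with exhaustive path enumeration is asserted to
  1e-9 on short tracks.
* Baum–Welch rows with zero expected transition counts keep their previous
  values rather than dividing by zero.
* Confidence-interval ties (equal-probability neighbors) extend toward the
  lower copy number, matching the published growth example.
* Allele-interval sharing uses `count >= 0.9 * n` exactly (18/20 passes);
  the qualifying integer set is kept contiguous around the seed.
* Degenerate inputs: empty masks, chromosomes under one window of unmasked
  sequence, constant depth tracks, all-zero posterior–prior products and
  samples with constant control CN are all handled explicitly (zero
  windows, zero-valued statistics with a degeneracy flag, or a fallback
  with warning) rather than producing NaNs.
* Resolution is bounded by the 1-kbp window: events smaller than a window
  surface only as noise, and region boundaries snap to window edges.
  Consecutive same-category windows merged into one region may still
  descend from distinct duplication/deletion events.
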