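---
title: "Rank-based signatures, network diffusion and APOE-SNP epistasis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based signatures, network diffusion and APOE-SNP epistasis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

apoenet implements an integrative transcriptomic–genomic workflow for
two-group molecular studies, with Alzheimer's disease APOE genotype contrasts
(ε3/ε3 vs ε4/ε4 carriers) as the motivating design. The pipeline has four
stages — a rank-based signature classifier, network expansion of its
biomarker by random walk with restart, over-representation analysis of the
expanded gene list, and a two-cohort SNP×APOE interaction scan on disease
age-at-onset — plus a synthetic-data module that generates every input with
planted ground truth. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic studies do and do
not demonstrate.

## The rank-based signature classifier

Expression profiles are compared on the rank scale, which removes
between-sample scaling and location differences without explicit
normalization. The procedure is:

1. **Probe filtering.** A two-sided Wilcoxon rank-sum test per probe between
   the two groups; probes with `p <= alpha_filter` are retained. The exact
   null distribution is used for tie-free data up to 50 samples, otherwise
   the normal approximation with tie and continuity correction (this matches
   `stats::wilcox.test`, which the tests verify).
2. **Signatures.** Each sample's retained probes are sorted by decreasing
   abundance (ties broken by probe id, so results are reproducible across
   platforms); the first `n1` and last `n2` probe ids form the sample's
   signature. `n1` and `n2` are shared by all samples.
3. **Distance.** For samples A and B, each sample's top and bottom sets are
   located in the *other* sample's full ranking with a weighted
   Kolmogorov–Smirnov enrichment score \(ES \in [-1, 1]\): walking down a
   ranking of length \(N\), hits accumulate weight
   \(|\,(N+1)/2 - i\,|^{q}\) at rank \(i\) and misses accumulate uniformly;
   the score is the running deviation of largest magnitude. Sample A's
   concordance against B is \(c_A = (ES(A_{top}) - ES(A_{bot}))/2\), and the
   distance is
   \[ d(A, B) = 1 - \frac{c_A + c_B + 2}{4} \in [0, 1], \]
   which is symmetric, zero for identical rankings and one for perfectly
   anti-correlated rankings. The weighting exponent `q` (default 1)
   emphasizes probes near the extremes of the ranking; `q = 0` recovers the
   classic unweighted statistic. This normalization is the one under which
   the distance honours all three contract properties (range, identity,
   anti-correlation); a raw sum of the four enrichment terms does not.
4. **Classification.** A sample is assigned to the group whose members have
   the smallest mean distance from it; exact ties go to the
   lexicographically smaller label and are flagged.

Accuracy is estimated by stratified 10-fold cross-validation in which the
probe filter and signatures are re-fit inside each training fold — feature
selection never sees test samples. Significance is assessed by a permutation
test that re-runs the *entire* procedure (filter, signatures, distances,
leave-one-out assignment) on each permuted dataset; reusing the
observed-label filter would hand the observed statistic a selection
advantage and makes the test anticonservative (we measured a ~30% rejection
rate under the null before adopting full re-fitting; it is ~5% after). The
leave-one-out accuracy is heavily tied at small n, so a bounded
group-separation margin (weighted 1e-4, far below the accuracy granularity
1/n) breaks ties and keeps the null p-value distribution near uniform. Two
permutation units are offered — sample labels (default, fast because sample
ranks are label-free) and per-sample probe shuffling — because published
descriptions of this family of methods are ambiguous about the unit.

Parameter selection (`n1`, `n2`, `alpha_filter`) uses a genetic algorithm
over user-supplied candidate values with fitness
\[ \text{mean CV accuracy} - \lambda_{len}\,(n_1 + n_2)/P, \]
where \(P\) is the retained probe count and \(\lambda_{len} = 0.01\); the
penalty prefers the shortest signature among equally accurate ones, which is
the point of a biomarker. GA defaults are population 40, 25 generations,
tournament size 3, uniform crossover 0.7, per-gene mutation 0.1, elitism 1;
tests and the worked examples use smaller populations (10–16) and spaces of
18–48 points, where the GA provably matches exhaustive search. Fitness
values are cached so each distinct parameter set is cross-validated once,
and a fixed seed reproduces the full trajectory.

The **biomarker** is the union of probes appearing in at least one sample
signature, with its gene image and the filter p-values; gene-level p-values
(minimum over a gene's probes) feed the network stage.

## Network expansion by random walk with restart

Biomarker genes present in a background protein-interaction network receive
node scores \(-\log_2 p\); all other genes receive a small
\(\varepsilon\) (default \(10^{-3}\) of the smallest positive biomarker
score) which keeps the restart distribution strictly positive and the walk
irreducible. The walk solves
\[ \pi = (1 - r)\,W\pi + r\,s, \]
with \(W\) the column-normalized adjacency matrix, \(s\) the scores
normalized to sum one, and restart probability \(r = 0.5\) (exposed as a
parameter), by fixed-point iteration to L1 tolerance \(10^{-10}\) (capped at
\(10^4\) iterations; non-convergence is an error, and the solution matches a
direct linear solve to \(10^{-8}\) on graphs up to 50 nodes in the tests).

Each edge u–v is scored by its stationary flux \(\pi(u)/\deg(u) +
\pi(v)/\deg(v)\), expressed as \(\log_2\) of the ratio between the weighted
walk's flux and the flux of a baseline walk with uniform restart mass — so a
positive score marks an edge carrying more diffusion mass than topology
alone explains, and uniform scores give exactly zero everywhere. A raw-flux
variant is available behind a flag.

The retained-edge threshold is placed at the "step" of the descending sorted
score curve: the midpoint of the largest gap whose upper score is at or
above the median. A gap only counts as a step if it dominates the searched
region — at least twice the mean gap *and* three times the next-largest gap.
The second condition matters: on a smooth score curve the largest gaps sit
among the sparse top order statistics, and the mean-gap test alone would
"detect" a step between the top two edges. When no gap qualifies the rule
falls back to retaining the top tenth of edges, with a warning; a manual
threshold can always be supplied. The rule is scale-equivariant. The
above-threshold subnetwork keeps all connected components by default
(reporting their sizes, largest flagged), with a largest-component-only
option.

## Over-representation analysis and the DE screen

Subnetwork genes are tested against gene-set collections with the upper
hypergeometric tail \(P(X \ge k)\) on the network's gene universe,
Benjamini–Hochberg adjusted within each collection, significance flagged at
`q <= 0.001`. BH is used deliberately: the web tools this step emulates do
not document their FDR variant, and BH is deterministic and reproducible.
Query genes outside the universe are dropped with a warning rather than
silently shrinking the universe.

A separate targeted screen, `de_filter()`, implements the simple
fold-change rule used for astrocyte-focused comparisons: linear-scale fold
change \(\ge 1.5\) *and* two-sided Welch-t \(p < 0.02\), with no
multiplicity correction in the pass rule (a BH column is attached for
context). The ordinary Welch t-test stands in for a moderated-t analysis;
with the small per-group variances of targeted panels the two agree closely,
but no variance shrinkage is performed and this is a documented divergence.

## The APOE×SNP interaction scan

Cohort quality control applies, in order: sample call rate \(\ge 0.95\),
then on the retained samples SNP autosome membership, SNP call rate
\(\ge 0.95\) and minor allele frequency \(\ge 0.05\). Population structure
is summarized by classical metric MDS of the allele-sharing distance
\(1 - \mathrm{IBS}\) (IBS = mean over jointly observed SNPs of
\((2 - |d_i - d_j|)/2\)); axis signs follow a deterministic convention
(largest-magnitude coordinate positive) and samples beyond 6 SD on any of
the top axes are flagged as outliers — the 6 SD rule is a package choice, as
no standard exists.

Per SNP, ordinary least squares regresses age-at-onset on an intercept, the
APOE ε4 allele count (0/1/2), the SNP dosage, their product, and the top
three MDS coordinates, using the samples with observed dosage (no
imputation). The interaction coefficient is reported in years per
(ε4-count × dosage) unit with its t-based two-sided p-value; rank-deficient
designs (e.g. monomorphic SNPs) yield flagged `NA` rows rather than
disappearing. APOE enters as an allele dosage by default — expression-study
designs contrast ε3/ε3 with ε4/ε4 only, genotype cohorts carry all three
counts, and dosage coding generalizes both; a binary contrast can be
emulated by subsetting.

Two cohorts are combined per SNP by the sample-size-weighted Z method:
\(z_i = \mathrm{sign}(\beta_i)\,\Phi^{-1}(1 - p_i/2)\), per-study genomic
control \(\lambda_i = \mathrm{median}(z_i^2)/\chi^2_{1,0.5}\) floored at 1
(deflation only), and
\(z_{meta} = (w_1 z_1 + w_2 z_2)/\sqrt{w_1^2 + w_2^2}\) with
\(w_i = \sqrt{N_i}\). Allele orientation is harmonized when SNP metadata are
supplied (swapped alleles flip the sign; incompatible alleles drop the SNP
with a warning). Only SNPs with concordant per-study effect directions are
taken forward, q-values are recomputed on that set (BH by default; a
Storey-type \(\pi_0\)-scaled option exists because the original analysis
used a density-estimation FDR tool whose exact settings are not
reproducible), and SNPs map to genes whose 1-based inclusive boundaries
contain their position. Composite-EM LD summaries (`ld_summary()`: r², D′
from unphased dosages) support reporting correlated SNP pairs.

## The synthetic-data module

The generators define the study conditions under which everything above is
tested:

- **Expression** (`simulate_expression`): Gaussian log-scale abundances
  (microarray mode) or log2 negative-binomial counts (RNA-seq mode), probe
  baselines N(8, 2), noise SD 1, groups of 43 and 34 samples (the two APOE
  genotype groups of the motivating design; the alternative 47/30 split
  reported elsewhere for the same cohort is reachable through the same
  config), 50 informative probes among 1000 with a standardized shift of 2
  noise SDs and random sign, and a many-to-one probe→gene map (~5% duplicate
  genes).
- **Network** (`simulate_network`): a preferential-attachment scale-free
  graph of 500 genes; a connected planted module of 50 genes grown by BFS
  and densified to mean intra-module degree 4 (functional modules are denser
  than the interactome background — chosen a priori, before any recovery
  test was run); 80% of the informative genes are placed inside the module.
- **Gene sets** (`simulate_gene_sets`): one designated set drawn from the
  module, the rest uniform from the gene universe.
- **Cohorts** (`simulate_cohorts`): 600 samples × 2000 SNPs each, MAFs
  uniform on the configured range, APOE ε4 counts with probabilities
  (0.30, 0.46, 0.24) as in genotyped AD case series, two latent
  subpopulations whose allele-frequency divergence and a 2·`structure_strength`
  year onset offset scale together (making MDS adjustment consequential),
  1% missing genotypes, and age-at-onset
  \[75 - 2.5\,\mathrm{APOE4} + 0.8\,(\mathrm{APOE4}\times d) +
    \text{structure} + N(0, 5^2)\]
  for the five planted SNPs (shared across cohorts with a common effect
  sign). The residual SD of 5 years and the ε4 main effect of −2.5
  years/allele are realistic for AD onset-age cohorts and were fixed before
  any testing.

## Statistical power at the planted-effect scale

A 0.8 year/unit interaction with MAF 0.3, N = 600 and residual SD 5 gives a
per-study standard error near 0.44, hence per-study \(z \approx 1.8\) and
meta \(z \approx 2.6\). Against ~2000 panel SNPs, whose null maximum |z| is
about 3.5, planted SNPs therefore concentrate deep in the upper tail of the
ranking (median rank within the top few percent) but do not reliably occupy
the very top ranks, and individual planted SNPs frequently miss q < 0.05.
This is the regime real onset-age interaction scans operate in — the
published hits of this design have meta |z| of 3.4–4.2 — and the package's
property tests assert what the conditions support: unbiased recovery of the
interaction coefficient (within 2 SE over 20 replicates), ~5% type-I error
under the null, and strong tail enrichment of planted SNPs (median planted
rank fraction ≤ 0.25 in ≥ 8/10 seeds against a null expectation of 0.5).
Demanding that all planted SNPs rank first would require an onset-age
residual SD under ~2.5 years, which no cohort shows.

## What the synthetic studies do and do not show

Passing tests demonstrate that each stage recovers what its generator
plants, under the stated conditions, and that every closed-form and
oracle-checkable quantity is computed correctly. They do not demonstrate
performance on real data: the generators have no probe-level correlation
structure beyond the planted shifts, no batch effects, no linkage
disequilibrium (each SNP is drawn independently), no haplotype structure,
and gene sets without the semantic overlap of real ontologies. Classifier
accuracy near 1.0 on effect-size-2 data therefore says the machinery works,
not that any real contrast is that separable.

## Problem sizes and runtimes

Tests and the acceptance script use: 77-sample × 1000-probe expression
datasets (10 seeds) for CV; 500-node networks for walk/threshold recovery;
600 × 2000 cohorts for the null scans and 600 × 50 for coefficient recovery
(20 seeds); 100 null repetitions at 99 permutations for permutation-test
calibration. These sizes make every stochastic check stable at the asserted
margins while a full run stays within a few minutes on one core.

## Known limitations

- The classifier is strictly two-group; multi-class designs are out of
  scope.
- Genotype input is text dosage only (no binary PLINK/VCF containers), and
  missing dosages are handled by per-SNP complete-case analysis.
- The edge-score threshold rule assumes a roughly unimodal background score
  mass; adversarial score curves should use the manual threshold.
- `de_filter` is an unmoderated Welch test; for genome-wide moderated
  analysis use a dedicated empirical-Bayes tool.
- BH (or the optional Storey variant) stands in for density-estimation FDR;
  q-values can differ near the significance boundary.
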