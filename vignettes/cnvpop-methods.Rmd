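---
title: "Population CNV analysis with cnvpop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population CNV analysis with cnvpop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

# Scope

cnvpop covers the analysis that starts *after* CNV calling: per-sample calls
from an HMM caller such as PennCNV are the input, and the package takes them
through call-level QC, population CNV-region (CNVR) compilation, permutation
tests of overlap with annotation, a genome-wide association of copy number
state with a quantitative phenotype, and qPCR-based validation. Producing
calls from intensity data (LRR/BAF), breeding-value estimation, and
functional enrichment are out of scope; calls, phenotypes and annotation
tracks are consumed as given.

A seeded synthetic-data generator stands in for the raw genotypes of a real
study population, so every stage can be exercised and tested end to end
without any external download.

# Coordinate conventions

All internal intervals are **1-based and inclusive** on both ends — the
native convention of the PennCNV text format and of the IRanges machinery
the interval arithmetic is built on. So `length = end - start + 1`, and two
intervals overlap when they share at least one base. BED files are 0-based
half-open on disk; `read_bed_track()`/`write_bed_track()` convert at the
boundary and nowhere else. Chromosome names are normalized by stripping a
leading `"chr"` and compared case-sensitively afterwards.

# Call-level quality control

`filter_calls()` applies the standard array-CNV filters, each with an
explicit boundary rule:

* **Sample exclusion**: samples with strictly more than 150 calls are
  removed entirely. An inflated call count indicates noisy intensities, and
  keeping such samples inflates downstream CNVR lengths through chains of
  false calls. The *pre-filter* call count decides, as in the caller's own
  QC — a sample is not rescued by the length filter removing some of its
  calls first.
* **Length**: calls strictly shorter than 5 kb are removed; a call of
  exactly 5,000 bp survives. Short array calls are poorly concordant with
  CGH.
* **Autosomes**: calls on sex chromosomes are removed; hemizygosity
  confounds intensity-based calling there.

Each removed call is tallied under exactly one reason with precedence
sample > chromosome > length, so the QC report always adds up.

# CNVR compilation

Calls are partitioned into losses (cn < 2) and gains (cn > 2) — cn = 2
records are rejected at parse time, so the partition is total. Within each
partition and chromosome, calls that transitively overlap by at least one
base form a cluster.

**Recurrence trimming.** Within a cluster of $n$ calls, the density at base
$b$ is $d(b)/n$, where $d(b)$ is the number of member calls covering $b$.
Bases with density strictly below the recurrence threshold (default 0.1)
are removed, and each maximal surviving run becomes a region; a cluster may
split. The denominator choice — calls in the cluster rather than the
population size — is a genuine design decision: the external tool this
stage emulates documents only that areas of density below 10% are excluded.
A cluster-based denominator reproduces the intended behavior (trimming
low-support tails contributed by one or two outlier calls) and is
well-defined without sample weights; the parameter is exposed so other
choices can be explored. With recurrence 0, regions are exactly the
per-type transitive-overlap unions.

**Gain/loss merging.** Overlapping gain and loss regions are merged,
transitively, into single regions of type `"both"` spanning their union: a
chain of alternating overlapping gain and loss regions collapses into one
region. Regions are then renumbered by (chromosome order, start).

**Frequency.** Member calls are all calls sharing at least one base with
the final region; the frequency is the number of *distinct samples* among
members divided by the population size, computed on the final (trimmed,
merged) regions. Regions above 1% frequency (strictly) are flagged
polymorphic. For high-frequency regions (> 75%), a single copy number state
accounting for more than 95% of member calls raises the `fixed_state` flag:
such regions are more plausibly reference-assembly differences (mapping
artifacts) than segregating variation.

The compilation is verified base-for-base against a brute-force per-base
oracle (union-find clustering plus explicit depth vectors) on hundreds of
randomized toy call sets in the test suite.

# Permutation overlap tests

`permutation_overlap_test()` asks whether a region set overlaps an
annotation track more or less than chance. Each permutation replaces every
query region with a uniformly placed interval of identical length on the
same chromosome; randomized regions may overlap one another (a
non-overlapping mode exists but is off by default, since forbidding
overlap distorts the null when regions are dense). Regions longer than
1 Mb are excluded — from the observed measure *and* the null alike, so the
two remain comparable; such extreme outliers cannot be placed
representatively.

Two measures are available: the number of query regions touching at least
one target region (not symmetric in query/target), and the total shared
genomic size in bp (symmetric). The one-sided p-value uses the add-one
estimator $p = (k+1)/(N+1)$, counting ties as extreme, so $p$ is never 0
and the minimum at $N = 1000$ is just under 0.001. A reported $p = 0.057$
corresponds to exactly 56 of 1000 permutations at least as extreme — the
convention is confirmed against this arithmetic in the tests, and the null
itself is calibrated against a closed-form placement count (one 10 bp query
and target on a 100 bp chromosome: 19 of 91 placements overlap).

Cross-study comparison uses strict mutual overlap: two regions are the same
event only when each covers more than 70% of the other.

# Copy-number association scan

The scan regresses a quantitative phenotype on integer copy number,
probe by probe, then aggregates probes into segments:

1. Every probe in every sample takes the state of the covering call, else
   2. Overlapping same-sample calls are invalid input and rejected.
2. Probes deviating from 2n in at least 5% of the population are selected
   (common copy number polymorphisms; rarer probes carry almost no
   association information at these sample sizes).
3. Per probe, ordinary least squares of phenotype on copy number (0–4, as
   an integer covariate, not factorized) with a two-sided t test on the
   slope at $n-2$ df. This is the simplest model consistent with a
   PLINK-style quantitative CNP scan; the closed-form fit is verified
   against `lm()` in the tests. Samples without a phenotype are dropped
   pairwise; probes constant among phenotyped samples are flagged
   degenerate ($p = 1$).
4. Selected probes are chained left to right into segments: a probe joins
   the open segment when it is on the same chromosome as the *previous
   selected probe* and the two have identical state in at least 95% of
   samples. Consecutive-in-selection is deliberate — intervening invariant
   probes do not break a segment, since selection (step 2) precedes
   chaining (step 4). Probes of a segment are identical by state, not
   necessarily by descent.
5. The probe with the smallest p-value represents its segment (ties:
   leftmost); per-state animal counts are taken at that probe.
6. Segment p-values are Benjamini–Hochberg adjusted (`stats::p.adjust`,
   cross-checked against an independent textbook step-up implementation in
   the tests), with 0.05 and 0.1 as the reported thresholds.

Significant segments are annotated with genes within 450 kb of their
boundaries (ordered by distance, 0 for overlapping), reflecting how far
copy number changes have been observed to perturb expression. No
kinship or population-structure correction is applied, matching the scan
this package reproduces; with related animals the per-probe p-values are
anti-conservative, which is a known limitation.

# qPCR validation

Relative quantification against a single-copy control gene and a diploid
reference cohort:

* **Efficiency correction**: a primer with per-cycle amplification factor
  $E \in (1, 2]$ contributes $ct \cdot \log_2 E$ corrected cycles, so the
  downstream base-2 arithmetic is exact for a perfectly doubling reaction.
  The exact correction used by any given lab is rarely recoverable from a
  paper's text; this form is the package's choice, is the identity at
  $E = 2$, and sits behind a single function so an alternative can be
  swapped in.
* **ΔCt** = mean corrected target Ct − mean corrected control Ct
  (triplicates averaged arithmetically; optionally one replicate more than
  1 cycle from the median is dropped, off by default).
* **ΔΔCt** = ΔCt − reference ΔCt, where the reference is the mean ΔCt over
  the samples the *array* called diploid for that primer. No diploid
  reference sample ⇒ error, the quantity is undefined.
* **NR** $= 2 \cdot 2^{-\Delta\Delta Ct}$, and the state is the $n$ with
  $\sqrt{n(n-1)} < NR \le \sqrt{n(n+1)}$ (geometric means of adjacent
  integers as boundaries; a ratio exactly on a boundary takes the lower
  state — a deterministic rule where none is conventionally fixed), state 5
  above $\sqrt{20}$, and state 0 whenever the reaction did not amplify.

A tested sample is **concordant** when array and qPCR agree in a
non-normal type (loss with loss, gain with gain), or when both platforms
see the diploid state. Normal/normal agreement counts toward the
per-region concordance percentage but *not* toward validation, which
requires at least one sample sharing a loss or gain; both percentages
(all tested samples, and non-normal samples only) are reported because the
denominator convention differs between published tables.

# The synthetic-data generator

`simulate_population()` emulates the statistical structure of an
SNP-array CNV study in a diploid livestock population at desk scale. The
defaults were chosen once, as the package's standing study conditions:

* **Genome and array**: 5 autosomes × 10 Mb with a probe every 3.2 kb —
  the density of a ~770k-probe high-density chip on a 2.5 Gb genome.
* **Loci**: 40 non-overlapping CNV loci, lengths log-uniform in 5–500 kb
  (CNVR length distributions are heavy-tailed; most regions fall in the
  5–50 kb bin). 40% of loci are gains, mirroring the roughly 1:1.6
  gain:loss ratio of published cattle maps.
* **Frequencies**: uniform in [0.02, 0.6]. Real maps span 0.1%–99.8%, but
  at 100 animals frequencies below 2% are unobservable; the upper end is
  kept below fixation so the diploid state remains the majority state
  everywhere.
* **States**: carriers of a loss locus are 1n (0n with probability 0.1);
  gains are 3n (4n with probability 0.1).
* **Noise**: emitted call boundaries are jittered by a Gaussian of SD one
  probe spacing, rounded to the probe grid and clipped so per-sample calls
  stay disjoint; Poisson(0.2) spurious calls per animal are added away
  from the animal's true calls. With jitter and false positives at zero
  the emitted calls equal the true locus spans exactly, which gives the
  round-trip identities the tests rely on.
* **Phenotype**: $y_i = \mu + \sum_l \beta_l (CN_{il} - 2) + \varepsilon_i$
  with $\varepsilon \sim N(0, 1)$; three causal loci at $\beta = 0.8$ by
  default.
* **qPCR**: corrected target Ct $= 25 - \log_2(CN/2)$ plus 0.1-cycle
  replicate noise, control Ct $= 25$, triplicates, no amplification at
  CN 0. Raw emitted Ct values are pre-divided by $\log_2 E$ so efficiency
  correction recovers the model exactly.

Random number use is split into named sub-streams (loci, carriers, jitter,
false positives, phenotype, annotation, qPCR), each seeded from the root
seed, so changing one component's settings does not perturb the draws of
another. Identical configurations reproduce every output byte for byte.

What the generator does **not** emulate: linkage disequilibrium between
loci, pedigree/kinship structure, intensity-level artifacts (genomic
waves), locus-specific call quality, and population stratification.
Passing tests therefore demonstrate correctness of the *analysis
arithmetic* under a clean generative model, not robustness to every
artifact of real array data.

# Numerical choices and degenerate inputs

* Recurrence trimming converts the density threshold to an integer minimum
  depth with `ceiling(recurrence * n - 1e-9)`; the epsilon guards the
  ceiling against floating-point representation of products like
  `0.1 * 30`.
* Bin edges of the length histogram are half-open `[lo, hi)`; an empty
  region set reports zero fractions with a warning rather than NaN.
* Empty query region sets are an error in the permutation test; an empty
  target yields observed 0 and $p = 1$ under the `greater` alternative
  naturally.
* `alternative = "auto"` picks the side by the sign of observed − null
  mean and never doubles: reported permutation p-values are one-sided.
* Probe association reports $p$ no smaller than the smallest positive
  double, keeping downstream `(0,1]` validation honest.
* Ties for the representative probe go to the leftmost; ratio ties on a
  qPCR category boundary go to the lower state.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
the default desk scale above (full pipeline runs in about a minute), with
two deliberate enlargements chosen for statistical resolution rather than
realism: frequency-convergence checks use 1,000 animals, and the
association calibration uses 1,000 null probes at 200 animals with the
causal-recovery check at 20 seeded replicates (locus frequency 0.2,
$\beta = 0.8$ residual SD). The permutation null is calibrated with 5,000
permutations on a 100 bp toy chromosome where the placement distribution
is enumerable in closed form.

# Limitations

* The recurrence-trimming denominator is a reconstruction (see above); a
  different denominator changes region boundaries at low call counts.
* OLS on integer copy number assumes an additive dosage effect; dominance
  or state-specific effects require the factorized model this package does
  not fit.
* Without kinship correction, association p-values in related populations
  are anti-conservative.
* qPCR efficiency correction is one of several defensible forms; results
  for $E$ well below 2 depend on the choice.
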