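---
title: "Methods: scanning inbred maize panels for low-nitrogen tolerance loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning inbred maize panels for low-nitrogen tolerance loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroscan)
```

## Scope and assumptions

`nitroscan` analyses a diversity panel of **fully homozygous inbred lines**
genotyped at biallelic SNPs and phenotyped for grain yield in paired
optimal-N (IN) / low-N (LN) field trials. Three assumptions run through the
whole chain and are worth stating up front:

* **Inbreeding is complete.** Genotypes take only the values homozygous
  reference (coded 0), homozygous alternate (coded 2) or missing. Each line
  therefore carries a single distinguishable allele per locus, which is why
  the fixation-index estimator uses haploid coding (below) and why
  identity-by-state per locus is simply 1 (same homozygote) or 0 (opposite
  homozygotes). Heterozygous calls in input files are treated as errors:
  set missing with a warning by default, or rejected under the strict
  policy.
* **Markers are analysed marginally.** The scan is a per-SNP contrast; no
  haplotype or linkage model is used beyond the LD *pruning* that thins
  redundant markers.
* **The phenotypic contrast defines the "populations".** The two groups
  compared by the scan are not geographic populations but the high- and
  low-tolerance phenotypic groups produced by the Scott–Knott step. Fst
  between them measures how strongly a locus's allele frequencies track the
  phenotype split, so loci under directional selection for the trait stand
  out.

## The phenotype side

### Adjusted means

Plot yields from an incomplete-block (lattice) design are modelled per
environment × N level as

$$y = X\beta + Zu + \varepsilon, \qquad
u \sim N(0, I\sigma_b^2), \quad \varepsilon \sim N(0, I\sigma^2),$$

with fixed intercept, replicate and genotype effects and random incomplete
blocks. `adjusted_means()` fits this with REML (`lme4::lmer`) and returns
the genotype BLUEs — fixed-effect predictions averaged over replicates —
plus the variance components. When the fitted block variance is zero the
BLUEs coincide with ordinary least-squares line means (asserted to 1e-8 in
the tests). A line absent from one trial yields `NA` there rather than an
extrapolated value; an environment × N level with a single replicate falls
back to raw means with a warning (or an error under
`single_rep_policy = "error"`), since the block variance is then
inestimable.

### The LNAE index

The Low-N Agronomic Efficiency of line $i$ in environment $j$ is

$$\mathrm{LNAE}_{ij} = GY^{LN}_{ij}\cdot
\frac{GY^{LN}_{ij}}{GY^{IN}_{ij}} = \frac{(GY^{LN}_{ij})^2}{GY^{IN}_{ij}},$$

the absolute low-N yield weighted by the low-N/optimal-N ratio, in
kg ha⁻¹. The product form is this package's reading of the index's verbal
definition (absolute low-N yield **and** relative yield retention); the
index function is pluggable in `lnae_table()` so other stress-tolerance
indices can reuse the IN/LN pairing logic. The per-line combined value is
reported both as the arithmetic mean over environments and as the
least-squares line estimate of the two-way `environment + line` model; the
two coincide for balanced data and the model-based one is preferred when
lines are missing from some environments.

### ANOVA and Scott–Knott grouping

`lnae_anova()` fits the fixed-effects two-way model
`lnae ~ environment + line`; the line effect's F test decides whether
grouping is meaningful, and the residual mean square and degrees of freedom
are the error inputs to the Scott–Knott step. With a single environment the
line effect has no error term under this model and the function refuses to
guess.

`scott_knott()` implements the Scott & Knott (1974) divisive procedure:
means are sorted; the cut maximizing the between-group sum of squares
$B_0$ is tested with

$$\lambda = \frac{\pi}{2(\pi-2)}\frac{B_0}{\hat\sigma_0^2},\qquad
\hat\sigma_0^2 = \frac{\sum_i(\bar y_i - \bar y)^2 + \nu s^2_{\bar y}}
{g + \nu},$$

where $s^2_{\bar y} = \mathrm{error\_ms}/n_{rep}$ is the variance of a
treatment mean and $\nu$ the error degrees of freedom; heterogeneity is
declared when $\lambda$ exceeds the $\chi^2$ quantile at $g/(\pi-2)$
(fractional) degrees of freedom, and the procedure recurses on both parts.
Numerical conventions: ties in the sort are broken by line name; a cut is
never placed between exactly equal means, so an all-equal group can never
split; group labels are assigned in descending order of group mean. Because
the split statistic needs the number of replicates behind each mean, the
function takes an explicit `n_rep` argument (the pipeline passes the number
of environments); `n_rep = 1` means the error mean square is already on the
mean scale. In a 1,000-replicate null calibration (20 lines × 3 replicates,
no line effect) the root split rejects at ≈ 3.6% for nominal α = 0.05 —
the χ² approximation is known to be slightly conservative — which the
acceptance suite checks against a 3-SD binomial band around α.

`sk_two_groups()` collapses the partition into the binary H/L contrast used
downstream (top group = H by default).

## The genotype side

### QC and LD pruning

`filter_markers()` keeps markers with call rate ≥ 0.90 and minor-allele
frequency ≥ 0.05 (inclusive thresholds; MAF computed on non-missing lines,
one allele draw per inbred line). `ld_prune()` slides a window of 50
markers advancing by 5 within each chromosome; within a window, while any
surviving pair has squared Pearson correlation of allele counts
(pairwise-complete) **strictly above** 0.13, the highest-r² pair is
resolved by dropping its lower-MAF member (tie: the later position). All
four numbers are exposed as arguments; 0.90/0.05/0.13 are the study's
settings and 50/5 are conventional window dimensions, since genotype r²
equals haplotype r² in inbred material no haplotype-based estimator is
needed. The rule set is deterministic, and with a window spanning a whole
chromosome it reduces exactly to all-pairs pruning (tested against a
brute-force oracle).

### Distances and ordination

`ibs_distance()` returns 1 − IBS per pair over the markers non-missing in
both lines; a pair sharing no markers gets `NA` and blocks ordination until
resolved. `pcoa()` is classical metric scaling: square the distances,
double-center ($-\tfrac12 J D^2 J$), eigendecompose; coordinates are
eigenvectors scaled by $\sqrt{\lambda_k}$ for positive eigenvalues, with
negative eigenvalues reported and their axes dropped. No standardization is
applied by default; a `standardize` flag rescales coordinate columns for
users who want variance-equalized axes. `evanno_delta_k()` consumes a plain
(K, run, logL) table from externally run Bayesian structure software —
the admixture MCMC itself is deliberately out of scope — and computes
ΔK = mean|L(K+1) − 2L(K) + L(K−1)| / sd(L(K)) with run-paired second
differences; endpoints and zero-spread K values are flagged `NA`.

### The Fst contrast scan

`wc_theta()` is the Weir–Cockerham (1984) moment estimator in its
haploid-sample form: fully homozygous diploids carry no within-individual
information, so each line enters as one allele draw and the
within-individual components of the full estimator vanish. This variant
reproduces the printed reference values for the study's strongest contrasts
— θ(29, 35; 0.43, 0.03) = 0.3666 → 0.37 and θ(29, 35; 0.33, 0.03) =
0.2559 → 0.26 at two decimals — which the acceptance suite asserts.
Conventions: monomorphic markers give `NA` (flagged, never dropped
silently); negative small-sample estimates are reported as computed, with
an optional `clamp` flag; a marker where either group has fewer than two
informative lines is flagged `insufficient_lines`. Per-group frequencies
use the non-missing lines of that group, i.e. sample sizes vary by marker
with missingness — the estimator note for data whose source tooling is
unknown.

`outlier_scan()` applies the strict θ > 0.2 rule and reports the
genome-wide mean θ. No multiple-testing control is applied: the fixed
threshold *is* the decision rule being studied, and the null false-positive
rate at n = 64 (≈ 0.1–0.6% per marker across seeds in the acceptance
suite) is recorded as a regression quantity.

### Favorable alleles and NFA

The favorable allele at an outlier marker is the allele **enriched in the H
group relative to L** (not the majority allele in H — at the study's
strongest SNP the favorable allele had frequency 0.43 in H), so
FFA_H ≥ FFA_L holds by construction and an exact frequency tie yields no
favorable allele (excluded with a warning). `nfa_scores()` counts loci (not
allele dosage — the two are proportional in inbred lines) at which a line
is homozygous favorable; a missing genotype contributes 0 by default
(conservative), with a `rescale` mode dividing by the line's completeness.
`nfa_lnae_association()` returns the Pearson r with its two-sided t test
and the simple regression of LNAE on NFA, asserting internally that
R² = r².

## The synthetic generator

`sim_config()` defaults encode the study conditions: 64 lines split a
priori 29 H / 35 L, 12,050 SNPs over 10 chromosomes of 210 Mb, four
selected loci with H/L alternate-allele frequencies (0.33, 0.03),
(0.22, 0), (0.43, 0.03), (0.24, 0), neutral frequencies uniform on
(0.05, 0.95) so the MAF filter removes few loci, 2% missing calls, three
environments × two replicates in blocks of 8 plots, and N doses 150/60,
100/35, 100/35 kg ha⁻¹. Yields follow
`baseline(N, env) + effect × NFA (LN only) + block + residual`; the
baselines (IN 6,000, LN 3,000 kg ha⁻¹, ±250 environment effects) and the
per-allele effect (800 kg ha⁻¹) were solved so the expected group LNAE
means land near the published 3,304 / 1,644 kg ha⁻¹; the residual SD
(1,200) and block SD (250) give the ~30% plot CV typical of low-N trials.
Truth labels are assigned a priori rather than post hoc so contrast-scan
power tests have an unambiguous ground truth; the effect sizes linking
genotype to yield are not published, so these defaults reproduce
qualitative structure (a two-group LNAE split, NFA–LNAE correlation of
roughly 0.7–0.8), not exact study values.

What the generator deliberately does **not** emulate: linkage
disequilibrium (markers are independent given the group label, so the LD
pruning step removes only chance correlations, not the 97% thinning seen
on real array data); pedigree relatedness (simulated 1 − IBS distances are
narrow, ~0.37–0.41, whereas real panels span ~0.03–0.41); population
substructure beyond the two-group frequency contrast (so structure-model
ΔK analyses are only exercised on hand-built likelihood tables); and
genotyping error beyond uniform missingness. Passing tests therefore
demonstrate correctness of the estimators and decision rules, not realism
of genome-wide LD patterns.

Reproducibility: one integer seed drives every draw (genotypes and
phenotypes use distinct sub-streams derived from it), and the test suite
asserts byte-identical regeneration.

## Problem sizes and numerical choices in the test suite

The suites run the estimator oracles at 100 random configurations (1e-12
agreement), planted-locus recovery at 64 lines × 2,004 SNPs over 20 seeds,
the Scott–Knott null calibration at 1,000 replicates, the adjusted-means
simulation at 200 replicated 16-line lattices, and the full study-scale
chain (64 × 12,050) once; the whole suite completes in well under a
minute. Tolerances follow the quantity's own precision: exact printed
values at two decimals, algebraic identities at 1e-12, geometry recovery
(Procrustes) at 1e-8, and simulation-based rates at 3-SD binomial bands.

## Known limitations

* The scan is a marginal, threshold-based rule; it does not model allele
  frequency uncertainty (a Bayesian outlier model would) and inherits the
  usual sensitivity of Fst outliers to group mis-assignment by the
  phenotypic clustering.
* Combined LNAE assumes environments are exchangeable; genotype ×
  environment interaction is averaged over, not modelled.
* The lattice is represented as random blocks within replicates; row/column
  spatial recovery is not attempted.
* PCoA on 1 − IBS can produce negative eigenvalues (the distance is not
  guaranteed Euclidean); affected axes are reported and dropped rather than
  corrected.
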