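---
title: "Inferring ancestry from methylation-array beta values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestry from methylation-array beta values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylancestry)
```

## The problem

Epigenome-wide association studies (EWAS) on Illumina methylation arrays are
vulnerable to population stratification: allele frequencies differ between
ancestral populations, many CpG measurements carry genetic signal (SNPs in
the probe body or at the interrogated site, methylation QTLs), and so do
phenotypes. When self-reported ethnicity is missing or unreliable — common
in placental cohorts assembled from multiple studies — an ancestry estimate
derived from the methylation data itself is the practical way to adjust for
this confounding.

`methylancestry` implements a complete framework for this task: it takes a
matrix of beta values (methylated fraction per site and sample, in $[0,1]$),
runs a quality-control cascade, fits a penalized multinomial classifier for
three ancestral groups (African, Asian, Caucasian), and returns per-sample
membership probabilities together with a discrete call that includes an
`Ambiguous` category for samples whose largest probability falls below a
confidence threshold. Because probabilities are returned, samples of mixed
ancestry are not forced into a discrete group: the probability vector itself
tracks admixture proportions and can be used directly as covariates.

## The model

For sample $i$ with (preprocessed) beta vector $x_i$ and class
$c \in \{$African, Asian, Caucasian$\}$, the classifier is symmetric softmax
multinomial logistic regression,

$$P(y_i = c \mid x_i) = \frac{\exp(\beta_{0c} + \beta_c^\top x_i)}
{\sum_k \exp(\beta_{0k} + \beta_k^\top x_i)},$$

fit by minimizing the elastic-net-penalized negative log-likelihood

$$-\frac{1}{N}\sum_i \log P(y_i \mid x_i)
  \;+\; \lambda \sum_c \Big[ \tfrac{1-\alpha}{2}\lVert\beta_c\rVert_2^2
  + \alpha \lVert\beta_c\rVert_1 \Big],$$

with unpenalized intercepts and the $\ell_1$ term applied per class
("ungrouped"). Features are standardized internally with training means and
SDs; reported coefficients are transformed back to the beta scale. The
penalty performs site selection: the model's *selected sites* are those with
a nonzero coefficient in at least one class. Fitting is delegated to
coordinate descent in `glmnet`; the package's tests verify the returned
solution against an independent proximal-gradient minimization of the same
objective.

Hyperparameters are chosen by 3-times-repeated stratified 5-fold
cross-validation over a grid of 6 $\alpha$ values log-spaced on
$[0.025, 0.5]$ and 8 $\lambda$ values log-spaced on $[0.0025, 0.25]$,
selecting the point with the smallest mean held-out log-loss. Log-loss is
the default metric because it penalizes over-confident misclassification,
which matters when the probabilities themselves are the product. The grid
endpoints follow the ranges standard for this application; the log spacing
and the CV-minimum selection rule (rather than a one-standard-error rule)
are this package's choices and are recorded in the fitted model.

### The ambiguity threshold

A sample is called `Ambiguous` when its maximum class probability is
*strictly below* the threshold (default 0.75); a maximum of exactly 0.75 is
called. Genetic ancestry is continuous, so a forced three-way call would
misrepresent admixed individuals; the threshold turns low-confidence calls
into an explicit category instead. `threshold_sweep()` reports accuracy,
kappa, and the ambiguous fraction across cutoffs so users can move the
trade-off; the ambiguous fraction is non-decreasing in the threshold by
construction.

## The QC cascade

`run_preprocess()` executes, in order:

1. **Platform overlap** — restrict to sites present on both the 450K and
   EPIC arrays (`on_epic`), so trained models transfer across platforms.
   SNP-class (rs) probes are kept: their genotype signal is the point.
   Probes that merely overlap a common SNP are deliberately *not* removed.
2. **Probe quality** — a measurement fails iff detection $p > 0.01$ or
   bead count $< 3$; a site is removed iff its failing fraction is strictly
   greater than 1%. Surviving failed measurements are set to missing.
3. **KNN imputation** — each missing value is replaced by the mean of the
   $k = 10$ nearest sites (Euclidean distance over samples observed in both
   sites, scaled by $\sqrt{\text{shared}/\text{total}}$ so distances are
   comparable across missingness patterns).
4. **Flagged sites** — cross-hybridizing probes and tissue-specific
   non-variable sites are dropped; SNP probes are exempt from the
   non-variable flag (trimodality is signal, not noise).
5. **Inter-array correlation** — samples whose mean pairwise-complete
   Pearson correlation with all other arrays is below 0.95 are removed.
   This runs *before* the sex check: a corrupted array would otherwise
   distort the sex-chromosome clustering.
6. **Sex concordance** — average-linkage hierarchical clustering (Euclidean)
   on sex-chromosome betas, cut at two clusters; the cluster with higher
   mean chrY methylation is male. The linkage and metric are this package's
   choices (the clustering approach itself is standard); if the two clusters
   show no chrY dimorphism (single-sex cohort) the step falls back to a
   per-sample chrY level rule with a warning. Samples discordant with their
   reported sex are removed.
7. **BMIQ** — per sample, a three-state beta mixture
   (unmethylated/hemimethylated/methylated) is fit to type I and type II
   CpG probes by EM (moment-matched M-step, quantile-third initialization,
   up to 100 iterations, tolerance $10^{-6}$ on the mean log-likelihood,
   with an additional stop when parameters stall; estimation on a
   deterministic quantile-thinned subsample of at most 2000 values), and
   type II values are mapped through the monotone mixture-CDF transform
   $F_{I}^{-1}(F_{II}(x))$. Monotonicity guarantees that within-sample
   ranks among type II probes are preserved. Component shapes are floored
   at 1 (each state is a peak). SNP probes bypass normalization; samples
   with fewer than 500 probes of either design type are passed through
   with a warning.

Every step emits a report with the exact ids removed; the cascade is
idempotent, and a defect-free matrix passes through unchanged.

Out-of-band background correction (NOOB) is out of scope: it needs raw
intensity files, and this package ingests beta matrices.

## Evaluation: leave-one-dataset-out

Random k-fold CV over a pooled multi-cohort dataset leaks cohort-specific
structure (batch effects correlated with ethnicity composition) into the
test folds and flatters the estimate. `lodocv()` instead holds out an
entire cohort: the full pipeline — QC, tuning, final fit — is re-run from
scratch on the remaining cohorts, and the held-out cohort only receives
per-sample normalization (BMIQ) before prediction, so no quantity derived
from it influences its own training. Aggregate metrics pool all held-out
predictions. Reported metrics: accuracy with `Ambiguous` counted as
incorrect (the headline number) and excluding ambiguous calls, Cohen's
kappa, per-class and macro positive predictive value, per-class accuracy,
and log-loss with probabilities clipped to $[10^{-15}, 1-10^{-15}]$.
`mcnemar_compare()` supports paired comparison of two classifiers on the
same samples (continuity-corrected $\chi^2$, exact binomial fallback when
the discordant count is below 25).

## Comparing population-structure methods

Different inference methods (a trained classifier, the 59 genotyping
probes, CpG sets near known variants, mQTL-based site lists) produce
different kinds of output, so `compare_methods()` reduces them to a common
currency: within each cohort, betas for a method's site set are
standardized per site, the top 10 principal components are computed
(deterministic sign convention: the largest-magnitude loading is positive),
and each PC is regressed on self-reported ethnicity (indicator encoding),
on each available covariate, and on genetic-ancestry coordinates (each
singly, and coordinates 1+2 jointly). The $R^2$ profile shows where
population signal concentrates. For classifier-derived site sets the
held-out models from `lodocv()` are reused, so a cohort is never scored on
sites selected with its own samples. Standardization is within cohort by
default. `barfield_distance_sets()` builds the nested variant-distance
sets (0, 1, 2, 5, 10, 50 bp).

## Enrichment of selected sites

`enrichment_report()` tests whether the selected sites are enriched,
relative to all sites available at training, for SNP probes, documented
SNPs within CpG probes, known mQTLs, each chromosome, and each CpG-island
relation. Each test is Fisher-exact with the hypergeometric null: the
two-sided p sums the probabilities of tables no more probable than the one
observed, and the upper-tail p is reported for directional enrichment; the
probability mass function is evaluated in log space so extreme tables do
not underflow. The background includes the SNP probes. No multiplicity
correction is applied to the 0.05 flag (matching common practice for this
handful of descriptive tests), but a Benjamini–Hochberg column is emitted.

## The synthetic-cohort generator

`simulate_cohorts()` generates studies with known truth, used both for the
package's tests and for power exploration:

- **Populations.** Three ancestral populations; per-variant allele
  frequencies follow the Balding–Nichols model: ancestral frequency
  $p \sim U(0.1, 0.9)$ and population frequency
  $\sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so the across-population
  variance is $F p (1-p)$. The default $F_{st} = 0.15$ corresponds to
  continental-scale differentiation.
- **Samples.** Five cohorts of 48/44/40/36/32 samples (sizes in the range
  typical for placental methylation cohorts). A fraction (default 10%) of
  individuals are admixed with proportions drawn from a symmetric
  Dirichlet(1,1,1); the rest are one-hot. Self-reported ethnicity is the
  argmax population — people report a single label — while the truth table
  keeps the full proportions, with hard label `Mixed` when the maximum is
  below 0.75 (the same rule the classifier uses, making
  "Ambiguous ⇔ Mixed" testable).
- **Sites.** 59 SNP probes whose betas cluster trimodally at
  0.05/0.50/0.95 (SD 0.03) by genotype $\sim \mathrm{Binomial}(2, q^\top
  p_{\mathrm{pop}})$; 200 mQTL CpGs whose logit-scale means shift by 0.15
  per alternate allele; 5000 background CpGs with means from a
  Beta(0.5,5)/Beta(5,5)/Beta(5,0.5) mixture; 300 non-variable sites
  (SD 0.005); 100 cross-hybridizing probes; 40 sex-chromosome sites (chrY
  0.8 M / 0.1 F, chrX 0.8 M / 0.5 F). Cohort batch shifts
  ($\mathrm{N}(0, 0.3)$) and measurement noise ($\mathrm{N}(0, 0.05)$) act
  on the logit scale so betas stay in $[0,1]$.
- **Planted defects.** 10 sites exceed the 1% failing-detection rule, 5 the
  bead-count rule, 30 single measurements fail without triggering site
  removal (imputation targets), 2 samples are uniform noise (inter-array
  outliers), 1 sample's reported sex is flipped, and 50 sites are flagged
  off-EPIC. The truth tables record every planted coordinate, so QC
  bookkeeping can be checked exactly.

Identical seeds reproduce identical outputs. What the generator does *not*
emulate: linkage disequilibrium between variants, probe-chemistry artefacts
beyond the design-type distribution shift, cell-composition variation, and
realistic missing-not-at-random patterns. Passing tests on these cohorts
therefore demonstrate that the machinery is correct and that the method
recovers planted structure at realistic signal strengths — not that any
particular accuracy will be attained on a given real cohort.

## Numerical and design choices

- Strict inequalities follow the stated QC rules: failing fraction
  $> 1\%$ removes a site; bead count $< 3$ and detection $p > 0.01$ fail a
  measurement; maximum probability $< 0.75$ is ambiguous.
- Exact probability ties at calling are broken by the fixed class order
  (African < Asian < Caucasian) and logged.
- Tuning folds are stratified by class; the fold assignment derives
  entirely from the user-supplied seed, and the caller's RNG state is
  restored afterwards, as it is after simulation.
- A constant covariate in `variance_explained()` returns $R^2 = 0$ with a
  warning rather than `NA`, keeping tables rectangular.
- A zero margin in a 2×2 enrichment table returns $p = 1$ with an
  undefined (NaN) odds ratio.
- Model files are JSON with a `schema_version` field; numbers are written
  with 17 significant digits so a reloaded model reproduces predictions
  bit-for-bit.

## Problem sizes used in the packaged checks

The packaged tests and the acceptance script run the full pipeline on the
generator's default five-cohort, 200-sample, ~5,300-site studies (a seed
grid of five replicates for the headline leave-one-dataset-out numbers) and
on reduced three-cohort fixtures (~100 samples, ~600 sites) for unit-level
checks. These sizes were chosen so the complete evaluation — including
repeated cross-validated tuning inside every held-out fold — exercises
every code path at realistic signal strength while remaining convenient to
re-run; the reduced fixtures use a correspondingly relaxed inter-array
correlation cutoff (0.8) because their site composition is more
genotype-heavy than a real array.

## Known limitations

- The probability threshold interacts with cross-cohort batch effects.
  Per-site cohort shifts displace the class logits of an unseen cohort as a
  whole; the argmax ranking is considerably more robust to this than the
  absolute probabilities, so strong batch structure inflates the
  `Ambiguous` fraction (and therefore depresses the headline
  ambiguous-counted accuracy) before it produces outright misclassification.
  The packaged leave-one-dataset-out runs on the default generator show
  exactly this behaviour. When cohorts are known to differ strongly in
  processing, compare the with- and without-ambiguous accuracies from
  `compute_metrics()` and consider the probability vector, rather than the
  thresholded call, as the adjustment covariate.
- Only the elastic-net classifier is implemented; the evaluation harness is
  classifier-agnostic, but alternative algorithms must be supplied by the
  user.
- BMIQ here is the quantile-mapping core; it does not reproduce any
  specific reference implementation's state-boundary interpolation
  details, though it preserves ranks and bounds by construction.
- The three-class label space is fixed by the training data's ancestry
  groups; finer-grained or additional ancestries require retraining with
  labels to match.
- Enrichment uses the training background recorded in the model; if a
  manifest covers more sites than the model saw, the extra sites are
  ignored.
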