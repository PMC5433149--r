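---
title: "Methods: 14q32 miRNA prognosis, subtype discovery, and miRNA-aware network inference"
author: "osteomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 14q32 miRNA prognosis, subtype discovery, and miRNA-aware network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomiR)
```

# Scientific setting

Osteosarcoma tumours differ in the expression of the microRNAs encoded in
the imprinted 14q32 (*DLK1–DIO3*) region — the largest miRNA cluster in the
genome — and these differences track patient outcome. `osteomiR`
re-implements, as a tested pipeline, the statistical machinery of that line
of analysis:

* a **signed-average prognostic index** evaluated by **time-dependent ROC**
  curves, with leave-one-out cross-validation, ridge-penalized Cox models,
  Kaplan–Meier/log-rank comparisons, permutation p-values, and a
  random-signature baseline;
* **molecular-subtype discovery**: average-linkage clustering, classical
  MDS, per-feature differential tests with Benjamini–Hochberg FDR, a
  random-splits null for the global amount of differential expression,
  Fisher/hypergeometric concordance tests, and KS/LS functional class
  scoring;
* **methylation context analysis**: CTCF-site/CpG-island interval
  annotation, Spearman correlation of methylation M-values with expression,
  conventional correlation-strength bins, and three-way
  methylation/expression/phenotype corner plots;
* **PUMA network inference**: PANDA-style message passing between a motif
  prior, a regulator-cooperativity (PPI) prior and gene coexpression, with
  the constraint that miRNA regulators never acquire cooperativity edges,
  plus permuted-background edge significance (the 4-SD rule), differential
  targeting, module extraction, and a local drug–gene interaction screen.

Because the original tumour cohorts are external data sets, the package
ships a first-class synthetic-data module that generates inputs with the
statistical structure the analysis assumes. Every downstream method is
exercised and tested against those generators and against independent
oracles (closed forms, enumerations, loop-coded references).

# The prognostic model

For a profile of $k$ features with signs $s_i \in \{+1,-1\}$ (the direction
of each feature's univariate Cox hazard ratio), the prognostic index of
sample $j$ is the signed average

$$\mathrm{score}_j = \frac{1}{k} \sum_{i=1}^{k} s_i\, x_{ij}.$$

Weighting by sign only — not by fitted coefficients — is deliberate: with
tens of samples and correlated features, fitted weights overfit, while the
signed average is nearly as discriminative and far more stable. Under
leave-one-out cross-validation (`loocv_risk_scores()`), the signs for sample
$j$ are re-estimated on the other $n-1$ samples, so a sample's outcome never
touches its own score. Signs are computed from the Cox score statistic
$U(0)$: the partial likelihood is concave in a scalar coefficient, so
$\mathrm{sign}(\hat\beta) = \mathrm{sign}(U(0))$ exactly; this avoids $n
\times p$ Newton solves and is verified against `survival::coxph()` in the
tests. A zero score statistic (a measure-zero event with continuous data)
is mapped to $+1$ with a warning.

`fit_cox()` maximizes the Breslow-ties log partial likelihood minus
$(\lambda/2)\lVert\beta\rVert^2$ by Newton–Raphson with step halving,
stopping when the penalized gradient norm falls below $10^{-8}$. Breslow
ties are the simplest standard choice; the L2 penalty follows the common
reading of "penalized Cox regression" (the ridge path is tested to be
monotone, and `choose_cox_lambda()` offers 5-fold cross-validated partial
likelihood when a data-driven penalty is wanted). Wald standard errors come
from the penalized information matrix; for $\lambda > 0$ they are shrinkage
approximations, as usual.

# Time-dependent ROC

At horizon $t$, cases are samples with an observed event by $t$ and controls
are samples followed beyond $t$ (the cumulative/dynamic convention).
Sensitivity and specificity at marker cut-off $c$ use the Kaplan–Meier
weighted estimator

$$\mathrm{Sens}(c,t) = \frac{\bigl(1 - S(t \mid M > c)\bigr)\,P(M > c)}{1 - S(t)},
\qquad
\mathrm{Spec}(c,t) = \frac{S(t \mid M \le c)\,P(M \le c)}{S(t)},$$

with subgroup Kaplan–Meier estimates inside the marker strata. This is the
canonical first estimator for time-dependent ROC analysis; it uses the
censoring distribution only through the KM weights and reduces *exactly* to
the empirical binary ROC when no observation is censored — a property the
tests exploit by fuzzing against an independent Mann–Whitney oracle at
$10^{-12}$. Censoring can make the raw curve slightly non-monotone; the
implementation sorts each coordinate isotonically before trapezoid
integration, which is a no-op on censoring-free data. Internally,
single-time KM values are computed with a per-observation sequential
product (events ordered before censorings at tied times), which equals the
aggregated $d_i/n_i$ formula identically.

Permutation p-values (`auc_permutation_pvalue()`) permute the (time, event)
rows jointly against the scores and use the add-one estimate
$p = (1 + \#\{\mathrm{AUC}^\ast \ge \mathrm{AUC}\})/(B+1)$, which can never
return zero. The default $B = 1000$ is a convention; calibration is checked
at $B = 99$ over hundreds of null replicates.

The random-profile baseline draws feature lists of size $k$ (default 3, as
in the published 20-random-3-miRNA control) and scores *every* list — and
the candidate — with the same LOOCV signed-average model. Using in-sample
signs here would flatter the random lists, because fitted signs on noise
features carry optimism.

# Subtype discovery

Differential expression uses Welch's t (vectorized across features) or the
Mann–Whitney U, both two-sided, with BH q-values; constant features yield
statistic 0 and $p = 1$ with a warning rather than NaN. The global
random-splits null re-labels samples preserving group sizes and asks how
often a random split yields as many features with $p < \alpha$ as the
proposed subtypes; the empirical p is the plain exceedance fraction,
matching the published "fewer than 5% of 100 random splits" rule.

Clustering is agglomerative with average linkage. The default distance is
$1 - r$ (Pearson) between sample profiles, the convention for expression
subtyping; Euclidean distance is available and is the right choice when the
discriminating signal is a *uniform* shift of a feature block, since
correlation distance removes per-sample constants and is blind to such
shifts. The synthetic cohorts plant exactly that kind of uniform shift, so
the recovery analyses cluster the signature block with Euclidean distance.
Classical (Torgerson) MDS on Euclidean distances is used for the 3-D sample
maps; it is algebraically PCA of the centered data, which the tests assert.

Gene-set scoring follows functional class scoring: for a set of per-feature
p-values, $LS = \mathrm{mean}(-\ln p)$ and $KS$ is the one-sample two-sided
Kolmogorov–Smirnov statistic against Uniform(0,1); significance permutes
which features form the set (add-one p-values).

# Methylation and CTCF context

Methylation is analyzed on the M-value scale, $M = \log_2\beta/(1-\beta)$,
clamped at $\varepsilon = 10^{-6}$ (clamp counts are reported). Coordinates
are 0-based half-open internally; BED files pass through unchanged and
1-based probe tables are shifted on ingest. A probe is `in_site` when it
lies inside a CTCF interval, `near_site` within `near_window_bp` of a
boundary (inclusive; default 1000 bp — the underlying analysis never
quantifies "near", so the window is a surfaced, tunable convention), else
`not_in_site`; the three classes partition the probes and are fuzz-tested
against a linear scan. Upstream CpG-island counts use a 100,000 bp window
with "upstream" meaning decreasing coordinates (+ strand); strand handling
for minus-strand genes belongs to the caller's annotation. The 14q32
region constant spans chr14:89,800,000–109,000,000.

Correlation strength uses the conventional magnitude bins: $\ge 0.5$
strong, $[0.3, 0.5)$ moderately strong, $[0.15, 0.3)$ moderate, else weak;
the sign is reported separately. The biological expectation encoded in the
generator and checked end-to-end: probes *inside* CTCF binding sites
correlate *positively* with 14q32 miRNA expression (methylation of an
insulator site relieves enhancer blocking), probes outside correlate
negatively (conventional silencing).

# PUMA message passing

All three priors — motif $W_0$ (regulators × genes), cooperativity $P_0$
(regulators × regulators, symmetric, unit diagonal) and coexpression $C_0$
(gene–gene Pearson correlation) — are conditioned by joint row/column
z-scoring, $Z = (z_{\mathrm{row}} + z_{\mathrm{col}})/\sqrt2$ (note this
operation is intentionally not idempotent; a fully standardized matrix maps
to $\sqrt2$ times itself). Each iteration computes responsibility
$R = T(P, W)$ and availability $A = T(W, C)$ with the continuous Tanimoto
kernel

$$T_{ij}(A,B) = \frac{A_i \cdot B_j}
{\sqrt{\lVert A_i\rVert^2 + \lVert B_j\rVert^2 - |A_i \cdot B_j|}},$$

then relaxes $W \leftarrow (1-\alpha)W + \alpha (R+A)/2$ and updates $P$ and
$C$ toward $T(W, W^\top)$ and $T(W^\top, W)$. The diagonal of each updated
similarity matrix is replaced by its own off-diagonal column standard
deviation (with a $\sqrt{(d-2)/(d-1)}$ finite-size correction) scaled by
$d\,e^{2\alpha\,\mathrm{iter}}$ — the annealing schedule of the canonical
message-passing implementation, which prevents self-similarity blow-up and
freezes the updates as iterations proceed. Defaults $\alpha = 0.1$ and a
mean-absolute-change tolerance of $10^{-3}$ follow that convention;
non-convergence at `max_iter` returns with a warning, never silently.

The PUMA constraint: after *every* cooperativity update, the rows and
columns of $P$ belonging to miRNA regulators are reset to their
(normalized) prior values, so miRNAs influence their targets only through
$W$ and never through induced cooperativity. With no miRNA regulators the
algorithm is plain PANDA, and the test suite holds it to within $10^{-8}$
of an independently loop-coded reference on 5×20 and 10×50 toys; a debug
flag records the constraint deviation at every iteration (exactly zero).

Edge significance between two sample groups re-infers one network per group
(group-specific coexpression, shared priors) and compares the per-edge score
difference against a background built by shuffling the sample-to-group
assignment `n_perm` times and re-inferring both networks; an edge is
significant when its observed difference exceeds four standard deviations of
its own background differences. The background is per-edge, not pooled,
because the 4-SD rule is stated per edge. Differential targeting is the
per-regulator row sum difference; module extraction keeps each seed
regulator's `top_k` (default 20) significant edges by absolute difference.

# The synthetic-data generators and what they do (and do not) emulate

`generate_cohort()` draws a latent high-risk subtype
($\pi = 0.5$ by default), shifts a co-regulated block of features by
$\delta$ standard deviations in high-risk samples, and draws event times
from an exponential proportional-hazards law
$h(t) = \lambda_0 e^{\beta z}$ with independent exponential censoring
truncated at the follow-up cap (administrative censoring). Defaults are the
package's study conditions: $n = 100$ samples, 769 features with a
27-feature signature block (the scale of the filtered global miRNA assay
and its prognostic 14q32 set), $\delta = 1.5$, subtype hazard ratio 3,
$\lambda_0 = 0.01$/month (median ~69 months in the low-risk group, ~23 in
the high-risk group), censoring hazard 0.008/month, 120-month cap. The
exponential law is the simplest one satisfying the Cox assumption the
analysis makes; the clinical generating process behind the real cohorts is
unknown, so these are declared conditions, not estimates.

Two structural consequences are worth knowing. First, because the subtype
is *binary*, a horizon-$t$ marker cannot beat the discrimination of the
true subtype itself; with the default hazards the oracle AUC at 60 months
is only moderately above 0.7, and any estimator that classifies the subtype
nearly perfectly sits at that ceiling. Second, because the signature shift
is *uniform* across the block, correlation distance cannot see it
(recovery analyses use Euclidean distance, as noted above). Both are
properties of the generator, not of the methods; real cohorts have
continuous risk gradients that binary subtypes only approximate. A related
consequence: random small feature lists that happen to include a signature
feature can approach the same ceiling, so "the candidate beats every random
list" is a much harder event under this generator than a single-cohort
anecdote suggests — the acceptance analysis reports the measured rate
rather than forcing it.

`generate_methylation_panel()` plants Gaussian-copula correlations between
probe M-values and a supplied latent factor: positive (`rho_in_ctcf`,
default 0.5) for in-site probes, negative (`rho_out_ctcf`, default −0.4)
outside, with `noise_sd` (default 0.3) attenuating the realized correlation
by $1/\sqrt{1+\mathrm{noise\_sd}^2}$ — so the infinite-noise limit is
exactly the null. Betas are the exact inverse M-transform of Gaussian
latents, hence strictly inside (0,1) and exactly Gaussian on the M scale.

`generate_network_truth()` plants Bernoulli(0.3) true edges (each regulator
guaranteed at least one target), exposes them in $W_0$ with probability
`prior_density`, adds false-positive prior edges on 5% of non-edges, and
plants cooperativity (weight 0.5, probability 0.2) among non-miRNA
regulator pairs only. Gene expression is a linear read-out of iid standard
normal regulator activities plus `noise_sd` Gaussian noise;
`simulate_network_expression()` can silence chosen regulators to create
group-specific (differential) edges. The false-positive prior edges are
adversarial on purpose: they make edge ranking a test of whether message
passing uses coexpression, not just the prior. The differential-edge
analyses use noise-free expression with 100 samples per group — the scale
of the larger public osteosarcoma resources — because the 4-SD rule with a
label-permutation background is conservative and needs well-estimated
coexpression to have power.

`generate_cell_line_panel()` (default 19 lines) emulates the in-vitro
panel: a continuous proliferation metric dichotomized at the median, a
composite migration/invasion/colony metric correlated 0.8 with
proliferation, signature miRNAs correlated `rho` (default 0.6, per
feature) with proliferation, and a methylation panel driven by the
proliferation axis.

None of the generators simulate raw array intensities, probe chemistry, or
batch effects; passing tests show the *statistical* machinery is correct
under the declared structure, not that any biological claim about real
tumours is reproduced.

# Numerical conventions and edge cases

* Quantile normalization: ties within a column get the mean of the target
  values over their rank span; the operation is idempotent and agrees with
  `limma::normalizeQuantiles()` on tie-free input.
* Variance filtering drops exactly $\lfloor f\,p\rfloor$ features (sample
  variance, $n-1$), breaking ties lexicographically by feature id;
  normalization precedes filtering in the pipeline's intended order.
* Median survival is the first time KM drops to 0.5 or below, reported as
  `"not reached"` when it never does; all-censored groups raise an error
  for the log-rank test rather than returning something undefined.
* All generator randomness flows through a per-call seeded RNG that
  restores the caller's `.Random.seed`; identical config implies identical
  output, and `puma_infer()` itself contains no randomness at all.
* Degenerate inputs fail loudly: constant covariates with $\lambda = 0$,
  horizons beyond follow-up, empty case/control sets, constant vectors in
  Spearman tables (flagged, not NaN), zero-variance rows in the z-scoring
  (overall-SD fallback with a warning), near-zero Tanimoto denominators
  (epsilon guard, reported).

# Problem sizes used by the shipped analyses

The test suite and `scripts/acceptance.R` run the full pipeline at sizes
chosen as the package's study conditions: 50 synthetic cohorts of
$n = 100$ for the prognostic recovery analyses; 20–50 noise-free 5×20
network toys for edge ranking and differential flagging (`n_perm = 20`,
100 samples per group); 100–200 replicates for the null calibrations of the
permutation AUC p-value ($B = 99$), the random-splits null (100 splits) and
the 4-SD edge rule; and $n = 200$ samples for methylation sign recovery.

# Known limitations

* The tdROC estimator is the KM (cumulative/dynamic) dialect; incident
  cases, covariate adjustment and confidence bands are out of scope.
* The ridge Cox fit reports penalized-information Wald errors; no
  de-biasing is attempted.
* The message-passing equations are fixed to one published dialect; other
  diagonal-update or availability orientations exist in the wild, and the
  loop-coded reference in the tests is the contract for this one.
* The drug screen is a join against a user-supplied table; no external
  database is queried.
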