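# osteomiR

Prognostic 14q32 miRNA signatures, molecular subtypes, and miRNA-aware
regulatory networks in osteosarcoma.

The microRNAs of the imprinted 14q32 (*DLK1–DIO3*) locus — the genome's
largest miRNA cluster — separate osteosarcoma tumours into risk groups with
different outcomes. `osteomiR` is a tested R implementation of the
statistical pipeline behind that kind of study, for biostatisticians and
computational biologists who want each step as a reusable, verifiable
function rather than a one-off analysis:

* **Prognosis.** The signed-average prognostic index
  `score_j = (1/k) Σ_i s_i x_ij`, where each signature feature is weighted
  only by the sign `s_i ∈ {±1}` of its univariate Cox hazard-ratio
  direction; leave-one-out cross-validation of the signs; ridge-penalized
  Cox regression (Breslow ties, Newton–Raphson on the penalized partial
  likelihood); Kaplan–Meier curves, medians and log-rank tests.
* **Evaluation.** Time-dependent ROC at a fixed horizon with the
  Kaplan–Meier-weighted cumulative/dynamic estimator
  `Sens(c,t) = (1 − S(t|M>c))·P(M>c)/(1 − S(t))`,
  `Spec(c,t) = S(t|M≤c)·P(M≤c)/S(t)`; label-permutation AUC p-values;
  a random-signature baseline (20 random 3-feature lists by default).
* **Subtypes.** Average-linkage clustering, classical MDS, Welch-t /
  Mann–Whitney differential tables with Benjamini–Hochberg FDR, a
  100-random-splits null for the global differential count, Fisher and
  hypergeometric concordance tests, and KS/LS functional class scoring.
* **Methylation context.** Beta→M transform, CTCF-site and CpG-island
  interval annotation (0-based half-open), Spearman correlation tables with
  conventional strength bins (0.15 / 0.3 / 0.5), three-way
  methylation–expression–phenotype corner scores.
* **Networks.** PUMA message passing — PANDA (motif prior + regulator
  cooperativity + gene coexpression combined by the continuous Tanimoto
  kernel) with miRNA regulators barred from cooperativity edges — plus
  permuted-background edge significance at 4 SD, differential targeting,
  module extraction, and a drug–gene interaction screen against a local
  table.
* **Synthetic data.** Generators for two-subtype survival cohorts,
  CTCF-structured methylation panels, cell-line aggressiveness panels and
  planted regulator→gene networks, so the whole pipeline is testable
  without the original cohort downloads.

## Worked example

```r
library(osteomiR)

co  <- generate_cohort(cohort_config(seed = 42))          # n = 100, HR = 3
sig <- grep("^miR\\.c", rownames(co$expression), value = TRUE)

lo <- loocv_risk_scores(co$expression[sig, ], co$survival)
tdroc_curve(lo$scores, co$survival, horizon = 60)
#> tdROC at 60 months: AUC = 0.706 (53 cases, 22 controls)

auc_permutation_pvalue(lo$scores, co$survival, horizon = 60,
                       B = 199, seed = 1)$p
#> [1] 0.005

grp <- ifelse(lo$scores > median(lo$scores), "high", "low")
km <- km_logrank(grp, co$survival)
km$medians
#>       high        low
#> "20.61984" "69.70125"
signif(km$p, 3)
#> [1] 4.03e-07
```

The cross-validated signed average of the planted 27-feature signature
discriminates 60-month outcome (AUC 0.71, permutation p = 0.005), and the
median-split risk groups have median survivals of 20.6 vs 69.7 months
(log-rank p ≈ 4e-07) — the high-risk subtype carries a hazard ratio of 3
by construction.

Subtype discovery on the same cohort:

```r
cl <- hierarchical_cluster(co$expression[sig, ], k = 2,
                           distance = "euclidean")
mclust::adjustedRandIndex(cl$labels, co$subtype)
#> [1] 1

de <- two_group_test(co$expression, cl$labels)
sum(de$p < 0.05)                                    # 63 of 769 probes
#> [1] 63
random_split_null(co$expression, cl$labels, n_splits = 100,
                  seed = 7)$empirical_p
#> [1] 0
```

Clustering recovers the planted subtype exactly (ARI = 1); 63 probes are
differential at p < 0.05 — including all 27 signature probes — and no
random split of the samples reaches that count (empirical p = 0).

Network inference on a noise-free planted toy:

```r
nt  <- generate_network_truth(network_truth_config(
  n_regulators = 5, n_mirnas = 2, n_genes = 20, noise_sd = 0, seed = 1))
net <- puma_infer(nt$priors)
net
#> Inferred network: 5 regulators x 20 genes, converged in 112 iterations (h = 0.001)
```

The final edge scores rank the planted true edges above non-edges (ranking
AUC ≈ 0.96 averaged over such toys), and the two miRNA regulators' rows of
the cooperativity matrix never leave their prior.

See `vignettes/osteomiR-methods.Rmd` for the models, parameter meanings,
generator assumptions and numerical conventions.

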