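#' Configuration for a synthetic two-subtype survival cohort
#'
#' The generator emulates the statistical structure assumed by the prognostic
#' analysis: a latent high-risk subtype of prevalence `prevalence_pi` whose
#' members over-express a co-regulated block of `n_cluster_features`
#' "14q32-like" features by `effect_size_delta` standard deviations, and whose
#' hazard is multiplied by `exp(log_hr_beta)` under an exponential
#' proportional-hazards law with independent exponential censoring truncated
#' at `follow_up_cap` months (administrative censoring).
#'
#' @param n_samples number of tumours (columns).
#' @param n_features total number of expression features (rows).
#' @param n_cluster_features size of the co-regulated prognostic block; the
#'   first `n_cluster_features` features carry the subtype shift.
#' @param effect_size_delta standardized mean shift of the cluster block in the
#'   high-risk subtype (feature noise has unit SD, so delta is in SD units).
#' @param prevalence_pi fraction of high-risk samples, in (0, 1).
#' @param baseline_hazard baseline event hazard, events per month.
#' @param log_hr_beta log hazard ratio of the high-risk subtype.
#' @param censor_rate per-month hazard of independent censoring (0 = none).
#' @param follow_up_cap administrative censoring time, months.
#' @param seed integer seed; identical config implies identical output.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 100L, n_features = 769L,
                          n_cluster_features = 27L, effect_size_delta = 1.5,
                          prevalence_pi = 0.5, baseline_hazard = 0.01,
                          log_hr_beta = log(3), censor_rate = 0.008,
                          follow_up_cap = 120, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_features = as.integer(n_features),
              n_cluster_features = as.integer(n_cluster_features),
              effect_size_delta = effect_size_delta,
              prevalence_pi = prevalence_pi,
              baseline_hazard = baseline_hazard,
              log_hr_beta = log_hr_beta,
              censor_rate = censor_rate,
              follow_up_cap = follow_up_cap,
              seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 2) stop("n_samples must be at least 2")
    if (n_cluster_features > n_features)
      stop("n_cluster_features must not exceed n_features")
    if (!is.finite(prevalence_pi) || prevalence_pi <= 0 || prevalence_pi >= 1)
      stop("prevalence_pi must lie strictly in (0, 1)")
    if (!is.finite(effect_size_delta)) stop("effect_size_delta must be finite")
    if (!is.finite(baseline_hazard) || baseline_hazard <= 0)
      stop("baseline_hazard must be a positive finite rate")
    if (!is.finite(log_hr_beta)) stop("log_hr_beta must be finite")
    if (!is.finite(censor_rate) || censor_rate < 0)
      stop("censor_rate must be a non-negative finite rate")
    if (!is.finite(follow_up_cap) || follow_up_cap <= 0)
      stop("follow_up_cap must be positive")
  })
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic survival cohort with a planted prognostic subtype
#'
#' Draws subtype labels `z ~ Bernoulli(prevalence_pi)`, expression
#' `x_ij = delta * z_j * I[i in cluster] + N(0, 1)`, event times from
#' `Exponential(baseline_hazard * exp(log_hr_beta * z_j))` and censoring times
#' from `Exponential(censor_rate)` truncated at `follow_up_cap`.
#'
#' @param config a [cohort_config()].
#' @return a list of class `os_cohort` with elements:
#'   * `expression` — features x samples matrix (cluster features first,
#'     ids prefixed `miR.c`),
#'   * `survival` — data.frame `sample`, `time_months`, `event`,
#'   * `subtype` — integer vector, 1 = high-risk (the planted truth),
#'   * `latent_factor` — standardized per-sample mean of the cluster block
#'     (the observable surrogate of the subtype axis, used downstream by the
#'     methylation generator).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_features
    k <- config$n_cluster_features
    z <- stats::rbinom(n, 1L, config$prevalence_pi)
    x <- matrix(stats::rnorm(p * n), nrow = p, ncol = n)
    if (k > 0)
      x[seq_len(k), ] <- x[seq_len(k), , drop = FALSE] +
        config$effect_size_delta * rep(z, each = k)
    feature_ids <- c(if (k > 0) sprintf("miR.c%03d", seq_len(k)),
                     if (p > k) sprintf("miR.b%03d", seq_len(p - k)))
    sample_ids <- sprintf("S%03d", seq_len(n))
    dimnames(x) <- list(feature_ids, sample_ids)

    rate_event <- config$baseline_hazard * exp(config$log_hr_beta * z)
    t_event <- stats::rexp(n, rate_event)
    t_cens <- if (config$censor_rate > 0)
      pmin(stats::rexp(n, config$censor_rate), config$follow_up_cap)
    else rep(config$follow_up_cap, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    latent <- if (k > 0) {
      lf <- colMeans(x[seq_len(k), , drop = FALSE])
      as.numeric(scale(lf))
    } else rep(0, n)

    structure(list(
      expression = x,
      survival = data.frame(sample = sample_ids, time_months = time,
                            event = event, stringsAsFactors = FALSE),
      subtype = z,
      latent_factor = latent,
      config = config), class = "os_cohort")
  })
}

#' Configuration for a synthetic methylation panel
#'
#' Encodes the CTCF-context sign hypothesis: probes inside CTCF binding sites
#' correlate positively with the cluster-miRNA latent factor (methylation of
#' an insulator site relieves enhancer blocking), probes outside correlate
#' negatively (conventional promoter methylation silences).
#'
#' Correlation targets are Gaussian-copula (latent Pearson) targets; the
#' realized correlation is attenuated by `1/sqrt(1 + noise_sd^2)`, so the
#' pure-noise limit `noise_sd -> Inf` yields correlations near zero.
#'
#' @param n_probes number of CpG probes.
#' @param frac_in_ctcf fraction of probes planted inside CTCF sites.
#' @param rho_in_ctcf target positive latent correlation for in-site probes.
#' @param rho_out_ctcf target negative latent correlation for the rest.
#' @param noise_sd SD of extra probe-level noise (>= 0).
#' @param seed integer seed.
#' @export
methyl_config <- function(n_probes = 50L, frac_in_ctcf = 0.3,
                          rho_in_ctcf = 0.5, rho_out_ctcf = -0.4,
                          noise_sd = 0.3, seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), frac_in_ctcf = frac_in_ctcf,
              rho_in_ctcf = rho_in_ctcf, rho_out_ctcf = rho_out_ctcf,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_probes < 1) stop("n_probes must be positive")
  if (cfg$frac_in_ctcf < 0 || cfg$frac_in_ctcf > 1)
    stop("frac_in_ctcf must lie in [0, 1]")
  if (abs(cfg$rho_in_ctcf) >= 1 || abs(cfg$rho_out_ctcf) >= 1)
    stop("correlation targets must have magnitude strictly below 1")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("noise_sd must be a non-negative finite number")
  structure(cfg, class = "methyl_config")
}

#' Generate a synthetic methylation panel tied to a cohort latent factor
#'
#' Probe M-values are built as `mu_p + rho*f + sqrt(1-rho^2)*eps +
#' noise_sd*eta` with `f` the standardized latent factor and `rho` the signed
#' in-site / out-of-site target; betas are the exact inverse M-transform
#' `2^M / (1 + 2^M)`, hence strictly inside (0, 1). Probe coordinates are
#' drawn uniformly inside the 14q32 region.
#'
#' @param config a [methyl_config()].
#' @param latent_factor numeric vector, one value per cohort sample (e.g.
#'   `generate_cohort(...)$latent_factor`).
#' @return a list of class `methylation_panel`: `beta` and `m` (probes x
#'   samples), and `annotation` (data.frame `probe`, `chrom`, `pos` 0-based,
#'   `ctcf_class` in `in_site`/`not_in_site`).
#' @export
generate_methylation_panel <- function(config, latent_factor) {
  stopifnot(inherits(config, "methyl_config"))
  if (!is.numeric(latent_factor) || length(latent_factor) < 3)
    stop("latent_factor must be a numeric vector (one value per sample)")
  f <- as.numeric(scale(latent_factor))
  n <- length(f)
  with_seed(config$seed, {
    np <- config$n_probes
    n_in <- round(config$frac_in_ctcf * np)
    in_site <- rep(c(TRUE, FALSE), c(n_in, np - n_in))
    rho <- ifelse(in_site, config$rho_in_ctcf, config$rho_out_ctcf)
    mu <- stats::rnorm(np, 0, 1.5)
    eps <- matrix(stats::rnorm(np * n), np, n)
    eta <- matrix(stats::rnorm(np * n), np, n)
    m <- mu + rho * matrix(f, np, n, byrow = TRUE) +
      sqrt(1 - rho^2) * eps + config$noise_sd * eta
    beta <- 2^m / (1 + 2^m)
    probe_ids <- sprintf("cg%06d", seq_len(np))
    dimnames(beta) <- dimnames(m) <- list(probe_ids, names(latent_factor))
    region <- c(89800000L, 109000000L)
    ann <- data.frame(
      probe = probe_ids,
      chrom = "chr14",
      pos = sample(region[1]:(region[2] - 1L), np, replace = TRUE),
      ctcf_class = ifelse(in_site, "in_site", "not_in_site"),
      stringsAsFactors = FALSE)
    structure(list(beta = beta, m = m, annotation = ann, config = config),
              class = "methylation_panel")
  })
}

#' Configuration for a planted regulator-gene network
#'
#' True edges are planted Bernoulli(0.3); the motif prior `W0` keeps each true
#' edge with probability `prior_density` and adds false-positive prior edges
#' on 5% of the non-edges. `P0` is the identity plus planted cooperativity
#' (weight 0.5, probability 0.2) among non-miRNA regulator pairs only.
#'
#' @param n_regulators number of regulators (rows of W0).
#' @param n_mirnas how many of the first regulators are miRNAs.
#' @param n_genes number of target genes.
#' @param prior_density fraction of true edges visible in W0, in (0, 1].
#' @param edge_strength linear effect of a regulator on its targets.
#' @param n_samples_expr samples in the generated expression matrix.
#' @param noise_sd SD of additive gene-level noise (0 gives noise-free toys).
#' @param seed integer seed.
#' @export
network_truth_config <- function(n_regulators = 10L, n_mirnas = 4L,
                                 n_genes = 40L, prior_density = 1,
                                 edge_strength = 1, n_samples_expr = 50L,
                                 noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_regulators = as.integer(n_regulators),
              n_mirnas = as.integer(n_mirnas),
              n_genes = as.integer(n_genes),
              prior_density = prior_density,
              edge_strength = edge_strength,
              n_samples_expr = as.integer(n_samples_expr),
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_mirnas > cfg$n_regulators)
    stop("n_mirnas must not exceed n_regulators")
  if (cfg$n_mirnas < 0) stop("n_mirnas must be non-negative")
  if (cfg$prior_density <= 0 || cfg$prior_density > 1)
    stop("prior_density must lie in (0, 1]")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("noise_sd must be non-negative")
  structure(cfg, class = "network_truth_config")
}

#' Simulate gene expression from a regulator-gene edge matrix
#'
#' Gene expression is a linear read-out of latent regulator activities over
#' the edges, `G = strength * t(E) %*% A + noise`, with activities iid
#' standard normal. `silence_regulators` zeroes the named regulators' rows of
#' the edge matrix, which plants group-specific (differential) edges.
#'
#' @param true_edges regulators x genes 0/1 matrix with dimnames.
#' @param edge_strength scalar effect size per edge.
#' @param n_samples number of samples to draw.
#' @param noise_sd SD of additive gene noise.
#' @param seed integer seed.
#' @param silence_regulators optional character vector of regulator ids whose
#'   outgoing edges are removed before simulation.
#' @return genes x samples expression matrix.
#' @export
simulate_network_expression <- function(true_edges, edge_strength = 1,
                                        n_samples = 50L, noise_sd = 0.5,
                                        seed = 1L, silence_regulators = NULL) {
  stopifnot(is.matrix(true_edges))
  e <- true_edges
  if (!is.null(silence_regulators)) {
    miss <- setdiff(silence_regulators, rownames(e))
    if (length(miss)) stop("unknown regulators: ", paste(miss, collapse = ", "))
    e[silence_regulators, ] <- 0
  }
  with_seed(seed, {
    m <- nrow(e); ng <- ncol(e)
    act <- matrix(stats::rnorm(m * n_samples), m, n_samples)
    g <- edge_strength * t(e) %*% act +
      noise_sd * matrix(stats::rnorm(ng * n_samples), ng, n_samples)
    # keep genes non-degenerate even when fully disconnected and noise-free
    if (noise_sd == 0) {
      flat <- row_vars(g) < .Machine$double.eps
      if (any(flat)) g[flat, ] <- 1e-8 * matrix(stats::rnorm(sum(flat) * n_samples),
                                                sum(flat), n_samples)
    }
    dimnames(g) <- list(colnames(e), sprintf("S%03d", seq_len(n_samples)))
    g
  })
}

#' Generate a planted-truth regulatory network with priors and expression
#'
#' @param config a [network_truth_config()].
#' @return list of class `network_truth`: `priors` (a [regulatory_priors()]),
#'   `true_edges` (regulators x genes 0/1), and `expression` (genes x
#'   samples; same object the priors carry for coexpression).
#' @export
generate_network_truth <- function(config) {
  stopifnot(inherits(config, "network_truth_config"))
  with_seed(config$seed, {
    m <- config$n_regulators; ng <- config$n_genes
    reg_ids <- c(if (config$n_mirnas > 0) sprintf("miR%02d", seq_len(config$n_mirnas)),
                 if (m > config$n_mirnas) sprintf("TF%02d", seq_len(m - config$n_mirnas)))
    gene_ids <- sprintf("G%03d", seq_len(ng))
    truth <- matrix(stats::rbinom(m * ng, 1L, 0.3), m, ng,
                    dimnames = list(reg_ids, gene_ids))
    # every regulator needs at least one target so its row is informative
    orphans <- rowSums(truth) == 0
    if (any(orphans))
      truth[cbind(which(orphans), sample.int(ng, sum(orphans), replace = TRUE))] <- 1L

    keep <- matrix(stats::rbinom(m * ng, 1L, config$prior_density), m, ng)
    fp <- matrix(stats::rbinom(m * ng, 1L, 0.05), m, ng)
    w0 <- truth * keep + (1 - truth) * fp
    dimnames(w0) <- dimnames(truth)

    p0 <- diag(m)
    if (m > config$n_mirnas + 1) {
      tfs <- (config$n_mirnas + 1):m
      for (i in tfs) for (j in tfs) if (i < j && stats::runif(1) < 0.2)
        p0[i, j] <- p0[j, i] <- 0.5
    }
    dimnames(p0) <- list(reg_ids, reg_ids)

    expr_seed <- config$seed + 1L
    expr <- simulate_network_expression(truth, config$edge_strength,
                                        config$n_samples_expr,
                                        config$noise_sd, seed = expr_seed)
    priors <- regulatory_priors(W0 = w0, P0 = p0, expression = expr,
                                mirna_ids = reg_ids[seq_len(config$n_mirnas)])
    structure(list(priors = priors, true_edges = truth, expression = expr,
                   config = config), class = "network_truth")
  })
}

#' Generate a synthetic osteosarcoma cell-line panel
#'
#' Emulates an in-vitro aggressiveness panel: a continuous proliferation
#' metric, its high/low dichotomization at the median, a composite
#' migration/invasion/colony-formation metric correlated with proliferation,
#' a miRNA expression matrix whose cluster block tracks proliferation with
#' latent correlation `rho`, and a methylation panel driven by the
#' proliferation axis.
#'
#' @param n_lines number of cell lines (>= 4); default 19.
#' @param rho planted latent correlation between cluster-miRNA expression and
#'   proliferation (0 gives the null panel).
#' @param n_features,n_cluster_features expression panel dimensions.
#' @param seed integer seed.
#' @return list of class `cell_line_panel`: `expression`, `methylation`
#'   (a `methylation_panel`), `aggressiveness` (data.frame `line`,
#'   `proliferation`, `prolif_class`, `composite`).
#' @export
generate_cell_line_panel <- function(n_lines = 19L, rho = 0.6,
                                     n_features = 150L,
                                     n_cluster_features = 15L, seed = 1L) {
  n_lines <- as.integer(n_lines)
  if (n_lines < 4) stop("n_lines must be at least 4")
  if (abs(rho) >= 1) stop("rho must have magnitude strictly below 1")
  with_seed(seed, {
    lines <- sprintf("OS.line%02d", seq_len(n_lines))
    prolif <- stats::rnorm(n_lines)
    composite <- 0.8 * prolif + sqrt(1 - 0.8^2) * stats::rnorm(n_lines)
    k <- n_cluster_features; p <- n_features
    x <- matrix(stats::rnorm(p * n_lines), p, n_lines)
    if (k > 0)
      x[seq_len(k), ] <- rho * rep(prolif, each = k) +
        sqrt(1 - rho^2) * x[seq_len(k), , drop = FALSE]
    dimnames(x) <- list(c(if (k > 0) sprintf("miR.c%03d", seq_len(k)),
                          if (p > k) sprintf("miR.b%03d", seq_len(p - k))),
                        lines)
    prolif_class <- ifelse(prolif > stats::median(prolif), "high", "low")
    meth_seed <- seed + 1L
    meth <- generate_methylation_panel(
      methyl_config(n_probes = 20L, seed = meth_seed),
      latent_factor = stats::setNames(prolif, lines))
    structure(list(
      expression = x,
      methylation = meth,
      aggressiveness = data.frame(line = lines, proliferation = prolif,
                                  prolif_class = prolif_class,
                                  composite = composite,
                                  stringsAsFactors = FALSE)),
      class = "cell_line_panel")
  })
}
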