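#' Construct a signed prognostic profile
#'
#' A signed profile is a set of features each weighted by the +/-1 sign of
#' its hazard-ratio direction in univariate Cox regression; the per-sample
#' signed average of the member features is the prognostic index.
#'
#' @param feature_ids unique character ids.
#' @param signs integer/numeric vector of +1 / -1, one per feature.
#' @export
signed_profile <- function(feature_ids, signs) {
  if (anyDuplicated(feature_ids)) stop("profile features must be unique")
  if (length(signs) != length(feature_ids) || !all(signs %in% c(-1, 1)))
    stop("signs must be +1 or -1, one per feature")
  structure(list(feature_ids = as.character(feature_ids),
                 signs = as.numeric(signs)), class = "signed_profile")
}

#' Signed-average prognostic scores
#'
#' `score_j = (1/k) * sum_i sign_i * x_ij` over the k profile features: the
#' per-sample mean of profile features, each weighted only by the sign of its
#' univariate Cox hazard ratio. The simplicity of the index is the point: it
#' minimizes overfitting relative to fitted multivariate weights.
#'
#' @param x features x samples expression matrix.
#' @param profile a [signed_profile()].
#' @return named numeric vector of per-sample scores.
#' @export
signed_average_scores <- function(x, profile) {
  check_expression_matrix(x)
  stopifnot(inherits(profile, "signed_profile"))
  missing <- setdiff(profile$feature_ids, rownames(x))
  if (length(missing))
    stop("profile features missing from expression matrix: ",
         paste(missing, collapse = ", "))
  xs <- x[profile$feature_ids, , drop = FALSE]
  colSums(xs * profile$signs) / length(profile$signs)
}

# Univariate Cox score statistic U(0) per feature, Breslow ties.
# The partial likelihood is concave, so sign(beta-hat) = sign(U(0)); this
# gives exact hazard-ratio directions without per-feature Newton iterations.
cox_score_stats <- function(x, time, event) {
  n <- length(time)
  ot <- order(time)
  ts <- time[ot]; es <- event[ot]
  xs <- x[, ot, drop = FALSE]
  # risk-set sums: sum over all samples with T_k >= t_(i), ties included
  first_pos <- match(ts, ts)                    # first index of each tied time
  rev_cs <- t(apply(xs, 1, function(v) rev(cumsum(rev(v)))))
  if (nrow(x) == 1) rev_cs <- matrix(rev_cs, nrow = 1)
  n_at_risk <- n - first_pos + 1
  ev <- which(es == 1)
  if (!length(ev)) stop("no events: score statistic undefined")
  risk_means <- rev_cs[, first_pos[ev], drop = FALSE] /
    rep(n_at_risk[ev], each = nrow(x))
  rowSums(xs[, ev, drop = FALSE] - risk_means)
}

# Hazard-ratio direction per feature; zero scores count as +1 with a warning.
cox_signs <- function(x, time, event) {
  u <- cox_score_stats(x, time, event)
  if (any(u == 0))
    warning("zero Cox score statistic for ",
            sum(u == 0), " feature(s); sign taken as +1")
  ifelse(u >= 0, 1, -1)
}

#' Leave-one-out cross-validated signed-average risk scores
#'
#' For every sample i the hazard-ratio signs of all features are re-estimated
#' by univariate Cox regression on the remaining n - 1 samples, and sample
#' i's prognostic index is the signed average under those held-out signs.
#' Sample i's own outcome therefore never influences its own score.
#'
#' @param x features x samples expression matrix (the candidate profile's
#'   features; pass a row subset to score a specific profile).
#' @param surv survival table matching the columns of `x`.
#' @return list with `scores` (named per-sample vector) and `signs`
#'   (features x samples matrix of the per-fold signs).
#' @export
loocv_risk_scores <- function(x, surv) {
  check_expression_matrix(x)
  check_survival_table(surv, x)
  n <- ncol(x)
  if (n < 3) stop("LOOCV needs at least 3 samples")
  time <- surv$time_months; event <- surv$event
  scores <- numeric(n)
  signs <- matrix(NA_real_, nrow(x), n, dimnames = dimnames(x))
  for (i in seq_len(n)) {
    if (sum(event[-i]) < 2)
      stop("fold ", i, " has fewer than 2 events; LOOCV signs unidentifiable")
    s <- cox_signs(x[, -i, drop = FALSE], time[-i], event[-i])
    signs[, i] <- s
    scores[i] <- mean(s * x[, i])
  }
  names(scores) <- colnames(x)
  list(scores = scores, signs = signs)
}

#' Ridge-penalized Cox proportional-hazards fit
#'
#' Maximizes the Breslow-ties log partial likelihood minus
#' `(lambda/2) * ||beta||^2` by Newton-Raphson with step halving, iterating
#' until the penalized gradient norm falls below `1e-8`. With `lambda = 0`
#' this is the ordinary maximum partial-likelihood estimate.
#'
#' @param x numeric matrix n x p of covariates (or a numeric vector for a
#'   single covariate); column names become coefficient names.
#' @param surv survival table with rows matching the rows of `x`.
#' @param lambda ridge penalty, `>= 0`.
#' @param max_iter Newton iteration cap.
#' @return object of class `cox_fit`: `coefficients`, `hazard_ratios`,
#'   `se`, `p` (Wald, from the penalized information), `lambda`, `loglik`
#'   (unpenalized partial log-likelihood at the estimate), `iterations`,
#'   `converged`.
#' @export
fit_cox <- function(x, surv, lambda = 0, max_iter = 50L) {
  if (is.vector(x)) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(!is.finite(x))) stop("covariates must be finite")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("lambda must be a non-negative scalar")
  req <- c("time_months", "event")
  if (!is.data.frame(surv) || !all(req %in% names(surv)))
    stop("survival table needs columns time_months and event")
  if (nrow(surv) != nrow(x)) stop("x and surv must have matching rows")
  time <- surv$time_months; event <- surv$event
  if (sum(event) < 2) stop("at least 2 events are required")
  p <- ncol(x)
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (lambda == 0 && any(const))
    stop("constant covariate(s) with lambda = 0 are non-identifiable: ",
         paste(colnames(x)[const], collapse = ", "))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  ot <- order(time)
  ts <- time[ot]; es <- event[ot]; xo <- x[ot, , drop = FALSE]
  first_pos <- match(ts, ts)
  ev <- which(es == 1)
  n <- length(ts)

  pll <- function(beta) {
    eta <- drop(xo %*% beta)
    w <- exp(eta)
    s0 <- rev(cumsum(rev(w)))
    sum(eta[ev] - log(s0[first_pos[ev]]))
  }
  grad_hess <- function(beta) {
    eta <- drop(xo %*% beta)
    w <- exp(eta)
    s0 <- rev(cumsum(rev(w)))[first_pos[ev]]
    wx <- xo * w
    s1 <- apply(wx, 2, function(v) rev(cumsum(rev(v))))[first_pos[ev], ,
                                                        drop = FALSE]
    g <- colSums(xo[ev, , drop = FALSE] - s1 / s0) - lambda * beta
    h <- matrix(0, p, p)
    # S2 accumulated via reverse cumulative sums of w * x x^T
    xx <- array(apply(xo, 1, tcrossprod), dim = c(p * p, n))
    wxx <- sweep(xx, 2, w, `*`)
    s2 <- t(apply(wxx, 1, function(v) rev(cumsum(rev(v)))))[, first_pos[ev],
                                                            drop = FALSE]
    for (j in seq_along(ev)) {
      mu <- s1[j, ] / s0[j]
      h <- h + matrix(s2[, j], p, p) / s0[j] - tcrossprod(mu)
    }
    list(grad = g, info = h + lambda * diag(p))
  }

  beta <- rep(0, p)
  obj <- pll(beta) - (lambda / 2) * sum(beta^2)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    gh <- grad_hess(beta)
    if (sqrt(sum(gh$grad^2)) < 1e-8) { converged <- TRUE; break }
    step <- solve(gh$info, gh$grad)
    t_step <- 1
    repeat {
      cand <- beta + t_step * step
      cand_obj <- pll(cand) - (lambda / 2) * sum(cand^2)
      if (is.finite(cand_obj) && cand_obj >= obj - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-10) break
    }
    beta <- beta + t_step * step
    obj <- pll(beta) - (lambda / 2) * sum(beta^2)
  }
  if (!converged) {
    gh <- grad_hess(beta)
    converged <- sqrt(sum(gh$grad^2)) < 1e-8
    if (!converged) warning("fit_cox: Newton iterations did not converge")
  }
  info <- grad_hess(beta)$info
  se <- sqrt(diag(solve(info)))
  names(beta) <- names(se) <- colnames(x)
  structure(list(coefficients = beta,
                 hazard_ratios = exp(beta),
                 se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 lambda = lambda,
                 loglik = pll(beta),
                 iterations = iter,
                 converged = converged), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Ridge Cox fit (lambda = %g, %s after %d iterations)\n",
              x$lambda, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                   se = x$se, p = x$p))
  invisible(x)
}

#' Choose a ridge penalty by cross-validated partial likelihood
#'
#' Standard Verweij-van Houwelingen cross-validated partial likelihood:
#' for each fold, `cvpl = l_full(beta_train) - l_train(beta_train)`; the
#' lambda maximizing the summed cvpl wins.
#'
#' @param x covariate matrix, `surv` survival table as in [fit_cox()].
#' @param surv survival table.
#' @param lambdas candidate penalties.
#' @param nfolds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return the selected lambda (with the cvpl path as attribute `cvpl`).
#' @export
choose_cox_lambda <- function(x, surv, lambdas = 2^seq(-4, 6, by = 1),
                              nfolds = 5L, seed = 1L) {
  if (is.vector(x)) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  n <- nrow(x)
  folds <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  pll_at <- function(xm, sv, beta) {
    ot <- order(sv$time_months)
    ts <- sv$time_months[ot]; es <- sv$event[ot]
    xo <- xm[ot, , drop = FALSE]
    eta <- drop(xo %*% beta); w <- exp(eta)
    s0 <- rev(cumsum(rev(w)))[match(ts, ts)]
    sum((eta - log(s0))[es == 1])
  }
  cvpl <- vapply(lambdas, function(lam) {
    sum(vapply(seq_len(nfolds), function(k) {
      tr <- folds != k
      fit <- tryCatch(fit_cox(x[tr, , drop = FALSE], surv[tr, , drop = FALSE],
                              lambda = lam),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pll_at(x, surv, fit$coefficients) -
        pll_at(x[tr, , drop = FALSE], surv[tr, , drop = FALSE],
               fit$coefficients)
    }, numeric(1)))
  }, numeric(1))
  best <- lambdas[which.max(cvpl)]
  attr(best, "cvpl") <- stats::setNames(cvpl, lambdas)
  best
}

#' Kaplan-Meier curves and log-rank comparison between groups
#'
#' Product-limit estimates with Greenwood variance per group, median survival
#' (first time the KM estimate drops to 0.5 or below, reported as
#' `"not reached"` when it never does), and the two-sided log-rank test.
#'
#' @param groups group labels, one per sample.
#' @param surv survival table in the same order.
#' @return list of class `km_logrank`: `curves` (data.frame group, time,
#'   n_risk, n_event, surv, std_err), `medians` (character, months or
#'   `"not reached"`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(groups, surv) {
  check_survival_table(surv)
  g <- factor(groups)
  if (length(g) != nrow(surv)) stop("groups and survival table length differ")
  if (any(table(g) == 0) || nlevels(g) < 2)
    stop("need at least 2 non-empty groups")
  if (sum(surv$event) == 0)
    stop("all samples censored: log-rank test undefined")
  sobj <- survival::Surv(surv$time_months, surv$event)
  sf <- survival::survfit(sobj ~ g)
  sd_ <- survival::survdiff(sobj ~ g)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^g=", "", strata), time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, std_err = sf$std.err,
                       stringsAsFactors = FALSE)
  medians <- vapply(levels(g), function(lv) {
    cv <- curves[curves$group == lv, ]
    hit <- cv$time[cv$surv <= 0.5]
    if (length(hit)) format(min(hit)) else "not reached"
  }, character(1))
  df <- nlevels(g) - 1
  p <- stats::pchisq(sd_$chisq, df, lower.tail = FALSE)
  structure(list(curves = curves, medians = medians, chisq = sd_$chisq,
                 df = df, p = p), class = "km_logrank")
}
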