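toy_surv <- function(time, event)
  data.frame(sample = sprintf("s%02d", seq_along(time)),
             time_months = time, event = event, stringsAsFactors = FALSE)

test_that("signed averages equal the loop computation and behave under sign flips", {
  set.seed(1)
  x <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
  # single feature, +1: the score is that feature
  expect_equal(signed_average_scores(x, signed_profile("f2", 1)),
               x["f2", ])
  # two features, signs (+1, -1), values (2, 3) -> -0.5
  y <- matrix(c(2, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(signed_average_scores(y, signed_profile(c("a", "b"),
                                                              c(1, -1)))),
               -0.5)
  # full profile equals an explicit double loop
  prof <- signed_profile(paste0("f", 1:5), c(1, -1, 1, 1, -1))
  loop <- vapply(seq_len(ncol(x)), function(j)
    sum(vapply(1:5, function(i) prof$signs[i] * x[prof$feature_ids[i], j],
               numeric(1))) / 5, numeric(1))
  expect_equal(unname(signed_average_scores(x, prof)), loop)
  # all +1 equals the plain mean; flipping all signs negates scores
  expect_equal(signed_average_scores(x, signed_profile(paste0("f", 1:5),
                                                       rep(1, 5))),
               colMeans(x))
  flipped <- signed_profile(prof$feature_ids, -prof$signs)
  expect_equal(signed_average_scores(x, flipped),
               -signed_average_scores(x, prof))
  expect_error(signed_average_scores(x, signed_profile("nope", 1)),
               "missing.*nope")
})

test_that("fit_cox matches survival::coxph and a grid-search oracle", {
  set.seed(3)
  n <- 40
  x <- rnorm(n)
  sv <- toy_surv(rexp(n, 0.05 * exp(0.8 * x)), rbinom(n, 1, 0.8))
  fit <- fit_cox(x, sv, lambda = 0)
  ref <- survival::coxph(survival::Surv(sv$time_months, sv$event) ~ x,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), sqrt(vcov(ref)[1, 1]), tolerance = 1e-5)
  expect_equal(fit$hazard_ratios, exp(fit$coefficients))

  # 8-sample toy, ridge: brute-force grid search of the penalized objective
  x8 <- c(-1.2, 0.5, 1.1, -0.3, 0.9, -0.7, 1.5, 0.1)
  sv8 <- toy_surv(c(3, 6, 2, 9, 4, 12, 1, 7), c(1, 1, 1, 0, 1, 1, 1, 1))
  for (lam in c(0, 2)) {
    fit8 <- fit_cox(x8, sv8, lambda = lam)
    grid <- seq(-3, 3, by = 1e-4)
    obj <- vapply(grid, function(b) {
      eta <- x8 * b
      ot <- order(sv8$time_months)
      es <- sv8$event[ot]; eo <- eta[ot]
      s0 <- rev(cumsum(rev(exp(eo))))
      sum((eo - log(s0))[es == 1]) - lam / 2 * b^2
    }, numeric(1))
    expect_lt(abs(unname(fit8$coefficients) - grid[which.max(obj)]), 1e-4)
  }
})

test_that("fit_cox respects shrinkage, location invariance and the ridge path", {
  set.seed(4)
  n <- 30
  x <- rnorm(n)
  sv <- toy_surv(rexp(n, 0.05 * exp(x)), rep(1, n))
  expect_lt(abs(fit_cox(x, sv, lambda = 1e6)$coefficients), 1e-3)
  shifted <- fit_cox(x + 100, sv, lambda = 0)
  expect_equal(unname(shifted$coefficients),
               unname(fit_cox(x, sv, lambda = 0)$coefficients),
               tolerance = 1e-6)
  norms <- vapply(c(0, 0.5, 1, 2, 4, 8, 16), function(l)
    sqrt(sum(fit_cox(x, sv, lambda = l)$coefficients^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
  expect_error(fit_cox(x, toy_surv(1:30, rep(0, 30))), "2 events")
  expect_error(fit_cox(rep(1, n), sv, lambda = 0), "non-identifiable")
})

test_that("univariate Cox score signs agree with fitted coefficient signs", {
  set.seed(6)
  n <- 50
  x <- matrix(rnorm(4 * n), 4, n,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:n)))
  tm <- rexp(n, 0.05 * exp(0.9 * x[1, ] - 0.9 * x[2, ]))
  ev <- rbinom(n, 1, 0.85)
  signs <- osteomiR:::cox_signs(x, tm, ev)
  for (i in 1:4) {
    b <- coef(survival::coxph(survival::Surv(tm, ev) ~ x[i, ],
                              ties = "breslow"))
    expect_equal(unname(signs[i]), unname(sign(b)))
  }
})

test_that("LOOCV scores never touch a sample's own outcome and have null AUC near 0.5", {
  co <- generate_cohort(cohort_config(n_samples = 40L, n_features = 10L,
                                      n_cluster_features = 3L, seed = 21L))
  x <- co$expression
  lo <- loocv_risk_scores(x, co$survival)
  expect_length(lo$scores, 40)
  expect_equal(dim(lo$signs), c(10L, 40L))
  # permuting sample i's outcome leaves its own score's dependence on other
  # folds only: other samples' scores change at most via their sign refits,
  # and sample i's expression never enters its own signs
  sv2 <- co$survival
  sv2$event[1] <- 1 - sv2$event[1]
  sv2$time_months[1] <- sv2$time_months[1] + 30
  lo2 <- loocv_risk_scores(x, sv2)
  expect_equal(lo$signs[, 1], lo2$signs[, 1])   # fold 1 excludes sample 1

  # feature independent of outcome: AUC distribution centered near 0.5
  aucs <- vapply(1:25, function(s) {
    coN <- generate_cohort(cohort_config(n_samples = 60L, n_features = 5L,
                                         n_cluster_features = 2L,
                                         effect_size_delta = 0,
                                         log_hr_beta = 0, seed = 500 + s))
    tdroc_curve(loocv_risk_scores(coN$expression, coN$survival)$scores,
                coN$survival, 60)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
  expect_error(loocv_risk_scores(x[, 1:2], co$survival[1:2, ]), "3 samples")
})

test_that("km_logrank matches a hand-worked two-group toy and handles degenerate input", {
  # identical groups: no difference to detect
  tm <- c(2, 4, 6, 8, 2, 4, 6, 8)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  same <- km_logrank(rep(c("a", "b"), each = 4), toy_surv(tm, ev))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # 6+6 toy, all events, distinct times: hand-computed log-rank
  # group a times 1,2,3,4,5,6; group b times 7,8,9,10,11,12
  tm2 <- c(1:6, 7:12); ev2 <- rep(1, 12)
  g2 <- rep(c("a", "b"), each = 6)
  res <- km_logrank(g2, toy_surv(tm2, ev2))
  # observed events in a: 6; expected = sum over first 6 deaths of n_a/n
  exp_a <- sum(c(6 / 12, 5 / 11, 4 / 10, 3 / 9, 2 / 8, 1 / 7)) + 0
  var_a <- sum(vapply(seq_len(11), function(i) {
    n <- 12 - i + 1
    na <- max(6 - (i - 1), 0)  # a-patients remaining before i-th death
    na / n * (1 - na / n) * (n - 1) / (n - 1)
  }, numeric(1)))
  chisq_hand <- (6 - exp_a)^2 / var_a
  expect_equal(res$chisq, chisq_hand, tolerance = 1e-10)
  expect_equal(res$medians[["a"]], "3")
  expect_equal(res$medians[["b"]], "9")

  # KM curve values against the aggregated-formula oracle
  cv <- res$curves[res$curves$group == "a", ]
  for (k in seq_len(nrow(cv)))
    expect_equal(cv$surv[k], oracle_km_at(1:6, rep(1, 6), cv$time[k]))

  # censored-beyond-half group reports "not reached"
  nr <- km_logrank(rep(c("a", "b"), each = 3),
                   toy_surv(c(1, 2, 3, 10, 20, 30),
                            c(1, 1, 1, 0, 0, 0)))
  expect_equal(nr$medians[["b"]], "not reached")
  expect_error(km_logrank(rep(c("a", "b"), 3),
                          toy_surv(1:6, rep(0, 6))), "censored")
})

test_that("cross-validated lambda selection returns a candidate from the grid", {
  set.seed(9)
  n <- 60
  x <- cbind(a = rnorm(n), b = rnorm(n))
  sv <- toy_surv(rexp(n, 0.05 * exp(0.7 * x[, 1])), rbinom(n, 1, 0.9))
  lam <- choose_cox_lambda(x, sv, lambdas = c(0.1, 1, 10), seed = 2L)
  expect_true(lam %in% c(0.1, 1, 10))
  expect_length(attr(lam, "cvpl"), 3)
})
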