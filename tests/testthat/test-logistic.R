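test_that("IRLS statistics at beta = 0 take their symmetric closed forms", {
  des <- rand_design(9, 3, seed = 21)
  set.seed(22); y <- rbinom(9, 1, 0.5)
  p <- compute_glm_intermediates(des, y, beta = numeric(3))
  expect_equal(p$components$gradient,
               unname(drop(crossprod(des$x, y - 0.5))), tolerance = 1e-14)
  expect_equal(unname(p$components$information),
               unname(crossprod(des$x) / 4), tolerance = 1e-14)
  expect_equal(p$components$loglik, 9 * log(0.5), tolerance = 1e-12)

  # all-zero outcome: gradient is -X'1/2
  p0 <- compute_glm_intermediates(des, rep(0, 9), beta = numeric(3))
  expect_equal(p0$components$gradient,
               unname(drop(-0.5 * crossprod(des$x, rep(1, 9)))),
               tolerance = 1e-14)
})

test_that("IRLS statistics match per-row accumulation on a random instance", {
  des <- rand_design(12, 3, seed = 31)
  set.seed(32)
  y <- rbinom(12, 1, 0.6)
  beta <- rnorm(3, 0, 0.5)
  p <- compute_glm_intermediates(des, y, beta)
  grad <- numeric(3); info <- matrix(0, 3, 3); ll <- 0
  for (i in 1:12) {
    xi <- des$x[i, ]
    mu <- 1 / (1 + exp(-sum(xi * beta)))
    grad <- grad + xi * (y[i] - mu)
    info <- info + tcrossprod(xi) * mu * (1 - mu)
    ll <- ll + y[i] * log(mu) + (1 - y[i]) * log(1 - mu)
  }
  expect_equal(p$components$gradient, unname(grad), tolerance = 1e-12)
  expect_equal(unname(p$components$information), info, tolerance = 1e-12)
  expect_equal(p$components$loglik, ll, tolerance = 1e-12)
})

test_that("a zero gradient is a stationary point of the IRLS step", {
  p <- dranet:::new_payload("glm_iteration", "s", 0L, "d", list(
    n = 10, gradient = numeric(3), information = diag(3), loglik = -5))
  beta <- c(0.3, -0.2, 1)
  expect_identical(irls_step(p, beta), beta)
})

test_that("intercept-only IRLS converges to the log-odds of the mean", {
  set.seed(41)
  y <- rbinom(40, 1, 0.7)
  des <- toy_design(matrix(1, 40, 1, dimnames = list(NULL, "(Intercept)")))
  beta <- 0
  for (i in 1:10) {
    agg <- aggregate_payloads(list(
      compute_glm_intermediates(des, y, beta)))
    beta <- irls_step(agg, beta)
  }
  expect_equal(beta, log(mean(y) / (1 - mean(y))), tolerance = 1e-10)
})

test_that("two-site distributed IRLS reproduces the pooled MLE", {
  set.seed(51)
  x <- cbind(1, rnorm(60), rnorm(60))
  colnames(x) <- c("(Intercept)", "a", "b")
  y <- rbinom(60, 1, plogis(drop(x %*% c(-0.3, 0.8, -0.5))))
  split <- list(1:25, 26:60)
  beta <- numeric(3)
  for (i in 1:30) {
    ps <- lapply(seq_along(split), function(s)
      compute_glm_intermediates(
        toy_design(x[split[[s]], , drop = FALSE]), y[split[[s]]], beta,
        paste0("s", s)))
    beta_new <- irls_step(aggregate_payloads(ps), beta)
    if (check_convergence(beta, beta_new, 1e-12)) break
    beta <- beta_new
  }
  ref <- glm.fit(x, y, family = binomial(),
                 control = glm.control(epsilon = 1e-12))
  expect_equal(beta, unname(ref$coefficients), tolerance = 1e-10)
})

test_that("convergence is the strict maximum-absolute-change criterion", {
  expect_true(check_convergence(c(1, 2), c(1, 2), 1e-9))
  expect_true(check_convergence(c(1, 2), c(1, 2.009), 0.01))
  expect_false(check_convergence(c(1, 2), c(1, 2.011), 0.01))
  expect_error(check_convergence(1:2, 1:3, 0.01),
               class = "dranet_protocol_error")
})

test_that("logistic fit statistics follow the -2logL conventions", {
  fs <- logistic_fit_statistics(-2711.62455, n = 5452, p = 24)
  expect_equal(fs$aic - fs$neg2loglik, 48)           # 2p for 24 parameters
  expect_equal(fs$sc - fs$neg2loglik, 24 * log(5452))
  fs0 <- logistic_fit_statistics(-10, n = 100, p = 0)
  expect_identical(fs0$aic, fs0$neg2loglik)
  expect_identical(fs0$sc, fs0$neg2loglik)

  # against an independent pooled fit
  set.seed(61)
  x <- cbind(1, rnorm(80))
  y <- rbinom(80, 1, plogis(0.4 * x[, 2]))
  ref <- glm(y ~ x[, 2], family = binomial())
  des <- toy_design(`colnames<-`(x, c("(Intercept)", "a")))
  beta <- numeric(2)
  for (i in 1:25) {
    agg <- aggregate_payloads(list(compute_glm_intermediates(des, y, beta)))
    beta <- irls_step(agg, beta)
  }
  ll <- aggregate_payloads(list(
    compute_glm_intermediates(des, y, beta)))$components$loglik
  fs <- logistic_fit_statistics(ll, 80, 2)
  expect_equal(fs$neg2loglik, ref$deviance, tolerance = 1e-8)
  expect_equal(fs$aic, AIC(ref), tolerance = 1e-8)
})

test_that("prediction binning is a sorted partition with a true-size tail", {
  set.seed(71)
  mu <- runif(12); y <- rbinom(12, 1, mu)
  b <- bin_predictions(mu, y, 6)
  expect_identical(nrow(b), 2L)
  expect_equal(sum(b[, "size"]), 12)
  expect_equal(sum(b[, "events"]), sum(y))
  expect_true(all(b[, "events"] + b[, "nonevents"] == b[, "size"]))
  expect_true(!is.unsorted(b[, "mean"]))

  # bin size 1: one bin per record, means are the records themselves
  b1 <- bin_predictions(mu, y, 1)
  expect_identical(nrow(b1), 12L)
  expect_equal(b1[, "mean"], sort(mu))

  # remainder rule: 13 records in bins of 6 -> sizes 6, 6, 1
  mu13 <- runif(13); y13 <- rbinom(13, 1, 0.5)
  expect_identical(bin_predictions(mu13, y13, 6)[, "size"], c(6, 6, 1))
})

test_that("binned ROC with unit bins equals all-pairs concordance", {
  set.seed(81)
  mu <- round(runif(40), 2)            # duplicates force tie handling
  y <- rbinom(40, 1, mu)
  roc <- roc_from_bins(bin_predictions(mu, y, 1))
  expect_equal(roc$auc, auc_concordance(mu, y), tolerance = 1e-12)

  # perfectly separated predictions
  sep <- roc_from_bins(bin_predictions(c(0.1, 0.2, 0.8, 0.9),
                                       c(0, 0, 1, 1), 1))
  expect_identical(sep$auc, 1)
  # uninformative predictions
  flat <- roc_from_bins(bin_predictions(rep(0.4, 10),
                                        c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
                                        1))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_from_bins(bin_predictions(runif(5), rep(1, 5), 1)),
               class = "dranet_degenerate_error")
})

test_that("Hosmer-Lemeshow decile grouping has df = 8 and a clean null", {
  set.seed(91)
  mu <- runif(500, 0.2, 0.9)
  y <- rbinom(500, 1, mu)
  bins <- bin_predictions(mu, y, 6)
  hl <- hosmer_lemeshow_from_bins(bins, 10)
  expect_identical(hl$df, 8L)
  expect_equal(sum(hl$table$size), 500)

  # O = E in every group gives chi-square 0, p = 1
  b <- cbind(mean = c(0.2, 0.5, 0.8), events = c(2, 5, 8),
             nonevents = c(8, 5, 2), size = c(10, 10, 10))
  hl0 <- hosmer_lemeshow_from_bins(b, 3)
  expect_equal(hl0$chisq, 0)
  expect_equal(hl0$p_value, 1)

  # constructed three-group table against the direct formula
  b2 <- cbind(mean = c(0.1, 0.4, 0.7), events = c(3, 3, 6),
              nonevents = c(7, 7, 4), size = c(10, 10, 10))
  hl2 <- hosmer_lemeshow_from_bins(b2, 3)
  e <- c(1, 4, 7)
  chi <- sum((c(3, 3, 6) - e)^2 / (e * (1 - e / 10)))
  expect_equal(hl2$chisq, chi, tolerance = 1e-12)
  expect_identical(hl2$df, 1L)
})

test_that("the distributed logistic fit converges within the iteration cap", {
  co <- small_cohort(seed = 9, n = c(250L, 300L, 200L))
  f <- dra_fit(co$sites, co$specs$logistic)
  expect_true(f$converged)
  expect_lte(f$iterations, 25L)
  expect_s3_class(f, "dra_fit")
  expect_true(all(is.finite(f$se)) && all(f$se > 0))
  expect_lte(f$fit_statistics$neg2loglik, Inf)
  expect_equal(f$fit_statistics$aic,
               f$fit_statistics$neg2loglik + 2 * length(coef(f)))
})
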