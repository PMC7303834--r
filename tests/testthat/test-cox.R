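test_that("risk-set sums at beta = 0 count subjects and sum covariates", {
  set.seed(101)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  tm <- c(2, 5, 5, 7, 8, 8, 8, 11, 12, 15)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 0, 1, 0)
  grid <- sort(unique(tm[ev == 1]))
  p <- compute_cox_intermediates(toy_design(x), tm, ev, numeric(2), grid)
  for (j in seq_along(grid)) {
    at <- tm >= grid[j]
    expect_equal(p$components$S0[j], sum(at))
    expect_equal(p$components$S1[j, ], unname(colSums(x[at, , drop = FALSE])))
  }
  # ties between an event and a censoring keep both at risk at that time
  expect_equal(p$components$S0[grid == 5], 9)
  expect_equal(p$components$d[grid == 8], 2)       # censored one excluded
})

test_that("a site with nobody at risk at a late grid time reports zero sums", {
  x <- matrix(1:3 / 10, 3, 1, dimnames = list(NULL, "a"))
  p <- compute_cox_intermediates(toy_design(x), c(1, 2, 3), c(1, 0, 1),
                                 0, grid = c(1, 3, 50))
  expect_equal(p$components$S0[3], 0)
  expect_equal(p$components$S1[3, ], 0)
})

test_that("risk-set and tied-event sums match per-subject accumulation", {
  set.seed(111)
  n <- 10
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  tm <- sample(c(3, 5, 5, 8, 8, 8, 10, 12, 12, 20))
  ev <- rbinom(n, 1, 0.8)
  beta <- c(0.4, -0.3)
  grid <- sort(unique(c(tm[ev == 1], 7)))   # includes a foreign event time
  p <- compute_cox_intermediates(toy_design(x), tm, ev, beta, grid)
  w <- exp(drop(x %*% beta))
  idx <- dranet:::lower_tri_index(2)
  for (j in seq_along(grid)) {
    at <- which(tm >= grid[j])
    S2 <- matrix(0, 2, 2)
    for (i in at) S2 <- S2 + w[i] * tcrossprod(x[i, ])
    expect_equal(p$components$S0[j], sum(w[at]), tolerance = 1e-12)
    expect_equal(p$components$S1[j, ],
                 unname(colSums(w[at] * x[at, , drop = FALSE])),
                 tolerance = 1e-12)
    expect_equal(p$components$S2[j, ], S2[idx], tolerance = 1e-12)
    dead <- which(ev == 1 & tm == grid[j])
    expect_equal(p$components$d[j], length(dead))
    if (length(dead)) {
      expect_equal(p$components$s[j, ],
                   unname(colSums(x[dead, , drop = FALSE])),
                   tolerance = 1e-12)
      expect_equal(p$components$S0D[j], sum(w[dead]), tolerance = 1e-12)
      S2D <- matrix(0, 2, 2)
      for (i in dead) S2D <- S2D + w[i] * tcrossprod(x[i, ])
      expect_equal(p$components$S2D[j, ], S2D[idx], tolerance = 1e-12)
    }
  }
})

test_that("Efron and Breslow coincide exactly when no times are tied", {
  set.seed(121)
  n <- 12
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  tm <- sample(seq_len(100), n)              # distinct times
  ev <- rbinom(n, 1, 0.7); ev[1] <- 1
  grid <- sort(unique(tm[ev == 1]))
  beta <- 0.3
  agg <- aggregate_payloads(list(
    compute_cox_intermediates(toy_design(x), tm, ev, beta, grid)))
  se_e <- cox_score_information(agg, beta, "efron")
  se_b <- cox_score_information(agg, beta, "breslow")
  expect_identical(se_e$loglik, se_b$loglik)
  expect_identical(se_e$gradient, se_b$gradient)
  expect_identical(se_e$hessian, se_b$hessian)
})

test_that("log partial likelihood and score match brute force with cross-site ties", {
  # 6 subjects across 2 sites; time 10 is tied across the sites
  x1 <- matrix(c(0.5, -0.2, 0.1), 3, 1, dimnames = list(NULL, "a"))
  x2 <- matrix(c(0.3, -0.4, 0.8), 3, 1, dimnames = list(NULL, "a"))
  t1 <- c(10, 15, 20); e1 <- c(1, 1, 0)
  t2 <- c(10, 12, 25); e2 <- c(1, 0, 1)
  beta <- 0.4
  grids <- list(
    dranet:::compute_event_grid(t1, e1, "s1", digest = "d"),
    dranet:::compute_event_grid(t2, e2, "s2", digest = "d"))
  grid <- collect_event_grid(grids)$components$times
  agg <- aggregate_payloads(list(
    compute_cox_intermediates(toy_design(x1), t1, e1, beta, grid, "s1",
                              digest = "d"),
    compute_cox_intermediates(toy_design(x2), t2, e2, beta, grid, "s2",
                              digest = "d")))
  xp <- rbind(x1, x2); tp <- c(t1, t2); ep <- c(e1, e2)
  for (ties in c("efron", "breslow")) {
    si <- cox_score_information(agg, beta, ties)
    expect_equal(si$loglik, brute_cox_loglik(xp, tp, ep, beta, ties),
                 tolerance = 1e-12)
    expect_equal(si$gradient,
                 brute_cox_gradient(xp, tp, ep, beta, ties),
                 tolerance = 1e-7)
  }
  # at beta = 0 a single event with R at risk contributes -log(R)
  agg0 <- aggregate_payloads(list(
    compute_cox_intermediates(toy_design(x1), c(5, 9, 9), c(1, 0, 0),
                              0, grid = 5)))
  si0 <- cox_score_information(agg0, 0, "efron")
  expect_equal(si0$loglik, -log(3), tolerance = 1e-14)
})

test_that("Newton steps are stationary at a zero gradient and detect divergence", {
  expect_identical(newton_step(numeric(2), -diag(2), c(1, 2)), c(1, 2))
  # monotone likelihood: the covariate perfectly orders the event times
  d <- data.frame(t = c(1, 2, 3, 4, 5, 6), e = 1,
                  x = c(6, 5, 4, 3, 2, 1))
  sp <- dra_spec("cox", c("t", "e"), "x")
  expect_warning(f <- dra_fit(list(d), sp), "did not converge")
  expect_false(f$converged)
  expect_identical(f$iterations, sp$max_iterations)
})

test_that("distributed Newton-Raphson reproduces an independent Efron fit", {
  skip_if_not_installed("survival")
  co <- small_cohort(seed = 15, n = c(150L, 180L, 120L))
  sp <- cohort_specs(co$truth$config, epsilon = 1e-10)$cox
  f <- dra_fit(co$sites, sp)
  pooled <- pooled_rows(co)
  X <- dra_design(pooled, sp)$x
  ref <- survival::coxph(
    survival::Surv(pooled$time_wl20, pooled$event_wl20) ~ X,
    ties = "efron")
  expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-9)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-9)
  expect_equal(f$fit_statistics$neg2loglik, -2 * ref$loglik[2],
               tolerance = 1e-8)
  # fit statistic identities
  p <- length(coef(f)); D <- f$fit_statistics$n_events
  expect_equal(f$fit_statistics$aic - f$fit_statistics$neg2loglik, 2 * p)
  expect_equal(f$fit_statistics$sbc - f$fit_statistics$neg2loglik,
               p * log(D))
  # the log partial likelihood never decreased across Newton rounds
  expect_true(all(diff(f$diagnostics$loglik_path) > -1e-8))
})

test_that("cox fit statistics collapse when p = 0", {
  fs <- cox_fit_statistics(-100, 0, 50)
  expect_identical(fs$neg2loglik, 200)
  expect_identical(fs$aic, 200)
  expect_identical(fs$sbc, 200)
})

test_that("baseline survival follows the Breslow estimator", {
  # beta = 0, one site, no censoring: H0 steps are d_j / R_j
  x <- matrix(0, 4, 1, dimnames = list(NULL, "a"))
  tm <- c(1, 2, 3, 4); ev <- rep(1, 4)
  grid <- tm
  agg <- aggregate_payloads(list(
    compute_cox_intermediates(toy_design(x), tm, ev, 0, grid)))
  sv <- baseline_survival(agg, 0, 0)
  h0 <- cumsum(1 / c(4, 3, 2, 1))
  expect_equal(attr(sv, "h0"), h0, tolerance = 1e-14)
  expect_equal(sv$surv, exp(-h0), tolerance = 1e-14)
  expect_true(all(diff(sv$surv) <= 0))
  expect_true(all(sv$surv <= 1))

  # median is the first time the step function reaches 0.5
  sv2 <- structure(data.frame(time = c(10, 20, 30),
                              surv = c(0.9, 0.6, 0.4)))
  med <- sv2$time[which(sv2$surv <= 0.5)[1]]
  expect_identical(med, 30)
  # and through the estimator itself: survival never reaching 0.5
  x2 <- matrix(0, 10, 1, dimnames = list(NULL, "a"))
  agg2 <- aggregate_payloads(list(
    compute_cox_intermediates(toy_design(x2), c(1:9, 10), c(1, rep(0, 9)),
                              0, grid = 1)))
  sv3 <- baseline_survival(agg2, 0, 0)
  expect_true(is.na(attr(sv3, "median")))
})

test_that("the distributed survival curve matches a per-subject Breslow oracle", {
  co <- small_cohort(seed = 17, n = c(100L, 140L, 80L))
  sp <- cohort_specs(co$truth$config, epsilon = 1e-9)$cox
  f <- dra_fit(co$sites, sp)
  pooled <- pooled_rows(co)
  X <- dra_design(pooled, sp)$x
  beta <- unname(coef(f))
  w <- exp(drop(X %*% beta))
  grid <- f$diagnostics$survival$time
  h0 <- vapply(grid, function(t)
    sum(pooled$event_wl20 == 1 & pooled$time_wl20 == t) /
      sum(w[pooled$time_wl20 >= t]), 0)
  H0 <- cumsum(h0)
  x_ref <- colMeans(X[pooled$event_wl20 == 1, , drop = FALSE])
  expect_equal(f$diagnostics$x_ref, unname(x_ref), tolerance = 1e-10,
               ignore_attr = TRUE)
  s_ref <- exp(-H0 * exp(sum(x_ref * beta)))
  expect_equal(f$diagnostics$survival$surv, s_ref, tolerance = 1e-10)
  med <- grid[which(s_ref <= 0.5)[1]]
  expect_identical(f$diagnostics$median_time, med)
})
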