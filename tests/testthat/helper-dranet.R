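# Shared fixtures: everything is generated in code at test time.

# A small three-site cohort plus its matching specs.
small_cohort <- function(seed = 7, n = c(120L, 150L, 90L), ...) {
  generate_cohort(cohort_config(n_sites = length(n), n_per_site = n,
                                seed = seed, ...))
}

pooled_rows <- function(cohort) {
  d <- do.call(rbind, cohort$sites)
  rownames(d) <- NULL
  d
}

# A plain numeric design for unit tests of the low-level operations.
toy_design <- function(x) list(x = x, names = colnames(x),
                               intercept = FALSE)

rand_design <- function(n, p, seed, intercept = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  if (intercept) x[, 1L] <- 1
  colnames(x) <- c(if (intercept) "(Intercept)",
                   paste0("x", seq_len(p - intercept)))
  list(x = x, names = colnames(x), intercept = intercept)
}

# All-pairs concordance AUC with ties counted 1/2 (brute force oracle).
auc_concordance <- function(mu, y) {
  pos <- mu[y == 1]
  neg <- mu[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force Cox log partial likelihood and gradient on pooled rows
# (direct per-subject evaluation, independent of the payload machinery).
brute_cox_loglik <- function(x, time, event, beta,
                             tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  ut <- sort(unique(time[event == 1]))
  ll <- 0
  for (t in ut) {
    dead <- which(event == 1 & time == t)
    atrisk <- which(time >= t)
    d <- length(dead)
    eta <- drop(x %*% beta)
    s0 <- sum(exp(eta[atrisk]))
    s0d <- sum(exp(eta[dead]))
    ll <- ll + sum(eta[dead])
    if (tie_method == "breslow" || d == 1) {
      ll <- ll - d * log(s0)
    } else {
      for (k in 0:(d - 1)) ll <- ll - log(s0 - (k / d) * s0d)
    }
  }
  ll
}

brute_cox_gradient <- function(x, time, event, beta, tie_method = "efron",
                               h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    (brute_cox_loglik(x, time, event, bp, tie_method) -
       brute_cox_loglik(x, time, event, bm, tie_method)) / (2 * h)
  }, 0)
}

max_fit_diff <- function(a, b) {
  cmp <- dra_compare(a, b)
  max(abs(cmp$coefficients$diff_estimate), abs(cmp$coefficients$diff_se))
}
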