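# Distributed Cox proportional hazards regression by distributed
# Newton-Raphson. The center first collects each site's distinct event
# times and tie counts and shares the merged global grid back, so that
# every site can evaluate its risk-set sums at every event time in the
# network (including times at which only other sites had events). Each
# Newton round a site returns, per global event time t:
#   S0(t) = sum_{i: T_i >= t} w_i,  S1(t) = sum x_i w_i,
#   S2(t) = sum x_i x_i' w_i,                w_i = exp(x_i' beta)
# plus event-side sums over its own events at exactly t: the tie count
# d_t, the event covariate total s_t, and the tied-event weighted sums
# S0D, S1D, S2D used by the Efron correction. Summed across sites these
# are exactly the pooled quantities, so cross-site ties are handled
# identically to a pooled analysis.
#
# Symmetric p x p blocks (S2, S2D) travel as their lower triangle, one row
# of p(p+1)/2 values per grid time.

#' Collect the global event-time grid
#'
#' @param grids List of per-site `event_grid` payloads (sorted distinct
#'   local event times with tie counts).
#' @return Aggregated `event_grid` payload: the sorted union of event
#'   times with summed tie counts.
#' @export
collect_event_grid <- function(grids) {
  agg <- aggregate_payloads(grids)
  if (length(agg$components$times) == 0L)
    stop_dranet("no events anywhere in the network",
                class = "dranet_no_events_error")
  agg
}

# Site-side event grid: distinct local event times and tie counts.
compute_event_grid <- function(times, events, site_id = "site",
                               iteration = 0L, digest = "") {
  et <- times[events == 1]
  ut <- sort(unique(et))
  d <- if (length(ut)) as.numeric(tabulate(match(et, ut))) else numeric(0)
  new_payload("event_grid", site_id, iteration, digest,
              list(n = as.numeric(length(times)), times = ut, d = d))
}

# indices packing the lower triangle (column-major, diagonal included) of
# a p x p symmetric matrix into a length p(p+1)/2 vector
lower_tri_index <- function(p) which(lower.tri(matrix(0, p, p), diag = TRUE))

pack_sym <- function(m, idx) m[idx]

unpack_sym <- function(v, p, idx) {
  m <- matrix(0, p, p)
  m[idx] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Site-side risk-set sums for one Newton round
#'
#' @param design Design list from [dra_design()] (no intercept column for
#'   the Cox family).
#' @param times,events Event time (days, > 0) and 0/1 event indicator per
#'   row. Subjects whose time equals a grid time are at risk at that time,
#'   whether they have the event or are censored there.
#' @param beta Current parameter vector.
#' @param grid Numeric vector of global event times (ascending).
#' @param site_id,iteration,digest Payload manifest fields.
#' @param kind Payload kind, `"cox_iteration"` or `"cox_diagnostics"`.
#' @return A payload with per-grid-time risk-set and tied-event sums.
#' @export
compute_cox_intermediates <- function(design, times, events, beta, grid,
                                      site_id = "site", iteration = 0L,
                                      digest = "", kind = "cox_iteration") {
  x <- design$x
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(beta) == p, length(grid) >= 1L)
  m <- length(grid)
  idx <- lower_tri_index(p)
  w <- exp(drop(x %*% beta))

  # ---- at-risk sums via descending-time block accumulation ----
  ord <- order(times, decreasing = TRUE)
  To <- times[ord]; wo <- w[ord]; Xo <- x[ord, , drop = FALSE]
  sT <- sort(times)
  # number of subjects with T >= t, exact on equal doubles
  k_at_risk <- n - findInterval(grid, sT, left.open = TRUE)
  cs0 <- cumsum(wo)
  cs1 <- apply(wo * Xo, 2L, cumsum)
  if (n == 1L) cs1 <- matrix(cs1, nrow = 1L)
  S0 <- ifelse(k_at_risk > 0L, cs0[pmax(k_at_risk, 1L)], 0)
  S1 <- matrix(0, m, p)
  S2 <- matrix(0, m, p * (p + 1L) / 2L)
  pos <- k_at_risk > 0L
  S1[pos, ] <- cs1[k_at_risk[pos], , drop = FALSE]
  # S2 grows as grid times decrease; accumulate blocks entering the risk set
  acc <- matrix(0, p, p)
  prev_k <- 0L
  for (j in order(grid, decreasing = TRUE)) {
    kj <- k_at_risk[j]
    if (kj > prev_k) {
      blk <- Xo[(prev_k + 1L):kj, , drop = FALSE] *
        sqrt(wo[(prev_k + 1L):kj])
      acc <- acc + crossprod(blk)
      prev_k <- kj
    }
    S2[j, ] <- pack_sym(acc, idx)
  }

  # ---- event-side sums at each grid time ----
  d <- numeric(m); s <- matrix(0, m, p)
  S0D <- numeric(m); S1D <- matrix(0, m, p)
  S2D <- matrix(0, m, p * (p + 1L) / 2L)
  ev <- which(events == 1)
  if (length(ev)) {
    gi <- match(times[ev], grid)
    if (anyNA(gi))
      stop_dranet("site %s: event time absent from the shared grid",
                  site_id, class = "dranet_protocol_error")
    for (j in unique(gi)) {
      rows <- ev[gi == j]
      d[j] <- length(rows)
      xb <- x[rows, , drop = FALSE]
      s[j, ] <- colSums(xb)
      wb <- w[rows]
      S0D[j] <- sum(wb)
      S1D[j, ] <- colSums(xb * wb)
      S2D[j, ] <- pack_sym(crossprod(xb * sqrt(wb)), idx)
    }
  }
  new_payload(kind, site_id, iteration, digest, list(
    n = as.numeric(n), times = as.numeric(grid),
    S0 = S0, S1 = S1, S2 = S2,
    d = d, s = s, S0D = S0D, S1D = S1D, S2D = S2D))
}

#' Log partial likelihood, score, and Hessian from aggregated sums
#'
#' Evaluates the Cox log partial likelihood and its first two derivatives
#' from the network-wide risk-set sums, under either tie convention.
#' Breslow, per event time t with d ties: `ll_t = s' beta - d log S0`.
#' Efron replaces the single denominator by
#' `r_k = S0 - (k/d) S0D, k = 0..d-1`, with `S1 - (k/d) S1D` and
#' `S2 - (k/d) S2D` entering the score and Hessian analogously. The two
#' coincide whenever every d equals 1.
#'
#' @param agg Aggregated `cox_iteration`/`cox_diagnostics` payload.
#' @param beta Current parameter vector.
#' @param tie_method `"efron"` or `"breslow"`.
#' @return List `loglik`, `gradient` (length p), `hessian` (p x p,
#'   negative semi-definite).
#' @export
cox_score_information <- function(agg, beta, tie_method = c("efron",
                                                            "breslow")) {
  tie_method <- match.arg(tie_method)
  cmp <- agg$components
  p <- length(beta)
  idx <- lower_tri_index(p)
  m <- length(cmp$times)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  for (j in seq_len(m)) {
    dj <- cmp$d[j]
    if (dj < 1) next
    S0 <- cmp$S0[j]
    if (S0 <= 0)
      stop_dranet("risk-set sum underflow at event time %g", cmp$times[j],
                  class = "dranet_riskset_error")
    S1 <- cmp$S1[j, ]
    S2 <- unpack_sym(cmp$S2[j, ], p, idx)
    sj <- cmp$s[j, ]
    ll <- ll + sum(sj * beta)
    if (tie_method == "breslow" || dj == 1) {
      u <- S1 / S0
      ll <- ll - dj * log(S0)
      grad <- grad + sj - dj * u
      hess <- hess - dj * (S2 / S0 - tcrossprod(u))
    } else {
      S0D <- cmp$S0D[j]
      S1D <- cmp$S1D[j, ]
      S2D <- unpack_sym(cmp$S2D[j, ], p, idx)
      for (k in 0:(dj - 1)) {
        f <- k / dj
        r <- S0 - f * S0D
        if (r <= 0)
          stop_dranet("Efron denominator underflow at event time %g",
                      cmp$times[j], class = "dranet_riskset_error")
        u <- (S1 - f * S1D) / r
        ll <- ll - log(r)
        grad <- grad - u
        hess <- hess - ((S2 - f * S2D) / r - tcrossprod(u))
      }
      grad <- grad + sj
    }
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

#' One Newton-Raphson update for the Cox model
#'
#' @param gradient,hessian Aggregated score and Hessian at `beta`.
#' @param beta Current parameter vector.
#' @return `beta + solve(-hessian, gradient)` via Cholesky of the observed
#'   information.
#' @export
newton_step <- function(gradient, hessian, beta) {
  sol <- tryCatch(chol_solve_sym(-hessian, gradient),
                  error = function(e)
                    stop_dranet(paste0(
                      "observed information is not positive definite ",
                      "(monotone likelihood or collinearity): %s"),
                      conditionMessage(e),
                      class = "dranet_identifiability_error"))
  as.numeric(beta + sol$x)
}

#' Cox-model fit statistics
#'
#' @param loglik Log partial likelihood at the final estimates.
#' @param p Number of covariate columns.
#' @param n_events Total number of events across the network (the
#'   effective sample size in the Schwarz criterion for partial
#'   likelihood).
#' @return Named list `neg2loglik`, `aic`, `sbc` with
#'   `AIC = -2logL + 2p`, `SBC = -2logL + p log(D)`.
#' @export
cox_fit_statistics <- function(loglik, p, n_events) {
  m2 <- -2 * loglik
  list(neg2loglik = m2, aic = m2 + 2 * p, sbc = m2 + p * log(n_events))
}

#' Baseline survival curve at a reference covariate vector
#'
#' Breslow cumulative baseline hazard `H0(t) = sum_{t_j <= t} d_j/S0(t_j)`
#' from the aggregated sums at the final estimates, with the survival
#' function `S(t | x) = exp(-H0(t) exp(x' beta))` evaluated at the given
#' reference covariates (conventionally the mean covariate vector of the
#' patients who experienced the event). The median is the smallest grid
#' time with `S <= 0.5`, without interpolation; it is `NA` when the curve
#' never reaches 0.5.
#'
#' @param agg Aggregated payload at the final estimates.
#' @param beta Final parameter vector.
#' @param x_ref Reference covariate vector (length p).
#' @return Object of class `"dra_survcurve"`: data frame `time`,
#'   `surv`, plus attributes `x_ref`, `median`, `h0` (baseline cumulative
#'   hazard).
#' @export
baseline_survival <- function(agg, beta, x_ref) {
  cmp <- agg$components
  keep <- cmp$d >= 1
  tj <- cmp$times[keep]
  h0 <- cumsum(cmp$d[keep] / cmp$S0[keep])
  risk <- exp(sum(x_ref * beta))
  surv <- exp(-h0 * risk)
  med <- if (any(surv <= 0.5)) tj[which(surv <= 0.5)[1L]] else NA_real_
  structure(data.frame(time = tj, surv = surv),
            x_ref = x_ref, median = med, h0 = h0,
            class = c("dra_survcurve", "data.frame"))
}

#' @export
print.dra_survcurve <- function(x, ...) {
  med <- attr(x, "median")
  cat(sprintf(
    "Baseline survival curve: %d event times, S(max) = %.4f, median = %s\n",
    nrow(x), x$surv[nrow(x)],
    if (is.na(med)) "not reached" else format(med)))
  invisible(x)
}
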