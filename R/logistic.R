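# Distributed logistic regression by distributed iteratively reweighted
# least squares (IRLS): each site returns the score vector X'(y - mu) and
# Fisher information X'WX at the current parameter vector; the center sums
# them and takes a Newton step. A final diagnostics round evaluates the
# log likelihood at the converged estimates and returns privacy-preserving
# prediction bins for the ROC curve and calibration test.

#' Site-side IRLS statistics for logistic regression
#'
#' At the current parameter vector, computes the site's row count, score
#' vector `X'(y - mu)`, Fisher information `X'WX` with
#' `W = diag(mu(1 - mu))`, and Bernoulli log-likelihood contribution,
#' where `mu = 1/(1 + exp(-X beta))`.
#'
#' @param design Design list from [dra_design()].
#' @param y 0/1 outcome vector.
#' @param beta Current parameter vector (length p).
#' @param site_id,iteration,digest Payload manifest fields.
#' @return A `glm_iteration` payload.
#' @export
compute_glm_intermediates <- function(design, y, beta, site_id = "site",
                                      iteration = 0L, digest = "") {
  x <- design$x
  p <- ncol(x)
  if (length(beta) != p)
    stop_dranet("beta has length %d, design width is %d", length(beta), p,
                class = "dranet_protocol_error")
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  # log-likelihood via log1p-stable forms
  ll <- sum(ifelse(eta > 0,
                   y * eta - eta - log1p(exp(-eta)),
                   y * eta - log1p(exp(eta))))
  new_payload("glm_iteration", site_id, iteration, digest, list(
    n = as.numeric(nrow(x)),
    gradient = as.numeric(crossprod(x, y - mu)),
    information = crossprod(x * sqrt(w), x * sqrt(w)),
    loglik = ll))
}

# Diagnostics-round payload: IRLS statistics at the final estimates plus
# the site's prediction bins.
compute_glm_diagnostics <- function(design, y, beta, bin_size,
                                    site_id = "site", iteration = 0L,
                                    digest = "") {
  base <- compute_glm_intermediates(design, y, beta, site_id, iteration,
                                    digest)
  mu <- plogis(drop(design$x %*% beta))
  bins <- bin_predictions(mu, y, bin_size)
  new_payload("glm_diagnostics", site_id, iteration, digest,
              c(base$components, list(bins = bins)))
}

#' One IRLS / Newton update from aggregated statistics
#'
#' @param agg Aggregated `glm_iteration` payload.
#' @param beta Current parameter vector.
#' @return Updated parameter vector
#'   `beta + solve(information, gradient)`, computed through a Cholesky
#'   factorization of the aggregated information.
#' @export
irls_step <- function(agg, beta) {
  info <- agg$components$information
  g <- agg$components$gradient
  sol <- tryCatch(chol_solve_sym(info, g),
                  error = function(e)
                    stop_dranet(paste0(
                      "aggregated information matrix is not positive definite",
                      " (complete separation or collinearity): %s"),
                      conditionMessage(e),
                      class = "dranet_identifiability_error"))
  as.numeric(beta + sol$x)
}

#' Convergence check on successive parameter vectors
#'
#' Declares convergence when the maximum absolute change across all
#' parameters is strictly below `epsilon`.
#'
#' @param beta,beta_new Parameter vectors of equal length.
#' @param epsilon Positive tolerance (network default 0.01).
#' @return Logical.
#' @export
check_convergence <- function(beta, beta_new, epsilon) {
  if (length(beta) != length(beta_new))
    stop_dranet("parameter vectors differ in length (%d vs %d)",
                length(beta), length(beta_new),
                class = "dranet_protocol_error")
  stopifnot(epsilon > 0)
  max(abs(beta_new - beta)) < epsilon
}

#' Logistic-model fit statistics
#'
#' @param loglik Total log likelihood at the final estimates.
#' @param n Total rows across sites.
#' @param p Number of design columns (including intercept).
#' @return Named list `neg2loglik`, `aic`, `sc` with
#'   `AIC = -2logL + 2p` and `SC = -2logL + p log(n)`.
#' @export
logistic_fit_statistics <- function(loglik, n, p) {
  m2 <- -2 * loglik
  list(neg2loglik = m2, aic = m2 + 2 * p, sc = m2 + p * log(n))
}

#' Privacy-preserving prediction bins
#'
#' Sorts a site's predicted probabilities ascending (stable, so ties keep
#' site-local row order), groups consecutive runs of `bin_size` records
#' (final partial bin kept at its true size), and reports per bin the mean
#' predicted value, the event and non-event counts, and the bin size.
#' Individual predictions never leave the site; only these bin summaries
#' do.
#'
#' @param mu Predicted probabilities.
#' @param y 0/1 outcomes aligned with `mu`.
#' @param bin_size Records per bin (>= 1).
#' @return Numeric matrix with columns `mean`, `events`, `nonevents`,
#'   `size`; row counts sum to `length(mu)`.
#' @export
bin_predictions <- function(mu, y, bin_size) {
  stopifnot(length(mu) == length(y), bin_size >= 1)
  n <- length(mu)
  if (n == 0L)
    return(matrix(numeric(0), ncol = 4L,
                  dimnames = list(NULL, c("mean", "events", "nonevents",
                                          "size"))))
  ord <- order(mu)                      # stable radix order: ties by row
  mu <- mu[ord]; y <- y[ord]
  grp <- (seq_len(n) - 1L) %/% bin_size
  size <- as.numeric(tabulate(grp + 1L))
  events <- as.numeric(rowsum(y, grp))
  means <- as.numeric(rowsum(mu, grp)) / size
  cbind(mean = means, events = events, nonevents = size - events,
        size = size)
}

#' ROC curve and AUC from aggregated prediction bins
#'
#' Merges all sites' bins, sorts them descending by mean predicted value
#' (bins with equal means collapse into a single operating-point step),
#' traces cumulative sensitivity against 1 - specificity, and integrates
#' the area by the trapezoidal rule. With `bin_size = 1` this reproduces
#' the exact pairwise-concordance AUC (ties counted 1/2).
#'
#' @param bins Matrix of bins as produced by [bin_predictions()], stacked
#'   across sites.
#' @return List with `points` (data frame `fpr`, `tpr`, one row per
#'   operating point including the (0,0) origin) and `auc`.
#' @export
roc_from_bins <- function(bins) {
  bins <- as_bins(bins)
  tot_ev <- sum(bins[, "events"])
  tot_ne <- sum(bins[, "nonevents"])
  if (tot_ev == 0 || tot_ne == 0)
    stop_dranet("AUC undefined: need at least one event and one non-event",
                class = "dranet_degenerate_error")
  # merge equal bin means into one step
  key <- bins[, "mean"]
  ord <- order(key, decreasing = TRUE)
  bins <- bins[ord, , drop = FALSE]
  grp <- cumsum(!duplicated(bins[, "mean"]))
  ev <- as.numeric(rowsum(bins[, "events"], grp))
  ne <- as.numeric(rowsum(bins[, "nonevents"], grp))
  tpr <- cumsum(ev) / tot_ev
  fpr <- cumsum(ne) / tot_ne
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (head_(tpr) + tail_(tpr)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# coerce a bare numeric matrix (e.g. fresh from a payload file, where
# dimnames do not survive serialization) back to the bin column layout
as_bins <- function(bins) {
  m <- as_matrix(bins)
  stopifnot(ncol(m) == 4L)
  colnames(m) <- c("mean", "events", "nonevents", "size")
  m
}

head_ <- function(v) v[-length(v)]
tail_ <- function(v) v[-1L]

#' Hosmer-Lemeshow calibration test from aggregated prediction bins
#'
#' Merged bins are sorted ascending by mean predicted value and partitioned
#' into `hl_groups` risk groups at the cumulative-count boundaries nearest
#' `n * k / hl_groups`. Within each group the expected event count is the
#' bin-size-weighted sum of bin means (individual predictions are not
#' available at the center by design), and
#' `chi^2 = sum (O - E)^2 / (E (1 - E/n_g))` with `df = hl_groups - 2`.
#'
#' @param bins Stacked bin matrix.
#' @param hl_groups Number of risk groups (>= 3).
#' @return List `chisq`, `df`, `p_value`, plus the per-group table.
#' @export
hosmer_lemeshow_from_bins <- function(bins, hl_groups = 10L) {
  bins <- as_bins(bins)
  hl_groups <- as.integer(hl_groups)
  stopifnot(hl_groups >= 3L)
  n <- sum(bins[, "size"])
  if (n < hl_groups)
    stop_dranet("fewer records (%d) than requested groups (%d)", n,
                hl_groups, class = "dranet_degenerate_error")
  ord <- order(bins[, "mean"])
  bins <- bins[ord, , drop = FALSE]
  csize <- cumsum(bins[, "size"])
  # group boundaries: for each target n*k/hl_groups pick the bin whose
  # cumulative count is nearest; bins up to and including a boundary bin
  # belong to that group
  targets <- n * seq_len(hl_groups) / hl_groups
  idx <- vapply(targets, function(t) which.min(abs(csize - t)), 0L)
  idx[hl_groups] <- nrow(bins)
  if (anyDuplicated(idx))
    stop_dranet("empty Hosmer-Lemeshow group: too few bins for %d groups",
                hl_groups, class = "dranet_degenerate_error")
  grp <- 1L + findInterval(seq_len(nrow(bins)) - 0.5, idx)
  o <- as.numeric(rowsum(bins[, "events"], grp))
  e <- as.numeric(rowsum(bins[, "mean"] * bins[, "size"], grp))
  ng <- as.numeric(rowsum(bins[, "size"], grp))
  if (any(e <= 0) || any(e >= ng))
    stop_dranet("degenerate Hosmer-Lemeshow group (expected count 0 or n)",
                class = "dranet_degenerate_error")
  chisq <- sum((o - e)^2 / (e * (1 - e / ng)))
  df <- hl_groups - 2L
  list(chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE),
       table = data.frame(group = seq_along(ng), size = ng,
                          observed = o, expected = e))
}
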