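# Distributed linear regression. One round of moment aggregation gives the
# closed-form least-squares solution; a second round returns residual-based
# error sums for the model fit statistics, so the protocol always completes
# in exactly two iterations.

#' Site-side moment statistics for linear regression
#'
#' Computes a site's sums-of-squares-and-cross-products contributions:
#' row count n, X'X, X'y, y'y, and the outcome sum. These are the complete
#' sufficient statistics for least squares, so a single exchange suffices
#' for estimates and standard errors.
#'
#' @param design Design list from [dra_design()].
#' @param y Numeric outcome vector, one value per design row.
#' @param site_id,iteration,digest Payload manifest fields.
#' @return A `linear_intermediates` payload.
#' @export
compute_linear_intermediates <- function(design, y, site_id = "site",
                                         iteration = 0L, digest = "") {
  x <- design$x
  if (nrow(x) != length(y))
    stop_dranet("design has %d rows but outcome has %d values", nrow(x),
                length(y), class = "dranet_schema_error")
  if (nrow(x) < 1L)
    stop_dranet("site %s holds no rows", site_id,
                class = "dranet_empty_site_error")
  new_payload("linear_intermediates", site_id, iteration, digest, list(
    n = as.numeric(nrow(x)),
    xtx = crossprod(x),
    xty = as.numeric(crossprod(x, y)),
    yty = sum(y * y),
    sum_y = sum(y)))
}

# Site-side second-round statistics: residual sum of squares at the final
# estimates plus the outcome moments needed for the total sum of squares.
compute_linear_diagnostics <- function(design, y, beta, site_id = "site",
                                       iteration = 1L, digest = "") {
  r <- y - drop(design$x %*% beta)
  new_payload("linear_diagnostics", site_id, iteration, digest, list(
    n = as.numeric(nrow(design$x)),
    sse = sum(r * r),
    sum_y = sum(y),
    yty = sum(y * y)))
}

#' Solve the aggregated least-squares problem
#'
#' Given the network-wide moment sums, computes the coefficient vector from
#' the normal equations via a Cholesky factorization (no explicit inverse
#' is formed for the solve), the error variance, and the coefficient
#' covariance matrix.
#'
#' @param agg Aggregated `linear_intermediates` payload.
#' @param intercept Whether the first design column is an intercept (the
#'   linear protocol always includes one). When it is, the solve goes
#'   through the corrected (mean-centered) SSCP matrix, the classical
#'   device that removes the intercept/covariate near-collinearity of raw
#'   moment matrices and keeps round-off far below the equivalence
#'   tolerances.
#' @return List with `beta`, `vcov`, `se`, `sigma2` (SSE/(n-p)), `sse`,
#'   `sst`, `n`, `p`.
#' @export
solve_linear <- function(agg, intercept = TRUE) {
  cmp <- agg$components
  a <- cmp$xtx
  b <- cmp$xty
  n <- cmp$n
  p <- ncol(a)
  if (n <= p)
    stop_dranet("n = %d rows cannot identify %d parameters", n, p,
                class = "dranet_identifiability_error")
  sst <- cmp$yty - cmp$sum_y^2 / n
  if (intercept) {
    ybar <- cmp$sum_y / n
    if (p == 1L) {                     # intercept-only model
      beta <- ybar
      sse <- sst
      sigma2 <- sse / (n - 1)
      vcov <- matrix(sigma2 / n, 1L, 1L)
      return(list(beta = beta, vcov = vcov, se = sqrt(diag(vcov)),
                  sigma2 = sigma2, sse = sse, sst = sst, n = n, p = p))
    }
    xbar <- a[1L, -1L] / n
    ac <- a[-1L, -1L, drop = FALSE] - n * tcrossprod(xbar)
    dimnames(ac) <- list(colnames(a)[-1L], colnames(a)[-1L])
    bc <- b[-1L] - n * xbar * ybar
    sol <- chol_solve_sym(ac, bc)
    slopes <- sol$x
    beta <- c(ybar - sum(xbar * slopes), slopes)
    sse <- sst - sum(bc * slopes)
    v <- drop(sol$inv %*% xbar)
    xtx_inv <- rbind(c(1 / n + sum(xbar * v), -v),
                     cbind(-v, sol$inv))
  } else {
    sol <- chol_solve_sym(a, b)
    beta <- sol$x
    sse <- cmp$yty - sum(beta * b)
    xtx_inv <- sol$inv
  }
  sigma2 <- sse / (n - p)
  vcov <- sigma2 * xtx_inv
  list(beta = as.numeric(beta), vcov = vcov,
       se = sqrt(pmax(diag(vcov), 0)),
       sigma2 = sigma2, sse = sse, sst = sst, n = n, p = p)
}

# Solve a symmetric positive-definite system (and return the inverse)
# through Jacobi-equilibrated Cholesky: scaling the moment matrix to unit
# diagonal before factorization keeps the factorization's rounding error
# from amplifying through the wide dynamic range of raw covariate scales,
# which is what makes two summation orders of the same moments agree near
# machine precision downstream.
chol_solve_sym <- function(a, b = NULL) {
  d <- sqrt(diag(a))
  if (any(!is.finite(d)) || any(d <= 0))
    stop_dranet("moment matrix has a nonpositive diagonal",
                class = "dranet_collinearity_error")
  as_ <- a / tcrossprod(d)
  dimnames(as_) <- dimnames(a)
  ch <- chol_or_collinearity(as_)
  inv <- chol2inv(ch) / tcrossprod(d)
  x <- if (!is.null(b))
    backsolve(ch, forwardsolve(t(ch), b / d)) / d
  list(x = as.numeric(x), inv = inv)
}

# Cholesky with a reciprocal-condition guard; names the dependent columns
# when the moment matrix is (near-)singular.
chol_or_collinearity <- function(a, rcond_min = 1e-10) {
  rc <- tryCatch(1 / kappa(a, exact = FALSE), error = function(e) 0)
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch) || rc < rcond_min) {
    q <- qr(a)
    dep <- colnames(a)[q$pivot[-seq_len(q$rank)]] %||% character(0)
    stop_dranet(
      "moment matrix is singular or near-singular (rcond ~ %.2e)%s",
      rc,
      if (length(dep)) paste0("; dependent column(s): ",
                              paste(dep, collapse = ", ")) else "",
      class = "dranet_collinearity_error")
  }
  ch
}

#' Linear-model fit statistics from aggregated error sums
#'
#' Computes R-squared, AIC, Sawa's BIC, and Schwarz's BIC in the
#' conventions of classical least-squares software:
#' `AIC = n log(SSE/n) + 2p`, `Schwarz BIC = n log(SSE/n) + p log(n)`, and
#' `Sawa BIC = n log(SSE/n) + 2(p+2)q - 2q^2` with `q = n sigma2 / SSE`.
#'
#' @param sse,sst Aggregated error and total sums of squares.
#' @param n,p Total rows and design columns.
#' @param sawa_sigma2 Error-variance estimator used inside Sawa's BIC:
#'   `"unbiased"` (default, SSE/(n-p), so q = n/(n-p)) or `"mle"`
#'   (SSE/n, so q = 1 and the statistic collapses to AIC + 2).
#' @return Named list `r_squared`, `aic`, `bic_sawa`, `bic_schwarz`. When
#'   SSE is exactly zero the information criteria are `NA` (flagged
#'   undefined) and R-squared is 1.
#' @export
linear_fit_statistics <- function(sse, sst, n, p,
                                  sawa_sigma2 = c("unbiased", "mle")) {
  sawa_sigma2 <- match.arg(sawa_sigma2)
  if (sst <= 0)
    stop_dranet("total sum of squares must be positive (constant outcome?)",
                class = "dranet_degenerate_error")
  r2 <- 1 - sse / sst
  if (sse <= 0)
    return(list(r_squared = 1, aic = NA_real_, bic_sawa = NA_real_,
                bic_schwarz = NA_real_))
  base <- n * log(sse / n)
  q <- if (sawa_sigma2 == "unbiased") n / (n - p) else 1
  list(r_squared = r2,
       aic = base + 2 * p,
       bic_sawa = base + 2 * (p + 2) * q - 2 * q^2,
       bic_schwarz = base + p * log(n))
}
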