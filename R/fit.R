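# The analysis-center algorithm. The same center code drives both the
# in-process engine (direct function calls per site) and the file-based
# master-worker protocol: the only difference is the `collect` closure
# through which directives go out and payloads come back. This guarantees
# that a file-based run and an in-process run of the same data and spec
# produce the identical fitted model.

# A computation directive: the instruction, iteration index, current
# parameter vector, and (for Cox rounds after the grid exchange) the
# shared global event-time grid.
new_directive <- function(instruction, iteration, spec, beta = NULL,
                          grid = NULL) {
  stopifnot(instruction %in% c("compute_intermediates",
                               "compute_diagnostics", "stop"))
  list(instruction = instruction, iteration = as.integer(iteration),
       family = spec$family, digest = spec$digest,
       beta = if (!is.null(beta)) as.numeric(beta),
       grid = if (!is.null(grid)) as.numeric(grid))
}

# Site-side dispatch: map one directive to one payload. `env` is the
# site's prepared state (design matrix and outcome vectors); directives
# never carry individual-level data and payloads never return it.
partner_compute <- function(directive, env) {
  spec <- env$spec
  if (directive$digest != spec$digest)
    stop_dranet("site %s: directive digest %s does not match local spec %s",
                env$site_id, directive$digest, spec$digest,
                class = "dranet_protocol_error")
  it <- directive$iteration
  dg <- spec$digest
  switch(
    paste(directive$family, directive$instruction, sep = "."),
    linear.compute_intermediates =
      compute_linear_intermediates(env$design, env$y, env$site_id, it, dg),
    linear.compute_diagnostics =
      compute_linear_diagnostics(env$design, env$y, directive$beta,
                                 env$site_id, it, dg),
    logistic.compute_intermediates =
      compute_glm_intermediates(env$design, env$y, directive$beta,
                                env$site_id, it, dg),
    logistic.compute_diagnostics =
      compute_glm_diagnostics(env$design, env$y, directive$beta,
                              spec$roc_bin_size, env$site_id, it, dg),
    cox.compute_intermediates =
      if (is.null(directive$grid))
        compute_event_grid(env$time, env$event, env$site_id, it, dg)
      else
        compute_cox_intermediates(env$design, env$time, env$event,
                                  directive$beta, directive$grid,
                                  env$site_id, it, dg),
    cox.compute_diagnostics =
      compute_cox_intermediates(env$design, env$time, env$event,
                                directive$beta, directive$grid,
                                env$site_id, it, dg,
                                kind = "cox_diagnostics"),
    stop_dranet("site %s: unsupported directive '%s' for family '%s'",
                env$site_id, directive$instruction, directive$family,
                class = "dranet_protocol_error"))
}

# Prepare a site's local state once per run.
site_env <- function(data, spec, site_id) {
  env <- list(site_id = as.character(site_id), spec = spec,
              design = dra_design(data, spec, site_id))
  if (spec$family == "cox") {
    oc <- site_outcome(data, spec, site_id)
    env$time <- oc$time
    env$event <- oc$event
  } else {
    env$y <- site_outcome(data, spec, site_id)
  }
  env
}

# ---------------------------------------------------------------------
# Center algorithm per family. `collect(directive)` returns the list of
# per-site payloads for that directive.

center_linear <- function(spec, collect) {
  agg <- aggregate_payloads(collect(
    new_directive("compute_intermediates", 0L, spec)))
  sol <- solve_linear(agg)
  dagg <- aggregate_payloads(collect(
    new_directive("compute_diagnostics", 1L, spec, beta = sol$beta)))
  cmp <- dagg$components
  sst <- cmp$yty - cmp$sum_y^2 / cmp$n
  fs <- linear_fit_statistics(cmp$sse, sst, cmp$n, sol$p)
  list(beta = sol$beta, se = sol$se, vcov = sol$vcov,
       fit_statistics = fs,
       iterations = 2L, converged = TRUE, n = cmp$n,
       diagnostics = list(error_sums = list(sigma2 = sol$sigma2,
                                            sse = cmp$sse, sst = sst)))
}

center_logistic <- function(spec, collect) {
  p <- design_width(spec)
  beta <- numeric(p)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(spec$max_iterations)) {
    agg <- aggregate_payloads(collect(
      new_directive("compute_intermediates", it - 1L, spec, beta = beta)))
    beta_new <- irls_step(agg, beta)
    iterations <- it
    converged <- check_convergence(beta, beta_new, spec$epsilon)
    beta <- beta_new
    if (converged) break
  }
  if (!converged)
    warning(sprintf(
      "logistic model did not converge in %d iterations (last max change >= %g)",
      spec$max_iterations, spec$epsilon), call. = FALSE)
  dagg <- aggregate_payloads(collect(
    new_directive("compute_diagnostics", iterations, spec, beta = beta)))
  cmp <- dagg$components
  vcov <- chol_solve_sym(cmp$information)$inv
  fs <- logistic_fit_statistics(cmp$loglik, cmp$n, p)
  roc <- tryCatch(roc_from_bins(cmp$bins), dranet_error = function(e) NULL)
  hl <- tryCatch(hosmer_lemeshow_from_bins(cmp$bins, spec$hl_groups),
                 dranet_error = function(e) NULL)
  list(beta = beta, se = sqrt(pmax(diag(vcov), 0)), vcov = vcov,
       fit_statistics = fs, iterations = iterations, converged = converged,
       n = cmp$n,
       diagnostics = list(roc = roc, hosmer_lemeshow = hl,
                          bins = cmp$bins))
}

center_cox <- function(spec, collect) {
  p <- design_width(spec)
  gagg <- collect_event_grid(collect(
    new_directive("compute_intermediates", 0L, spec)))
  grid <- gagg$components$times
  d_total <- gagg$components$d
  n_events <- sum(d_total)
  beta <- numeric(p)
  converged <- FALSE
  iterations <- 0L
  ll_path <- numeric(0)
  for (it in seq_len(spec$max_iterations)) {
    agg <- aggregate_payloads(collect(
      new_directive("compute_intermediates", it, spec, beta = beta,
                    grid = grid)))
    si <- cox_score_information(agg, beta, spec$tie_method)
    ll_path <- c(ll_path, si$loglik)
    beta_new <- newton_step(si$gradient, si$hessian, beta)
    iterations <- it
    converged <- check_convergence(beta, beta_new, spec$epsilon)
    beta <- beta_new
    if (converged) break
  }
  if (!converged)
    warning(sprintf(
      "Cox model did not converge in %d iterations (monotone likelihood?)",
      spec$max_iterations), call. = FALSE)
  dagg <- aggregate_payloads(collect(
    new_directive("compute_diagnostics", iterations + 1L, spec,
                  beta = beta, grid = grid)))
  si <- cox_score_information(dagg, beta, spec$tie_method)
  vcov <- chol_solve_sym(-si$hessian)$inv
  fs <- cox_fit_statistics(si$loglik, p, n_events)
  # mean covariate vector of patients with events, network-wide
  x_ref <- colSums(as_matrix(dagg$components$s)) / n_events
  surv <- baseline_survival(dagg, beta, x_ref)
  list(beta = beta, se = sqrt(pmax(diag(vcov), 0)), vcov = vcov,
       fit_statistics = c(fs, list(n_events = n_events)),
       iterations = iterations, converged = converged,
       n = dagg$components$n,
       diagnostics = list(survival = surv,
                          median_time = attr(surv, "median"),
                          loglik_path = ll_path, x_ref = x_ref,
                          event_grid = list(times = grid, d = d_total)))
}

run_center_algorithm <- function(spec, collect) {
  switch(spec$family,
         linear = center_linear(spec, collect),
         logistic = center_logistic(spec, collect),
         cox = center_cox(spec, collect))
}

# ---------------------------------------------------------------------

#' Fit a regression model across a distributed data network
#'
#' Fits a linear, logistic, or Cox proportional hazards model on
#' horizontally partitioned data: each site contributes only summary-level
#' intermediate statistics (moment matrices, score vectors and information
#' matrices, per-event-time risk-set sums), which the analysis center
#' aggregates and iterates on. The result is mathematically equivalent to
#' the pooled individual-level fit — agreement is at machine precision —
#' while no individual-level record ever leaves its site.
#'
#' Linear models complete in exactly two exchange rounds (closed-form
#' estimates, then fit statistics). Logistic models run distributed
#' iteratively reweighted least squares and Cox models run distributed
#' Newton-Raphson (Efron or Breslow tie handling), both until the maximum
#' absolute parameter change falls below `spec$epsilon` or
#' `spec$max_iterations` is reached, followed by one diagnostics round
#' (log likelihood and standard errors at the final estimates, binned ROC
#' and calibration inputs for logistic, baseline survival for Cox).
#'
#' @param sites A list of data frames, one per site, or a single data
#'   frame (treated as a one-site network). Names are used as site ids
#'   when present.
#' @param spec A [dra_spec()] model specification.
#' @param engine `"memory"` runs center and sites in-process;
#'   `"files"` runs the full file-based exchange protocol (directives,
#'   payloads, and trigger files under `workdir`) with cooperative
#'   scheduling in this process.
#' @param workdir Directory for the file-based protocol; a temporary
#'   directory by default.
#' @param keep_workdir Keep the protocol files after a `"files"` run (for
#'   example to audit the transfer directories); default discards them.
#' @return An object of class `"dra_fit"` with components
#'   `coefficients`, `se`, `vcov`, `fit_statistics`, `iterations`,
#'   `converged`, `n`, `site_sizes`, `diagnostics`, and (for file runs)
#'   `transfer_log`. Supports `print`, `summary`, `coef`, `vcov`,
#'   `confint`, `predict`, and `plot`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_site = c(120, 150, 90),
#'                                         seed = 7))
#' spec <- cohort$specs$linear
#' fit <- dra_fit(cohort$sites, spec)
#' coef(fit)[1:3]
#' @export
dra_fit <- function(sites, spec, engine = c("memory", "files"),
                    workdir = NULL, keep_workdir = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "dra_spec"))
  if (is.data.frame(sites)) sites <- list(site1 = sites)
  stopifnot(is.list(sites), length(sites) >= 1L)
  ids <- names(sites) %||% paste0("site", seq_along(sites))
  if (is.null(names(sites)) || any(names(sites) == ""))
    ids <- paste0("site", seq_along(sites))
  envs <- Map(site_env, sites, list(spec), ids)

  if (engine == "memory") {
    collect <- function(directive)
      lapply(envs, function(e) partner_compute(directive, e))
    res <- run_center_algorithm(spec, collect)
    log <- NULL
  } else {
    run <- run_protocol_cooperative(envs, spec, workdir = workdir,
                                    keep_workdir = keep_workdir)
    res <- run$result
    log <- run$transfer_log
  }

  cn <- design_colnames(spec)
  beta <- stats::setNames(res$beta, cn)
  se <- stats::setNames(res$se, cn)
  vcov <- res$vcov
  dimnames(vcov) <- list(cn, cn)
  structure(
    list(coefficients = beta, se = se, vcov = vcov,
         fit_statistics = res$fit_statistics,
         iterations = res$iterations, converged = res$converged,
         n = res$n, site_ids = ids,
         site_sizes = stats::setNames(vapply(sites, nrow, 0L), ids),
         diagnostics = res$diagnostics, spec = spec, engine = engine,
         transfer_log = log, call = match.call()),
    class = "dra_fit")
}

#' Pooled individual-level reference fit
#'
#' Fits the same model on the concatenation of all sites' rows, using the
#' identical formula conventions (dummy coding, tie handling, convergence
#' procedure, fit-statistic definitions) as the distributed protocol.
#' This is the pooled reference against which a distributed fit is
#' verified; any difference between the two is purely floating-point
#' summation reordering.
#'
#' @param sites List of site data frames (or one data frame).
#' @param spec A [dra_spec()] specification.
#' @return A `"dra_fit"` object with `engine = "pooled"`.
#' @export
dra_pooled_fit <- function(sites, spec) {
  if (is.data.frame(sites)) sites <- list(sites)
  pooled <- do.call(rbind, lapply(sites, function(d) {
    rownames(d) <- NULL
    d
  }))
  rownames(pooled) <- NULL
  fit <- dra_fit(list(pooled = pooled), spec, engine = "memory")
  fit$engine <- "pooled"
  fit$call <- match.call()
  fit
}
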