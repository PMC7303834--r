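# Synthetic horizontally partitioned cohorts with known truth, emulating
# the variable structure of a multi-site bariatric-surgery follow-up
# study: a continuous change-in-BMI outcome, a binary >=20%-weight-loss
# indicator, and a time-to-event outcome with administrative censoring at
# day 365 and event times rounded up to whole days (which deliberately
# creates ties within and across sites — the hardest path for the Efron
# correction). All three outcomes are generated from one shared covariate
# draw per subject.

#' Configuration for a synthetic distributed cohort
#'
#' Defaults describe a three-site network of 5452 patients (site sizes
#' 1706, 2728, 1018) with a mostly-female, exposure-prevalence-0.18
#' bariatric-style covariate mix: age ~ Uniform(18, 79); baseline BMI ~
#' Normal(45, 7) truncated at 35; six count covariates with Poisson
#' utilisation rates; 6-level race (reference white), binary sex, 6-level
#' surgery year (reference 2010). The site indicator enters the model as
#' an ordinary categorical covariate. True coefficient vectors for the
#' three families default to magnitudes typical of such cohorts and are
#' all configurable.
#'
#' @param n_sites Number of data partners.
#' @param n_per_site Integer vector of per-site sample sizes (recycled to
#'   `n_sites`).
#' @param beta_linear,beta_logistic,beta_cox Named true coefficient
#'   vectors on the design scale (names must match the design columns;
#'   see [design_colnames()]). `NULL` keeps the defaults.
#' @param sigma_linear Residual SD of the continuous outcome.
#' @param weibull_shape,weibull_scale Baseline Weibull hazard
#'   `h0(t) = scale * shape * t^(shape-1)`; the default scale makes
#'   roughly three quarters of subjects reach the event inside the
#'   365-day administrative window.
#' @param censor_day Administrative censoring day.
#' @param round_days Round event times up to whole days (`TRUE`, the
#'   tie-producing default) or keep them continuous (`FALSE`, tie-free).
#' @param exposure_prob Bernoulli exposure prevalence.
#' @param seed Master seed (mandatory); per-site substreams are derived
#'   deterministically from it.
#' @return An object of class `"dra_cohort_config"`.
#' @export
cohort_config <- function(n_sites = 3L,
                          n_per_site = c(1706L, 2728L, 1018L),
                          beta_linear = NULL, beta_logistic = NULL,
                          beta_cox = NULL,
                          sigma_linear = 2,
                          weibull_shape = 1.2,
                          weibull_scale = 0.00264,
                          censor_day = 365,
                          round_days = TRUE,
                          exposure_prob = 0.18,
                          seed) {
  if (missing(seed) || !is_count(seed + 1))
    stop_dranet("a master seed is mandatory", class = "dranet_spec_error")
  stopifnot(n_sites >= 1L, all(n_per_site >= 1L), sigma_linear > 0,
            weibull_shape > 0, weibull_scale > 0, censor_day > 0,
            exposure_prob > 0, exposure_prob < 1)
  n_per_site <- rep_len(as.integer(n_per_site), n_sites)
  site_ids <- paste0("site", seq_len(n_sites))
  cfg <- structure(
    list(n_sites = as.integer(n_sites), n_per_site = n_per_site,
         site_ids = site_ids, sigma_linear = sigma_linear,
         weibull_shape = weibull_shape, weibull_scale = weibull_scale,
         censor_day = censor_day, round_days = isTRUE(round_days),
         exposure_prob = exposure_prob, seed = as.integer(seed)),
    class = "dra_cohort_config")
  defaults <- default_truth(cfg)
  cfg$beta_linear <- beta_linear %||% defaults$linear
  cfg$beta_logistic <- beta_logistic %||% defaults$logistic
  cfg$beta_cox <- beta_cox %||% defaults$cox
  cfg
}

cohort_levels <- function(cfg) {
  lv <- list(race = c("white", "unknown", "aian", "asian", "black", "nhpi"),
             year = c("2010", "2011", "2012", "2013", "2014", "2015"))
  # a site indicator only makes sense with more than one site
  if (cfg$n_sites > 1L) lv$site <- cfg$site_ids
  lv
}

cohort_covariates <- function(cfg) {
  c("exposure", "age", "bmi_base", "comorbidity", "amb_visits",
    "ed_visits", "inpatient", "nonacute", "other_amb", "days_bmi",
    "race", "female", "year", if (cfg$n_sites > 1L) "site")
}

#' Model specifications matching the synthetic cohort
#'
#' @param cfg A [cohort_config()].
#' @param ... Passed on to [dra_spec()] (for example `tie_method` or
#'   `epsilon`).
#' @return Named list of `dra_spec` objects `linear`, `logistic`, `cox`.
#' @export
cohort_specs <- function(cfg, ...) {
  lv <- cohort_levels(cfg)
  covs <- cohort_covariates(cfg)
  list(
    linear = dra_spec("linear", "bmi_change", covs, levels = lv, ...),
    logistic = dra_spec("logistic", "wl20", covs, levels = lv, ...),
    cox = dra_spec("cox", c("time_wl20", "event_wl20"), covs,
                   levels = lv, ...))
}

# True coefficients on the design scale, in design-column order.
default_truth <- function(cfg) {
  lv <- cohort_levels(cfg)
  base <- c(exposure = NA, age = NA, bmi_base = NA, comorbidity = NA,
            amb_visits = NA, ed_visits = NA, inpatient = NA,
            nonacute = NA, other_amb = NA, days_bmi = NA)
  race <- paste0("race", lv$race[-1L])
  year <- paste0("year", lv$year[-1L])
  site <- paste0("site", lv$site[-1L])
  mk <- function(intercept, cont, race_v, female, year_v, site_v) {
    v <- c(if (!is.na(intercept)) c("(Intercept)" = intercept), cont,
           stats::setNames(race_v, race), c(female = female),
           stats::setNames(year_v, year),
           stats::setNames(rep_len(site_v, length(site)), site))
    v
  }
  list(
    linear = mk(34.0,
                c(exposure = 2.05, age = -0.033, bmi_base = -1.0,
                  comorbidity = 0.044, amb_visits = -0.031,
                  ed_visits = 0.103, inpatient = 0.887, nonacute = 1.323,
                  other_amb = 0.022, days_bmi = 0.012),
                c(0.94, -0.31, -0.17, 1.52, -1.22), -1.22,
                c(0.15, -0.25, -0.02, 0.33, -0.26), c(-1.11, -0.11)),
    logistic = mk(1.8,
                  c(exposure = 1.07, age = -0.016, bmi_base = 0.0003,
                    comorbidity = -0.026, amb_visits = 0.012,
                    ed_visits = -0.062, inpatient = -0.121,
                    nonacute = 0.425, other_amb = 0.004,
                    days_bmi = -0.0027),
                  c(-0.40, -0.14, -0.37, -0.30, -0.03), 0.20,
                  c(-0.10, 0.06, -0.12, -0.11, 0.04), c(-0.10, 0.76)),
    cox = mk(NA,
             c(exposure = -0.58, age = -0.011, bmi_base = -0.0001,
               comorbidity = -0.008, amb_visits = 0.006,
               ed_visits = -0.019, inpatient = -0.086, nonacute = 0.066,
               other_amb = 0.003, days_bmi = -0.0022),
             c(-0.19, -0.07, -0.22, -0.18, -0.20), -0.009,
             c(-0.08, -0.025, -0.095, -0.169, 0.248), c(-0.15, 0.33)))
}

# Deterministic per-site substream seeds derived from the master seed.
site_seeds <- function(cfg) {
  (cfg$seed + 7919L * seq_len(cfg$n_sites)) %% 2147483647L
}

#' Generate a synthetic horizontally partitioned cohort
#'
#' Draws one covariate vector per subject and, on that shared draw, all
#' three outcomes: `bmi_change = x' beta_lin + Normal(0, sigma)`,
#' `wl20 ~ Bernoulli(plogis(x' beta_log))`, and a proportional-hazards
#' Weibull event time with linear predictor `x' beta_cox`, rounded up to
#' whole days when `round_days` is set and administratively censored at
#' `censor_day`.
#'
#' @param cfg A [cohort_config()].
#' @return List with `sites` (named list of per-site data frames),
#'   `truth` (the true coefficient vectors, seeds, and config echo), and
#'   `specs` (the matching model specifications).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "dra_cohort_config"))
  lv <- cohort_levels(cfg)
  seeds <- site_seeds(cfg)
  specs <- cohort_specs(cfg)
  sites <- vector("list", cfg$n_sites)
  names(sites) <- cfg$site_ids
  total_events <- 0L
  for (i in seq_len(cfg$n_sites)) {
    set.seed(seeds[i])
    n <- cfg$n_per_site[i]
    d <- data.frame(
      exposure = stats::rbinom(n, 1L, cfg$exposure_prob),
      age = stats::runif(n, 18, 79),
      bmi_base = truncnorm_min(n, 45, 7, 35),
      comorbidity = stats::rpois(n, 1),
      amb_visits = stats::rpois(n, 8),
      ed_visits = stats::rpois(n, 1),
      inpatient = stats::rpois(n, 0.3),
      nonacute = stats::rpois(n, 0.05),
      other_amb = stats::rpois(n, 4),
      days_bmi = stats::rpois(n, 30),
      race = sample(lv$race, n, replace = TRUE,
                    prob = c(0.60, 0.15, 0.02, 0.05, 0.12, 0.06)),
      female = stats::rbinom(n, 1L, 0.78),
      year = sample(lv$year, n, replace = TRUE),
      site = cfg$site_ids[i],
      stringsAsFactors = FALSE)
    lp <- function(spec, beta) {
      x <- dra_design(d, spec, cfg$site_ids[i])$x
      beta <- beta[colnames(x)]
      if (anyNA(beta))
        stop_dranet("truth vector does not cover all design columns",
                    class = "dranet_spec_error")
      drop(x %*% beta)
    }
    d$bmi_change <- lp(specs$linear, cfg$beta_linear) +
      stats::rnorm(n, 0, cfg$sigma_linear)
    d$wl20 <- stats::rbinom(n, 1L, stats::plogis(
      lp(specs$logistic, cfg$beta_logistic)))
    eta <- lp(specs$cox, cfg$beta_cox)
    u <- stats::runif(n)
    t_raw <- (-log(u) / (cfg$weibull_scale * exp(eta)))^(1 / cfg$weibull_shape)
    if (cfg$round_days) t_raw <- ceiling(t_raw)
    event <- as.numeric(t_raw <= cfg$censor_day)
    d$time_wl20 <- pmin(t_raw, cfg$censor_day)
    d$event_wl20 <- event
    # guard against pathological zero times from rounding-free draws
    d$time_wl20 <- pmax(d$time_wl20, .Machine$double.eps)
    total_events <- total_events + sum(event)
    sites[[i]] <- d
  }
  if (total_events < 2L)
    warning(sprintf(
      "degenerate survival configuration: only %d event(s) generated",
      total_events), call. = FALSE)
  list(sites = sites,
       truth = list(beta_linear = cfg$beta_linear,
                    beta_logistic = cfg$beta_logistic,
                    beta_cox = cfg$beta_cox,
                    seed = cfg$seed, site_seeds = seeds,
                    n_events = total_events, config = cfg),
       specs = specs)
}

truncnorm_min <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

#' Write a generated cohort to per-site CSV files plus a truth record
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in names(cohort$sites)) {
    p <- file.path(dir, paste0(s, ".csv"))
    utils::write.csv(cohort$sites[[s]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.json")
  truth <- cohort$truth
  # named coefficient vectors as JSON objects, not bare arrays
  for (nm in c("beta_linear", "beta_logistic", "beta_cox"))
    truth[[nm]] <- as.list(truth[[nm]])
  cfg <- unclass(truth$config)
  for (nm in c("beta_linear", "beta_logistic", "beta_cox"))
    cfg[[nm]] <- as.list(cfg[[nm]])
  truth$config <- cfg
  writeLines(as.character(jsonlite::toJSON(truth, auto_unbox = TRUE,
                                           digits = I(17))), tp)
  invisible(c(paths, tp))
}

#' Partition a fixed dataset across k synthetic sites
#'
#' Splits the rows of one data frame into `k` disjoint site datasets whose
#' union restores the input exactly — the device behind partition-
#' invariance checks.
#'
#' @param rows A data frame.
#' @param k Number of sites (1 <= k <= nrow(rows)).
#' @param scheme `"contiguous"` (consecutive blocks, earlier blocks
#'   larger), `"round_robin"` (row i to site ((i-1) mod k) + 1), or
#'   `"random"` (a seeded permutation, then contiguous blocks).
#' @param seed Seed for the `"random"` scheme.
#' @return Named list of `k` data frames.
#' @export
partition_rows <- function(rows, k,
                           scheme = c("contiguous", "round_robin",
                                      "random"),
                           seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(rows)
  if (k > n)
    stop_dranet("cannot split %d rows across %d sites", n, k,
                class = "dranet_spec_error")
  idx <- switch(scheme,
                contiguous = sort(rep_len(seq_len(k), n)),
                round_robin = rep_len(seq_len(k), n),
                random = {
                  set.seed(seed)
                  sort(rep_len(seq_len(k), n))[sample.int(n)]
                })
  out <- lapply(seq_len(k), function(i) {
    d <- rows[idx == i, , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(out) <- paste0("part", seq_len(k))
  out
}
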