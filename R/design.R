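#' Expand a site's data to the shared design matrix
#'
#' Constructs the design matrix used by every distributed computation.
#' Column layout is fully determined by the specification: an intercept
#' column first (linear and logistic families only; the Cox partial
#' likelihood has no intercept), then one column per covariate in declared
#' order, categorical covariates expanding to one indicator column per
#' non-reference level in declared level order. Because the layout never
#' depends on the data actually observed at a site, all sites produce
#' identical column orderings and their cross-product matrices can be summed
#' elementwise.
#'
#' @param data A data frame holding one site's individual-level records.
#' @param spec A [dra_spec()] object.
#' @param site_id Optional site identifier used in error messages.
#' @return A list with components `x` (numeric matrix, n x p, with column
#'   names), `names` (column names), and `intercept` (logical).
#' @examples
#' d <- data.frame(age = c(40, 50), race = c("white", "black"), y = c(1, 2))
#' spec <- dra_spec("linear", "y", c("age", "race"),
#'                  levels = list(race = c("white", "black", "asian")))
#' dra_design(d, spec)$x
#' @export
dra_design <- function(data, spec, site_id = "?") {
  stopifnot(is.data.frame(data), inherits(spec, "dra_spec"))
  missing_cols <- setdiff(spec$covariates, names(data))
  if (length(missing_cols))
    stop_dranet("site %s: missing column(s): %s", site_id,
                paste(missing_cols, collapse = ", "),
                class = "dranet_schema_error")
  n <- nrow(data)
  cols <- list()
  cn <- character(0)
  if (spec$intercept) {
    cols[["(Intercept)"]] <- rep(1, n)
    cn <- "(Intercept)"
  }
  for (cov in spec$covariates) {
    v <- data[[cov]]
    if (cov %in% names(spec$levels)) {
      lv <- spec$levels[[cov]]
      v <- as.character(v)
      bad <- setdiff(unique(v), lv)
      if (length(bad))
        stop_dranet(
          "site %s: covariate '%s' has value(s) outside declared levels: %s",
          site_id, cov, paste(bad, collapse = ", "),
          class = "dranet_schema_error")
      for (l in lv[-1L]) {              # reference level = first declared
        nm <- paste0(cov, l)
        cols[[nm]] <- as.numeric(v == l)
        cn <- c(cn, nm)
      }
    } else {
      if (!is.numeric(v))
        stop_dranet(
          "site %s: covariate '%s' is not numeric and has no declared levels",
          site_id, cov, class = "dranet_schema_error")
      if (anyNA(v))
        stop_dranet("site %s: covariate '%s' contains missing values",
                    site_id, cov, class = "dranet_schema_error")
      cols[[cov]] <- as.numeric(v)
      cn <- c(cn, cov)
    }
  }
  x <- matrix(unlist(cols, use.names = FALSE), nrow = n,
              dimnames = list(NULL, cn))
  list(x = x, names = cn, intercept = spec$intercept)
}

# Number of design columns implied by a spec (without seeing any data).
design_width <- function(spec) {
  p <- as.integer(spec$intercept)
  for (cov in spec$covariates)
    p <- p + if (cov %in% names(spec$levels))
      length(spec$levels[[cov]]) - 1L else 1L
  p
}

design_colnames <- function(spec) {
  cn <- if (spec$intercept) "(Intercept)" else character(0)
  for (cov in spec$covariates) {
    cn <- c(cn, if (cov %in% names(spec$levels))
      paste0(cov, spec$levels[[cov]][-1L]) else cov)
  }
  cn
}

# Extract and validate the outcome vector(s) for a site.
site_outcome <- function(data, spec, site_id = "?") {
  absent <- setdiff(spec$outcome, names(data))
  if (length(absent))
    stop_dranet("site %s: missing outcome column(s): %s", site_id,
                paste(absent, collapse = ", "),
                class = "dranet_schema_error")
  if (spec$family == "cox") {
    tm <- data[[spec$outcome[1L]]]
    ev <- data[[spec$outcome[2L]]]
    if (anyNA(tm) || anyNA(ev))
      stop_dranet("site %s: missing values in time/event columns", site_id,
                  class = "dranet_schema_error")
    if (any(tm <= 0))
      stop_dranet("site %s: event times must be strictly positive", site_id,
                  class = "dranet_schema_error")
    if (!all(ev %in% c(0, 1)))
      stop_dranet("site %s: event indicator must be 0/1", site_id,
                  class = "dranet_schema_error")
    list(time = as.numeric(tm), event = as.numeric(ev))
  } else {
    y <- data[[spec$outcome]]
    if (anyNA(y))
      stop_dranet("site %s: missing values in outcome '%s'", site_id,
                  spec$outcome, class = "dranet_schema_error")
    if (spec$family == "logistic" && !all(y %in% c(0, 1)))
      stop_dranet("site %s: logistic outcome '%s' must be 0/1", site_id,
                  spec$outcome, class = "dranet_schema_error")
    as.numeric(y)
  }
}
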