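#' Specify a distributed regression model
#'
#' Builds the model specification shared verbatim by the analysis center and
#' every data-partner site. The specification fixes the regression family,
#' the outcome column(s), the covariates and their categorical codings, the
#' tie-handling method for proportional hazards models, and the iteration
#' controls of the distributed fitting protocol. Because design-matrix
#' construction is driven entirely by this object, every site expands its
#' local data to an identical column layout, which is what makes the
#' summary-level intermediate statistics additive across sites.
#'
#' Categorical covariates are supplied through `levels`: a named list whose
#' names are covariate names and whose elements are character vectors of the
#' declared levels, the first of which is the reference level. Dummy
#' indicator columns are emitted for the non-reference levels in declared
#' order, so the column layout is deterministic and does not depend on the
#' data observed at any site.
#'
#' @param family One of `"linear"`, `"logistic"`, `"cox"`.
#' @param outcome For `"linear"` and `"logistic"`, the name of the outcome
#'   column. For `"cox"`, a character vector of length 2: the event-time
#'   column (days, strictly positive) followed by the event-indicator column
#'   (1 = event, 0 = censored).
#' @param covariates Character vector of covariate column names, in the
#'   order their design columns should appear.
#' @param levels Named list declaring the levels of each categorical
#'   covariate; first element of each vector is the reference level.
#'   Covariates not named here are treated as numeric.
#' @param tie_method Tie handling for the Cox partial likelihood:
#'   `"efron"` (default) or `"breslow"`. Ignored for other families.
#' @param epsilon Convergence criterion: iteration stops when the maximum
#'   absolute change in the parameter vector falls below this value.
#'   Default 0.01.
#' @param max_iterations Cap on parameter-update iterations. Default 25.
#' @param roc_bin_size Number of patients per privacy-preserving prediction
#'   bin used for the distributed ROC curve. Default 6.
#' @param hl_groups Number of risk-ordered groups for the Hosmer-Lemeshow
#'   calibration test. Default 10.
#'
#' @return An object of class `"dra_spec"`.
#' @examples
#' dra_spec("logistic", outcome = "wl20",
#'          covariates = c("exposure", "age", "race"),
#'          levels = list(race = c("white", "black", "asian")))
#' @export
dra_spec <- function(family = c("linear", "logistic", "cox"),
                     outcome,
                     covariates,
                     levels = list(),
                     tie_method = c("efron", "breslow"),
                     epsilon = 0.01,
                     max_iterations = 25L,
                     roc_bin_size = 6L,
                     hl_groups = 10L) {
  family <- match.arg(family)
  tie_method <- match.arg(tie_method)
  if (family == "cox") {
    if (length(outcome) != 2L)
      stop_dranet("cox family needs outcome = c(time, event), got %d name(s)",
                  length(outcome), class = "dranet_spec_error")
  } else if (length(outcome) != 1L) {
    stop_dranet("%s family needs a single outcome column", family,
                class = "dranet_spec_error")
  }
  stopifnot(is.character(outcome), is.character(covariates),
            length(covariates) >= 1L)
  if (anyDuplicated(covariates))
    stop_dranet("duplicated covariate names", class = "dranet_spec_error")
  if (!is.list(levels) ||
      (length(levels) && is.null(names(levels))))
    stop_dranet("'levels' must be a named list", class = "dranet_spec_error")
  unknown <- setdiff(names(levels), covariates)
  if (length(unknown))
    stop_dranet("levels declared for unknown covariate(s): %s",
                paste(unknown, collapse = ", "), class = "dranet_spec_error")
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv))
      stop_dranet("covariate '%s': declared levels must be >=2 distinct strings",
                  nm, class = "dranet_spec_error")
  }
  if (!(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0))
    stop_dranet("epsilon must be a positive number", class = "dranet_spec_error")
  if (!is_count(max_iterations))
    stop_dranet("max_iterations must be a positive integer",
                class = "dranet_spec_error")
  if (!is_count(roc_bin_size))
    stop_dranet("roc_bin_size must be a positive integer",
                class = "dranet_spec_error")
  if (!is_count(hl_groups) || hl_groups < 3)
    stop_dranet("hl_groups must be an integer >= 3", class = "dranet_spec_error")

  spec <- structure(
    list(family = family,
         outcome = unname(outcome),
         covariates = unname(covariates),
         levels = levels[intersect(covariates, names(levels))],
         intercept = family != "cox",
         tie_method = tie_method,
         epsilon = as.numeric(epsilon),
         max_iterations = as.integer(max_iterations),
         roc_bin_size = as.integer(roc_bin_size),
         hl_groups = as.integer(hl_groups)),
    class = "dra_spec")
  spec$digest <- spec_digest(spec)
  spec
}

# Canonical fingerprint of everything that determines the design layout and
# the fitting procedure. Sites refuse to aggregate payloads whose digest
# differs from the directive's.
spec_digest <- function(spec) {
  canon <- paste(
    spec$family,
    paste(spec$outcome, collapse = ","),
    paste(spec$covariates, collapse = ","),
    paste(vapply(names(spec$levels), function(nm)
      paste0(nm, "=", paste(spec$levels[[nm]], collapse = "|")), ""),
      collapse = ";"),
    spec$tie_method,
    fmt_real(spec$epsilon),
    spec$max_iterations,
    spec$roc_bin_size,
    spec$hl_groups,
    sep = "\n")
  fnv1a32(canon)
}

#' @export
print.dra_spec <- function(x, ...) {
  cat("Distributed regression model specification\n")
  cat("  family        :", x$family,
      if (x$family == "cox") sprintf("(%s ties)", x$tie_method) else "", "\n")
  cat("  outcome       :", paste(x$outcome, collapse = " + "), "\n")
  cat("  covariates    :", paste(x$covariates, collapse = ", "), "\n")
  if (length(x$levels)) {
    for (nm in names(x$levels))
      cat(sprintf("    %s: levels {%s}, reference '%s'\n", nm,
                  paste(x$levels[[nm]], collapse = ", "), x$levels[[nm]][1L]))
  }
  cat(sprintf("  convergence   : max |change| < %g, at most %d iterations\n",
              x$epsilon, x$max_iterations))
  cat(sprintf("  diagnostics   : ROC bin size %d, Hosmer-Lemeshow groups %d\n",
              x$roc_bin_size, x$hl_groups))
  cat("  spec digest   :", x$digest, "\n")
  invisible(x)
}

# Serialize / restore a spec through plain JSON (used by the file protocol
# and the command-line tools).
spec_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = I(17))
}

spec_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  lv <- x$levels
  if (length(lv) == 0L) lv <- list() else lv <- as.list(lv)
  dra_spec(family = x$family, outcome = x$outcome,
           covariates = x$covariates, levels = lv,
           tie_method = x$tie_method %||% "efron",
           epsilon = x$epsilon %||% 0.01,
           max_iterations = x$max_iterations %||% 25L,
           roc_bin_size = x$roc_bin_size %||% 6L,
           hl_groups = x$hl_groups %||% 10L)
}
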