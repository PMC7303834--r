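# Equivalence verification: signed differences between a distributed fit
# and its pooled individual-level reference, shaped like the side-by-side
# difference tables used to validate distributed regression deployments.

#' Compare a distributed fit against a pooled reference fit
#'
#' Produces per-coefficient differences in estimates and standard errors,
#' per-statistic differences in the model fit measures, and the maximum
#' absolute difference overall, judged against a stated tolerance.
#'
#' @param distributed,pooled `"dra_fit"` objects fitted under the same
#'   specification.
#' @param tolerance Pass/fail bound on the maximum absolute difference
#'   (default `1e-6`, the conventional success bound; well-conditioned
#'   runs come in far below it).
#' @return Object of class `"dra_comparison"`: list with `coefficients`
#'   (data frame of estimates/SEs and their differences),
#'   `fit_statistics`, `max_abs_diff`, `tolerance`, `pass`.
#' @export
dra_compare <- function(distributed, pooled, tolerance = 1e-6) {
  stopifnot(inherits(distributed, "dra_fit"), inherits(pooled, "dra_fit"))
  if (distributed$spec$digest != pooled$spec$digest)
    stop_dranet("fits were produced under different specifications",
                class = "dranet_schema_error")
  if (!identical(names(distributed$coefficients),
                 names(pooled$coefficients)))
    stop_dranet("coefficient names do not match",
                class = "dranet_schema_error")
  co <- data.frame(
    term = names(distributed$coefficients),
    estimate_dra = unname(distributed$coefficients),
    se_dra = unname(distributed$se),
    estimate_pooled = unname(pooled$coefficients),
    se_pooled = unname(pooled$se),
    stringsAsFactors = FALSE)
  co$diff_estimate <- co$estimate_dra - co$estimate_pooled
  co$diff_se <- co$se_dra - co$se_pooled

  fs_d <- unlist(distributed$fit_statistics)
  fs_p <- unlist(pooled$fit_statistics)
  common <- intersect(names(fs_d), names(fs_p))
  fs <- data.frame(statistic = common, dra = unname(fs_d[common]),
                   pooled = unname(fs_p[common]),
                   stringsAsFactors = FALSE)
  fs$diff <- fs$dra - fs$pooled

  diffs <- c(co$diff_estimate, co$diff_se, fs$diff)
  max_abs <- max(abs(diffs[is.finite(diffs)]))
  structure(list(coefficients = co, fit_statistics = fs,
                 max_abs_diff = max_abs, tolerance = tolerance,
                 pass = max_abs < tolerance,
                 family = distributed$spec$family),
            class = "dra_comparison")
}

#' @export
print.dra_comparison <- function(x, digits = 5, ...) {
  cat(sprintf("Distributed vs pooled %s regression\n\n", x$family))
  co <- x$coefficients
  df <- data.frame(
    Covariate = co$term,
    `Estimate (DRA)` = sprintf("%.*f", digits, co$estimate_dra),
    `SE (DRA)` = sprintf("%.*f", digits, co$se_dra),
    `Estimate (pooled)` = sprintf("%.*f", digits, co$estimate_pooled),
    `SE (pooled)` = sprintf("%.*f", digits, co$se_pooled),
    `Diff estimate` = sprintf("%.2e", co$diff_estimate),
    `Diff SE` = sprintf("%.2e", co$diff_se),
    check.names = FALSE)
  print(df, row.names = FALSE, right = FALSE)
  cat("\nModel fit statistics\n")
  fs <- x$fit_statistics
  print(data.frame(Statistic = fs$statistic,
                   DRA = sprintf("%.6f", fs$dra),
                   Pooled = sprintf("%.6f", fs$pooled),
                   Diff = sprintf("%.2e", fs$diff), check.names = FALSE),
        row.names = FALSE, right = FALSE)
  cat(sprintf("\nMax |difference| = %.3e (tolerance %.0e): %s\n",
              x$max_abs_diff, x$tolerance,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Write a comparison report as a delimited table
#'
#' @param x A `"dra_comparison"`.
#' @param path Output file; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "dra_comparison"))
  utils::write.table(x$coefficients, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cat("\n", file = path, append = TRUE)
  suppressWarnings(utils::write.table(x$fit_statistics, path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(path)
}
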