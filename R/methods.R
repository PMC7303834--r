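# S3 methods for fitted distributed regression models.

#' @export
print.dra_fit <- function(x, digits = 5, ...) {
  cat(sprintf("Distributed %s regression (%s engine)\n", x$spec$family,
              x$engine))
  cat(sprintf("  %d site(s), n = %d; %d iteration(s); %s\n",
              length(x$site_ids), as.integer(x$n), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.dra_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  pv <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = pv)
  structure(list(fit = object, coefficients = tab),
            class = "summary.dra_fit")
}

#' @export
print.summary.dra_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Distributed %s regression, %d site(s), n = %d\n",
              f$spec$family, length(f$site_ids), as.integer(f$n)))
  if (f$spec$family == "cox")
    cat(sprintf("  ties: %s; events: %d\n", f$spec$tie_method,
                as.integer(f$fit_statistics$n_events)))
  cat(sprintf("  %d iteration(s), epsilon = %g, %s\n\n", f$iterations,
              f$spec$epsilon,
              if (f$converged) "converged" else "NOT converged"))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nFit statistics:\n")
  fs <- unlist(f$fit_statistics)
  for (nm in names(fs))
    cat(sprintf("  %-12s %s\n", nm, format(fs[[nm]], digits = 10)))
  dg <- f$diagnostics
  if (!is.null(dg$roc))
    cat(sprintf("\nBinned ROC AUC: %.4f (bin size %d)\n", dg$roc$auc,
                f$spec$roc_bin_size))
  if (!is.null(dg$hosmer_lemeshow))
    cat(sprintf("Hosmer-Lemeshow: chi-square %.4f, df %d, p = %.4f\n",
                dg$hosmer_lemeshow$chisq, dg$hosmer_lemeshow$df,
                dg$hosmer_lemeshow$p_value))
  if (!is.null(dg$median_time))
    cat(sprintf("\nMedian time to event: %s days\n",
                if (is.na(dg$median_time)) "not reached"
                else format(dg$median_time)))
  invisible(x)
}

#' @export
coef.dra_fit <- function(object, ...) object$coefficients

#' @export
vcov.dra_fit <- function(object, ...) object$vcov

#' @export
confint.dra_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients
  se <- object$se
  if (missing(parm)) parm <- names(est)
  a <- (1 - level) / 2
  z <- stats::qnorm(1 - a)
  out <- cbind(est[parm] - z * se[parm], est[parm] + z * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  out
}

#' Predictions from a distributed regression fit
#'
#' Uses only the model coefficients (and, for Cox models, the aggregated
#' baseline cumulative hazard), so prediction works anywhere without
#' access to the training rows.
#'
#' @param object A `"dra_fit"`.
#' @param newdata Data frame with the model covariates.
#' @param type `"link"` for the linear predictor; `"response"` for the
#'   outcome scale (fitted value, probability, or survival probability);
#'   `"risk"` for `exp(lp)` (Cox only).
#' @param times For Cox `"response"` predictions: the times at which to
#'   evaluate survival (defaults to the event-time grid maximum).
#' @param ... Unused.
#' @return Numeric vector, or for Cox `"response"` a matrix (rows =
#'   `newdata` rows, columns = `times`).
#' @export
predict.dra_fit <- function(object, newdata,
                            type = c("link", "response", "risk"),
                            times = NULL, ...) {
  type <- match.arg(type)
  design <- dra_design(newdata, object$spec, "newdata")
  eta <- drop(design$x %*% object$coefficients[design$names])
  fam <- object$spec$family
  if (type == "link") return(eta)
  if (type == "risk") {
    if (fam != "cox")
      stop_dranet("type = 'risk' applies to Cox models only",
                  class = "dranet_spec_error")
    return(exp(eta))
  }
  switch(fam,
         linear = eta,
         logistic = stats::plogis(eta),
         cox = {
           surv <- object$diagnostics$survival
           if (is.null(surv))
             stop_dranet("fit carries no baseline survival curve",
                         class = "dranet_spec_error")
           h0 <- attr(surv, "h0")
           grid <- surv$time
           if (is.null(times)) times <- max(grid)
           H <- c(0, h0)[findInterval(times, grid) + 1L]
           out <- outer(exp(eta), H, function(r, h) exp(-h * r))
           dimnames(out) <- list(NULL, format(times))
           drop(out)
         })
}

#' Plot diagnostics of a distributed regression fit
#'
#' Logistic fits draw the binned ROC curve; Cox fits draw the survival
#' curve at the event-patient mean covariates; linear fits have no
#' center-side plottable diagnostic and signal an error.
#'
#' @param x A `"dra_fit"`.
#' @param ... Passed to the underlying plotting call.
#' @export
plot.dra_fit <- function(x, ...) {
  dg <- x$diagnostics
  if (x$spec$family == "logistic" && !is.null(dg$roc)) {
    pts <- dg$roc$points
    graphics::plot(pts$fpr, pts$tpr, type = "l",
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   main = sprintf("Binned ROC (AUC = %.4f)", dg$roc$auc),
                   ...)
    graphics::abline(0, 1, lty = 3)
  } else if (x$spec$family == "cox" && !is.null(dg$survival)) {
    sv <- dg$survival
    graphics::plot(sv$time, sv$surv, type = "s", ylim = c(0, 1),
                   xlab = "Days", ylab = "Survival probability",
                   main = "Survival at event-patient mean covariates",
                   ...)
    graphics::abline(h = 0.5, lty = 3)
  } else {
    stop_dranet("no plottable diagnostics for a %s fit", x$spec$family,
                class = "dranet_spec_error")
  }
  invisible(x)
}
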