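#' Univariate proportional-hazards fit for risk mapping
#'
#' Fits a one-covariate Cox model on the weighted partial likelihood with
#' Breslow tie handling (via [survival::coxph]) and extracts the weighted
#' Breslow baseline cumulative hazard. This is the risk mapping the
#' censored continuous NRI is built on; it is not intended as a
#' multivariable prognostic model.
#'
#' @param cohort an [as_cohort()] data frame.
#' @param marker marker column name; must not be constant.
#' @param cause \code{"all_cause"} or \code{"lung_cancer"}.
#' @return an object of class \code{ph_fit}: \code{beta}, \code{se},
#'   \code{times}, \code{cumhaz} (baseline cumulative hazard at
#'   \code{times} for marker value 0), \code{marker}.
#' @export
fit_univariate_ph <- function(cohort, marker, cause = "all_cause") {
  m <- marker_values(cohort, marker)
  if (length(unique(m)) < 2L) stop("marker '", marker, "' is constant")
  status <- cause_event(cohort, cause)
  df <- data.frame(time = cohort$time, status = status, m = m,
                   w = cohort$weight)
  fit <- survival::coxph(survival::Surv(time, status) ~ m, data = df,
                         weights = w, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (!is.finite(stats::coef(fit)))
    stop("proportional-hazards fit did not converge for marker '", marker, "'")
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(beta = unname(stats::coef(fit)),
                 se = unname(sqrt(stats::vcov(fit)[1, 1])),
                 times = bh$time, cumhaz = bh$hazard, marker = marker),
            class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("ph_fit: %s, beta = %.4f (SE %.4f), HR/unit = %.3f\n",
              x$marker, x$beta, x$se, exp(x$beta)))
  invisible(x)
}

#' Predicted event risk from a univariate PH fit
#'
#' \code{risk(t | m) = 1 - exp(-Lambda0(t) * exp(beta * m))}, with the
#' baseline cumulative hazard evaluated as a right-continuous step
#' function (0 before the first event time).
#'
#' @param fit a [fit_univariate_ph()] result.
#' @param marker_value marker value(s).
#' @param horizon time in days.
#' @return event probabilities in [0, 1).
#' @export
predicted_risk_at <- function(fit, marker_value, horizon) {
  stopifnot(inherits(fit, "ph_fit"))
  idx <- findInterval(horizon, fit$times)
  L0 <- if (idx == 0L) 0 else fit$cumhaz[idx]
  1 - exp(-L0 * exp(fit$beta * marker_value))
}
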