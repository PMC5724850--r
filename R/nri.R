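#' Continuous net reclassification improvement for censored data
#'
#' Quantifies how much a new marker moves predicted risks in the right
#' direction relative to an old marker. Both markers are mapped to
#' predicted event risks at the horizon through univariate
#' proportional-hazards fits ([fit_univariate_ph()]). Subjects whose risk
#' increases under the new marker form the "up" group, those whose risk
#' decreases the "down" group (exact ties belong to neither). Event
#' probabilities by the horizon are estimated under censoring with weighted
#' Kaplan-Meier curves inside each group, and the event/non-event
#' conditionals follow by Bayes' rule from the weighted group fractions:
#' \deqn{NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) -
#'   P(up|nonevent)]}
#' reported in percent. Confidence intervals come from the stratified
#' bootstrap (resampling events and non-events separately, refitting both
#' risk models per replicate).
#'
#' @param cohort an [as_cohort()] data frame.
#' @param marker_old,marker_new marker column names.
#' @param horizon evaluation time in days.
#' @param config a [stats_config()]; \code{n_boot = 0} skips the CI.
#' @param cause \code{"all_cause"} or \code{"lung_cancer"}.
#' @return an object of class \code{nri_result}: \code{horizon}, \code{nri}
#'   (percent), \code{components} (p_up_event, p_down_event, p_up_nonevent,
#'   p_down_nonevent), \code{ci_low}, \code{ci_high}, \code{n_boot}.
#' @export
continuous_nri <- function(cohort, marker_old, marker_new, horizon,
                           config = stats_config(), cause = "all_cause") {
  status <- cause_event(cohort, cause)
  est <- nri_point(cohort, marker_old, marker_new, horizon, cause)
  ci <- c(NA_real_, NA_real_)
  nb <- 0L
  if (!is.null(config) && config$n_boot > 0L) {
    set.seed(config$seed)
    idx_ev <- which(status == 1); idx_nv <- which(status == 0)
    reps <- rep(NA_real_, config$n_boot)
    for (b in seq_len(config$n_boot)) {
      idx <- c(sample(idx_ev, replace = TRUE), sample(idx_nv, replace = TRUE))
      bc <- cohort[idx, , drop = FALSE]
      bc$id <- seq_len(nrow(bc))
      r <- try(suppressWarnings(
        nri_point(bc, marker_old, marker_new, horizon, cause)$nri),
        silent = TRUE)
      if (!inherits(r, "try-error")) reps[b] <- r
    }
    ci <- stats::quantile(reps, c(config$alpha / 2, 1 - config$alpha / 2),
                          na.rm = TRUE, names = FALSE)
    nb <- config$n_boot
  }
  structure(c(est, list(ci_low = ci[1], ci_high = ci[2], n_boot = nb)),
            class = "nri_result")
}

nri_point <- function(cohort, marker_old, marker_new, horizon, cause,
                      fits = NULL) {
  w <- cohort$weight
  mo <- marker_values(cohort, marker_old)
  mn <- marker_values(cohort, marker_new)
  if (identical(mo, mn)) {
    up <- down <- rep(FALSE, nrow(cohort))
  } else {
    if (is.null(fits))
      fits <- list(old = fit_univariate_ph(cohort, marker_old, cause),
                   new = fit_univariate_ph(cohort, marker_new, cause))
    p_old <- predicted_risk_at(fits$old, mo, horizon)
    p_new <- predicted_risk_at(fits$new, mn, horizon)
    up <- p_new > p_old
    down <- p_new < p_old
  }
  s_all <- km_eval(km_curve(cohort, cause = cause), horizon)
  p_event <- 1 - s_all
  grp <- function(sel) {
    if (!any(sel)) return(NULL)
    p_g <- sum(w[sel]) / sum(w)
    p_ev_g <- 1 - km_eval(km_curve(cohort, subset = sel, cause = cause),
                          horizon)
    list(p = p_g, p_ev = p_ev_g)
  }
  gu <- grp(up); gd <- grp(down)
  if (is.null(gu)) warning("'up' group is empty; its terms are 0")
  if (is.null(gd)) warning("'down' group is empty; its terms are 0")
  cond <- function(g, event) {
    if (is.null(g)) return(0)
    if (event) {
      if (p_event <= 0) return(0)
      g$p_ev * g$p / p_event
    } else {
      if (p_event >= 1) return(0)
      (1 - g$p_ev) * g$p / (1 - p_event)
    }
  }
  comp <- c(p_up_event = cond(gu, TRUE), p_down_event = cond(gd, TRUE),
            p_up_nonevent = cond(gu, FALSE), p_down_nonevent = cond(gd, FALSE))
  nri <- 100 * ((comp["p_up_event"] - comp["p_down_event"]) +
                  (comp["p_down_nonevent"] - comp["p_up_nonevent"]))
  list(horizon = horizon, nri = unname(nri), components = comp)
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("continuous NRI at day %g: %.1f%%", x$horizon, x$nri))
  if (!is.na(x$ci_low))
    cat(sprintf(" (95%% CI %.1f%% to %.1f%%, %d bootstrap replicates)",
                x$ci_low, x$ci_high, x$n_boot))
  cat("\n")
  invisible(x)
}
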