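#' Weighted Kaplan-Meier survival curve
#'
#' Product-limit estimator with sampling weights multiplying both the
#' risk-set and the event counts (the weighted estimator equals the
#' unweighted one computed on a cohort where each record is replicated
#' `weight` times). Backed by [survival::survfit].
#'
#' @param cohort an [as_cohort()] data frame.
#' @param subset optional logical vector selecting records (e.g. one
#'   emphysema category).
#' @param cause \code{"all_cause"} or \code{"lung_cancer"}; for the
#'   cause-specific curve, deaths from other causes are censored at their
#'   death time.
#' @param use_weights use the sampling weights (default TRUE).
#' @return an object of class \code{km_curve}: \code{times} (sorted event
#'   times), \code{survival}, \code{at_risk}, \code{events} (weighted).
#' @export
km_curve <- function(cohort, subset = NULL, cause = "all_cause",
                     use_weights = TRUE) {
  time <- cohort$time
  status <- cause_event(cohort, cause)
  w <- if (use_weights) cohort$weight else rep(1, nrow(cohort))
  if (!is.null(subset)) {
    time <- time[subset]; status <- status[subset]; w <- w[subset]
  }
  if (length(time) == 0L) stop("no records selected")
  km_from_surv(time, status, w)
}

#' Kaplan-Meier curve of the censoring distribution
#'
#' The product-limit estimator with the event indicator inverted
#' (censoring treated as the event), the ingredient of
#' inverse-probability-of-censoring weighting.
#'
#' @inheritParams km_curve
#' @return a \code{km_curve} of the censoring survival function G(t).
#' @export
censoring_km <- function(cohort, cause = "all_cause", use_weights = TRUE) {
  status <- 1 - cause_event(cohort, cause)
  w <- if (use_weights) cohort$weight else rep(1, nrow(cohort))
  km_from_surv(cohort$time, status, w)
}

km_from_surv <- function(time, status, w) {
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, weights = w,
                           se.fit = FALSE)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], events = fit$n.event[keep]),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Step-function evaluation: \code{km_eval(km, t)} is S(t) (right
#' continuous); \code{left = TRUE} gives the left limit S(t-), used for
#' IPCW case weights.
#'
#' @param km a \code{km_curve}.
#' @param t times at which to evaluate.
#' @param left evaluate the left limit.
#' @return numeric vector of survival probabilities.
#' @export
km_eval <- function(km, t, left = FALSE) {
  if (length(km$times) == 0L) return(rep(1, length(t)))
  idx <- if (left) findInterval(t, km$times, left.open = TRUE)
  else findInterval(t, km$times)
  c(1, km$survival)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d event times, final S = %.4f\n",
              length(x$times),
              if (length(x$survival)) min(x$survival) else 1))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ..., xlab = "Days", ylab = "Survival") {
  tt <- c(0, rep(x$times, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-(2 * length(x$survival))])
  graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Pairwise log-rank comparisons between emphysema categories
#'
#' Weighted two-group log-rank test for every pair of categories, with the
#' Bonferroni-corrected significance threshold for three groups
#' (p < 0.0167).
#'
#' @param cohort an [as_cohort()] data frame.
#' @param categories factor of group labels (one per record), e.g. from
#'   [categorize()].
#' @param config a [stats_config()]; supplies \code{pairwise_alpha}.
#' @param cause \code{"all_cause"} or \code{"lung_cancer"}.
#' @return data frame with one row per pair: \code{group1, group2, chi2, p,
#'   significant}.
#' @export
pairwise_logrank <- function(cohort, categories, config = stats_config(),
                             cause = "all_cause") {
  categories <- as.factor(categories)
  if (length(categories) != nrow(cohort))
    stop("'categories' must have one entry per cohort record")
  lev <- levels(droplevels(categories))
  if (length(lev) < 2L) stop("need at least two categories")
  prs <- utils::combn(lev, 2)
  out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    chi2 = NA_real_, p = NA_real_, significant = NA)
  for (i in seq_len(ncol(prs))) {
    sel <- categories %in% prs[, i]
    lr <- logrank2(cohort$time[sel], cause_event(cohort, cause)[sel],
                   cohort$weight[sel], categories[sel] == prs[1, i])
    out$chi2[i] <- lr$chi2
    out$p[i] <- lr$p
  }
  out$significant <- out$p < config$pairwise_alpha
  attr(out, "alpha") <- config$pairwise_alpha
  out
}

# weighted two-group log-rank statistic
logrank2 <- function(time, status, w, in_group1) {
  et <- sort(unique(time[status == 1]))
  o_minus_e <- 0; v <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(w[at]); n1 <- sum(w[at & in_group1])
    ev <- status == 1 & time == t
    d <- sum(w[ev]); d1 <- sum(w[ev & in_group1])
    if (n <= 0 || d <= 0) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
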