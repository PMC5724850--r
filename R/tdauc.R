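#' Statistical analysis configuration
#'
#' @param n_boot bootstrap replicates for confidence intervals (default
#'   6000; reduce for quick runs, 0 skips CIs where supported).
#' @param alpha two-sided CI level complement (default 0.05).
#' @param pairwise_alpha Bonferroni-corrected threshold for the three
#'   pairwise log-rank tests (default 0.0167).
#' @param horizons evaluation horizons in days (default years 1..7 at
#'   365.25 days/year).
#' @param seed RNG seed for all bootstrap resampling.
#' @return an object of class \code{stats_config}.
#' @export
stats_config <- function(n_boot = 6000, alpha = 0.05, pairwise_alpha = 0.0167,
                         horizons = round(365.25 * (1:7)), seed = 1L) {
  stopifnot(n_boot >= 0, alpha > 0, alpha < 1, all(horizons > 0))
  structure(list(n_boot = as.integer(n_boot), alpha = alpha,
                 pairwise_alpha = pairwise_alpha,
                 horizons = as.numeric(horizons), seed = as.integer(seed)),
            class = "stats_config")
}

#' Time-dependent ROC AUC under censoring (cumulative/dynamic, IPCW)
#'
#' Discrimination of a marker for events by a horizon t: cases are subjects
#' with an observed event at or before t, controls are subjects still
#' event-free (under follow-up) beyond t. Censoring is corrected by inverse
#' probability of censoring weights from the censoring Kaplan-Meier curve
#' G: a case i gets weight \code{w_i / G(T_i-)}, a control j gets
#' \code{w_j / G(t)}, with sampling weights w. The AUC is the weighted
#' proportion of case-control pairs ranked concordantly by the marker, ties
#' counting 1/2. Subjects censored before t belong to neither set.
#'
#' @param cohort an [as_cohort()] data frame.
#' @param marker marker column name.
#' @param horizon evaluation time in days.
#' @param cause \code{"all_cause"} or \code{"lung_cancer"}.
#' @return an object of class \code{td_auc_result}: \code{horizon},
#'   \code{auc}, \code{n_cases}, \code{n_controls} (unweighted counts);
#'   CI fields are filled by [auc_difference_bootstrap()] or
#'   [evaluate_markers()].
#' @export
td_auc <- function(cohort, marker, horizon, cause = "all_cause") {
  m <- marker_values(cohort, marker)
  status <- cause_event(cohort, cause)
  auc <- td_auc_value(cohort$time, status, m, cohort$weight, horizon)
  structure(list(horizon = horizon, auc = auc$auc,
                 n_cases = auc$n_cases, n_controls = auc$n_controls,
                 ci_low = NA_real_, ci_high = NA_real_),
            class = "td_auc_result")
}

td_auc_value <- function(time, status, m, w, horizon) {
  if (horizon <= 0 || horizon > max(time))
    stop("horizon must lie within the follow-up range")
  G <- km_from_surv(time, 1 - status, w)
  is_case <- status == 1 & time <= horizon
  is_ctrl <- time > horizon
  if (!any(is_case)) stop("no cases by the horizon")
  if (!any(is_ctrl)) stop("no controls beyond the horizon")
  g_case <- km_eval(G, time[is_case], left = TRUE)
  g_t <- km_eval(G, horizon)
  if (any(g_case <= 0) || g_t <= 0)
    stop("censoring survival reaches zero before the horizon; IPCW undefined")
  wc <- w[is_case] / g_case
  wk <- w[is_ctrl] / g_t
  list(auc = weighted_concordance(m[is_case], wc, m[is_ctrl], wk),
       n_cases = sum(is_case), n_controls = sum(is_ctrl))
}

# weighted P(marker_case > marker_control) + 0.5 P(tie), O(n log n)
weighted_concordance <- function(mc, wc, mk, wk) {
  ug <- sort(unique(mk))
  wsum <- as.vector(rowsum(wk, group = match(mk, ug)))  # ordered by group index
  below <- c(0, cumsum(wsum))                 # ctrl weight strictly below ug[i+1]
  pos_lt <- findInterval(mc, ug, left.open = TRUE)  # ctrl values < case value
  pos_le <- findInterval(mc, ug)                    # ctrl values <= case value
  w_lt <- below[pos_lt + 1L]
  w_tie <- below[pos_le + 1L] - w_lt
  sum(wc * (w_lt + 0.5 * w_tie)) / (sum(wc) * sum(wk))
}

#' Bootstrap difference between two markers' time-dependent AUCs
#'
#' Resamples subjects with replacement, stratified by event status (so the
#' case-control design is preserved), recomputes both AUCs per replicate,
#' and returns the percentile confidence interval of the difference
#' \code{AUC_B - AUC_A}. The point estimate is computed on the original
#' sample. Deterministic given \code{config$seed}.
#'
#' @param cohort an [as_cohort()] data frame.
#' @param marker_a,marker_b marker column names (difference is B minus A).
#' @param horizon evaluation time in days.
#' @param config a [stats_config()].
#' @param cause \code{"all_cause"} or \code{"lung_cancer"}.
#' @return an object of class \code{auc_diff_result}: \code{horizon},
#'   \code{diff}, \code{ci_low}, \code{ci_high}, \code{n_boot}.
#' @export
auc_difference_bootstrap <- function(cohort, marker_a, marker_b, horizon,
                                     config = stats_config(),
                                     cause = "all_cause") {
  ma <- marker_values(cohort, marker_a)
  mb <- marker_values(cohort, marker_b)
  status <- cause_event(cohort, cause)
  time <- cohort$time; w <- cohort$weight
  d0 <- td_auc_value(time, status, mb, w, horizon)$auc -
    td_auc_value(time, status, ma, w, horizon)$auc
  if (config$n_boot == 0L)
    return(structure(list(horizon = horizon, diff = d0, ci_low = NA_real_,
                          ci_high = NA_real_, n_boot = 0L),
                     class = "auc_diff_result"))
  set.seed(config$seed)
  idx_ev <- which(status == 1); idx_nv <- which(status == 0)
  diffs <- rep(NA_real_, config$n_boot)
  for (b in seq_len(config$n_boot)) {
    idx <- c(sample(idx_ev, replace = TRUE), sample(idx_nv, replace = TRUE))
    db <- try(td_auc_value(time[idx], status[idx], mb[idx], w[idx], horizon)$auc -
                td_auc_value(time[idx], status[idx], ma[idx], w[idx], horizon)$auc,
              silent = TRUE)
    if (!inherits(db, "try-error")) diffs[b] <- db
  }
  ci <- stats::quantile(diffs, c(config$alpha / 2, 1 - config$alpha / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(horizon = horizon, diff = d0, ci_low = ci[1],
                 ci_high = ci[2], n_boot = config$n_boot),
            class = "auc_diff_result")
}
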