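#' Censored survival cohort with sampling weights and marker values
#'
#' A cohort is a data frame with one row per subject and the columns
#' \code{id}, \code{time} (days of follow-up, > 0), \code{event_all_cause}
#' (1 = death from any cause), \code{event_lung_cancer} (1 = death from
#' lung cancer; implies an all-cause event), \code{weight} (sampling weight
#' >= 1), plus one numeric column per marker (e.g. \code{origES},
#' \code{normES}). Under a case-control design (all deaths retained, a
#' fraction of survivors sampled) every death has weight 1 and each sampled
#' survivor carries weight \code{1/control_fraction}, the deterministic
#' equivalent of uniformly resampling the alive subcohort back to full size.
#'
#' @param data a data frame with the columns above.
#' @param design \code{"full"} or \code{"case_control"}.
#' @param control_fraction sampled fraction of survivors (case-control
#'   designs only).
#' @return an object of classes \code{es_cohort} and \code{data.frame}.
#' @export
as_cohort <- function(data, design = c("full", "case_control"),
                      control_fraction = NA_real_) {
  design <- match.arg(design)
  need <- c("id", "time", "event_all_cause", "event_lung_cancer", "weight")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("cohort misses column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$id)) stop("subject ids must be unique")
  if (any(data$time <= 0)) stop("follow-up times must be positive")
  for (cc in c("event_all_cause", "event_lung_cancer"))
    if (!all(data[[cc]] %in% c(0, 1))) stop(cc, " must be 0/1")
  if (any(data$event_lung_cancer == 1 & data$event_all_cause == 0))
    stop("a lung-cancer death must also be an all-cause event")
  if (any(data$weight < 1)) stop("sampling weights must be >= 1")
  if (design == "case_control") {
    if (any(data$event_all_cause == 1 & data$weight != 1))
      stop("under a case-control design every death must have weight 1")
    if (!is.na(control_fraction) &&
        (control_fraction <= 0 || control_fraction > 1))
      stop("'control_fraction' must be in (0, 1]")
  }
  structure(as.data.frame(data),
            design = design, control_fraction = control_fraction,
            class = c("es_cohort", "data.frame"))
}

#' @export
print.es_cohort <- function(x, ...) {
  cat(sprintf("es_cohort: %d subjects (%d deaths, %d lung-cancer deaths), %s design\n",
              nrow(x), sum(x$event_all_cause), sum(x$event_lung_cancer),
              attr(x, "design")))
  NextMethod()
}

#' Read or write a cohort CSV
#'
#' Columns: \code{id, time_days, event_all_cause, event_lung_cancer,
#' weight}, then one column per marker. A header is required.
#'
#' @param path CSV file.
#' @param design,control_fraction see [as_cohort()].
#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path, design = NULL, control_fraction = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_days" %in% names(df))
    stop("cohort CSV misses the 'time_days' column")
  names(df)[names(df) == "time_days"] <- "time"
  if (is.null(design))
    design <- if (all(df$weight == 1)) "full" else "case_control"
  as_cohort(df, design, control_fraction)
}

#' @param cohort an [as_cohort()] data frame.
#' @rdname cohort_io
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  names(df)[names(df) == "time"] <- "time_days"
  utils::write.csv(df, path, row.names = FALSE)
}

# event indicator for a cause; other-cause deaths are censored at death time
cause_event <- function(cohort, cause = c("all_cause", "lung_cancer")) {
  cause <- match.arg(cause)
  if (cause == "all_cause") cohort$event_all_cause else cohort$event_lung_cancer
}

marker_values <- function(cohort, marker) {
  if (!marker %in% names(cohort)) stop("cohort has no marker column '", marker, "'")
  v <- cohort[[marker]]
  if (!is.numeric(v)) stop("marker '", marker, "' is not numeric")
  v
}

#' Percentile category cuts for an emphysema marker
#'
#' Severity categories follow the 60th/80th percentile convention: low
#' below the 60th percentile, medium from the 60th through the 80th, high
#' above the 80th. Cuts are linear-interpolation sample quantiles; with
#' sampling weights they are computed on the weighted distribution so they
#' refer to the full (resampled) cohort.
#'
#' @param scores marker values over the full analysis cohort.
#' @param weights optional sampling weights.
#' @return an object of class \code{category_cuts} with \code{p60, p80}.
#' @export
category_cuts <- function(scores, weights = NULL) {
  if (is.null(weights)) {
    q <- stats::quantile(scores, c(0.6, 0.8), type = 7, names = FALSE)
  } else {
    q <- weighted_quantile(scores, weights, c(0.6, 0.8))
  }
  structure(list(p60 = q[1], p80 = q[2]), class = "category_cuts")
}

# weighted quantile by linear interpolation of the weighted midpoint ECDF
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  p <- (cw - w / 2) / sum(w)
  stats::approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Assign low / medium / high emphysema categories
#'
#' \code{low} iff score < p60; \code{medium} iff p60 <= score <= p80;
#' \code{high} iff score > p80.
#'
#' @param scores marker values.
#' @param cuts a [category_cuts()] object.
#' @return a factor with levels \code{low, medium, high}.
#' @export
categorize <- function(scores, cuts) {
  stopifnot(inherits(cuts, "category_cuts"))
  if (cuts$p60 > cuts$p80) stop("invalid cuts: p60 > p80")
  out <- ifelse(scores < cuts$p60, "low",
                ifelse(scores > cuts$p80, "high", "medium"))
  factor(out, levels = c("low", "medium", "high"))
}
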