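#' Simulated case-control survival cohort specification
#'
#' Emulates a screening-cohort marker study: a right-skewed true emphysema
#' extent, an exponential event-time model whose log hazard is linear in
#' true extent, administrative plus uniform early censoring, observed
#' markers corrupted by a per-kernel noise model (the conventional score
#' carries kernel-dependent bias, the normalized score does not), and
#' case-control subsampling of survivors corrected by sampling weights.
#'
#' @param n number of subjects before subsampling (default 2000).
#' @param baseline_hazard per-day hazard at zero emphysema (default
#'   1.15e-4, about 25 percent baseline 7-year mortality; with the skewed
#'   extent distribution roughly 30 percent of subjects die before
#'   administrative censoring).
#' @param log_hazard_slope log-hazard increase per emphysema percentage
#'   point (default 0.05).
#' @param admin_censor_day end of follow-up (default 2650 days, about 7.3
#'   years: administrative censoring extends just past the last evaluation
#'   horizon, as in a trial whose final follow-up outlasts the last
#'   reported year).
#' @param early_censor_fraction fraction lost to follow-up uniformly
#'   before the administrative end (default 0.1).
#' @param zero_fraction probability of (near-)zero true extent; the rest
#'   draw from a gamma tail (default 0.55).
#' @param gamma_shape,gamma_scale gamma tail parameters (defaults 1.6, 7).
#' @param lc_intercept,lc_slope logistic model for a death being
#'   lung-cancer-specific given true extent (defaults -1.7, 0.06; about a
#'   quarter of deaths overall).
#' @param kernels data frame with columns \code{kernel, orig_bias,
#'   orig_slope, orig_sd, norm_bias, norm_slope, norm_sd}: the per-kernel
#'   affine marker error model, \code{marker = bias + slope * trueES +
#'   N(0, sd)}, normally measured from the imaging pipeline by per-kernel
#'   regression against phantom ground truth (see [end_to_end_fixture()]).
#'   The conventional score carries strongly kernel-dependent intercepts
#'   and gains (sharp kernels inflate, thick soft kernels dilute); the
#'   normalized score's calibration is nearly kernel-independent. The
#'   default is the model measured at the package's default phantom and
#'   kernel settings.
#' @param control_fraction fraction of survivors retained (default 0.5);
#'   retained survivors get weight \code{1/control_fraction}, all deaths
#'   are kept with weight 1. 1.0 keeps the full cohort.
#' @param seed RNG seed.
#' @return an object of class \code{cohort_sim_spec}.
#' @export
cohort_sim_spec <- function(n = 2000, baseline_hazard = 1.15e-4,
                            log_hazard_slope = 0.05,
                            admin_censor_day = 2650,
                            early_censor_fraction = 0.1,
                            zero_fraction = 0.55, gamma_shape = 1.6,
                            gamma_scale = 7, lc_intercept = -1.7,
                            lc_slope = 0.06, kernels = default_kernel_noise(),
                            control_fraction = 0.5, seed = 1L) {
  stopifnot(n >= 10, baseline_hazard > 0, admin_censor_day > 0,
            early_censor_fraction >= 0, early_censor_fraction <= 1,
            zero_fraction >= 0, zero_fraction < 1,
            control_fraction > 0, control_fraction <= 1,
            all(c("kernel", "orig_bias", "orig_slope", "orig_sd",
                  "norm_bias", "norm_slope", "norm_sd") %in% names(kernels)))
  structure(list(n = as.integer(n), baseline_hazard = baseline_hazard,
                 log_hazard_slope = log_hazard_slope,
                 admin_censor_day = admin_censor_day,
                 early_censor_fraction = early_censor_fraction,
                 zero_fraction = zero_fraction, gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale, lc_intercept = lc_intercept,
                 lc_slope = lc_slope, kernels = kernels,
                 control_fraction = control_fraction,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' @rdname cohort_sim_spec
#' @export
default_kernel_noise <- function() {
  data.frame(kernel = c("soft", "medium", "sharp"),
             orig_bias = c(0.1, 0.8, 19), orig_slope = c(0.27, 0.75, 0.80),
             orig_sd = c(0.15, 0.25, 0.5),
             norm_bias = c(0.15, 0.13, 0.07),
             norm_slope = c(0.21, 0.18, 0.07), norm_sd = c(0.15, 0.2, 0.15))
}

#' Simulate a case-control survival cohort
#'
#' @param spec a [cohort_sim_spec()].
#' @return an [as_cohort()] data frame with marker columns \code{trueES},
#'   \code{origES}, \code{normES} and a \code{kernel} column; the design is
#'   case-control (or full when \code{control_fraction} is 1).
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n
  true_es <- ifelse(stats::runif(n) < spec$zero_fraction, 0,
                    stats::rgamma(n, spec$gamma_shape,
                                  scale = spec$gamma_scale))
  true_es <- pmin(true_es, 60)
  haz <- spec$baseline_hazard * exp(spec$log_hazard_slope * true_es)
  t_event <- stats::rexp(n, haz)
  cens <- rep(spec$admin_censor_day, n)
  early <- stats::runif(n) < spec$early_censor_fraction
  cens[early] <- stats::runif(sum(early), 0, spec$admin_censor_day)
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  p_lc <- stats::plogis(spec$lc_intercept + spec$lc_slope * true_es)
  event_lc <- as.integer(event == 1 & stats::runif(n) < p_lc)
  k <- spec$kernels[sample.int(nrow(spec$kernels), n, replace = TRUE), ]
  orig_es <- pmax(0, k$orig_bias + k$orig_slope * true_es +
                    stats::rnorm(n, 0, k$orig_sd))
  norm_es <- pmax(0, k$norm_bias + k$norm_slope * true_es +
                    stats::rnorm(n, 0, k$norm_sd))
  df <- data.frame(id = sprintf("s%05d", seq_len(n)), time = pmax(time, 0.5),
                   event_all_cause = event, event_lung_cancer = event_lc,
                   weight = 1, trueES = true_es, origES = orig_es,
                   normES = norm_es, kernel = k$kernel)
  if (spec$control_fraction >= 1)
    return(as_cohort(df, "full"))
  surv_idx <- which(df$event_all_cause == 0)
  keep <- sort(sample(surv_idx, round(spec$control_fraction *
                                        length(surv_idx))))
  df <- df[c(which(df$event_all_cause == 1), keep), ]
  df <- df[order(df$id), ]
  df$weight[df$event_all_cause == 0] <- 1 / spec$control_fraction
  as_cohort(df, "case_control", spec$control_fraction)
}
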