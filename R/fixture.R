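#' End-to-end phantom and cohort fixture
#'
#' The package's demonstration study, fully seeded: a set of digital
#' phantoms with varying emphysema burden is rendered under the soft,
#' medium and sharp simulated kernels; every rendition is scored both
#' conventionally (origES) and through the harmonization pipeline (normES,
#' with a reference profile taken from the soft renditions); each kernel's
#' marker error against phantom ground truth (additive bias and residual
#' standard deviation) is then measured, and a survival cohort is simulated
#' whose hazard depends on true emphysema extent and whose observed markers
#' are drawn from that measured per-kernel noise model. This couples the
#' cohort's marker corruption to the imaging pipeline itself while keeping
#' the subject count at a scale a phantom study cannot reach directly.
#'
#' @param seed master seed; phantom seeds, noise seeds and the cohort seed
#'   derive from it.
#' @param n_phantoms number of phantoms (default 20).
#' @param n_subjects simulated cohort size before subsampling (default
#'   2000).
#' @param config a [quant_config()].
#' @param out_dir optional directory; when given, writes
#'   \code{phantom_scores.csv}, \code{reference_profile.json},
#'   \code{cohort.csv}, \code{manifest.json} and (with
#'   \code{write_volumes}) the first phantom's renditions as MetaImage.
#' @param write_volumes also write example volumes (default FALSE).
#' @param cohort_args named list of overrides passed to
#'   [cohort_sim_spec()] (e.g. \code{list(n = 500)}).
#' @return a list: \code{scores} (data frame phantom x kernel with trueES,
#'   origES, normES), \code{profile}, \code{noise_model}, \code{cohort},
#'   \code{config}.
#' @export
end_to_end_fixture <- function(seed = 1L, n_phantoms = 20L,
                               n_subjects = 2000L,
                               config = quant_config(), out_dir = NULL,
                               write_volumes = FALSE, cohort_args = list()) {
  seed <- as.integer(seed) %% 100000L
  kernels <- list(soft = kernel_sim("soft"), medium = kernel_sim("medium"),
                  sharp = kernel_sim("sharp"))
  set.seed(seed)
  # emphysema burden varies across phantoms, from none to heavy
  cluster_counts <- round(seq(0, 60, length.out = n_phantoms))
  phantoms <- lapply(seq_len(n_phantoms), function(i)
    generate_phantom(phantom_spec(n_clusters = cluster_counts[i],
                                  seed = seed + 100L * i)))
  rendition <- function(p, i, kname) {
    k <- kernels[[kname]]
    vol <- simulate_kernel(p$volume, k, seed = seed + 100L * i +
                             match(kname, names(kernels)))
    msk <- resample_z(p$volume, p$lung_mask, k$thickness)$mask
    list(volume = vol, mask = msk)
  }
  # reference profile: soft renditions at the target slice thickness
  soft <- lapply(seq_len(n_phantoms), function(i)
    rendition(phantoms[[i]], i, "soft"))
  at_target <- lapply(soft, function(r)
    resample_z(r$volume, r$mask, config$target_slice_thickness))
  profile <- compute_reference_profile(
    lapply(at_target, `[[`, "volume"), lapply(at_target, `[[`, "mask"),
    config)

  rows <- list()
  for (i in seq_len(n_phantoms)) {
    p <- phantoms[[i]]
    for (kname in names(kernels)) {
      r <- if (kname == "soft") soft[[i]] else rendition(p, i, kname)
      es_o <- compute_orig_es(r$volume, r$mask, config)
      es_n <- compute_norm_es(r$volume, r$mask, profile, config)
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = i, kernel = kname, trueES = p$true_es,
        origES = es_o$score, normES = es_n$score)
    }
  }
  scores <- do.call(rbind, rows)

  # per-kernel affine calibration of each marker against ground truth:
  # marker = bias + slope * trueES + N(0, sd)
  calib <- function(col, kname) {
    d <- scores[scores$kernel == kname, ]
    if (nrow(d) >= 3 && stats::sd(d$trueES) > 0) {
      f <- stats::lm(d[[col]] ~ d$trueES)
      c(bias = unname(stats::coef(f)[1]), slope = unname(stats::coef(f)[2]),
        sd = max(summary(f)$sigma, 0.05))
    } else {
      c(bias = mean(d[[col]] - d$trueES), slope = 1,
        sd = max(stats::sd(d[[col]] - d$trueES), 0.05))
    }
  }
  noise_model <- do.call(rbind, lapply(c("soft", "medium", "sharp"),
    function(kname) {
      o <- calib("origES", kname); n <- calib("normES", kname)
      data.frame(kernel = kname, orig_bias = o["bias"],
                 orig_slope = o["slope"], orig_sd = o["sd"],
                 norm_bias = n["bias"], norm_slope = n["slope"],
                 norm_sd = n["sd"])
    }))
  rownames(noise_model) <- NULL

  spec_args <- c(list(n = n_subjects, kernels = noise_model,
                      seed = seed + 7L), cohort_args)
  cohort <- simulate_cohort(do.call(cohort_sim_spec, spec_args))

  out <- list(scores = scores, profile = profile, noise_model = noise_model,
              cohort = cohort, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "phantom_scores.csv"),
                     row.names = FALSE)
    write_profile(profile, file.path(out_dir, "reference_profile.json"))
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(list(seed = seed, n_phantoms = n_phantoms,
                              n_subjects = n_subjects,
                              noise_model = noise_model),
                         file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    if (write_volumes) {
      write_volume(phantoms[[1]]$volume, file.path(out_dir, "phantom1_clean.mha"))
      write_mask(phantoms[[1]]$lung_mask, file.path(out_dir, "phantom1_mask.mha"))
      for (kname in names(kernels))
        write_volume(simulate_kernel(phantoms[[1]]$volume, kernels[[kname]],
                                     seed = seed + 100L + match(kname, names(kernels))),
                     file.path(out_dir, sprintf("phantom1_%s.mha", kname)))
    }
  }
  out
}
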