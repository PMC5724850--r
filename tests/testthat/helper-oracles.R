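# Independent oracles and small fixture builders shared across tests.

# stack-based 8-connected flood-fill labeling, written independently of the
# package's bwlabel + diagonal-merge implementation
oracle_label8 <- function(m) {
  d <- dim(m)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  for (i0 in seq_len(d[1])) for (j0 in seq_len(d[2])) {
    if (!m[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i0, j0), ncol = 2)
    lab[i0, j0] <- cur
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= d[1] && nj >= 1 && nj <= d[2] &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          stack <- rbind(stack, c(ni, nj))
        }
      }
    }
  }
  lab
}

oracle_filter_clusters <- function(m, spacing, min_area) {
  lab <- oracle_label8(m)
  if (max(lab) == 0L) return(m & FALSE)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * spacing[1] * spacing[2] >= min_area)
  matrix(lab %in% keep, nrow(m))
}

# O(n^2) weighted concordance enumeration for the cumulative/dynamic AUC
# with no censoring: cases have time <= t, controls time > t
oracle_td_auc_uncensored <- function(time, marker, weight, horizon) {
  ic <- which(time <= horizon)
  ik <- which(time > horizon)
  num <- 0; den <- 0
  for (i in ic) for (j in ik) {
    w <- weight[i] * weight[j]
    num <- num + w * (if (marker[i] > marker[j]) 1
                      else if (marker[i] == marker[j]) 0.5 else 0)
    den <- den + w
  }
  num / den
}

# small fast phantom for unit tests (extent 36 x 72 x 72 mm)
tiny_phantom <- function(seed = 1, n_clusters = 8, texture_sd = 40) {
  generate_phantom(phantom_spec(shape = c(24, 48, 48),
                                spacing = c(1.5, 1.5, 1.5),
                                n_clusters = n_clusters,
                                cluster_radius = c(2.5, 5),
                                texture_sd = texture_sd, seed = seed))
}

# band schedule that fits small volumes without coarse-scale warnings
small_config <- function(...) quant_config(n_bands = 4, ...)

# hand-rolled uncensored survival cohort around a marker
toy_cohort <- function(n = 40, seed = 1, weights = NULL) {
  set.seed(seed)
  m <- rnorm(n)
  time <- round(rexp(n, 1 / 1000 * exp(0.5 * m)) + 1)
  df <- data.frame(id = sprintf("t%03d", seq_len(n)), time = time,
                   event_all_cause = 1, event_lung_cancer = 0,
                   weight = if (is.null(weights)) 1 else weights,
                   marker = m)
  as_cohort(df, "full")
}
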