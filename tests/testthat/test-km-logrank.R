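hand_cohort <- function() {
  # 10 subjects with interleaved censoring; the product-limit estimate was
  # worked by hand: S = 0.9, 0.8, 0.685714..., 0.548571..., 0.365714...
  as_cohort(data.frame(
    id = letters[1:10],
    time = c(2, 3, 3, 5, 6, 8, 9, 11, 12, 14),
    event_all_cause = c(1, 0, 1, 1, 0, 1, 0, 1, 0, 0),
    event_lung_cancer = 0, weight = 1), "full")
}

test_that("the product-limit estimate matches the hand computation", {
  km <- km_curve(hand_cohort())
  expect_equal(km$times, c(2, 3, 5, 8, 11))
  expect_equal(km$survival,
               c(0.9, 0.8, 0.68571428571428572, 0.54857142857142857,
                 0.36571428571428571), tolerance = 1e-12)
  expect_equal(km_eval(km, c(0, 2, 7, 100)),
               c(1, 0.9, 0.68571428571428572, 0.36571428571428571),
               tolerance = 1e-12)
  expect_equal(km_eval(km, 2, left = TRUE), 1)
})

test_that("integer-weight KM equals KM on the replicated cohort exactly", {
  set.seed(8)
  n <- 25
  df <- data.frame(id = sprintf("w%02d", 1:n),
                   time = round(rexp(n, 1 / 50)) + 1,
                   event_all_cause = rbinom(n, 1, 0.6),
                   event_lung_cancer = 0,
                   weight = sample(1:3, n, TRUE))
  co <- as_cohort(df, "full")
  rep_idx <- rep(seq_len(n), df$weight)
  rep_df <- df[rep_idx, ]
  rep_df$id <- sprintf("r%03d", seq_along(rep_idx))
  rep_df$weight <- 1
  rep_co <- as_cohort(rep_df, "full")
  kw <- km_curve(co)
  kr <- km_curve(rep_co)
  expect_equal(kw$times, kr$times)
  expect_equal(kw$survival, kr$survival, tolerance = 1e-12)
  expect_equal(kw$events, kr$events)
})

test_that("degenerate censoring patterns behave as limits", {
  allcens <- as_cohort(data.frame(id = letters[1:5], time = 1:5,
                                  event_all_cause = 0,
                                  event_lung_cancer = 0, weight = 1), "full")
  km <- km_curve(allcens)
  expect_length(km$times, 0)
  expect_equal(km_eval(km, c(1, 10)), c(1, 1))
  # no censoring: S(t) is the weighted empirical survival
  noc <- as_cohort(data.frame(id = letters[1:6], time = c(1, 2, 2, 4, 6, 9),
                              event_all_cause = 1, event_lung_cancer = 0,
                              weight = c(1, 2, 1, 1, 3, 1)), "full")
  km2 <- km_curve(noc)
  for (t in c(1, 2, 4, 6, 9))
    expect_equal(km_eval(km2, t),
                 sum(noc$weight[noc$time > t]) / sum(noc$weight),
                 tolerance = 1e-12)
})

test_that("the censoring curve is the product-limit with roles swapped", {
  co <- hand_cohort()
  G <- censoring_km(co)
  flipped <- co
  flipped$event_all_cause <- 1 - flipped$event_all_cause
  expect_equal(G$times, km_curve(flipped)$times)
  expect_equal(G$survival, km_curve(flipped)$survival)
})

test_that("two-group log-rank matches survival::survdiff", {
  set.seed(31)
  n <- 60
  df <- data.frame(id = sprintf("s%02d", 1:n),
                   time = round(rexp(n, 1 / 40)) + 1,
                   event_all_cause = rbinom(n, 1, 0.7),
                   event_lung_cancer = 0, weight = 1,
                   grp = factor(sample(c("a", "b"), n, TRUE)))
  co <- as_cohort(df, "full")
  mine <- pairwise_logrank(co, df$grp, stats_config(n_boot = 1))
  ref <- survival::survdiff(survival::Surv(time, event_all_cause) ~ grp,
                            data = df)
  expect_equal(mine$chi2[1], ref$chisq, tolerance = 1e-9)
  expect_equal(mine$p[1],
               stats::pchisq(ref$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("identical groups give a null statistic; 3 groups give 3 pairs", {
  base <- data.frame(time = c(3, 5, 8, 11, 13), event_all_cause = c(1, 1, 0, 1, 0),
                     event_lung_cancer = 0, weight = 1)
  dup <- rbind(base, base)
  dup$id <- sprintf("d%02d", seq_len(nrow(dup)))
  co <- as_cohort(dup, "full")
  grp <- factor(rep(c("g1", "g2"), each = 5))
  out <- pairwise_logrank(co, grp, stats_config(n_boot = 1))
  expect_lt(out$chi2[1], 1e-10)
  expect_gt(out$p[1], 0.999)

  set.seed(5)
  n <- 45
  df3 <- data.frame(id = sprintf("t%02d", 1:n),
                    time = round(rexp(n, 1 / 30)) + 1,
                    event_all_cause = rbinom(n, 1, 0.6),
                    event_lung_cancer = 0, weight = 1)
  co3 <- as_cohort(df3, "full")
  g3 <- factor(rep(c("low", "medium", "high"), each = 15),
               levels = c("low", "medium", "high"))
  out3 <- pairwise_logrank(co3, g3, stats_config(n_boot = 1))
  expect_equal(nrow(out3), 3)
  expect_equal(attr(out3, "alpha"), 0.0167)
  expect_setequal(paste(out3$group1, out3$group2),
                  c("low medium", "low high", "medium high"))
  expect_equal(out3$significant, out3$p < 0.0167)
})
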