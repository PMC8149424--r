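test_that("enamel metric sums connected intensities and handles degenerate images", {
  expect_warning(z <- enamel_metric(matrix(0, 20, 20), calibration_scale = 1),
                 "empty foreground")
  expect_equal(z$metric_um, 0)
  u <- suppressWarnings(enamel_metric(matrix(3, 100, 100),
                                      calibration_scale = 1))
  expect_equal(u$connected_intensity_sum, 100 * 100 * 3)
  expect_equal(u$connected_px, 10000L)
  expect_warning(enamel_metric(matrix(c(0, 5), 20, 20)), "calibration_scale")
})

test_that("phantom treatment series yields strictly decreasing en-face metrics", {
  th <- list(base = 120, amplitude = 60, period = 200)
  mets <- vapply(c(0, 10, 20, 30), function(d) {
    sp <- clean_spec(rows = 260, cols = 200, surface = 40,
                     thickness = list(base = 120 - d, amplitude = 60,
                                      period = 200))
    v <- generate_volume(sp, n_slices = 6)
    ef <- extract_enface(v$volume, 500)
    suppressWarnings(enamel_metric(ef))$connected_intensity_sum
  }, numeric(1))
  expect_true(all(diff(mets) < 0))
})

test_that("stage mean differences reproduce the published group arithmetic", {
  means <- c(765.70, 640.30, 567.80, 498.13)
  d <- mean_differences(means)
  get <- function(a, b) d$mean_difference[d$stage_a == a & d$stage_b == b]
  labs <- treatment_stage_labels()
  expect_equal(get(labs[1], labs[2]), 125.40)
  expect_equal(get(labs[3], labs[4]), 69.67)
  expect_equal(get(labs[1], labs[4]), 267.57)
  # antisymmetry by construction + transitive additivity
  expect_equal(get(labs[1], labs[2]) + get(labs[2], labs[4]),
               get(labs[1], labs[4]))
})

test_that("group summaries report sample SD and recoverable statistics", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  gs <- group_summary(m)
  expect_equal(gs$summary$mean, c(2, 3))
  expect_equal(gs$summary$sd, c(sqrt(2), sqrt(2)))
  expect_equal(gs$summary$min, c(1, 2))
  expect_equal(gs$summary$max, c(3, 4))
  const <- matrix(5, 4, 3)
  gc <- group_summary(const)
  expect_true(all(gc$summary$sd == 0))
  expect_true(all(gc$differences$mean_difference == 0))
  expect_error(group_summary(matrix(1:4, 1, 4)), "2 subjects")
  expect_equal(tidy(gs), gs$summary)
})

test_that("repeated-measures ANOVA matches the brute-force sums of squares", {
  set.seed(15)
  for (i in 1:5) {
    m <- matrix(rnorm(20), 5, 4)
    fit <- rm_anova(m)
    oracle <- oracle_rm_anova(m)
    expect_equal(fit$statistic, oracle$F, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
    expect_equal(fit$df_treatment, 3L)
    expect_equal(fit$df_error, 12L)
  }
  m3 <- matrix(c(1, 2, 3, 2, 4, 6, 3, 6, 9), 3, 3)
  expect_equal(rm_anova(m3)$statistic, oracle_rm_anova(m3)$F, tolerance = 1e-10)
})

test_that("RM-ANOVA agrees with aov's within-subject decomposition", {
  set.seed(16)
  m <- matrix(rnorm(30, 100, 10), 6, 5)
  long <- data.frame(y = as.vector(m), subject = factor(rep(1:6, 5)),
                     stage = factor(rep(1:5, each = 6)))
  ref <- summary(aov(y ~ stage + Error(subject/stage), data = long))
  Fref <- ref[["Error: subject:stage"]][[1]]["stage", "F value"]
  expect_equal(rm_anova(m)$statistic, Fref, tolerance = 1e-8)
})

test_that("two-stage RM-ANOVA collapses to the squared paired t statistic", {
  set.seed(17)
  m <- matrix(rnorm(24, 50, 5), 12, 2)
  fit <- rm_anova(m)
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(fit$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("RM-ANOVA degenerates gracefully and respects invariances", {
  ident <- matrix(rep(c(3, 7, 9), each = 4), 4, 3)  # stages identical per subject?
  # per-subject constant rows: no treatment effect at all
  flat <- matrix(rep(c(3, 7, 9, 11), times = 3), 4, 3)
  fit <- rm_anova(flat)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p_value, 1)
  set.seed(18)
  m <- matrix(rnorm(20), 5, 4)
  f0 <- rm_anova(m)$statistic
  expect_equal(rm_anova(m + 100)$statistic, f0, tolerance = 1e-9)
  expect_equal(rm_anova(m + rnorm(5) %o% rep(1, 4))$statistic, f0,
               tolerance = 1e-9)
  mm <- m; mm[2, 3] <- NA
  expect_error(rm_anova(mm), "missing")
  expect_error(rm_anova(matrix(1:4, 4, 1)), "2 subjects|2 stages")
})

test_that("Bonferroni pairs multiply raw p-values by the number of pairs, capped at one", {
  set.seed(19)
  m <- matrix(rnorm(120, 100, 15), 30, 4)
  bp <- bonferroni_pairs(m)
  expect_equal(nrow(bp), 6L)
  for (i in seq_len(6)) {
    a <- which(treatment_stage_labels() == bp$stage_a[i])
    b <- which(treatment_stage_labels() == bp$stage_b[i])
    raw <- t.test(m[, a], m[, b], paired = TRUE)$p.value
    expect_equal(bp$p_raw[i], raw, tolerance = 1e-12)
    expect_equal(bp$p_adj[i], min(1, 6 * raw), tolerance = 1e-12)
    expect_equal(bp$p_adj[i],
                 p.adjust(c(raw, rep(1, 5)), method = "bonferroni")[1],
                 tolerance = 1e-12)
  }
  expect_true(all(bp$p_adj >= bp$p_raw))
  # identical stages: all adjusted p = 1, none significant
  const <- matrix(rep(rnorm(10), 4), 10, 4)
  bpc <- bonferroni_pairs(const)
  expect_true(all(bpc$p_adj == 1))
  expect_true(all(!bpc$significant))
  # a single pair: adjustment is the identity
  bp1 <- bonferroni_pairs(m[, 1:2])
  expect_equal(bp1$p_adj, bp1$p_raw)
})

test_that("KS normality statistic equals the brute-force supremum", {
  set.seed(20)
  for (i in 1:5) {
    x <- rnorm(5 + i, 10, 2)
    expect_equal(ks_normality(x)$statistic, oracle_ks_D(x), tolerance = 1e-12)
  }
  big <- rnorm(1e4)
  expect_lt(ks_normality(big)$statistic, 0.02)
  expect_error(ks_normality(rep(3, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2)), "at least 3")
})

test_that("KS statistic matches the Lilliefors statistic from nortest", {
  skip_if_not_installed("nortest")
  set.seed(21)
  x <- rgamma(40, 2)
  expect_equal(ks_normality(x)$statistic,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-10)
})

test_that("the full group report ties summary, normality, ANOVA and post-hoc together", {
  met <- simulate_enamel_metrics(n_subjects = 30, seed = 22)
  gs <- run_group_stats(met)
  expect_equal(dim(gs$matrix), c(30L, 4L))
  expect_equal(nrow(gs$normality), 4L)
  expect_equal(nrow(gs$pairs), 6L)
  expect_lt(gs$anova$p_value, 0.001)
  # stage means decrease as built into the simulated effects
  expect_true(all(diff(gs$summary$summary$mean) < 0))
  rep <- group_stats_report(gs)
  expect_named(rep, c("summary", "mean_differences", "normality", "rm_anova",
                      "bonferroni", "alpha"))
  expect_s3_class(glance(gs), "tbl_df")
  expect_s3_class(autoplot(gs), "ggplot")
})

test_that("metric simulation reproduces its cohort structure deterministically", {
  a <- simulate_enamel_metrics(seed = 23)
  b <- simulate_enamel_metrics(seed = 23)
  expect_identical(a, b)
  expect_equal(nrow(a), 120L)
  m <- enameloct:::as_stage_matrix(a)
  expect_equal(dim(m), c(30L, 4L))
  # stage effects appear in the column means (within sampling noise)
  expect_equal(unname(colMeans(m)[1] - colMeans(m)[4]), 267.57,
               tolerance = 60)
})
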