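# Statistical battery: paired t, ANOVA, RM-ANOVA, post-hoc procedures.

test_that("paired t-test matches the hand-computed closed form", {
  # differences {1, 2, 3}: t = 2 / (1/sqrt(3)) = 3.4641, df = 2
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$mean_difference, 2)
  # one-tailed p halves the two-tailed p in the hypothesized direction
  one <- paired_t(c(1, 2, 3), c(2, 4, 6), tail = "less")
  expect_equal(one$p, res$p / 2, tolerance = 1e-10)
  expect_error(paired_t(c(1, 2), c(1, 2, 3)), "paired")
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
})

test_that("paired t p-value agrees with the exact sign-flip enumeration", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(8, mean = 0.4)
    y <- rnorm(8)
    p_t <- paired_t(x, y)$p
    p_perm <- signflip_p(x - y)
    expect_lte(abs(p_t - p_perm), 0.05)
    if (p_t > 0.05 && p_t < 0.95)      # away from the discrete extremes
      expect_lte(abs(p_t - p_perm), 0.03)
  }
})

test_that("paired t type-I error is calibrated at the nominal 5% level", {
  set.seed(13)
  rejections <- sum(vapply(1:2000, function(i) {
    x <- rnorm(10); y <- rnorm(10)
    paired_t(x, y)$p < 0.05
  }, logical(1)))
  env <- qbinom(c(0.025, 0.975), 2000, 0.05)
  expect_gte(rejections, env[1])
  expect_lte(rejections, env[2])
})

test_that("one-way ANOVA has the design df and matches brute-force sums of squares", {
  g_ident <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r0 <- one_way_anova(g_ident)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  set.seed(14)
  g3x10 <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  r <- one_way_anova(g3x10)
  expect_equal(r$df_between, 2)
  expect_equal(r$df_within, 27)
  bf <- anova_bruteforce(g3x10)
  expect_equal(r$F, bf$F, tolerance = 1e-10)
  expect_equal(r$p, bf$p, tolerance = 1e-10)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "observations")
})

test_that("ANOVA F is invariant to location shifts and group relabelling", {
  set.seed(15)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  F0 <- one_way_anova(g)$F
  shifted <- lapply(g, function(v) v + 42)
  expect_equal(one_way_anova(shifted)$F, F0, tolerance = 1e-10)
  expect_equal(one_way_anova(g[c(3, 1, 2)])$F, F0, tolerance = 1e-10)
})

test_that("RM-ANOVA df and F match the within-subject closed form", {
  set.seed(16)
  m86 <- matrix(rnorm(48), nrow = 8, ncol = 6)
  r <- rm_anova(m86)
  expect_equal(r$df_between, 5)
  expect_equal(r$df_within, 35)
  bf <- rm_anova_bruteforce(m86)
  expect_equal(r$F, bf$F, tolerance = 1e-10)

  m33 <- matrix(c(3, 5, 4,  4, 7, 6,  6, 8, 9), nrow = 3)
  r33 <- rm_anova(m33)
  bf33 <- rm_anova_bruteforce(m33)
  expect_equal(r33$F, bf33$F, tolerance = 1e-10)
  expect_equal(c(r33$df_between, r33$df_within), c(bf33$df1, bf33$df2))

  const <- matrix(rnorm(8), nrow = 4, ncol = 2)[, c(1, 1)]
  expect_equal(rm_anova(const)$F, 0)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("RM-ANOVA df are (k-1, (k-1)(n-1)) for any complete design", {
  set.seed(17)
  for (dims in list(c(4, 3), c(8, 6), c(5, 5), c(12, 2))) {
    r <- rm_anova(matrix(rnorm(prod(dims)), dims[1], dims[2]))
    expect_equal(r$df_between, dims[2] - 1)
    expect_equal(r$df_within, (dims[2] - 1) * (dims[1] - 1))
  }
})

test_that("Tukey-Kramer reduces to the pooled two-sample t-test at k = 2", {
  set.seed(18)
  g <- list(a = rnorm(9), b = rnorm(11, 0.8))
  tk <- tukey_kramer(g)
  tt <- t.test(g$b, g$a, var.equal = TRUE)
  expect_equal(tk$p_adjusted, tt$p.value, tolerance = 1e-8)
  expect_equal(tk$estimate, mean(g$b) - mean(g$a), tolerance = 1e-10)
})

test_that("post-hoc procedures keep p-values in [0,1] and Bonferroni dominates", {
  set.seed(19)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 0.5))
  tk <- tukey_kramer(g)
  expect_true(all(tk$p_adjusted >= 0 & tk$p_adjusted <= 1))
  lsd <- lsd_pairwise(g)
  lsd_b <- lsd_pairwise(g, adjust = "bonferroni")
  expect_true(all(lsd_b$p_adjusted >= lsd$p_adjusted - 1e-12))
  expect_equal(bonferroni_adjust(0.02, m = 3), 0.06)
  expect_equal(bonferroni_adjust(c(0.5, 0.9), m = 3), c(1, 1))
})

test_that("dialysis report reproduces the relative-increase arithmetic and design df", {
  cfg0 <- dialysis_config(
    condition_sds = setNames(rep(0, 8), names(dialysis_config()$condition_means)),
    run_effect_sd = 0)
  rep0 <- analyze_dialysis(generate_dialysis_samples(cfg0))
  expect_equal(rep0$relative_increase_vs_ctrl_pct[["FF_set4"]],
               100 * (0.65 / 0.55 - 1), tolerance = 1e-10)   # 18.18%
  s <- generate_dialysis_samples(dialysis_config(seed = 5))
  rep1 <- analyze_dialysis(s)
  expect_equal(rep1$rm_anova_ff_sets$df_between, 5)
  expect_equal(rep1$rm_anova_ff_sets$df_within, 35)
  expect_equal(rep1$rm_anova_conditions$df_between, 2)
  expect_equal(rep1$rm_anova_conditions$df_within, 14)
  expect_true(all(rep1$pairwise_ff$p_adjusted <= 1, na.rm = TRUE))
})

test_that("cohort report covers summaries, paired tests and between-group ANOVA", {
  set.seed(20)
  idx <- tibble::tibble(
    animal_id = rep(sprintf("r%02d", 1:15), each = 2),
    group = rep(rep(c("A", "B", "C"), each = 5), each = 2),
    period = rep(c("pre", "post"), 15),
    ictal_count = rpois(30, 40),
    ictal_duration_per_event_s = rlnorm(30, log(5), 0.3),
    ictal_amplitude_per_event_uv = rlnorm(30, log(100), 0.3),
    hours_observed = 24)
  nrm <- suppressMessages(normalize_indices(idx))
  rep <- analyze_cohort(nrm, idx)
  expect_s3_class(rep$group_summary, "tbl_df")
  expect_equal(nrow(rep$group_summary), 9)          # 3 indices x 3 groups
  expect_equal(rep$anova$count$df_between, 2)
  expect_equal(rep$anova$count$df_within, 12)
  expect_equal(rep$paired_tests$count$A$tail, "less")
  expect_equal(rep$paired_tests$amplitude$A$tail, "two")
  # degenerate single-group design: between-group tests skipped with warning
  idx1 <- idx[idx$group == "A", ]
  nrm1 <- suppressMessages(normalize_indices(idx1))
  w <- capture_warnings(rep1 <- analyze_cohort(nrm1, idx1))
  expect_length(w, 3)                     # one skip per index
  expect_true(all(grepl("skipped", w)))
  expect_null(rep1$anova$count)
})

test_that("between-group ANOVA is calibrated under a null cohort", {
  # identical intervention effects in all arms: the between-group ANOVA on
  # normalized changes must reject at its nominal rate and produce p-values
  # close to uniform. (Count ratios are integer-granular and heteroscedastic
  # across animals, so exact KS-uniformity is not attainable; rejection-rate
  # calibration is the operative property.)
  null_effects <- list("PHT+FUS" = intervention_effect(),
                       "PHT_ONLY" = intervention_effect(),
                       "FUS_ONLY" = intervention_effect())
  pv <- vapply(1:500, function(i) {
    cfg <- cohort_config(session_hours = 1, sessions_per_period = 8,
                         n_per_group = 10, effects = null_effects,
                         seed = 3000 + i)
    tr <- simulate_cohort_truth(cfg)
    ev <- tr$events[!tr$events$is_subthreshold, ]
    ev$amplitude_uv <- ev$peak_amplitude_uv
    idx <- compute_indices(ev, 8, animals = tr$animals[c("animal_id", "group")])
    nrm <- suppressMessages(normalize_indices(idx))
    fc <- is.finite(nrm$count_change_pct)
    fd <- is.finite(nrm$duration_change_pct)
    c(one_way_anova(split(nrm$count_change_pct[fc], nrm$group[fc]))$p,
      one_way_anova(split(nrm$duration_change_pct[fd], nrm$group[fd]))$p)
  }, numeric(2))
  for (r in 1:2) {
    for (alpha in c(0.05, 0.10)) {
      env <- qbinom(c(0.005, 0.995), 500, alpha)
      expect_gte(sum(pv[r, ] < alpha), env[1])
      expect_lte(sum(pv[r, ] < alpha), env[2])
    }
    ks <- suppressWarnings(stats::ks.test(pv[r, ], "punif"))
    expect_gt(ks$p.value, 0.001)
  }
})
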