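test_that("ocular perfusion pressure evaluates the published formula", {
  expect_equal(compute_opp(116.0, 69.2, 17.1), 39.43, tolerance = 1e-3)
  expect_equal(compute_opp(111.0, 67.2, 13.7), 40.83, tolerance = 1e-3)
  expect_equal(compute_opp(0.01, 0.01, 0), 0.01 * 2 / 3, tolerance = 1e-9)
  x <- c(80, 120, 95)
  expect_equal(compute_opp(x, x, 0), 2 * x / 3)
  # linearity: scaling all inputs scales the output
  a <- 1.7
  expect_equal(compute_opp(a * 116, a * 69.2, a * 17.1),
               a * compute_opp(116, 69.2, 17.1))
  expect_error(compute_opp(60, 70, 10), "systolic")
  expect_error(compute_opp(120, -1, 10), "positive")
  expect_error(compute_opp(120, 80, -1), "non-negative")
})

test_that("logMAR conversion is -log10 of decimal acuity", {
  expect_equal(decimal_to_logmar(1.0), 0)
  expect_equal(decimal_to_logmar(0.5), 0.301, tolerance = 1e-3)
  expect_equal(decimal_to_logmar(2.0), -0.301, tolerance = 1e-3)
  expect_error(decimal_to_logmar(0), "positive")
  expect_error(decimal_to_logmar(-0.5), "positive")
})

test_that("percent change is computed per subject, not from group means", {
  expect_equal(percent_change(1.0, 1.149), 14.9, tolerance = 1e-9)
  expect_equal(percent_change(17.1, 17.1), 0)
  expect_error(percent_change(0, 1), "non-zero")
  # on skewed data, mean-of-per-subject-changes != change-of-means: a
  # 5-subject toy table, verified by direct arithmetic
  base <- c(1, 1, 1, 1, 10)
  fup <- c(2, 2, 2, 2, 10)
  per_subject <- mean(percent_change(base, fup))      # 80%
  of_means <- percent_change(mean(base), mean(fup))   # ~28.6%
  expect_equal(per_subject, 80)
  expect_equal(of_means, 100 * (3.6 - 2.8) / 2.8)
  expect_gt(abs(per_subject - of_means), 50)
})

test_that("group comparison handles identical and degenerate groups", {
  co <- simulate_cohort(seed = 12)
  # identical groups: force POAG baseline to mirror healthy
  h <- co[co$group == "healthy", ]
  p <- h
  p$group <- "POAG"; p$subject_id <- sub("H", "P", p$subject_id)
  twin <- rbind(h, p)
  res <- compare_groups(twin, variables = c("pbfv_mm_s", "iop_mmHg"),
                        include_sex = FALSE)
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  # constant-in-both variable is flagged, not tested
  twin$flat <- 5
  res2 <- compare_groups(twin, variables = "flat", include_sex = FALSE)
  expect_true(is.na(res2$p_value))
  expect_match(res2$test, "degenerate")
  expect_error(compare_groups(co[co$group == "POAG", ]), ">= 2 baseline")
})

test_that("group comparison runs the study roster with both tests", {
  co <- simulate_cohort(seed = 13)
  co$opp_mmHg <- compute_opp(co$sbp_mmHg, co$dbp_mmHg, co$iop_mmHg)
  res <- compare_groups(co)
  expect_true(all(c("pbfv_mm_s", "iop_mmHg", "opp_mmHg", "sex_male") %in%
                    res$variable))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_equal(res$test[res$variable == "sex_male"], "chi-square")
  # equal-variance t by default; Welch behind the flag changes the statistic
  res_w <- compare_groups(co, variables = "pbfv_mm_s", welch = TRUE,
                          include_sex = FALSE)
  expect_equal(res_w$test, "Welch t")
})

test_that("longitudinal analysis of constant data is degenerate exactly", {
  co <- simulate_cohort(cohort_sim_config(
    longitudinal_effects = FALSE, missing_week12 = 0,
    poag_sds = lapply(cohort_sim_config()$poag_sds, function(x) x * 0)),
    seed = 14)
  la <- longitudinal_analysis(co, "pbfv_mm_s")
  expect_equal(la$rm_anova$F, 0)
  expect_equal(la$rm_anova$p, 1)
  expect_equal(la$post_hoc$p, rep(1, 3))
  expect_equal(la$visit_stats$mean_pct_change, rep(0, 4))
})

test_that("missing week-12 subjects drop from the ANOVA but keep their pairs", {
  co <- simulate_cohort(cohort_sim_config(missing_week12 = 2), seed = 15)
  la <- longitudinal_analysis(co, "iop_mmHg")
  expect_equal(la$rm_anova$n, 9)            # complete cases only
  expect_equal(la$post_hoc$n_pairs, c(11, 11, 9))
  expect_equal(la$visit_stats$n, c(11, 11, 11, 9))
})

test_that("the ANOVA is refused below 3 complete cases, post hoc retained", {
  co <- simulate_cohort(seed = 16)
  poag <- co[co$group == "POAG", ]
  two <- poag[poag$subject_id %in% unique(poag$subject_id)[1:2], ]
  la <- longitudinal_analysis(rbind(co[co$group == "healthy", ], two),
                              "pbfv_mm_s")
  expect_true(la$rm_anova$refused)
  expect_false(anyNA(la$post_hoc$p))
})

test_that("RM-ANOVA matches a permutation oracle on a small dataset", {
  set.seed(99)
  mat <- matrix(rnorm(44), 11, 4) + rep(c(0, 0.4, 0.5, 0.3), each = 11) +
    rnorm(11)
  co <- data.frame(subject_id = rep(sprintf("S%02d", 1:11), each = 4),
                   group = "POAG", visit = rep(visit_levels(), 11),
                   v = as.vector(t(mat)))
  la <- longitudinal_analysis(co, "v")
  ssq <- function(m) nrow(m) * sum((colMeans(m) - mean(m))^2)
  obs <- ssq(mat); cnt <- 0L
  for (b in 1:4000) {
    if (ssq(t(apply(mat, 1, sample))) >= obs - 1e-12) cnt <- cnt + 1L
  }
  p_perm <- (cnt + 1) / 4001
  expect_lt(abs(la$rm_anova$p - p_perm),
            0.015 + 3 * sqrt(p_perm * (1 - p_perm) / 4000))
})

test_that("Bonferroni-corrected significance implies nominal significance", {
  for (s in 1:5) {
    co <- simulate_cohort(seed = 100 + s)
    la <- longitudinal_analysis(co, "pbfv_mm_s")
    sig <- la$post_hoc$significant_bonferroni
    expect_true(all(la$post_hoc$p[sig %in% TRUE] < 0.05))
    expect_true(all(la$post_hoc$p[sig %in% TRUE] < 0.05 / 3))
  }
})

test_that("required sample size reproduces the design computation", {
  # the published design: f = 0.4, alpha = 0.05, power = 0.8, 4 occasions
  expect_identical(required_sample_size(power_spec()), 10L)
  # power -> 0+ collapses to the minimum admissible n
  expect_identical(required_sample_size(power_spec(power = 1e-6)), 2L)
  expect_error(required_sample_size(power_spec(effect_size_f = 0)),
               "no finite")
  expect_error(power_spec(alpha = 0), "alpha")
})

test_that("sample-size search agrees with a brute-force power curve", {
  brute <- function(spec) {
    pw <- rm_anova_power(2:500, spec)
    (2:500)[which(pw >= spec$power)[1]]
  }
  set.seed(77)
  for (i in 1:20) {
    spec <- power_spec(effect_size_f = runif(1, 0.15, 0.8),
                       alpha = runif(1, 0.01, 0.1),
                       power = runif(1, 0.5, 0.95),
                       n_timepoints = sample(2:6, 1),
                       corr_among_reps = runif(1, 0, 0.8))
    expect_identical(required_sample_size(spec), as.integer(brute(spec)))
  }
})

test_that("required sample size is monotone in its drivers", {
  base <- power_spec()
  n0 <- required_sample_size(base)
  expect_lte(required_sample_size(power_spec(effect_size_f = 0.6)), n0)
  expect_lte(required_sample_size(power_spec(corr_among_reps = 0.7)), n0)
  expect_gte(required_sample_size(power_spec(power = 0.95)), n0)
})
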