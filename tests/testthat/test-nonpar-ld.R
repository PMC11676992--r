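test_that("baseline adjustment zeroes T1-pre and keeps differences", {
  coh <- make_toy_cohort(n1 = 2, n2 = 2, values = 0)
  s1 <- coh$subject_id == "S01"
  coh$y[s1 & coh$time == "T1" & coh$phase == "pre"] <- 900
  coh$y[s1 & coh$time == "T1" & coh$phase == "post"] <- 950
  coh$y[s1 & coh$time == "T10" & coh$phase == "pre"] <- 910
  coh$y[s1 & coh$time == "T10" & coh$phase == "post"] <- 960
  adj <- baseline_adjust(coh, "y")
  got <- adj$y[s1][order(adj$time[s1], adj$phase[s1])]
  expect_setequal(adj$y[s1], c(0, 50, 10, 60))
  expect_true(all(adj$y[adj$time == "T1" & adj$phase == "pre"] == 0))
})

test_that("baseline adjustment refuses a missing T1-pre value", {
  coh <- make_toy_cohort(seed = 2)
  coh$y[coh$subject_id == "S03" & coh$time == "T1" &
          coh$phase == "pre"] <- NA
  expect_error(baseline_adjust(coh, "y"), "S03")
})

test_that("relative effects equal the brute-force pairwise definition", {
  for (s in 1:6) {
    coh <- make_toy_cohort(n1 = 4, n2 = 3, seed = s)
    if (s %% 2 == 0) coh$y <- round(coh$y)  # force ties
    for (scope in c("condition", "phase", "time", "treatment-condition")) {
      re <- relative_effects(coh, "y", scope = scope)
      cond <- switch(scope,
        "condition" = paste0(coh$time, ":", coh$phase),
        "phase" = as.character(coh$phase),
        "time" = as.character(coh$time),
        "treatment-condition" = paste0(coh$treatment, ":", coh$time, ":",
                                       coh$phase))
      brute <- brute_force_relative_effects(coh$y, cond)
      expect_equal(re$estimate, unname(brute[re$condition]),
                   tolerance = 1e-12)
      # observation-weighted mean of condition effects is exactly 1/2
      expect_equal(sum(re$estimate * re$n) / sum(re$n), 0.5,
                   tolerance = 1e-12)
    }
    # within-time scope: pooled set restricted to each time level
    rew <- relative_effects(coh, "y", scope = "within-time")
    for (tl in c("T1", "T10")) {
      sel <- coh$time == tl
      brute <- brute_force_relative_effects(
        coh$y[sel], paste0(tl, ":", coh$phase[sel]))
      got <- rew[grepl(paste0("^", tl, ":"), rew$condition), ]
      expect_equal(got$estimate, unname(brute[got$condition]),
                   tolerance = 1e-12)
      expect_equal(sum(got$estimate), 1, tolerance = 1e-12)
    }
  }
})

test_that("fully tied data give degenerate relative effects", {
  coh <- make_toy_cohort(values = 7)
  expect_warning(re <- relative_effects(coh, "y"), "tied")
  expect_true(all(re$estimate == 0.5))
  expect_true(all(re$ci_lower == 0.5 & re$ci_upper == 0.5))
})

test_that("CI bounds are ordered, clipped, and logit CIs stay in (0,1)", {
  coh <- make_toy_cohort(n1 = 5, n2 = 4, seed = 9)
  for (m in c("normal", "logit")) {
    re <- relative_effects(coh, "y", ci_method = m)
    expect_true(all(re$ci_lower <= re$estimate & re$estimate <= re$ci_upper))
    expect_true(all(re$ci_lower >= 0 & re$ci_upper <= 1))
  }
})

test_that("ANOVA-type tests return seven nonnegative statistics with valid
           p-values", {
  coh <- make_toy_cohort(n1 = 5, n2 = 4, seed = 4)
  res <- anova_type_tests(coh, "y")
  expect_equal(nrow(res), 7)
  expect_setequal(res$effect, c("Treat", "Time", "Phase", "Treat:Time",
                                "Treat:Phase", "Time:Phase",
                                "Treat:Time:Phase"))
  expect_true(all(res$statistic >= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # every effect carries Box-approximated numerator and denominator df
  expect_true(all(is.finite(res$df_num) & res$df_num > 0))
  expect_true(all(is.finite(res$df_den) & res$df_den > 0))
})

test_that("tests and effects are invariant under strictly increasing
           transforms", {
  coh <- make_toy_cohort(n1 = 6, n2 = 4, seed = 11)
  coh$y <- coh$y + 3            # keep positive for the power transform
  t0 <- anova_type_tests(coh, "y")
  r0 <- relative_effects(coh, "y")
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    coh2 <- coh; coh2$y <- f(coh2$y)
    expect_equal(anova_type_tests(coh2, "y"), t0, tolerance = 1e-12)
    expect_equal(relative_effects(coh2, "y"), r0, tolerance = 1e-12)
  }
})

test_that("degenerate designs are refused", {
  coh <- make_toy_cohort(values = 1)
  expect_error(anova_type_tests(coh, "y"), "tied")
  coh2 <- make_toy_cohort(seed = 3)
  expect_error(anova_type_tests(coh2[-1, ], "y"), "incomplete")
  coh3 <- make_toy_cohort(seed = 3)
  coh3$treatment <- ifelse(coh3$subject_id == "S01", "-55C", "-110C")
  expect_error(anova_type_tests(coh3, "y"), "at least 2 subjects")
})

test_that("the phase test tracks an exact permutation reference", {
  # moderate toy design so the large-sample reference is meaningful
  set.seed(2)
  N <- 16
  Y <- matrix(stats::rnorm(N * 4), N, 4,
              dimnames = list(sprintf("S%02d", 1:N),
                              cryohrv:::sub_plot_cells()))
  group <- factor(rep(c("-55C", "-110C"), each = 8),
                  levels = c("-55C", "-110C"))
  res <- phase_permutation_p(Y, group, n_perm = 4000, seed = 5)
  expect_lt(abs(res$p_ats - res$p_perm), 0.04)
})

test_that("CI-overlap flags follow the disjointness rules", {
  eff <- data.frame(variable = "ansi", scope = "within-time",
                    condition = c("T1:pre", "T1:post"),
                    estimate = c(0.315, 0.685),
                    ci_lower = c(0.271, 0.579),
                    ci_upper = c(0.421, 0.729), n = c(23, 23))
  fl <- ci_overlap_significance(eff)
  expect_true(fl$pairs$disjoint)
  expect_true(all(fl$vs_pooled$excludes_half))

  eff2 <- eff
  eff2$ci_lower <- c(0.40, 0.50); eff2$ci_upper <- c(0.55, 0.60)
  fl2 <- ci_overlap_significance(eff2)
  expect_false(fl2$pairs$disjoint)

  eff3 <- eff
  eff3$ci_lower[1] <- 0.46; eff3$ci_upper[1] <- 0.52
  expect_false(ci_overlap_significance(eff3)$vs_pooled$excludes_half[1])

  eff$scope <- c("within-time", "condition")
  expect_error(ci_overlap_significance(eff), "mix")
})

test_that("an injected phase shift is detected with high power", {
  rate <- simulate_rejection_rate(120, phase_effect = 1.5, seed = 33)
  expect_gt(rate, 0.8)
})
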