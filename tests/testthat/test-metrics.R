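test_that("relative thresholds are exact and linear", {
  expect_equal(relative_ed50(35.54, 30.52), 5.02)
  expect_equal(relative_ed50(36.18, 30.52), 5.66)
  expect_equal(relative_ed50(30.52, 30.52), 0)
  # exact linearity in the threshold
  x <- c(31.7, 35.54, 40.01)
  expect_equal(relative_ed50(x + 1.3), relative_ed50(x) + 1.3)
  expect_error(relative_ed50(NA), class = "coralscreen_domain_error")
})

test_that("treatment temperatures are baseline plus offsets", {
  expect_equal(treatment_temperatures(30.5, c(4, 6, 9)), c(34.5, 36.5, 39.5))
  expect_equal(treatment_temperatures(30.5, numeric()), numeric())
  expect_equal(treatment_temperatures(30.5, 0), 30.5)
  expect_error(treatment_temperatures(30.5, -2),
               class = "coralscreen_config_error")
})

test_that("summarize_groups computes mean +/- SEM per group", {
  one <- tibble::tibble(species = "A", site = "S1", condition = "donor",
                        timepoint = "T1", ed50 = 38.22)
  expect_warning(s1 <- summarize_groups(one), "single colony")
  expect_equal(s1$mean_relative_ed50, 7.70)
  expect_equal(s1$sem, 0)

  two <- tibble::tibble(species = "A", site = "S1", condition = "donor",
                        timepoint = "T1", ed50 = c(5, 7) + 30.52)
  s2 <- summarize_groups(two)
  expect_equal(s2$mean_relative_ed50, 6)
  expect_equal(s2$sem, 1)
  expect_error(summarize_groups(two[0, ]), class = "coralscreen_data_error")
})

test_that("compare_paired applies the complete-pairs rule and normality gate", {
  base <- tibble::tibble(
    id = rep(sprintf("c%02d", 1:10), 2),
    grp = rep(c("nursery", "donor"), each = 10),
    val = c(rnorm(10, 5), rnorm(10, 7)))

  # identical paired vectors: degenerate, no p-value
  same <- base
  same$val[11:20] <- same$val[1:10]
  res <- compare_paired(same, "val", "grp", "id")
  expect_true(res$degenerate)
  expect_equal(res$mean_diff, 0)
  expect_true(is.na(res$p_value))

  # unpaired extras are dropped: n_pairs is the id intersection
  extra <- dplyr::bind_rows(
    base, tibble::tibble(id = c("x1", "x2"), grp = "nursery", val = c(5, 6)))
  res2 <- withr::with_seed(1, {
    d <- extra
    d$val <- rnorm(nrow(d), ifelse(d$grp == "nursery", 5, 7))
    compare_paired(d, "val", "grp", "id",
                   group_levels = c("nursery", "donor"))
  })
  expect_equal(res2$n_pairs, 10L)

  # symmetry: swapping groups negates the effect, p unchanged
  d <- withr::with_seed(2, dplyr::mutate(base, val = rnorm(20, 5) +
                                           (grp == "donor") * 2))
  ab <- compare_paired(d, "val", "grp", "id",
                       group_levels = c("nursery", "donor"))
  ba <- compare_paired(d, "val", "grp", "id",
                       group_levels = c("donor", "nursery"))
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$test_used, "paired-t")

  # strongly non-normal differences fall through to the Wilcoxon branch
  skewed <- withr::with_seed(8, tibble::tibble(
    id = rep(sprintf("c%02d", 1:20), 2),
    grp = rep(c("a", "b"), each = 20),
    val = c(rexp(20)^3, rep(0, 20))))
  expect_equal(compare_paired(skewed, "val", "grp", "id")$test_used,
               "wilcoxon-signed")

  expect_error(compare_paired(base[c(1, 2, 11, 12), ], "val", "grp", "id"),
               class = "coralscreen_insufficient_data")
})

test_that("a published-size deficit is detected in nearly every replicate", {
  # true shift 2.68 degC, sd of paired differences 1, n = 14 pairs
  hits <- withr::with_seed(99, {
    vapply(1:200, function(i) {
      diffs <- rnorm(14, -2.68, 1)
      d <- tibble::tibble(id = rep(1:14, 2),
                          grp = rep(c("nursery", "donor"), each = 14),
                          val = c(diffs, rep(0, 14)))
      compare_paired(d, "val", "grp", "id")$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Tukey-Kramer HSD behaves at the extremes and under relabeling", {
  withr::with_seed(3, {
    base <- rnorm(10)
    same <- tibble::tibble(val = rep(base, 4),
                           grp = rep(c("g1", "g2", "g3", "g4"), each = 10))
  })
  res <- compare_sites_tukey(same, "val", "grp")
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_value > 0.999))

  sep <- withr::with_seed(4, tibble::tibble(
    val = c(rnorm(10), rnorm(10) + 10), # 10 pooled-sd units apart
    grp = rep(c("low", "high"), each = 10)))
  expect_lt(compare_sites_tukey(sep, "val", "grp")$p_value, 0.001)

  # relabeling permutes rows but not p-values
  shuffled <- dplyr::mutate(same, grp = dplyr::recode(grp, g1 = "z9",
                                                      g2 = "a0"))
  res2 <- compare_sites_tukey(shuffled, "val", "grp")
  expect_equal(sort(res2$p_value), sort(res$p_value))

  # adjusted p >= unadjusted pairwise p (studentized range vs t)
  rnd <- withr::with_seed(5, tibble::tibble(
    val = rnorm(24), grp = rep(c("a", "b", "c"), each = 8)))
  tk <- compare_sites_tukey(rnd, "val", "grp")
  unadj <- 2 * pt(abs(tk$statistic) / sqrt(2), tk$df, lower.tail = FALSE)
  expect_true(all(tk$p_value >= unadj - 1e-12))

  small <- tibble::tibble(val = c(1, 2, 3, 4, 5), grp = c("a", "a", "b", "b", "c"))
  expect_warning(compare_sites_tukey(small, "val", "grp"), "n < 2")
})

make_lme_data <- function(seed, cond_effect = 0, site_sd = 0, time_sd = 0,
                          n_col = 3, noise = 0.05) {
  withr::with_seed(seed, {
    d <- tidyr::expand_grid(tank_temperature_c = c(31, 35, 37, 40),
                            condition = c("donor", "nursery"),
                            site = c("Site 1", "Site 2"),
                            timepoint = c("T1", "T2"),
                            colony = seq_len(n_col))
    site_eff <- setNames(rnorm(2, 0, site_sd), c("Site 1", "Site 2"))
    time_eff <- setNames(rnorm(2, 0, time_sd), c("T1", "T2"))
    d |>
      dplyr::mutate(
        fvfm = pmin(1, pmax(0, ll3_predict(tank_temperature_c, 40, 0.6, 37) +
                              cond_effect * (condition == "nursery") +
                              site_eff[site] + time_eff[timepoint] +
                              rnorm(dplyr::n(), 0, noise))))
  })
}

test_that("condition LME reduces to OLS when random variances vanish", {
  d <- make_lme_data(6, cond_effect = -0.08)
  res <- fit_condition_lme(d)
  ols <- lm(fvfm ~ factor(tank_temperature_c) + condition, data = d)
  expect_equal(res$estimate, unname(coef(ols)["conditionnursery"]),
               tolerance = 1e-6)
  expect_true(res$singular)
  expect_equal(res$test_used, "lm-condition")
  expect_lt(res$p_value, 0.001)
})

test_that("condition LME recovers the sign of a nursery deficit", {
  # nursery colonies depressed, with real site/season variation
  d <- make_lme_data(7, cond_effect = -0.08, site_sd = 0.03, time_sd = 0.03,
                     n_col = 6)
  res <- fit_condition_lme(d)
  expect_lt(res$estimate, 0)
  expect_lt(res$p_value, 0.01)
})

test_that("condition LME keeps its size under the null", {
  ps <- vapply(1:300, function(i) {
    d <- make_lme_data(1000 + i, cond_effect = 0, site_sd = 0.02,
                       time_sd = 0.02)
    fit_condition_lme(d)$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.07)
})
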