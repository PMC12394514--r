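test_that("campaign generation is deterministic and schema-stable", {
  cfg <- sim_config()
  a <- simulate_campaign(cfg, seed = 7)
  b <- simulate_campaign(cfg, seed = 7)
  expect_identical(a, b)
  c <- simulate_campaign(cfg, seed = 8)
  expect_false(identical(a$measurements$fvfm, c$measurements$fvfm))
  expect_identical(names(a$measurements), names(c$measurements))

  # measurement invariants: one fragment per colony per tank per assay
  counts <- dplyr::count(a$measurements, colony_id, condition, timepoint,
                         tank_temperature_c)
  expect_true(all(counts$n == 1))
  expect_true(all(a$measurements$fvfm >= 0 & a$measurements$fvfm <= 1))
  expect_true(all(a$measurements$tank_temperature_c > 0))
})

test_that("degenerate variance puts every donor exactly at the group mean", {
  cfg <- one_group_config(n = 6, between_colony_sd = 0)
  col <- generate_colonies(cfg, seed = 1)
  donors <- dplyr::filter(col, condition == "donor")
  expect_true(all(donors$true_ed50 == 38.22))
})

test_that("donor-nursery latent correlation matches its target at large n", {
  cfg <- one_group_config(n = 1000, donor_nursery_correlation = 0.8)
  col <- generate_colonies(cfg, seed = 21)
  wide <- col |>
    dplyr::filter(timepoint == "T1") |>
    tidyr::pivot_wider(id_cols = colony_id, names_from = condition,
                       values_from = true_ed50)
  expect_lt(abs(cor(wide$donor, wide$nursery) - 0.8), 0.05)
})

test_that("default group means carry the printed deficit structure", {
  cfg <- sim_config()
  gm <- cfg$group_means
  pick <- function(sp, st, cond, tp) {
    gm$mean_ed50[gm$species == sp & gm$site == st & gm$condition == cond &
                   gm$timepoint == tp]
  }
  expect_equal(pick("A. cytherea", "Site 1", "nursery", "T1"), 35.54)
  expect_equal(relative_ed50(pick("A. cytherea", "Site 1", "nursery", "T1"),
                             cfg$mmm), 5.02)
  # transient deficit: nursery means rejoin donor means at T2
  expect_equal(pick("A. cytherea", "Site 1", "nursery", "T2"),
               pick("A. cytherea", "Site 1", "donor", "T2"))
  # large-n latent means land on the configured group means
  big <- sim_config(design = dplyr::mutate(default_design(),
                                           n_colonies = 800L))
  col <- generate_colonies(big, seed = 3)
  mu <- col |>
    dplyr::group_by(species, site, condition, timepoint) |>
    dplyr::summarise(m = mean(true_ed50), .groups = "drop") |>
    dplyr::left_join(gm, by = c("species", "site", "condition", "timepoint"))
  expect_true(all(abs(mu$m - mu$mean_ed50) < 3 * 1.9 / sqrt(800)))
})

test_that("zero-noise measurements lie exactly on the latent curve", {
  cfg <- one_group_config(n = 4, noise_sd_fvfm = 0)
  col <- generate_colonies(cfg, seed = 2)
  m <- simulate_cbass(col, cfg, seed = 2)
  truth <- dplyr::filter(col, timepoint == "T1")
  joined <- dplyr::inner_join(m, truth,
                              by = c("colony_id", "condition", "species",
                                     "site", "timepoint"))
  expect_equal(joined$fvfm,
               ll3_predict(joined$tank_temperature_c, joined$true_hill,
                           joined$true_fmax, joined$true_ed50),
               tolerance = 1e-12)
  expect_error(simulate_cbass(col, cfg, timepoint = "T9"),
               class = "coralscreen_data_error")
})

test_that("baseline-tank Fv/Fm approaches the mean latent fmax", {
  cfg <- one_group_config(n = 600, noise_sd_fvfm = 0.05)
  col <- generate_colonies(cfg, seed = 12)
  m <- simulate_cbass(col, cfg, seed = 12)
  base <- dplyr::filter(m, tank_temperature_c == 31)
  # LL.3 at 31 degC sits ~0.99 fmax for ed50 ~ 38; noise is mean-zero
  expect_equal(mean(base$fvfm),
               mean(dplyr::filter(col, timepoint == "T1")$true_fmax),
               tolerance = 0.01)
})

test_that("growth generator hits its trade-off and size targets", {
  # perfect anti-correlation, within one species x site group
  cfg1 <- one_group_config(n = 30, tradeoff_r = -1)
  col1 <- generate_colonies(cfg1, seed = 4)
  g1 <- growth_rates(simulate_growth(col1, cfg1, seed = 4))
  ed1 <- dplyr::filter(col1, condition == "nursery", timepoint == "T1")
  j1 <- dplyr::inner_join(g1, ed1, by = c("colony_id", "species", "site"))
  expect_equal(cor(j1$sgr, j1$true_ed50), -1, tolerance = 1e-9)

  # independence at large n
  cfg0 <- one_group_config(n = 1000, tradeoff_r = 0)
  col0 <- generate_colonies(cfg0, seed = 5)
  g0 <- growth_rates(simulate_growth(col0, cfg0, seed = 5))
  j0 <- dplyr::inner_join(g0,
                          dplyr::filter(col0, condition == "nursery",
                                        timepoint == "T1"),
                          by = c("colony_id", "species", "site"))
  expect_lt(abs(cor(j0$sgr, j0$true_ed50)), 0.07)

  # a configured target is recovered within +/- 0.05 at n = 1000
  cfg37 <- one_group_config(n = 1000, tradeoff_r = -0.37)
  col37 <- generate_colonies(cfg37, seed = 6)
  g37 <- growth_rates(simulate_growth(col37, cfg37, seed = 6))
  j37 <- dplyr::inner_join(g37,
                           dplyr::filter(col37, condition == "nursery",
                                         timepoint == "T1"),
                           by = c("colony_id", "species", "site"))
  expect_lt(abs(cor(j37$sgr, j37$true_ed50) - (-0.37)), 0.05)

  # initial sizes: species means near their configured values (default design)
  g <- growth_rates(simulate_growth(generate_colonies(sim_config(), seed = 9),
                                    sim_config(), seed = 9))
  cyt <- dplyr::filter(g, species == "A. cytherea")
  expect_equal(mean(cyt$gmr0), 2.77, tolerance = 3 * 0.65 / sqrt(nrow(cyt)))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(fmax_range = c(0.2, 0.6)),
               class = "coralscreen_config_error")
  expect_error(sim_config(hill_range = c(10, 120)),
               class = "coralscreen_config_error")
  expect_error(sim_config(donor_nursery_correlation = 1.2),
               class = "coralscreen_config_error")
  expect_error(sim_config(between_colony_sd = -0.1),
               class = "coralscreen_config_error")
  expect_error(sim_config(noise_sd_fvfm = NA),
               class = "coralscreen_config_error")
  expect_error(sim_config(treatment_temps = numeric()),
               class = "coralscreen_config_error")
  expect_error(sim_config(tradeoff_r = -2),
               class = "coralscreen_config_error")
})

test_that("fitting simulated data recovers the generating group means", {
  cfg <- sim_config()
  camp <- simulate_campaign(cfg, seed = 31)
  fits <- fit_ed50s(dplyr::filter(camp$measurements, timepoint == "T1"),
                    scope = "colony")
  rec <- fits |>
    dplyr::group_by(species, site, condition) |>
    dplyr::summarise(m = mean(ed50), sem = sd(ed50) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::left_join(dplyr::filter(cfg$group_means, timepoint == "T1"),
                     by = c("species", "site", "condition"))
  # generating mean within 2 SEM of the fitted mean for every group (n >= 12)
  expect_true(all(abs(rec$m - rec$mean_ed50) <= 2 * rec$sem))
})
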