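test_that("ll3_predict matches the closed form and its limits", {
  # half-maximum definition holds for any slope
  for (hill in c(12, 20, 55, 95)) {
    expect_equal(ll3_predict(36, hill, 0.6, 36), 0.3)
  }
  # lower-asymptote limit
  expect_equal(ll3_predict(1e-9, 20, 0.64, 36), 0.64, tolerance = 1e-6)
  # direct evaluation of the closed form (independent arithmetic)
  expect_equal(ll3_predict(40, 20, 0.6, 36), 0.6 / (1 + (40 / 36)^20))
  expect_equal(round(ll3_predict(40, 20, 0.6, 36), 4), 0.0650)
  expect_error(ll3_predict(-1, 20, 0.6, 36), class = "coralscreen_domain_error")
  expect_error(ll3_predict(0, 20, 0.6, 36), class = "coralscreen_domain_error")
})

test_that("ll3_predict is monotone decreasing in T and increasing in ed50", {
  # parameter/temperature ranges kept clear of double-precision saturation of
  # the logistic tail (where the curve is numerically == fmax)
  withr::with_seed(11, {
    for (i in 1:25) {
      hill <- runif(1, 10, 60)
      fmax <- runif(1, 0.3, 0.8)
      ed50 <- runif(1, 31, 42)
      temps <- sort(runif(8, 30, 45))
      y <- ll3_predict(temps, hill, fmax, ed50)
      expect_true(all(diff(y) < 0))
      expect_true(all(y > 0 & y < fmax))
      e2 <- ed50 + runif(1, 0.1, 3)
      expect_true(all(ll3_predict(temps, hill, fmax, e2) > y))
    }
  })
})

test_that("fit_ll3 recovers noise-free parameters and respects bounds", {
  truth <- list(c(40, 0.6, 36), c(18, 0.45, 33.5), c(55, 0.72, 38.5))
  for (p in truth) {
    d <- make_ll3_data(p[1], p[2], p[3])
    fit <- fit_ll3(d)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$params - c(hill = p[1], fmax = p[2], ed50 = p[3]))),
              1e-4)
    expect_false(any(fit$at_bound))
  }
  # unconstrained optimum below the ed50 floor is clamped to 30 and flagged
  d_low <- make_ll3_data(40, 0.6, 28, temps = c(26, 29, 32, 35))
  fit_low <- fit_ll3(d_low)
  expect_equal(unname(fit_low$params["ed50"]), 30, tolerance = 1e-6)
  expect_true(fit_low$at_bound[["ed50"]])
  expect_true(fit_low$converged)
})

test_that("fit_ll3 rejects unusable inputs", {
  d3 <- tibble::tibble(temperature = c(31, 35, 37), fvfm = c(0.6, 0.5, 0.2))
  expect_error(fit_ll3(d3), class = "coralscreen_insufficient_data")
  d_2temps <- tibble::tibble(temperature = c(31, 31, 40, 40),
                             fvfm = c(0.6, 0.61, 0.1, 0.12))
  expect_error(fit_ll3(d_2temps), class = "coralscreen_insufficient_data")
  d_zero <- tibble::tibble(temperature = c(31, 35, 37, 40), fvfm = rep(0, 4))
  expect_error(fit_ll3(d_zero), class = "coralscreen_degenerate_fit")
  d_bad <- tibble::tibble(temperature = c(31, 35, 37, 40),
                          fvfm = c(0.5, 0.4, 1.2, 0.1))
  expect_error(fit_ll3(d_bad), class = "coralscreen_domain_error")
})

test_that("fit_ll3 is never beaten by a brute-force parameter grid", {
  withr::with_seed(202, {
    for (i in 1:10) {
      p <- c(runif(1, 12, 90), runif(1, 0.35, 0.75), runif(1, 31, 41))
      d <- make_ll3_data(p[1], p[2], p[3], noise_sd = 0.05)
      fit <- fit_ll3(d)
      oracle <- grid_min_sse(d$temperature, d$fvfm, n = 40)
      expect_lte(fit$sse, oracle + 1e-9)
    }
  })
})

test_that("fit_ll3 is scale-consistent in the response", {
  d <- make_ll3_data(35, 0.75, 36.5, noise_sd = 0.02, seed = 5)
  fit1 <- fit_ll3(d)
  for (c_scale in c(0.9, 0.7)) {
    d2 <- dplyr::mutate(d, fvfm = fvfm * c_scale)
    fit2 <- fit_ll3(d2)
    expect_equal(unname(fit2$params["fmax"]),
                 unname(fit1$params["fmax"]) * c_scale, tolerance = 0.02)
    expect_equal(unname(fit2$params["ed50"]), unname(fit1$params["ed50"]),
                 tolerance = 0.05)
  }
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- fit_ll3(make_ll3_data(40, 0.6, 36))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("hill", "fmax", "ed50"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$n_points, 4L)
})

test_that("bootstrap ED50 uncertainty behaves like a sampling SE", {
  d0 <- make_ll3_data(40, 0.6, 36)
  f0 <- ed50_uncertainty(fit_ll3(d0), n_boot = 100, seed = 3)
  expect_lt(f0$ed50_se, 1e-3) # noise-free: ~zero spread

  # CI width shrinks monotonically as measurement noise falls
  widths <- vapply(c(0.10, 0.05, 0.01), function(ns) {
    d <- purrr::map(1:4, function(r) { # 4 fragments per temp for stability
      make_ll3_data(40, 0.6, 36, noise_sd = ns, seed = 100 + r)
    }) |> purrr::list_rbind()
    f <- ed50_uncertainty(fit_ll3(d), n_boot = 150, seed = 9)
    diff(f$ed50_ci95)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # pooling 14 colonies x 4 temperatures beats a single colony at equal noise
  # (identical latent curves isolate the replication benefit)
  cfg <- one_group_config(n = 14, noise_sd_fvfm = 0.05,
                          between_colony_sd = 0,
                          fmax_range = c(0.6, 0.6), hill_range = c(40, 40))
  m <- simulate_cbass(generate_colonies(cfg, seed = 8), cfg, seed = 8) |>
    dplyr::filter(condition == "donor")
  pop <- fit_ll3(tibble::tibble(temperature = m$tank_temperature_c,
                                fvfm = m$fvfm), scope = "population")
  pop <- ed50_uncertainty(pop, n_boot = 150, seed = 10)
  one <- m |> dplyr::filter(colony_id == colony_id[1])
  single <- ed50_uncertainty(
    fit_ll3(tibble::tibble(temperature = one$tank_temperature_c,
                           fvfm = one$fvfm)), n_boot = 150, seed = 10)
  expect_lt(pop$ed50_se, single$ed50_se)
  expect_error(ed50_uncertainty(fit_ll3(d0), n_boot = 20),
               class = "coralscreen_config_error")
})
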