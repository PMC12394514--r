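# Independent oracles and small data builders shared across tests.

# Brute-force LL.3 oracle: minimum SSE over an n^3 grid spanning the bounds
# (vectorized; independent of the package's optimizer).
grid_min_sse <- function(temperature, fvfm, n = 50,
                         hill_range = c(10, 100), fmax_range = c(0.3, 0.8),
                         ed50_range = c(30, 45)) {
  hills <- seq(hill_range[1], hill_range[2], length.out = n)
  fmaxs <- seq(fmax_range[1], fmax_range[2], length.out = n)
  ed50s <- seq(ed50_range[1], ed50_range[2], length.out = n)
  grid <- expand.grid(hill = hills, fmax = fmaxs, ed50 = ed50s)
  best <- Inf
  # chunk to keep memory modest: pred matrix is nrow(chunk) x length(temps)
  idx <- split(seq_len(nrow(grid)), ceiling(seq_len(nrow(grid)) / 25000))
  for (i in idx) {
    g <- grid[i, ]
    pred <- outer(g$hill, log(temperature)) -
      g$hill * log(g$ed50) # hill * (log T - log ed50)
    pred <- g$fmax / (1 + exp(pred))
    sse <- rowSums((pred - matrix(fvfm, nrow(g), length(fvfm),
                                  byrow = TRUE))^2)
    best <- min(best, min(sse))
  }
  best
}

# Set-intersection oracle for cohort misassignment: average count of colonies
# in each of a's top-k/bottom-k cohorts missing from b's.
brute_misassignment <- function(ids, ed50_a, ed50_b, k) {
  ord_a <- ids[order(-ed50_a, ids)]
  ord_b <- ids[order(-ed50_b, ids)]
  top_a <- ord_a[1:k]
  top_b <- ord_b[1:k]
  bot_a <- rev(ord_a)[1:k]
  bot_b <- rev(ord_b)[1:k]
  ((k - length(intersect(top_a, top_b))) +
      (k - length(intersect(bot_a, bot_b)))) / 2
}

# Noise-free or noisy LL.3 measurements at the standard four tank temperatures.
make_ll3_data <- function(hill, fmax, ed50, temps = c(31, 35, 37, 40),
                          noise_sd = 0, seed = NULL) {
  f <- function() {
    y <- ll3_predict(temps, hill, fmax, ed50)
    if (noise_sd > 0) y <- pmin(1, pmax(0, y + rnorm(length(temps), 0, noise_sd)))
    tibble::tibble(temperature = temps, fvfm = y)
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# A single-group config (one species, one site) for focused generator tests.
one_group_config <- function(n = 14, mean_donor_t1 = 38.22, ...,
                             between_colony_sd = 1.9) {
  sim_config(
    design = tibble::tibble(species = "A. test", site = "Site 1",
                            n_colonies = as.integer(n)),
    group_means = tidyr::expand_grid(species = "A. test", site = "Site 1",
                                     condition = c("donor", "nursery"),
                                     timepoint = c("T1", "T2")) |>
      dplyr::mutate(mean_ed50 = mean_donor_t1),
    growth_means = tibble::tibble(species = "A. test", site = "Site 1",
                                  mean_sgr = 0.21, mean_gmr0 = 2.77,
                                  sd_gmr0 = 0.65),
    between_colony_sd = between_colony_sd,
    ...)
}
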