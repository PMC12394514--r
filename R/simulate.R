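# Synthetic CBASS campaign generator.
#
# The generator states a world with the structure the downstream analysis
# assumes: paired donor/nursery colonies of two Acropora species at two sites,
# latent colony-level ED50s drawn around species x site x condition x
# timepoint group means, LL.3-shaped Fv/Fm responses at four treatment
# temperatures with additive measurement noise, a transient nursery deficit at
# the first assay season only, and nursery growth rates with a configurable
# correlation to thermal tolerance.

default_group_means <- function() {
  tibble::tribble(
    ~species,       ~site,    ~condition, ~timepoint, ~mean_ed50,
    "A. cytherea",  "Site 1", "donor",    "T1",       38.22,
    "A. cytherea",  "Site 2", "donor",    "T1",       37.79,
    "A. cytherea",  "Site 1", "donor",    "T2",       38.75,
    "A. cytherea",  "Site 2", "donor",    "T2",       38.07,
    "A. cytherea",  "Site 1", "nursery",  "T1",       35.54,
    "A. cytherea",  "Site 2", "nursery",  "T1",       36.18,
    "A. cytherea",  "Site 1", "nursery",  "T2",       38.75,
    "A. cytherea",  "Site 2", "nursery",  "T2",       38.07,
    "A. florida",   "Site 1", "donor",    "T1",       39.55,
    "A. florida",   "Site 2", "donor",    "T1",       39.28,
    "A. florida",   "Site 1", "donor",    "T2",       39.55,
    "A. florida",   "Site 2", "donor",    "T2",       39.28,
    "A. florida",   "Site 1", "nursery",  "T1",       39.55,
    "A. florida",   "Site 2", "nursery",  "T1",       39.28,
    "A. florida",   "Site 1", "nursery",  "T2",       39.55,
    "A. florida",   "Site 2", "nursery",  "T2",       39.28)
}

default_design <- function() {
  tibble::tribble(
    ~species,      ~site,    ~n_colonies,
    "A. cytherea", "Site 1", 14L,
    "A. cytherea", "Site 2", 13L,
    "A. florida",  "Site 1", 12L,
    "A. florida",  "Site 2", 12L)
}

default_growth_means <- function() {
  tibble::tribble(
    ~species,      ~site,    ~mean_sgr, ~mean_gmr0, ~sd_gmr0,
    "A. cytherea", "Site 1", 0.21,      2.77,       0.65,
    "A. cytherea", "Site 2", 0.28,      2.77,       0.65,
    "A. florida",  "Site 1", 0.07,      3.39,       0.80,
    "A. florida",  "Site 2", 0.18,      3.39,       0.80)
}

#' Configuration for a synthetic CBASS screening campaign
#'
#' All defaults state the study design of a two-species, two-site, two-season
#' paired donor/nursery campaign: group mean ED50s at their published values
#' (the nursery deficit at the first season is carried by the nursery T1
#' means), a between-colony ED50 standard deviation of 1.9 degC and a
#' donor-nursery latent correlation of 0.25 (both implied by the published
#' group SEMs and paired-test p-values), Fv/Fm noise of 0.05, and measured
#' hold temperatures of 31, 35, 37 and 40 degC.
#'
#' @param seed default root seed for campaign generation.
#' @param design tibble (`species`, `site`, `n_colonies`) giving the number of
#'   paired colonies per species x site.
#' @param group_means tibble (`species`, `site`, `condition`, `timepoint`,
#'   `mean_ed50`) of latent group mean ED50s (degC). A missing nursery-T1 row
#'   falls back to the donor mean plus `nursery_offset_t1`.
#' @param between_colony_sd SD of latent colony ED50s around their group mean
#'   (degC, >= 0).
#' @param donor_nursery_correlation latent correlation between a donor genet's
#'   ED50 and its nursery propagule's, in \[-1, 1\].
#' @param nursery_offset_t1 additional transient shift (degC) applied to
#'   nursery latent ED50s at timepoint T1 (default 0: the default
#'   `group_means` already encode the deficit).
#' @param noise_sd_fvfm SD of additive measurement noise on Fv/Fm (>= 0).
#' @param fmax_range,hill_range uniform ranges for colony-level curve
#'   constants; must lie within the fitting bounds (\[0.3, 0.8\] and
#'   \[10, 100\]).
#' @param treatment_temps measured hold-phase temperatures (degC) of the four
#'   treatment tanks.
#' @param timepoints assay season labels.
#' @param growth_means tibble (`species`, `site`, `mean_sgr`, `mean_gmr0`,
#'   `sd_gmr0`): mean specific growth rate (%/day) and initial geometric mean
#'   radius (cm) per group.
#' @param sgr_sd between-colony SD of SGR (%/day).
#' @param growth_days days between the two size measurements.
#' @param tradeoff_r target Pearson correlation between nursery SGR and the
#'   colony's latent nursery T1 ED50, in \[-1, 1\] (default 0: no trade-off).
#' @param mmm maximum monthly mean climatology (degC), used for relative
#'   thresholds downstream.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$treatment_temps
sim_config <- function(seed = 1,
                       design = default_design(),
                       group_means = default_group_means(),
                       between_colony_sd = 1.9,
                       donor_nursery_correlation = 0.25,
                       nursery_offset_t1 = 0,
                       noise_sd_fvfm = 0.05,
                       fmax_range = c(0.50, 0.65),
                       hill_range = c(25, 60),
                       treatment_temps = c(31, 35, 37, 40),
                       timepoints = c("T1", "T2"),
                       growth_means = default_growth_means(),
                       sgr_sd = 0.08,
                       growth_days = 176,
                       tradeoff_r = 0,
                       mmm = 30.52) {
  cfg <- list(seed = as.integer(seed), design = tibble::as_tibble(design),
              group_means = tibble::as_tibble(group_means),
              between_colony_sd = between_colony_sd,
              donor_nursery_correlation = donor_nursery_correlation,
              nursery_offset_t1 = nursery_offset_t1,
              noise_sd_fvfm = noise_sd_fvfm,
              fmax_range = fmax_range, hill_range = hill_range,
              treatment_temps = treatment_temps, timepoints = timepoints,
              growth_means = tibble::as_tibble(growth_means),
              sgr_sd = sgr_sd, growth_days = growth_days,
              tradeoff_r = tradeoff_r, mmm = mmm)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_columns(cfg$design, c("species", "site", "n_colonies"), "design")
  check_columns(cfg$group_means,
                c("species", "site", "condition", "timepoint", "mean_ed50"),
                "group_means")
  check_number(cfg$design$n_colonies, "n_colonies", min = 1)
  check_number(cfg$group_means$mean_ed50, "mean_ed50",
               min = .Machine$double.eps)
  check_number(cfg$between_colony_sd, "between_colony_sd", min = 0)
  check_number(cfg$donor_nursery_correlation, "donor_nursery_correlation",
               min = -1, max = 1)
  check_number(cfg$nursery_offset_t1, "nursery_offset_t1")
  check_number(cfg$noise_sd_fvfm, "noise_sd_fvfm", min = 0)
  check_number(cfg$fmax_range, "fmax_range", min = 0.3, max = 0.8)
  check_number(cfg$hill_range, "hill_range", min = 10, max = 100)
  if (cfg$fmax_range[1] > cfg$fmax_range[2] ||
      cfg$hill_range[1] > cfg$hill_range[2]) {
    abort("fmax_range and hill_range must be increasing intervals.",
          class = "coralscreen_config_error")
  }
  if (!length(cfg$treatment_temps)) {
    abort("`treatment_temps` must be non-empty.",
          class = "coralscreen_config_error")
  }
  check_number(cfg$treatment_temps, "treatment_temps",
               min = .Machine$double.eps)
  check_number(cfg$sgr_sd, "sgr_sd", min = 0)
  check_number(cfg$growth_days, "growth_days", min = 1)
  check_number(cfg$tradeoff_r, "tradeoff_r", min = -1, max = 1)
  check_number(cfg$mmm, "mmm", min = .Machine$double.eps)
  invisible(cfg)
}

group_mean_lookup <- function(cfg, species, site, condition, timepoint) {
  gm <- cfg$group_means
  hit <- gm$mean_ed50[gm$species == species & gm$site == site &
                        gm$condition == condition & gm$timepoint == timepoint]
  if (length(hit) == 1) return(hit)
  if (condition == "nursery") {
    donor <- group_mean_lookup(cfg, species, site, "donor", timepoint)
    offset <- if (timepoint == cfg$timepoints[1]) {
      off <- cfg$nursery_offset_t1
      if (!is.null(names(off)) && species %in% names(off)) off[[species]]
      else off[[1]]
    } else 0
    return(donor + offset)
  }
  abort(sprintf("No group mean for %s / %s / %s / %s.",
                species, site, condition, timepoint),
        class = "coralscreen_config_error")
}

#' Generate paired donor/nursery colonies with latent curve parameters
#'
#' For each species x site group, donor latent ED50s are drawn
#' Normal(group mean, `between_colony_sd`); the nursery propagule of each
#' genet is its bivariate-normal partner at correlation
#' `donor_nursery_correlation`, centred on the nursery group mean (which
#' carries any transient first-season deficit). The colony-level z-scores are
#' shared across timepoints (a genet effect), so season-to-season changes in
#' latent tolerance come from the group means; assay-to-assay scatter comes
#' from measurement noise. Curve shape constants `fmax` and `hill` are drawn
#' once per colony and shared across conditions and seasons.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`); output is deterministic
#'   given it.
#' @return A "colony truth" tibble: one row per colony x condition x
#'   timepoint with columns `colony_id`, `species`, `site`, `condition`,
#'   `timepoint`, `true_ed50`, `true_fmax`, `true_hill`.
#' @export
#' @examples
#' col <- generate_colonies(sim_config(), seed = 7)
#' dplyr::count(col, species, site, condition, timepoint)
generate_colonies <- function(config, seed = config$seed) {
  validate_sim_config(config)
  rho <- config$donor_nursery_correlation
  sdc <- config$between_colony_sd
  withr::with_seed(derive_seed(seed, "colonies"), {
    purrr::pmap(config$design, function(species, site, n_colonies) {
      z_d <- rnorm(n_colonies)
      z_x <- rnorm(n_colonies)
      z_n <- rho * z_d + sqrt(1 - rho^2) * z_x
      fmax <- runif(n_colonies, config$fmax_range[1], config$fmax_range[2])
      hill <- runif(n_colonies, config$hill_range[1], config$hill_range[2])
      ids <- sprintf("%s_%s_%02d", gsub("[^A-Za-z]", "", species),
                     gsub(" ", "", site), seq_len(n_colonies))
      sp <- species
      st <- site
      tidyr::expand_grid(idx = seq_len(n_colonies),
                         condition = c("donor", "nursery"),
                         timepoint = config$timepoints) |>
        dplyr::mutate(
          colony_id = ids[.data$idx],
          species = sp, site = st,
          true_ed50 = purrr::pmap_dbl(
            list(.data$condition, .data$timepoint, .data$idx),
            function(cond, tp, i) {
              mu <- group_mean_lookup(config, sp, st, cond, tp)
              z <- if (cond == "donor") z_d[i] else z_n[i]
              mu + sdc * z
            }),
          true_fmax = fmax[.data$idx],
          true_hill = hill[.data$idx]) |>
        dplyr::select("colony_id", "species", "site", "condition",
                      "timepoint", "true_ed50", "true_fmax", "true_hill")
    }) |>
      purrr::list_rbind()
  })
}

#' Simulate one season of CBASS Fv/Fm measurements
#'
#' Each colony contributes exactly one fragment per treatment tank (no tank
#' replication): `fvfm = LL3(true params, temperature) + Normal(0,
#' noise_sd_fvfm)`, clipped to the physical \[0, 1\] range of a quantum-yield
#' ratio.
#'
#' @param colonies colony truth tibble from [generate_colonies()].
#' @param config a [sim_config()].
#' @param timepoint which assay season to simulate (default the first).
#' @param seed integer seed; deterministic given it.
#' @return A measurement tibble with columns `colony_id`, `species`, `site`,
#'   `condition`, `timepoint`, `tank_temperature_c`, `fvfm`.
#' @export
simulate_cbass <- function(colonies, config, timepoint = config$timepoints[1],
                           seed = config$seed) {
  validate_sim_config(config)
  check_columns(colonies, c("colony_id", "species", "site", "condition",
                            "timepoint", "true_ed50", "true_fmax",
                            "true_hill"), "colonies")
  latent <- dplyr::filter(colonies, .data$timepoint == !!timepoint)
  if (!nrow(latent)) {
    abort(sprintf("No colonies carry latent parameters for timepoint '%s'.",
                  timepoint),
          class = "coralscreen_data_error")
  }
  out <- tidyr::expand_grid(latent,
                            tank_temperature_c = config$treatment_temps)
  withr::with_seed(derive_seed(seed, paste0("cbass_", timepoint)), {
    out |>
      dplyr::mutate(
        fvfm = pmin(1, pmax(0, ll3_predict(.data$tank_temperature_c,
                                           .data$true_hill, .data$true_fmax,
                                           .data$true_ed50) +
                              rnorm(dplyr::n(), 0, config$noise_sd_fvfm)))) |>
      dplyr::select("colony_id", "species", "site", "condition", "timepoint",
                    "tank_temperature_c", "fvfm")
  })
}

#' Simulate nursery growth records
#'
#' Draws an initial geometric mean radius per nursery colony, a specific
#' growth rate whose correlation with the colony's latent first-season nursery
#' ED50 is exactly targeted at `tradeoff_r` (Gaussian construction on the
#' standardized latent value), and triaxial dimensions at both dates whose
#' shape varies but whose GMR reproduces the drawn sizes exactly.
#'
#' @inheritParams simulate_cbass
#' @return A growth tibble: `colony_id`, `species`, `site`, `date0`, `date1`,
#'   `length0`, `width0`, `height0`, `length1`, `width1`, `height1` (cm).
#' @export
simulate_growth <- function(colonies, config, seed = config$seed) {
  validate_sim_config(config)
  r <- config$tradeoff_r
  latent <- colonies |>
    dplyr::filter(.data$condition == "nursery",
                  .data$timepoint == config$timepoints[1])
  withr::with_seed(derive_seed(seed, "growth"), {
    latent |>
      dplyr::left_join(config$growth_means, by = c("species", "site")) |>
      dplyr::group_by(.data$species, .data$site) |>
      dplyr::mutate(
        z_ed50 = if (config$between_colony_sd > 0) {
          (.data$true_ed50 - mean(.data$true_ed50)) / config$between_colony_sd
        } else 0,
        sgr_true = .data$mean_sgr + config$sgr_sd *
          (r * .data$z_ed50 + sqrt(1 - r^2) * rnorm(dplyr::n())),
        gmr0 = pmax(0.3, rnorm(dplyr::n(), .data$mean_gmr0, .data$sd_gmr0)),
        gmr1 = .data$gmr0 * exp(.data$sgr_true * config$growth_days / 100),
        a = runif(dplyr::n(), 0.8, 1.25),
        b = runif(dplyr::n(), 0.8, 1.25)) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        date0 = as.Date("2022-03-29"),
        date1 = .data$date0 + config$growth_days,
        length0 = 2 * .data$gmr0 * .data$a,
        width0 = 2 * .data$gmr0 * .data$b,
        height0 = 2 * .data$gmr0 / (.data$a * .data$b),
        length1 = .data$length0 * .data$gmr1 / .data$gmr0,
        width1 = .data$width0 * .data$gmr1 / .data$gmr0,
        height1 = .data$height0 * .data$gmr1 / .data$gmr0) |>
      dplyr::select("colony_id", "species", "site", "date0", "date1",
                    "length0", "width0", "height0",
                    "length1", "width1", "height1")
  })
}

#' Simulate a complete two-season screening campaign
#'
#' Convenience wrapper: colonies, Fv/Fm measurements at every configured
#' timepoint, and nursery growth records, all from one root seed.
#'
#' @inheritParams generate_colonies
#' @return A list with `colonies` (truth table), `measurements` (all seasons,
#'   row-bound) and `growth`.
#' @export
#' @examples
#' camp <- simulate_campaign(sim_config(), seed = 1)
#' nrow(camp$measurements)
simulate_campaign <- function(config = sim_config(), seed = config$seed) {
  colonies <- generate_colonies(config, seed = seed)
  measurements <- purrr::map(config$timepoints, function(tp) {
    simulate_cbass(colonies, config, timepoint = tp, seed = seed)
  }) |> purrr::list_rbind()
  growth <- simulate_growth(colonies, config, seed = seed)
  list(colonies = colonies, measurements = measurements, growth = growth)
}
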