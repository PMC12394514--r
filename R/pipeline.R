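# Full analysis pipeline: fits -> relative thresholds -> retention/recovery
# comparisons -> reproducibility & screening curves -> growth trade-offs,
# with an optional on-disk report bundle.

group_label <- function(site, condition) {
  cap <- paste0(toupper(substr(condition, 1, 1)), substring(condition, 2))
  paste(site, "-", cap)
}

#' Run the complete screening analysis pipeline
#'
#' Chains every stage of the campaign analysis. If `measurements` is `NULL`, a
#' synthetic campaign is generated from `config` (so the pipeline is fully
#' testable without field data); otherwise validated field tables are used.
#'
#' Stages, per species: constrained LL.3 fits per colony and per population;
#' relative thermal thresholds; group summaries (mean +/- SEM); paired
#' nursery-vs-donor tests at each season (per site, and site-pooled for the
#' species headline) and donor season-vs-season tests; Tukey HSD across the
#' four site x condition groups of each season; a condition linear mixed
#' model; colony-level ED50 reproducibility across seasons; donor-vs-nursery
#' screening curves per season; and growth rates with trade-off correlations
#' and growth-group comparisons.
#'
#' The report's headline booleans are `deficit_at_t1` (site-pooled paired test
#' significant with nursery below donor at the first season) and
#' `no_difference_at_t2` (site-pooled test non-significant at the second
#' season) for each species.
#'
#' @param config a [sim_config()]; also supplies MMM and the significance
#'   level context for synthetic runs.
#' @param seed root seed; every randomized stage derives its own stream from
#'   it, so reruns are byte-identical.
#' @param measurements optional measurement tibble (see
#'   [read_measurements()]); default: simulated.
#' @param growth optional wide growth records (see [read_growth()]); default:
#'   simulated alongside `measurements`.
#' @param alpha significance level for all tests.
#' @param k cohort size for screening curves.
#' @param n_iterations Monte-Carlo subsamples per screening size.
#' @param out_dir if non-`NULL`, the report bundle (CSVs + `report.json`) is
#'   written there.
#' @return A list of class `cbass_report`: `fits_colony`, `fits_population`,
#'   `summaries`, `comparisons`, `lme`, `reproducibility`, `screening`,
#'   `growth`, `tradeoffs`, `growth_groups`, `headline`, `seed`,
#'   `config_hash`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(sim_config(), seed = 1)
#' rep$headline
#' }
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         measurements = NULL, growth = NULL,
                         alpha = 0.05, k = 5, n_iterations = 1000,
                         out_dir = NULL) {
  validate_sim_config(config)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(measurements)) {
      camp <- simulate_campaign(config, seed = seed)
      measurements <- camp$measurements
      growth <- growth %||% camp$growth
      colonies <- camp$colonies
    } else {
      colonies <- NULL
    }
    tps <- sort(unique(measurements$timepoint))

    stage <- "fit"
    fits_colony <- fit_ed50s(measurements, scope = "colony") |>
      dplyr::mutate(relative_ed50 = relative_ed50(.data$ed50, config$mmm))
    fits_population <- fit_ed50s(measurements, scope = "population") |>
      dplyr::mutate(relative_ed50 = relative_ed50(.data$ed50, config$mmm))

    stage <- "summaries"
    summaries <- summarize_groups(fits_colony, mmm = config$mmm)

    stage <- "comparisons"
    species_list <- sort(unique(fits_colony$species))
    comparisons <- list()
    for (sp in species_list) {
      sp_fits <- dplyr::filter(fits_colony, .data$species == sp)
      for (tp in tps) {
        tp_fits <- dplyr::filter(sp_fits, .data$timepoint == tp)
        # site-pooled species headline test (nursery - donor)
        comparisons <- c(comparisons, list(
          compare_paired(tp_fits, "relative_ed50", "condition", "colony_id",
                         group_levels = c("nursery", "donor"),
                         alpha = alpha) |>
            dplyr::mutate(species = sp, site = "pooled", timepoint = tp,
                          contrast = "nursery-vs-donor")))
        for (st in sort(unique(tp_fits$site))) {
          comparisons <- c(comparisons, list(
            compare_paired(dplyr::filter(tp_fits, .data$site == st),
                           "relative_ed50", "condition", "colony_id",
                           group_levels = c("nursery", "donor"),
                           alpha = alpha) |>
              dplyr::mutate(species = sp, site = st, timepoint = tp,
                            contrast = "nursery-vs-donor")))
        }
      }
      # seasons compared within each site-condition group (complete pairs)
      if (length(tps) == 2) {
        for (st in sort(unique(sp_fits$site))) {
          for (cond in c("donor", "nursery")) {
            grp <- dplyr::filter(sp_fits, .data$site == st,
                                 .data$condition == cond)
            comparisons <- c(comparisons, list(
              compare_paired(grp, "relative_ed50", "timepoint", "colony_id",
                             group_levels = tps, alpha = alpha) |>
                dplyr::mutate(species = sp, site = st, timepoint = "both",
                              contrast = paste0(cond, "-across-seasons"))))
          }
        }
      }
      # Tukey HSD across the four site x condition groups, per season
      for (tp in tps) {
        tuk <- dplyr::filter(sp_fits, .data$timepoint == tp) |>
          dplyr::mutate(grp = group_label(.data$site, .data$condition))
        comparisons <- c(comparisons, list(
          compare_sites_tukey(tuk, "relative_ed50", "grp") |>
            dplyr::mutate(species = sp, site = "all", timepoint = tp,
                          contrast = "site-condition-tukey",
                          degenerate = FALSE)))
      }
    }
    comparisons <- purrr::list_rbind(comparisons)

    stage <- "lme"
    lme <- purrr::map(species_list, function(sp) {
      fit_condition_lme(dplyr::filter(measurements, .data$species == sp),
                        alpha = alpha) |>
        dplyr::mutate(species = sp, .before = 1)
    }) |> purrr::list_rbind()

    stage <- "reproducibility"
    reproducibility <- NULL
    screening <- NULL
    if (length(tps) == 2) {
      reproducibility <- fits_colony |>
        dplyr::select("colony_id", "species", "condition", "timepoint",
                      "ed50") |>
        tidyr::pivot_wider(names_from = "timepoint", values_from = "ed50") |>
        dplyr::rename(ed50_a = dplyr::all_of(tps[1]),
                      ed50_b = dplyr::all_of(tps[2])) |>
        dplyr::filter(is.finite(.data$ed50_a), is.finite(.data$ed50_b)) |>
        dplyr::group_by(.data$species, .data$condition) |>
        dplyr::group_modify(function(d, key) {
          r <- ed50_reproducibility(d)
          tibble::tibble(n = r$n, fraction = r$fraction)
        }) |>
        dplyr::ungroup()
    }

    stage <- "screening"
    screening <- purrr::map(species_list, function(sp) {
      purrr::map(tps, function(tp) {
        paired <- fits_colony |>
          dplyr::filter(.data$species == sp, .data$timepoint == tp) |>
          dplyr::select("colony_id", "condition", "ed50") |>
          tidyr::pivot_wider(names_from = "condition", values_from = "ed50") |>
          dplyr::filter(is.finite(.data$donor), is.finite(.data$nursery)) |>
          dplyr::rename(ed50_a = "donor", ed50_b = "nursery")
        screening_curve(paired, k = k, n_iterations = n_iterations,
                        seed = derive_seed(seed, paste("screen", sp, tp))) |>
          dplyr::mutate(species = sp, timepoint = tp)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()

    stage <- "growth"
    tradeoffs <- NULL
    growth_groups <- NULL
    growth_out <- NULL
    if (!is.null(growth)) {
      growth_out <- growth_rates(growth)
      nursery_t1 <- dplyr::filter(fits_colony, .data$condition == "nursery",
                                  .data$timepoint == tps[1])
      tradeoffs <- growth_out |>
        dplyr::group_by(.data$species, .data$site) |>
        dplyr::group_modify(function(d, key) {
          tradeoff_correlation(d, nursery_t1, alpha = alpha)
        }) |>
        dplyr::ungroup()
      growth_groups <- compare_growth_groups(
        growth_out |>
          dplyr::mutate(group = paste(.data$species, "|",
                                      group_label(.data$site, "nursery"))),
        group = "group", alpha = alpha)
    }

    stage <- "headline"
    headline <- purrr::map(species_list, function(sp) {
      pooled <- dplyr::filter(comparisons, .data$species == sp,
                              .data$site == "pooled",
                              .data$contrast == "nursery-vs-donor")
      t1 <- pooled[pooled$timepoint == tps[1], ]
      t2 <- pooled[pooled$timepoint == tps[length(tps)], ]
      tibble::tibble(
        species = sp,
        deficit_at_t1 = isTRUE(t1$p_value < alpha && t1$mean_diff < 0),
        no_difference_at_t2 = isTRUE(t2$p_value >= alpha))
    }) |> purrr::list_rbind()

    structure(
      list(fits_colony = fits_colony, fits_population = fits_population,
           summaries = summaries, comparisons = comparisons, lme = lme,
           reproducibility = reproducibility, screening = screening,
           growth = growth_out, tradeoffs = tradeoffs,
           growth_groups = growth_groups, headline = headline,
           measurements = measurements, colonies = colonies,
           seed = as.integer(seed), alpha = alpha,
           config_hash = rlang::hash(config)),
      class = "cbass_report")
  }, error = function(e) {
    if (inherits(e, "coralscreen_pipeline_error")) stop(e)
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "coralscreen_pipeline_error", parent = e)
  })
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

#' @export
print.cbass_report <- function(x, ...) {
  cat("CBASS screening analysis report\n")
  cat(sprintf("  seed %d, config %s\n", x$seed, x$config_hash))
  cat(sprintf("  %d colony fits, %d population fits\n",
              nrow(x$fits_colony), nrow(x$fits_population)))
  cat("  headline:\n")
  for (i in seq_len(nrow(x$headline))) {
    cat(sprintf("    %s: deficit at T1 = %s, no difference at T2 = %s\n",
                x$headline$species[i], x$headline$deficit_at_t1[i],
                x$headline$no_difference_at_t2[i]))
  }
  invisible(x)
}

round_cols <- function(df, cols, digits = 2) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

#' Write a pipeline report bundle to disk
#'
#' Writes `fits_colony.csv`, `fits_population.csv`, `group_summaries.csv`,
#' `comparisons.csv`, `screening_curve.csv`, `growth.csv`,
#' `measurements.csv`, `colony_truth.csv` (synthetic runs) and `report.json`
#' (seed, config hash, headline booleans). Temperatures and thresholds are
#' rounded to 0.01 degC in the CSVs.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(report, out_dir) {
  stopifnot(inherits(report, "cbass_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name, cols = c("ed50", "relative_ed50",
                                   "tank_temperature_c", "mean_relative_ed50",
                                   "ed50_a", "ed50_b")) {
    if (!is.null(df)) {
      readr::write_csv(round_cols(tibble::as_tibble(df), cols),
                       file.path(out_dir, name))
    }
  }
  w(report$fits_colony, "fits_colony.csv")
  w(report$fits_population, "fits_population.csv")
  w(report$summaries, "group_summaries.csv")
  w(report$comparisons, "comparisons.csv")
  w(report$screening, "screening_curve.csv")
  w(report$lme, "lme_condition.csv")
  w(report$reproducibility, "reproducibility.csv")
  if (!is.null(report$growth)) {
    readr::write_csv(growth_to_long(report$growth),
                     file.path(out_dir, "growth.csv"))
    w(report$tradeoffs, "tradeoffs.csv")
    w(report$growth_groups$comparisons, "growth_tukey.csv")
    w(report$growth_groups$letters, "growth_letters.csv")
  }
  w(report$measurements, "measurements.csv")
  if (!is.null(report$colonies)) w(report$colonies, "colony_truth.csv",
                                   cols = "true_ed50")
  jsonlite::write_json(
    list(package = "coralscreen",
         version = as.character(utils::packageVersion("coralscreen")),
         seed = report$seed, alpha = report$alpha,
         config_hash = report$config_hash,
         headline = report$headline),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
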