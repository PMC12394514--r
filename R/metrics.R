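# Relative thermal thresholds and the retention/recovery comparisons:
# group summaries, normality-gated paired tests, unequal-n Tukey HSD, and the
# condition linear mixed model.

#' Relative thermal threshold (ED50 minus local MMM)
#'
#' Standardizes an absolute ED50 against the site's maximum monthly mean
#' climatology so thresholds are comparable across locations.
#'
#' @param ed50 absolute threshold(s), degC.
#' @param mmm local maximum monthly mean temperature, degC (default 30.52).
#' @return `ed50 - mmm`, exactly.
#' @export
#' @examples
#' relative_ed50(35.54) # 5.02
relative_ed50 <- function(ed50, mmm = 30.52) {
  if (any(!is.finite(ed50)) || any(!is.finite(mmm))) {
    abort("`ed50` and `mmm` must be finite.",
          class = "coralscreen_domain_error")
  }
  ed50 - mmm
}

#' Heat-hold treatment temperatures from a baseline and offsets
#'
#' @param baseline baseline (control) temperature, degC, typically the MMM.
#' @param offsets heat-hold offsets above baseline, degC (>= 0).
#' @return `baseline + offsets`, order preserved.
#' @export
#' @examples
#' treatment_temperatures(30.5, c(4, 6, 9)) # 34.5 36.5 39.5
treatment_temperatures <- function(baseline = 30.5, offsets = c(4, 6, 9)) {
  check_number(baseline, "baseline", min = .Machine$double.eps)
  if (length(offsets)) check_number(offsets, "offsets", min = 0)
  baseline + offsets
}

#' Group summaries of relative thermal thresholds
#'
#' Per species x site x condition x timepoint group: sample size, mean
#' relative ED50 and its standard error of the mean. Singleton groups get
#' `sem = 0` and are flagged.
#'
#' @param fits a colony-level fits tibble (see [fit_ed50s()]) with an `ed50`
#'   column and grouping labels.
#' @param mmm local MMM (degC) used by [relative_ed50()].
#' @return tibble with `species`, `site`, `condition`, `timepoint`, `n`,
#'   `mean_relative_ed50`, `sem`, `singleton`.
#' @export
summarize_groups <- function(fits, mmm = 30.52) {
  check_columns(fits, c("species", "site", "condition", "timepoint", "ed50"),
                "fits")
  if (!nrow(fits)) {
    abort("Empty fits table.", class = "coralscreen_data_error")
  }
  out <- fits |>
    dplyr::mutate(rel = relative_ed50(.data$ed50, mmm)) |>
    dplyr::group_by(.data$species, .data$site, .data$condition,
                    .data$timepoint) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_relative_ed50 = mean(.data$rel),
                     sem = if (dplyr::n() > 1) {
                       sd(.data$rel) / sqrt(dplyr::n())
                     } else 0,
                     .groups = "drop") |>
    dplyr::mutate(singleton = .data$n == 1L)
  if (any(out$singleton)) {
    warn("Some groups contain a single colony; their SEM is reported as 0.")
  }
  out
}

#' Paired comparison with a normality gate
#'
#' Restricts two labelled groups to complete pairs (ids present in both), then
#' tests the paired differences: Shapiro-Wilk on the differences decides
#' between a two-tailed paired t-test (normal at `alpha`) and a Wilcoxon
#' signed-rank test. Identical vectors (zero-variance differences) are flagged
#' degenerate and get no p-value.
#'
#' @param data tibble with one row per observation.
#' @param value name of the numeric column to compare (e.g. relative ED50).
#' @param group name of the two-level grouping column.
#' @param id name of the pairing-key column (colony/genet id).
#' @param group_levels optional length-2 character giving the order (a, b);
#'   `mean_diff` is mean(a) - mean(b). Defaults to sorted unique levels.
#' @param alpha significance level for the normality gate.
#' @return One-row tibble: `group_a`, `group_b`, `test_used`, `n_pairs`,
#'   `statistic`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
#' @examples
#' d <- tibble::tibble(id = rep(1:6, 2),
#'                     grp = rep(c("nursery", "donor"), each = 6),
#'                     rel = c(rnorm(6, 5), rnorm(6, 7)))
#' compare_paired(d, "rel", "grp", "id")
compare_paired <- function(data, value, group, id,
                           group_levels = NULL, alpha = 0.05) {
  check_columns(data, c(value, group, id), "paired data")
  levels <- group_levels %||% sort(unique(as.character(data[[group]])))
  if (length(levels) != 2) {
    abort("`group` must have exactly two levels.",
          class = "coralscreen_data_error")
  }
  wide <- data |>
    dplyr::select(id = dplyr::all_of(id), grp = dplyr::all_of(group),
                  val = dplyr::all_of(value)) |>
    dplyr::filter(.data$grp %in% levels) |>
    tidyr::pivot_wider(names_from = "grp", values_from = "val") |>
    dplyr::filter(stats::complete.cases(dplyr::pick(dplyr::everything())))
  n_pairs <- nrow(wide)
  if (n_pairs < 3) {
    abort(sprintf("Need >= 3 complete pairs, got %d.", n_pairs),
          class = "coralscreen_insufficient_data")
  }
  diffs <- wide[[levels[1]]] - wide[[levels[2]]]
  res <- tibble::tibble(group_a = levels[1], group_b = levels[2],
                        test_used = NA_character_, n_pairs = n_pairs,
                        statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, mean_diff = mean(diffs),
                        degenerate = FALSE)
  if (stats::var(diffs) == 0) {
    res$degenerate <- TRUE
    res$test_used <- "degenerate"
    return(res)
  }
  normal <- shapiro.test(diffs)$p.value >= alpha
  if (normal) {
    tt <- t.test(diffs)
    res$test_used <- "paired-t"
    res$statistic <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p_value <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(diffs, exact = FALSE))
    res$test_used <- "wilcoxon-signed"
    res$statistic <- unname(wt$statistic)
    res$p_value <- wt$p.value
  }
  res
}

# Tukey-Kramer studentized-range comparisons for unequal group sizes, built on
# stats::ptukey. Used both for relative-threshold site comparisons and SGR
# group comparisons.
tukey_kramer <- function(values, groups) {
  groups <- as.character(groups)
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warn(sprintf("Excluding group(s) with n < 2 from Tukey HSD: %s.",
                 paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
    counts <- table(groups)
  }
  k <- length(counts)
  if (k < 2) {
    abort("Tukey HSD needs >= 2 groups with n >= 2.",
          class = "coralscreen_insufficient_data")
  }
  means <- tapply(values, groups, mean)
  ns <- as.numeric(counts[names(means)])
  df <- sum(ns) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df
  pairs <- utils::combn(names(means), 2)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- means[[a]] - means[[b]]
    se <- sqrt(mse / 2 * (1 / ns[names(means) == a] +
                            1 / ns[names(means) == b]))
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p <- if (is.finite(q)) ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
         else 0
    tibble::tibble(group_a = a, group_b = b, test_used = "tukey-hsd",
                   n_pairs = NA_integer_, statistic = q, df = df,
                   p_value = p, mean_diff = unname(diff))
  }) |> purrr::list_rbind()
}

#' All-pairs Tukey HSD for unequal sample sizes
#'
#' Compares relative thermal thresholds among the site x condition groups of
#' one season with the Tukey-Kramer studentized-range procedure (pooled
#' one-way MSE; exact for unequal n in the Kramer form). Groups with fewer
#' than 2 values are excluded with a warning.
#'
#' @param data tibble of colony-level values.
#' @param value name of the numeric column (e.g. relative ED50).
#' @param group name of the grouping column (e.g. "Site 1 - Nursery").
#' @return tibble of pairwise rows: `group_a`, `group_b`, `test_used`,
#'   `statistic` (studentized range q), `df`, `p_value` (Tukey-adjusted),
#'   `mean_diff`.
#' @export
compare_sites_tukey <- function(data, value, group) {
  check_columns(data, c(value, group), "group data")
  tukey_kramer(data[[value]], data[[group]])
}

#' Mixed-model test of the nursery/donor condition effect
#'
#' Fits fragment-level Fv/Fm for one species with temperature (categorical)
#' and condition as fixed effects and random intercepts for site and season:
#' `fvfm ~ temperature + condition + (1|site) + (1|time)`. Fixed effects are
#' backward-eliminated by likelihood-ratio tests on ML refits (an effect is
#' kept when its removal p-value is < `alpha`); the condition effect is always
#' reported, from a model containing it. If the random-effect structure is
#' singular (site/season variance ~ 0) the model downgrades to ordinary least
#' squares with a flag. The t-statistic's df uses a containment-style
#' approximation (observations minus fixed-effect rank minus random-intercept
#' levels).
#'
#' @param measurements fragment-level tibble for a single species with columns
#'   `fvfm`, `tank_temperature_c`, `condition`, `site`, `timepoint`.
#' @param alpha threshold used during backward elimination.
#' @return One-row tibble: `test_used` (`"lme-condition"` or the
#'   `"lm-condition"` downgrade), `n_obs`, `estimate` (condition effect for
#'   the second condition level, nursery vs donor), `se`, `statistic`, `df`,
#'   `p_value`, `eliminated` (fixed effects dropped), `singular`.
#' @export
fit_condition_lme <- function(measurements, alpha = 0.05) {
  check_columns(measurements, c("fvfm", "tank_temperature_c", "condition",
                                "site", "timepoint"), "measurements")
  if ("species" %in% names(measurements) &&
      length(unique(measurements$species)) > 1) {
    abort("Fit one species at a time.", class = "coralscreen_data_error")
  }
  d <- measurements |>
    dplyr::transmute(fvfm = .data$fvfm,
                     temperature = factor(.data$tank_temperature_c),
                     condition = factor(.data$condition,
                                        levels = c("donor", "nursery")),
                     site = factor(.data$site),
                     time = factor(.data$timepoint))
  n <- nrow(d)

  fit_lmm <- function(formula) {
    suppressMessages(suppressWarnings(
      lme4::lmer(formula, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular =
                                               lme4::.makeCC(action = "ignore",
                                                             tol = 1e-4)))))
  }
  full <- tryCatch(fit_lmm(fvfm ~ temperature + condition + (1 | site) + (1 | time)),
                   error = function(e) NULL)
  singular <- is.null(full) || lme4::isSingular(full, tol = 1e-4)

  if (singular) {
    # Random intercepts carry no variance: plain two-factor linear model.
    lmfit <- lm(fvfm ~ temperature + condition, data = d)
    eliminated <- character()
    for (term in c("temperature")) {
      red <- lm(as.formula(paste("fvfm ~", setdiff(c("temperature", "condition"), term))),
                data = d)
      p_rm <- anova(red, lmfit)[2, "Pr(>F)"]
      if (!is.na(p_rm) && p_rm >= alpha) eliminated <- c(eliminated, term)
    }
    model <- if (length(eliminated)) {
      lm(fvfm ~ condition, data = d)
    } else lmfit
    sm <- summary(model)$coefficients
    row <- grep("^condition", rownames(sm))
    return(tibble::tibble(
      test_used = "lm-condition", n_obs = n,
      estimate = sm[row, "Estimate"], se = sm[row, "Std. Error"],
      statistic = sm[row, "t value"], df = model$df.residual,
      p_value = sm[row, "Pr(>|t|)"],
      eliminated = paste(eliminated, collapse = ","),
      singular = TRUE))
  }

  # Backward elimination of the temperature effect (condition always reported
  # from a model that contains it).
  eliminated <- character()
  no_temp <- fit_lmm(fvfm ~ condition + (1 | site) + (1 | time))
  p_rm <- anova(no_temp, full)[2, "Pr(>Chisq)"]
  model <- full
  if (!is.na(p_rm) && p_rm >= alpha) {
    eliminated <- "temperature"
    model <- no_temp
  }
  sm <- summary(model)$coefficients
  row <- grep("^condition", rownames(sm))
  est <- sm[row, "Estimate"]
  se <- sm[row, "Std. Error"]
  tstat <- sm[row, "t value"]
  n_re_levels <- sum(vapply(lme4::ranef(model), nrow, integer(1)))
  df <- n - nrow(sm) - n_re_levels
  tibble::tibble(test_used = "lme-condition", n_obs = n,
                 estimate = est, se = se, statistic = tstat, df = df,
                 p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE),
                 eliminated = paste(eliminated, collapse = ","),
                 singular = FALSE)
}
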