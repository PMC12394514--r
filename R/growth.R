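# Coral growth: geometric mean radius, specific growth rate, growth-group
# comparisons, and the growth-tolerance trade-off correlation.

#' Geometric mean radius of a coral fragment
#'
#' Combines triaxial dimensions into one size metric: the cube root of the
#' product of the three semi-axes, `((L/2)(W/2)(H/2))^(1/3)`. Set
#' `semi_axes = FALSE` to use the full axes (a constant factor of 2; growth
#' *rates* are unaffected by the choice).
#'
#' @param length,width,height fragment dimensions in cm (> 0); vectorized.
#' @param semi_axes divide dimensions by 2 before the geometric mean
#'   (default `TRUE`).
#' @return geometric mean radius in cm.
#' @export
#' @examples
#' gmr(2, 2, 2)  # 1
#' gmr(2, 2, 16) # 2
gmr <- function(length, width, height, semi_axes = TRUE) {
  if (any(!is.finite(c(length, width, height))) ||
      any(c(length, width, height) <= 0)) {
    abort("Dimensions must be finite and > 0 cm.",
          class = "coralscreen_domain_error")
  }
  s <- if (semi_axes) 2 else 1
  ((length / s) * (width / s) * (height / s))^(1 / 3)
}

#' Specific growth rate from two sizes
#'
#' `SGR = (ln(final) - ln(initial)) * 100 / days`, in percent growth per day.
#' Shrinkage yields a negative rate, not an error.
#'
#' @param gmr_initial,gmr_final geometric mean radii (cm, > 0).
#' @param days elapsed days (> 0).
#' @return specific growth rate, % / day.
#' @export
#' @examples
#' sgr(1, 2, 176) # ~0.3939 %/day (a doubling over 176 days)
sgr <- function(gmr_initial, gmr_final, days) {
  if (any(!is.finite(c(gmr_initial, gmr_final))) ||
      any(c(gmr_initial, gmr_final) <= 0)) {
    abort("GMR values must be finite and > 0.",
          class = "coralscreen_domain_error")
  }
  if (any(!is.finite(days)) || any(days <= 0)) {
    abort("`days` must be finite and > 0.",
          class = "coralscreen_domain_error")
  }
  (log(gmr_final) - log(gmr_initial)) * 100 / days
}

#' Derive GMR and SGR columns from raw growth records
#'
#' @param records tibble with `date0`, `date1` and triaxial dimensions
#'   `length0`, `width0`, `height0`, `length1`, `width1`, `height1` (cm), as
#'   from [simulate_growth()] or [read_growth()].
#' @param semi_axes see [gmr()].
#' @return the records with `gmr0`, `gmr1` (cm) and `sgr` (%/day) appended.
#' @export
growth_rates <- function(records, semi_axes = TRUE) {
  check_columns(records, c("date0", "date1", "length0", "width0", "height0",
                           "length1", "width1", "height1"), "growth records")
  days <- as.numeric(as.Date(records$date1) - as.Date(records$date0))
  if (any(days <= 0)) {
    abort("date1 must be after date0 for every record.",
          class = "coralscreen_data_error")
  }
  records |>
    dplyr::mutate(
      gmr0 = gmr(.data$length0, .data$width0, .data$height0, semi_axes),
      gmr1 = gmr(.data$length1, .data$width1, .data$height1, semi_axes),
      sgr = sgr(.data$gmr0, .data$gmr1, days))
}

#' Growth-tolerance trade-off correlation
#'
#' Pearson product-moment correlation between specific growth rate and the
#' thermal threshold of the same colonies, with a two-sided test. A
#' significantly negative correlation signals a trade-off. (The correlation is
#' identical for absolute and relative ED50: the MMM shift is constant.)
#'
#' @param growth tibble with `colony_id` and `sgr` (see [growth_rates()]).
#' @param fits tibble with `colony_id` and `ed50` (colony-level fits of the
#'   matching condition/season).
#' @param alpha significance level for the trade-off flag.
#' @return one-row tibble: `r`, `p_value`, `n`, `tradeoff` (logical: r < 0
#'   and p < alpha).
#' @export
tradeoff_correlation <- function(growth, fits, alpha = 0.05) {
  check_columns(growth, c("colony_id", "sgr"), "growth")
  check_columns(fits, c("colony_id", "ed50"), "fits")
  merged <- dplyr::inner_join(growth[, c("colony_id", "sgr")],
                              fits[, c("colony_id", "ed50")],
                              by = "colony_id") |>
    dplyr::filter(is.finite(.data$sgr), is.finite(.data$ed50))
  if (nrow(merged) < 3) {
    abort(sprintf("Need >= 3 complete (SGR, ED50) pairs, got %d.",
                  nrow(merged)),
          class = "coralscreen_insufficient_data")
  }
  if (var(merged$sgr) == 0 || var(merged$ed50) == 0) {
    abort("Zero variance in SGR or ED50: correlation undefined.",
          class = "coralscreen_degenerate_fit")
  }
  ct <- cor.test(merged$sgr, merged$ed50, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(merged),
                 tradeoff = unname(ct$estimate) < 0 & ct$p.value < alpha)
}

# Compact letter display via insert-absorb: start from one letter covering all
# groups; every significant pair splits each letter set containing both;
# duplicate/contained sets are absorbed. Guarantees that significant pairs
# share no letter and non-significant pairs share at least one.
cld_letters <- function(group_names, sig_pairs) {
  sets <- list(group_names)
  for (j in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group_a[j]
    b <- sig_pairs$group_b[j]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (l in seq_along(new_sets)) {
        if (i != l && keep[i] &&
            all(new_sets[[i]] %in% new_sets[[l]]) &&
            (length(new_sets[[i]]) < length(new_sets[[l]]) || i > l)) {
          keep[i] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[order(purrr::map_dbl(sets, function(s) min(match(s, group_names))))]
  letters_used <- letters[seq_along(sets)]
  vapply(group_names, function(g) {
    paste0(letters_used[purrr::map_lgl(sets, function(s) g %in% s)],
           collapse = "")
  }, character(1))
}

#' Compare growth rates across groups (Tukey HSD + letters)
#'
#' All-pairs Tukey-Kramer comparison of specific growth rates among species x
#' site x condition groups, with a compact letter display: groups sharing a
#' letter are not significantly different at `alpha`.
#'
#' @param growth tibble with an `sgr` column and a grouping column.
#' @param group name of the grouping column (default `"group"`); build it
#'   e.g. as `paste(species, site)`.
#' @param alpha significance level for the letter display.
#' @return list with `comparisons` (pairwise tibble, see
#'   [compare_sites_tukey()]) and `letters` (tibble `group`, `n`, `mean_sgr`,
#'   `letters`).
#' @export
compare_growth_groups <- function(growth, group = "group", alpha = 0.05) {
  check_columns(growth, c("sgr", group), "growth")
  comparisons <- tukey_kramer(growth$sgr, growth[[group]])
  groups <- unique(c(comparisons$group_a, comparisons$group_b))
  sig <- comparisons[comparisons$p_value < alpha, c("group_a", "group_b")]
  letter_map <- cld_letters(groups, sig)
  kept <- growth[growth[[group]] %in% groups, ]
  letters_tbl <- kept |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(n = dplyr::n(), mean_sgr = mean(.data$sgr),
                     .groups = "drop") |>
    dplyr::mutate(letters = unname(letter_map[.data$group]))
  list(comparisons = comparisons, letters = letters_tbl)
}
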