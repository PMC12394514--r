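# Colony-level ED50 reproducibility and top/bottom cohort-assignment
# consistency as a function of screening effort (number of colonies assayed).

#' Colony-level ED50 reproducibility
#'
#' Flags each colony whose two ED50 determinations (e.g. warm season vs
#' monsoon season, or donor vs nursery) agree to within `threshold` degC
#' (strict inequality by default, so a difference of exactly 1.0 degC does not
#' count as reproduced).
#'
#' @param paired tibble with columns `colony_id`, `ed50_a`, `ed50_b`.
#' @param threshold agreement threshold in degC (default 1.0).
#' @param strict if `TRUE` (default) use `|a - b| < threshold`, else `<=`.
#' @return list with `fraction` (proportion reproduced), `n`, and `flags`
#'   (tibble `colony_id`, `diff`, `reproduced`).
#' @export
#' @examples
#' tab <- tibble::tibble(colony_id = c("c1", "c2", "c3"),
#'                       ed50_a = c(36.0, 35.0, 38.0),
#'                       ed50_b = c(36.5, 37.0, 37.8))
#' ed50_reproducibility(tab)$fraction # 2/3
ed50_reproducibility <- function(paired, threshold = 1.0, strict = TRUE) {
  check_columns(paired, c("colony_id", "ed50_a", "ed50_b"), "paired ED50s")
  if (!nrow(paired)) {
    abort("Empty paired ED50 table.", class = "coralscreen_data_error")
  }
  if (anyDuplicated(paired$colony_id)) {
    abort("colony_id must be unique in the paired table.",
          class = "coralscreen_data_error")
  }
  if (any(!is.finite(paired$ed50_a)) || any(!is.finite(paired$ed50_b))) {
    abort("Both ED50 columns must be finite.",
          class = "coralscreen_data_error")
  }
  check_number(threshold, "threshold", min = 0)
  d <- abs(paired$ed50_a - paired$ed50_b)
  flag <- if (strict) d < threshold else d <= threshold
  list(fraction = mean(flag), n = nrow(paired),
       flags = tibble::tibble(colony_id = paired$colony_id, diff = d,
                              reproduced = flag))
}

rank_ids <- function(ids, ed50) {
  # Rank from most to least heat tolerant; ties broken by colony id so that
  # rankings (and everything downstream) are deterministic.
  ids[order(-ed50, ids)]
}

#' Top/bottom cohort misassignment between two rankings
#'
#' Given two rankings of the same colonies (most to least tolerant), counts
#' how many of ranking a's top-k cohort are absent from ranking b's top-k, and
#' likewise for the bottom-k cohorts, and returns the average of the two
#' counts (a value in \[0, k\]).
#'
#' @param ranking_a,ranking_b character vectors: the same colony ids, each
#'   ordered by its own ED50 ranking (see [rank_colonies()]).
#' @param k cohort size (default 5); needs at least `2k` colonies.
#' @return Mean number of misassigned colonies across the two cohorts.
#' @export
#' @examples
#' cohort_misassignment(letters[1:10], rev(letters[1:10]), k = 2) # 2
cohort_misassignment <- function(ranking_a, ranking_b, k = 5) {
  check_number(k, "k", min = 1)
  if (!setequal(ranking_a, ranking_b) ||
      length(ranking_a) != length(ranking_b)) {
    abort("Rankings must be permutations of the same colony id set.",
          class = "coralscreen_data_error")
  }
  n <- length(ranking_a)
  if (n < 2 * k) {
    abort(sprintf("Need >= 2k = %d colonies, got %d.", 2 * k, n),
          class = "coralscreen_size_error")
  }
  top_miss <- length(setdiff(head(ranking_a, k), head(ranking_b, k)))
  bot_miss <- length(setdiff(tail(ranking_a, k), tail(ranking_b, k)))
  (top_miss + bot_miss) / 2
}

#' Rank colonies by ED50
#'
#' @param ids colony ids.
#' @param ed50 matching ED50 values (degC).
#' @return ids ordered from highest to lowest ED50, ED50 ties broken by id.
#' @export
rank_colonies <- function(ids, ed50) {
  if (length(ids) != length(ed50)) {
    abort("`ids` and `ed50` must have equal length.",
          class = "coralscreen_data_error")
  }
  rank_ids(as.character(ids), ed50)
}

#' Cohort-assignment consistency as a function of screening effort
#'
#' For each screening size `s`, repeatedly subsamples `s` colonies without
#' replacement from a paired ED50 table, ranks the two columns within the
#' subsample, and computes the top/bottom-k [cohort_misassignment()];
#' reports the Monte-Carlo mean and its standard error per size. Under
#' perfect concordance the curve is identically zero; under independent
#' rankings it approaches `k - k^2/s`.
#'
#' @param paired tibble with `colony_id`, `ed50_a`, `ed50_b` (e.g. donor vs
#'   nursery ED50s of the same genets in one season).
#' @param k cohort size (default 5, i.e. top-5 and bottom-5).
#' @param sizes screening sizes to evaluate; default every integer from `2k`
#'   to the number of colonies.
#' @param n_iterations Monte-Carlo subsamples per size (default 1000).
#' @param seed integer seed; the curve is deterministic given it.
#' @return tibble of class `screening_curve`: `size`, `mean_misassigned`,
#'   `se`, `n_iterations`, `k`, `seed`.
#' @export
#' @examples
#' tab <- tibble::tibble(colony_id = sprintf("c%02d", 1:20),
#'                       ed50_a = rnorm(20, 36), ed50_b = rnorm(20, 36))
#' screening_curve(tab, k = 5, sizes = c(10, 15, 20), n_iterations = 200,
#'                 seed = 1)
screening_curve <- function(paired, k = 5, sizes = NULL, n_iterations = 1000,
                            seed = 1) {
  check_columns(paired, c("colony_id", "ed50_a", "ed50_b"), "paired ED50s")
  n <- nrow(paired)
  check_number(n_iterations, "n_iterations", min = 1)
  check_number(k, "k", min = 1)
  if (n < 2 * k) {
    abort(sprintf("Need >= 2k = %d colonies, got %d.", 2 * k, n),
          class = "coralscreen_size_error")
  }
  sizes <- sizes %||% seq.int(2 * k, n)
  bad <- sizes[sizes > n | sizes < 2 * k]
  if (length(bad)) {
    abort(sprintf("Screening size(s) outside [2k, n] = [%d, %d]: %s.",
                  2 * k, n, paste(bad, collapse = ", ")),
          class = "coralscreen_size_error")
  }
  ids <- as.character(paired$colony_id)
  out <- withr::with_seed(as.integer(seed), {
    purrr::map(sizes, function(s) {
      mis <- vapply(seq_len(n_iterations), function(i) {
        idx <- sample.int(n, s)
        cohort_misassignment(rank_ids(ids[idx], paired$ed50_a[idx]),
                             rank_ids(ids[idx], paired$ed50_b[idx]),
                             k = k)
      }, numeric(1))
      tibble::tibble(size = s, mean_misassigned = mean(mis),
                     se = if (n_iterations > 1) {
                       sd(mis) / sqrt(n_iterations)
                     } else 0)
    }) |> purrr::list_rbind()
  })
  out$n_iterations <- as.integer(n_iterations)
  out$k <- as.integer(k)
  out$seed <- as.integer(seed)
  class(out) <- c("screening_curve", class(out))
  out
}

#' @rdname screening_curve
#' @param object a `screening_curve`.
#' @param ... unused.
#' @method autoplot screening_curve
#' @export
autoplot.screening_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size,
                                       y = .data$mean_misassigned)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_misassigned - .data$se,
                                      ymax = .data$mean_misassigned + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Screening effort (colonies assayed)",
                  y = sprintf("Mean misassigned colonies (top/bottom %d)",
                              object$k[1])) +
    ggplot2::theme_minimal()
}
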