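# Three-parameter log-logistic (LL.3) dose-response model and constrained
# least-squares fitting. The LL.3 curve with zero lower asymptote is
#
#   f(T) = fmax / (1 + exp(hill * (log(T) - log(ed50))))
#
# where `hill` is the (positive) slope at the inflection, `fmax` the upper
# asymptote (baseline Fv/Fm), and `ed50` the temperature at which the response
# has dropped to half of fmax. Temperature in degrees C is used directly as
# the dose (all assay temperatures are far from 0 degC so the log transform is
# well defined).

#' Default LL.3 parameter bounds
#'
#' Box constraints used for dose-response fitting: `hill` in \[10, 100\],
#' `fmax` in \[0.3, 0.8\], `ed50` in \[30, Inf). These mirror the limits used
#' in CBASS ED50 studies so that fits on few points cannot wander into
#' biologically meaningless regions (e.g. baseline Fv/Fm above 0.8, thresholds
#' below plausible tropical sea temperatures).
#'
#' @param hill,fmax,ed50 length-2 numeric `c(lower, upper)` overrides.
#' @return A list with `lower` and `upper` named numeric triples
#'   (`hill`, `fmax`, `ed50`).
#' @export
#' @examples
#' ll3_bounds()
ll3_bounds <- function(hill = c(10, 100), fmax = c(0.3, 0.8),
                       ed50 = c(30, Inf)) {
  lower <- c(hill = hill[1], fmax = fmax[1], ed50 = ed50[1])
  upper <- c(hill = hill[2], fmax = fmax[2], ed50 = ed50[2])
  if (any(lower > upper)) {
    abort("Lower bounds must not exceed upper bounds.",
          class = "coralscreen_config_error")
  }
  if (any(lower[c("hill", "ed50")] <= 0) || lower["fmax"] <= 0 ||
      upper["fmax"] > 1) {
    abort("Bounds must satisfy hill > 0, ed50 > 0, 0 < fmax <= 1.",
          class = "coralscreen_config_error")
  }
  list(lower = lower, upper = upper)
}

#' Predict Fv/Fm from a three-parameter log-logistic curve
#'
#' @param temperature temperature(s) in degrees C; must be > 0.
#' @param hill positive slope parameter (dimensionless).
#' @param fmax upper asymptote, the unstressed Fv/Fm, in (0, 1\].
#' @param ed50 temperature (degC) at which the response equals `fmax / 2`.
#' @return Predicted Fv/Fm value(s) in (0, fmax); strictly decreasing in
#'   temperature for `hill > 0`.
#' @export
#' @examples
#' ll3_predict(36, hill = 20, fmax = 0.6, ed50 = 36) # exactly 0.3
ll3_predict <- function(temperature, hill, fmax, ed50) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    abort("`temperature` must be finite and > 0 degC.",
          class = "coralscreen_domain_error")
  }
  check_number(hill, "hill", min = .Machine$double.eps)
  check_number(fmax, "fmax", min = .Machine$double.eps, max = 1)
  check_number(ed50, "ed50", min = .Machine$double.eps)
  fmax / (1 + exp(hill * (log(temperature) - log(ed50))))
}

ll3_sse <- function(par, temperature, fvfm) {
  pred <- par[2] / (1 + exp(par[1] * (log(temperature) - log(par[3]))))
  sum((fvfm - pred)^2)
}

#' Fit a constrained three-parameter log-logistic dose-response curve
#'
#' Least-squares fit of Fv/Fm against temperature under box constraints,
#' using a deterministic multi-start bounded quasi-Newton search so that
#' results are run-to-run reproducible: `ed50` starts at every observed
#' temperature (clamped into bounds), `hill` starts at 15, 40 and 80, and
#' `fmax` starts at the maximum observed Fv/Fm (clamped). The best
#' sum-of-squares wins; ties are broken toward the smallest `ed50`.
#'
#' @param data data frame with columns `temperature` (degC) and `fvfm`
#'   (fraction in \[0, 1\]); at least 4 points spanning at least 3 distinct
#'   temperatures.
#' @param bounds parameter box, as returned by [ll3_bounds()].
#' @param scope `"colony"` (a single colony's four fragments) or
#'   `"population"` (pooled fragments of a site-condition group); metadata
#'   only, the fitting procedure is identical.
#' @return An object of class `ll3_fit`: a list with `params` (named vector
#'   `hill`, `fmax`, `ed50`), `sse`, `converged`, `at_bound` (named logical;
#'   flags parameters pinned at a box constraint), `n_points`, `scope`,
#'   `data`, and optional bootstrap fields `ed50_se` / `ed50_ci95` filled in
#'   by [ed50_uncertainty()]. Use [tidy()] / [glance()] for tibble views.
#' @export
#' @examples
#' d <- tibble::tibble(temperature = c(31, 35, 37, 40),
#'                     fvfm = ll3_predict(c(31, 35, 37, 40), 40, 0.6, 36))
#' fit <- fit_ll3(d)
#' tidy(fit)
fit_ll3 <- function(data, bounds = ll3_bounds(), scope = "colony") {
  check_columns(data, c("temperature", "fvfm"), "measurement data")
  temperature <- as.numeric(data$temperature)
  fvfm <- as.numeric(data$fvfm)
  ok <- is.finite(temperature) & is.finite(fvfm)
  temperature <- temperature[ok]
  fvfm <- fvfm[ok]
  if (length(fvfm) < 4 || length(unique(temperature)) < 3) {
    abort(sprintf(
      "LL.3 needs >= 4 points over >= 3 distinct temperatures (got %d points, %d temperatures).",
      length(fvfm), length(unique(temperature))),
      class = "coralscreen_insufficient_data")
  }
  if (any(temperature <= 0)) {
    abort("Temperatures must be > 0 degC.", class = "coralscreen_domain_error")
  }
  if (any(fvfm < 0 | fvfm > 1)) {
    abort("fvfm values must lie in [0, 1].", class = "coralscreen_domain_error")
  }
  if (all(fvfm == 0)) {
    abort("All responses are zero: the upper asymptote is unidentifiable (degenerate fit).",
          class = "coralscreen_degenerate_fit")
  }
  lower <- bounds$lower
  upper <- bounds$upper
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  ed50_starts <- unique(clamp(sort(unique(temperature)),
                              lower["ed50"],
                              min(upper["ed50"], max(temperature) + 10)))
  hill_starts <- unique(clamp(c(15, 40, 80), lower["hill"], upper["hill"]))
  fmax_start <- clamp(max(fvfm), lower["fmax"], upper["fmax"])

  # L-BFGS-B needs finite bounds only where given; Inf upper is allowed.
  best <- NULL
  for (e0 in ed50_starts) {
    for (h0 in hill_starts) {
      res <- tryCatch(
        optim(c(h0, fmax_start, e0), ll3_sse,
              temperature = temperature, fvfm = fvfm,
              method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(factr = 1e2, pgtol = 1e-12, maxit = 500)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) ||
          res$value < best$value - 1e-12 ||
          (abs(res$value - best$value) <= 1e-12 && res$par[3] < best$par[3])) {
        best <- res
      }
    }
  }
  if (is.null(best)) {
    abort("LL.3 optimisation failed from every start.",
          class = "coralscreen_degenerate_fit")
  }
  # polish at machine-precision convergence from the winning start, with the
  # parameters brought onto comparable scales (hill ~ tens, fmax ~ tenths);
  # the convergence flag reflects the multi-start stage — the polish may stop
  # with an "abnormal" code simply because it is run past double resolution
  converged <- best$convergence == 0
  polish <- tryCatch(
    optim(best$par, ll3_sse, temperature = temperature, fvfm = fvfm,
          method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(factr = 1, pgtol = 0, maxit = 1000,
                         parscale = c(50, 0.5, 35))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    best <- polish
    converged <- converged || polish$convergence == 0
  }
  par <- setNames(best$par, c("hill", "fmax", "ed50"))
  tol_bound <- 1e-6
  at_bound <- (par - lower <= tol_bound * pmax(1, abs(lower))) |
    (is.finite(upper) & (upper - par <= tol_bound * pmax(1, abs(upper))))
  structure(
    list(params = par,
         sse = best$value,
         converged = converged,
         at_bound = at_bound,
         n_points = length(fvfm),
         scope = scope,
         data = tibble::tibble(temperature = temperature, fvfm = fvfm),
         ed50_se = NA_real_,
         ed50_ci95 = c(NA_real_, NA_real_)),
    class = "ll3_fit")
}

#' @export
print.ll3_fit <- function(x, ...) {
  cat(sprintf("LL.3 fit (%s scope, %d points)\n", x$scope, x$n_points))
  cat(sprintf("  hill = %.3f, fmax = %.4f, ed50 = %.2f degC\n",
              x$params["hill"], x$params["fmax"], x$params["ed50"]))
  cat(sprintf("  sse = %.5g, converged = %s%s\n", x$sse, x$converged,
              if (any(x$at_bound)) paste0(", at bound: ",
                paste(names(x$at_bound)[x$at_bound], collapse = ", ")) else ""))
  if (!is.na(x$ed50_se)) {
    cat(sprintf("  ed50 se = %.3f degC, 95%% CI [%.2f, %.2f]\n",
                x$ed50_se, x$ed50_ci95[1], x$ed50_ci95[2]))
  }
  invisible(x)
}

#' @rdname fit_ll3
#' @param x an `ll3_fit` object.
#' @param ... unused.
#' @method tidy ll3_fit
#' @export
tidy.ll3_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unname(x$params),
                 at_bound = unname(x$at_bound))
}

#' @rdname fit_ll3
#' @method glance ll3_fit
#' @export
glance.ll3_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, converged = x$converged,
                 n_points = x$n_points, scope = x$scope,
                 ed50 = unname(x$params["ed50"]),
                 ed50_se = x$ed50_se,
                 ed50_ci_lo = x$ed50_ci95[1], ed50_ci_hi = x$ed50_ci95[2])
}

#' Bootstrap uncertainty for a fitted ED50
#'
#' Non-parametric case-resampling bootstrap: measurement rows are resampled
#' with replacement and the LL.3 curve refit (starting from the original
#' estimates). Resamples with fewer than 3 distinct temperatures leave the
#' curve unidentified and are redrawn. Attaches `ed50_se` (bootstrap standard
#' deviation) and `ed50_ci95` (percentile interval).
#'
#' @param fit a converged [fit_ll3()] result.
#' @param n_boot number of bootstrap resamples (>= 50).
#' @param seed integer seed; the bootstrap is deterministic given it.
#' @param bounds parameter box used for refits.
#' @return The `ll3_fit` with `ed50_se` and `ed50_ci95` filled in, plus a
#'   `boot_ed50` vector attribute.
#' @export
ed50_uncertainty <- function(fit, n_boot = 200, seed = 1,
                             bounds = ll3_bounds()) {
  stopifnot(inherits(fit, "ll3_fit"))
  if (!fit$converged) {
    abort("Bootstrap requires a converged fit.",
          class = "coralscreen_config_error")
  }
  check_number(n_boot, "n_boot", min = 50)
  dat <- fit$data
  n <- nrow(dat)
  boot_ed50 <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      for (try in 1:50) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(dat$temperature[idx])) >= 3) break
      }
      d <- dat[idx, ]
      res <- tryCatch(
        optim(unname(fit$params), ll3_sse,
              temperature = d$temperature, fvfm = d$fvfm,
              method = "L-BFGS-B", lower = bounds$lower, upper = bounds$upper,
              control = list(factr = 1e4, pgtol = 1e-12, maxit = 500)),
        error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$par[3]
    }, numeric(1))
  })
  boot_ed50 <- boot_ed50[is.finite(boot_ed50)]
  fit$ed50_se <- stats::sd(boot_ed50)
  fit$ed50_ci95 <- unname(quantile(boot_ed50, c(0.025, 0.975), names = FALSE))
  attr(fit, "boot_ed50") <- boot_ed50
  fit
}

#' Fit LL.3 curves across a measurement table
#'
#' Groups a tidy measurement table and fits one constrained LL.3 curve per
#' group: per colony (`scope = "colony"`, grouping by colony, condition and
#' timepoint — each colony contributes one fragment per treatment tank) or
#' per population (`scope = "population"`, pooling all fragments of a
#' species/site/condition/timepoint group).
#'
#' @param measurements tibble with columns `colony_id`, `species`, `site`,
#'   `condition`, `timepoint`, `tank_temperature_c`, `fvfm` (see
#'   [read_measurements()] / [simulate_cbass()]).
#' @param bounds parameter box, see [ll3_bounds()].
#' @param scope `"colony"` or `"population"`.
#' @return A tibble with the grouping labels and columns `hill`, `fmax`,
#'   `ed50`, `sse`, `n_points`, `converged`, `at_bound` (TRUE if any
#'   parameter is pinned at a constraint), `scope`.
#' @export
fit_ed50s <- function(measurements, bounds = ll3_bounds(),
                      scope = c("colony", "population")) {
  scope <- match.arg(scope)
  check_columns(measurements,
                c("species", "site", "condition", "timepoint",
                  "tank_temperature_c", "fvfm"), "measurements")
  keys <- if (scope == "colony") {
    check_columns(measurements, "colony_id", "measurements")
    c("colony_id", "species", "site", "condition", "timepoint")
  } else {
    c("species", "site", "condition", "timepoint")
  }
  measurements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_ll3(
        tibble::tibble(temperature = d$tank_temperature_c, fvfm = d$fvfm),
        bounds = bounds, scope = scope)
      tibble::tibble(hill = fit$params[["hill"]],
                     fmax = fit$params[["fmax"]],
                     ed50 = fit$params[["ed50"]],
                     sse = fit$sse,
                     n_points = fit$n_points,
                     converged = fit$converged,
                     at_bound = any(fit$at_bound))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(scope = scope)
}
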