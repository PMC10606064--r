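#' Fit the exponential-plateau model to a ThS time course
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `Y(t) = Y0 + A * exp(t / t_const)` to thioflavin-S fluorescence versus
#' time.  With the signed convention `A < 0`, `t_const < 0` this is an
#' exponential approach to the plateau `Y0`, which is the quantity used
#' downstream to compute percent inhibition of assembly.  Default starting
#' values: `Y0` = last observed intensity, `A` = first minus last,
#' `t_const` = minus a third of the time span.
#'
#' @param data Tibble with columns `time_min` and `intensity` (>= 8 rows).
#' @param init Optional named list with starting values `Y0`, `A`,
#'   `t_const`.
#' @param maxiter,ftol Levenberg-Marquardt iteration cap and relative
#'   tolerance (defaults 500 and 1e-10).
#' @return An object of class `exp_plateau_fit` with `Y0`, `A`, `t_const`,
#'   `rss`, `converged`, `degenerate`, `n`.  An all-constant signal yields
#'   `Y0` equal to that constant, `A = 0` and `degenerate = TRUE` without
#'   attempting a nonlinear fit.  Supports [tidy()], [glance()],
#'   [augment()] and [autoplot()].
#' @examples
#' tr <- aggregation_truth(half_inhibition_conc = 17.3, noise_cv = 0, seed = 1)
#' tc <- simulate_ths_timecourse(tr, compound_conc = 0)
#' fit_exp_plateau(tc)
#' @export
fit_exp_plateau <- function(data, init = NULL, maxiter = 500, ftol = 1e-10) {
  req <- c("time_min", "intensity")
  if (!all(req %in% names(data))) {
    abort("time-course data needs columns `time_min` and `intensity`.")
  }
  if (nrow(data) < 8) abort("time course needs at least 8 points.")
  check_increasing(data$time_min, "time_min")
  if (any(!is.finite(data$intensity)) || any(data$intensity < 0)) {
    abort("intensities must be finite and non-negative.")
  }

  y <- data$intensity
  if (diff(range(y)) == 0) {
    return(new_fit(list(Y0 = y[1L], A = 0, t_const = NA_real_, rss = 0,
                        converged = TRUE, degenerate = TRUE, n = length(y),
                        data = data), "exp_plateau_fit"))
  }

  span <- diff(range(data$time_min))
  init <- init %||% list(Y0 = y[length(y)], A = y[1L] - y[length(y)],
                         t_const = -span / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ Y0 + A * exp(time_min / t_const),
      data = data, start = init,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_fit(list(Y0 = NA_real_, A = NA_real_, t_const = NA_real_,
                        rss = NA_real_, converged = FALSE, degenerate = FALSE,
                        n = length(y), data = data), "exp_plateau_fit"))
  }
  cf <- coef(fit)
  new_fit(list(
    Y0 = unname(cf["Y0"]), A = unname(cf["A"]), t_const = unname(cf["t_const"]),
    rss = sum(stats::residuals(fit)^2),
    converged = isTRUE(fit$convInfo$isConv),
    degenerate = FALSE, n = length(y), data = data, nls = fit
  ), "exp_plateau_fit")
}

#' Plateau value of a fitted time course
#'
#' @param fit An `exp_plateau_fit`.
#' @param fallback_last_n When the fit did not converge, fall back to the
#'   mean of the last `fallback_last_n` observed points (default 3; set 0
#'   to disable the fallback and error instead).
#' @return The plateau intensity (the model's `t -> -Inf`-side asymptote
#'   `Y0` under the signed convention).
#' @export
plateau_value <- function(fit, fallback_last_n = 3) {
  stopifnot(inherits(fit, "exp_plateau_fit"))
  if (fit$converged) return(fit$Y0)
  if (fallback_last_n > 0) {
    return(mean(tail(fit$data$intensity, fallback_last_n)))
  }
  abort("plateau unavailable: fit did not converge.")
}

#' @export
tidy.exp_plateau_fit <- function(x, ...) {
  tibble::tibble(term = c("Y0", "A", "t_const"),
                 estimate = c(x$Y0, x$A, x$t_const))
}

#' @export
glance.exp_plateau_fit <- function(x, ...) {
  tibble::tibble(Y0 = x$Y0, A = x$A, t_const = x$t_const, rss = x$rss,
                 converged = x$converged, degenerate = x$degenerate, n = x$n)
}

#' @export
augment.exp_plateau_fit <- function(x, ...) {
  d <- tibble::as_tibble(x$data)
  d$.fitted <- if (x$degenerate) rep(x$Y0, nrow(d)) else
    x$Y0 + x$A * exp(d$time_min / x$t_const)
  d$.resid <- d$intensity - d$.fitted
  d
}

#' @export
autoplot.exp_plateau_fit <- function(object, ...) {
  d <- augment(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "ThS fluorescence (a.u.)",
                  title = sprintf("Exponential-plateau fit: plateau = %.4g a.u.",
                                  object$Y0))
}

#' Percent inhibition of filament assembly from plateau values
#'
#' `100 * (plateau_control - plateau_treated) / (plateau_control -
#' baseline)`, capped at 100: the treated plateau cannot report more than
#' full suppression of assembly.  The baseline is the ThS background (the
#' unassembled signal); the formula is invariant to adding a constant to
#' all three inputs.
#'
#' @param plateau_treated,plateau_control Fitted plateau intensities
#'   (a.u.); `plateau_treated` may be a vector.
#' @param baseline Background intensity (a.u.), strictly below
#'   `plateau_control`.
#' @return Percent inhibition (<= 100; negative values indicate apparent
#'   enhancement).
#' @export
inhibition_percent <- function(plateau_treated, plateau_control, baseline) {
  check_number(plateau_control, "plateau_control")
  check_number(baseline, "baseline")
  if (plateau_control <= baseline) {
    abort("`plateau_control` must exceed `baseline`.")
  }
  pmin(100, 100 * (plateau_control - plateau_treated) /
         (plateau_control - baseline))
}

#' Estimate the 50 %-inhibition concentration from a dose scatter
#'
#' Ordinary least squares of percent inhibition against `log10`
#' concentration over the sub-saturating points (values at the 100 % cap
#' are excluded: the underlying dose law is linear-then-plateau, and the
#' plateau carries no slope information); the IC50 is the concentration at
#' which the fitted line crosses 50 %:
#' `ic50 = 10^((50 - intercept) / slope)`.
#'
#' The readout is linear in concentration while the fit is linear in its
#' logarithm, so panels should bracket the 50 % point tightly (see
#' [ths_panel_concentrations()]); wide panels incur a curvature bias.
#'
#' @param data Tibble with columns `conc_uM` and `inhibition_pct` (>= 3
#'   finite rows).
#' @param literal_rule Also record the literal reading "ten raised to the
#'   power of the slope" as `ic50_literal` (always computed; this flag only
#'   promotes it to the reported `ic50`).  That reading is dimensionally
#'   inconsistent and not recommended.
#' @return An object of class `ic50_fit` with `ic50` (uM), `slope` (% per
#'   decade), `intercept`, `r_squared`, `n_points`, `n_saturated`,
#'   `ic50_literal` and `flags` (may contain `"extrapolated"` when no
#'   observed points straddle 50 %).
#' @export
estimate_ic50 <- function(data, literal_rule = FALSE) {
  req <- c("conc_uM", "inhibition_pct")
  if (!all(req %in% names(data))) {
    abort("dose data needs columns `conc_uM` and `inhibition_pct`.")
  }
  d <- data[is.finite(data$inhibition_pct) & data$conc_uM > 0, , drop = FALSE]
  if (nrow(d) < 3) abort("need at least 3 concentrations with finite inhibition.")
  sat <- d$inhibition_pct >= 100 - 1e-9
  if (all(sat)) abort("all points are saturated at 100 % inhibition; no dose response can be fitted.")
  n_saturated <- sum(sat)
  d <- d[!sat, , drop = FALSE]
  if (nrow(d) < 3) {
    abort(sprintf("only %d sub-saturating point(s); need at least 3.", nrow(d)))
  }

  fit <- lm(inhibition_pct ~ log10(conc_uM), data = d)
  slope <- unname(coef(fit)[2L]); intercept <- unname(coef(fit)[1L])
  if (slope <= 0) abort("no dose response: inhibition does not increase with concentration.")
  ic50 <- 10^((50 - intercept) / slope)
  ic50_literal <- 10^slope

  flags <- character()
  if (min(d$inhibition_pct) > 50 || max(d$inhibition_pct) < 50) {
    flags <- c(flags, "extrapolated")
  }
  new_fit(list(
    ic50 = if (literal_rule) ic50_literal else ic50,
    ic50_interpolated = ic50, ic50_literal = ic50_literal,
    slope = slope, intercept = intercept,
    r_squared = r_squared_lm(fit),
    n_points = nrow(d), n_saturated = n_saturated,
    flags = flags, points = tibble::as_tibble(d)
  ), "ic50_fit")
}

#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_points = x$n_points,
                 n_saturated = x$n_saturated,
                 flags = paste(x$flags, collapse = ";"))
}

#' @export
tidy.ic50_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope", "ic50"),
                 estimate = c(x$intercept, x$slope, x$ic50))
}

#' @export
autoplot.ic50_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = log10(.data$conc_uM),
                               y = .data$inhibition_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = "log10 concentration (uM)", y = "inhibition (%)",
                  title = sprintf("IC50 = %.3g uM", object$ic50))
}

#' Full inhibition chain for a ThS dose panel
#'
#' Fits each well's plateau, converts plateaus to percent inhibition
#' against the zero-concentration control (baseline taken as the control
#' fit's time-zero intercept `Y0 + A` by default), and estimates the IC50.
#'
#' @param panel Long tibble from [simulate_ths_panel()] or
#'   [read_ths_timecourses()]: columns `well`, `conc_uM`, `time_min`,
#'   `intensity`; must contain a `conc_uM == 0` control well.
#' @param baseline Optional explicit ThS background (a.u.); default NULL
#'   uses the control fit's time-zero intercept.
#' @param ... Passed to [estimate_ic50()].
#' @return A list with `ic50_fit` (class `ic50_fit`), `plateaus` (per-well
#'   tibble) and `baseline`.
#' @export
ths_inhibition_analysis <- function(panel, baseline = NULL, ...) {
  if (!any(panel$conc_uM == 0)) {
    abort("panel must contain a `conc_uM == 0` control well.")
  }
  fits <- panel |>
    dplyr::group_by(.data$well, .data$conc_uM) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(fit = purrr::map(.data$data, fit_exp_plateau),
                  plateau = purrr::map_dbl(.data$fit, plateau_value))
  control <- fits[fits$conc_uM == 0, ]
  plateau_control <- control$plateau[1L]
  ctrl_fit <- control$fit[[1L]]
  baseline <- baseline %||%
    (if (ctrl_fit$degenerate) min(panel$intensity) else ctrl_fit$Y0 + ctrl_fit$A)
  treated <- fits[fits$conc_uM > 0, ]
  curve <- tibble::tibble(
    conc_uM = treated$conc_uM,
    inhibition_pct = inhibition_percent(treated$plateau, plateau_control,
                                        baseline)
  )
  list(
    ic50_fit = estimate_ic50(curve, ...),
    plateaus = dplyr::select(fits, "well", "conc_uM", "plateau"),
    baseline = baseline
  )
}

#' Dissolution trend of a preformed-filament time course
#'
#' For assays that start from mature filaments near plateau: OLS slope of
#' intensity against time, the total relative decrease along the fitted
#' line, and a classification into `"dissolving"` / `"stable"` by a sign
#' test on successive intensity differences.
#'
#' @param data Tibble with columns `time_min`, `intensity` (>= 8 rows).
#' @param alpha Significance level of the sign test (default 0.05).
#' @return A tibble with `slope` (a.u./min), `relative_drop_pct` (% of the
#'   initial fitted level lost over the record; positive = decreasing),
#'   `p_value`, `classification`.
#' @export
dissolution_trend <- function(data, alpha = 0.05) {
  if (!all(c("time_min", "intensity") %in% names(data))) {
    abort("time-course data needs columns `time_min` and `intensity`.")
  }
  if (nrow(data) < 8) abort("too few points for a trend (need >= 8).")
  fit <- lm(intensity ~ time_min, data = data)
  pr <- predict(fit, newdata = data.frame(time_min = range(data$time_min)))
  rel_drop <- 100 * (pr[1L] - pr[2L]) / pr[1L]
  dd <- diff(data$intensity)
  dd <- dd[dd != 0]
  p <- if (length(dd) == 0) 1 else
    binom.test(sum(dd < 0), length(dd), alternative = "greater")$p.value
  tibble::tibble(
    slope = unname(coef(fit)[2L]),
    relative_drop_pct = unname(rel_drop),
    p_value = p,
    classification = if (p < alpha && unname(coef(fit)[2L]) < 0) "dissolving" else "stable"
  )
}
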