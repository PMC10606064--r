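#' Normalise raw MTT absorbances to viability fractions
#'
#' Viability at each dose is the blank-corrected mean treated absorbance
#' over the blank-corrected mean untreated absorbance.  Replicate wells
#' are averaged before the ratio is taken.  Values are clipped to
#' [0, 1.5]; doses with viability above 1 (apparent stimulation) are
#' flagged so the median-effect fit can exclude them.
#'
#' @param data Tibble with columns `dose_uM` (0 marks untreated wells),
#'   `absorbance`, and optionally `compound`, `cell_line`, `replicate`.
#' @param blank Blank absorbance (default 0); must not exceed the smallest
#'   well mean.
#' @return A tibble with one row per compound x cell line x positive dose:
#'   `dose_uM`, `viability`, `flag_stimulated`.
#' @export
normalize_plate <- function(data, blank = 0) {
  req <- c("dose_uM", "absorbance")
  if (!all(req %in% names(data))) {
    abort("plate data needs columns `dose_uM` and `absorbance`.")
  }
  if (!any(data$dose_uM == 0)) abort("plate needs untreated wells (dose_uM == 0).")
  grp <- intersect(c("compound", "cell_line"), names(data))
  means <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "dose_uM")))) |>
    dplyr::summarise(mean_abs = mean(.data$absorbance), .groups = "drop")
  out <- means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(g, key) {
      untreated <- g$mean_abs[g$dose_uM == 0]
      if (!length(untreated)) abort("a plate group lacks untreated wells.")
      u <- mean(untreated)
      if (u <= blank) abort("untreated absorbance must exceed the blank.")
      t <- g[g$dose_uM > 0, , drop = FALSE]
      v <- (t$mean_abs - blank) / (u - blank)
      tibble::tibble(dose_uM = t$dose_uM,
                     viability = pmin(1.5, pmax(0, v)),
                     flag_stimulated = v > 1)
    }) |>
    dplyr::ungroup()
  out
}

#' Chou-Talalay median-effect fit of a dose-response
#'
#' Linearises the median-effect equation `fa/fu = (D/Dm)^m` (with affected
#' fraction `fa = 1 - viability` and unaffected fraction `fu = viability`)
#' as `log10(fa/fu) = m log10(D) - m log10(Dm)` and fits it by ordinary
#' least squares.  `Dm` is the 50 %-effect dose, i.e. the IC50.  Doses
#' whose viability is at or beyond the 0/1 limits carry no information on
#' the ratio and are excluded (clipping them would fabricate dynamic
#' range); the number excluded is reported.
#'
#' @param data Tibble with columns `dose_uM` and `viability`.
#' @return An object of class `median_effect_fit` with `m`, `Dm` (uM),
#'   `se_m`, `se_Dm` (delta method), `r_squared`, `n_points`,
#'   `n_excluded`.  Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' dr <- simulate_viability(m = 1, Dm = 1.6, doses = 0.2 * 2^(0:6), seed = 1)
#' fit_median_effect(dr)
#' @export
fit_median_effect <- function(data) {
  req <- c("dose_uM", "viability")
  if (!all(req %in% names(data))) {
    abort("dose-response data needs columns `dose_uM` and `viability`.")
  }
  usable <- data$viability > 0 & data$viability < 1 & data$dose_uM > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "fit_median_effect: excluded %d dose(s) with viability at or beyond the (0, 1) limits.",
      n_excluded))
  }
  d <- data[usable, , drop = FALSE]
  if (nrow(d) < 3) {
    abort("insufficient dynamic range: fewer than 3 doses with viability strictly inside (0, 1).")
  }
  x <- log10(d$dose_uM)
  y <- log10((1 - d$viability) / d$viability)
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2L]); b0 <- unname(coef(fit)[1L])
  if (m <= 0) abort("no dose response: median-effect slope is not positive.")
  Dm <- 10^(-b0 / m)
  vc <- suppressWarnings(vcov(fit))  # perfect fits are a designed use
  # delta method on Dm = 10^(-b0/m)
  g <- Dm * log(10) * c(-1 / m, b0 / m^2)
  se_Dm <- sqrt(max(0, g[1]^2 * vc[1, 1] + g[2]^2 * vc[2, 2] +
                      2 * g[1] * g[2] * vc[1, 2]))
  new_fit(list(
    m = m, Dm = Dm, se_m = sqrt(vc[2, 2]), se_Dm = se_Dm,
    r_squared = r_squared_lm(fit),
    n_points = nrow(d), n_excluded = n_excluded,
    points = tibble::tibble(dose_uM = d$dose_uM, viability = d$viability,
                            log10_dose = x, log10_fa_fu = y)
  ), "median_effect_fit")
}

#' @export
tidy.median_effect_fit <- function(x, ...) {
  tibble::tibble(term = c("m", "Dm"),
                 estimate = c(x$m, x$Dm),
                 std.error = c(x$se_m, x$se_Dm))
}

#' @export
glance.median_effect_fit <- function(x, ...) {
  tibble::tibble(m = x$m, Dm = x$Dm, ic50 = x$Dm, r_squared = x$r_squared,
                 n_points = x$n_points, n_excluded = x$n_excluded)
}

#' @export
autoplot.median_effect_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$log10_dose, y = .data$log10_fa_fu)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = -object$m * log10(object$Dm),
                         slope = object$m, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = log10(object$Dm), linetype = "dashed") +
    ggplot2::labs(x = "log10 dose (uM)", y = "log10(fa/fu)",
                  title = sprintf("Median-effect fit: m = %.3g, Dm = %.3g uM",
                                  object$m, object$Dm))
}
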