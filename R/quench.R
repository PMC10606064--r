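#' Inner-filter correction of observed fluorescence
#'
#' Undoes the attenuation of the recorded signal by sample absorbance at
#' the excitation and emission wavelengths:
#' `F = F_obs * exp((A_ex + A_em) / 2)` (Lakowicz correction).  Vectorised;
#' the correction is the exact inverse of the attenuation applied by
#' [simulate_titration()].
#'
#' @param F_obs Observed intensity (> 0).
#' @param A_ex,A_em Absorbances at the excitation and emission wavelengths
#'   (>= 0).
#' @return Corrected intensity, monotone increasing in each absorbance.
#' @export
inner_filter_correct <- function(F_obs, A_ex = 0, A_em = 0) {
  if (any(F_obs <= 0)) abort("`F_obs` must be positive.")
  if (any(A_ex < 0) || any(A_em < 0)) abort("absorbances must be non-negative.")
  F_obs * exp((A_ex + A_em) / 2)
}

# Validate a titration table and return it with a corrected-intensity
# column `F` plus attributes F0 / corrected flag.
prepare_titration <- function(data, inner_filter = TRUE) {
  req <- c("conc_M", "F_obs")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(sprintf("titration data lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) < 4) abort("titration needs at least 4 points.")
  check_increasing(data$conc_M, "conc_M")
  if (!any(data$conc_M == 0)) {
    abort("titration must include a [Q] = 0 reference point.")
  }
  if (any(data$F_obs <= 0)) abort("intensities must be positive.")

  has_abs <- all(c("A_ex", "A_em") %in% names(data))
  corrected <- inner_filter && has_abs
  f <- if (corrected) {
    inner_filter_correct(data$F_obs, data$A_ex, data$A_em)
  } else {
    data$F_obs
  }
  data$F_corr <- f
  attr(data, "corrected") <- corrected
  data
}

#' Transform a titration to modified Stern-Volmer coordinates
#'
#' Computes the points `(1/[Q], F0 / dF)` with `dF = F0 - F`, where `F0` is
#' the (inner-filter-corrected, when absorbance columns are present)
#' intensity of the ligand-free reference.  In these coordinates the
#' two-population quench model is the straight line
#' `F0/dF = 1/(f_a K) * (1/[Q]) + 1/f_a`.
#'
#' @param data Titration tibble with columns `conc_M`, `F_obs` and
#'   optionally `A_ex`, `A_em`; must contain a `conc_M == 0` row.
#' @param inner_filter Apply the inner-filter correction when absorbance
#'   columns are present (default TRUE).
#' @return A tibble with columns `conc_M`, `inv_conc`, `F0_over_dF`.  The
#'   `[Q] = 0` row is excluded (its abscissa is undefined) and rows with
#'   `dF <= 0` (no apparent quench, e.g. noise at low [Q]) are dropped;
#'   attributes `F0`, `n_dropped` and `corrected` record the reference
#'   intensity, the number of dropped points and whether the correction
#'   was applied.
#' @export
stern_volmer_points <- function(data, inner_filter = TRUE) {
  data <- prepare_titration(data, inner_filter)
  F0 <- data$F_corr[data$conc_M == 0][1L]
  pts <- data[data$conc_M > 0, , drop = FALSE]
  dF <- F0 - pts$F_corr
  usable <- dF > 0
  n_dropped <- sum(!usable)
  if (sum(usable) < 3) {
    abort(sprintf(
      "fit not possible: only %d usable point(s) with positive quench (dF > 0) — no quench.",
      sum(usable)))
  }
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "stern_volmer_points: dropped %d point(s) with dF <= 0.", n_dropped))
  }
  out <- tibble::tibble(
    conc_M = pts$conc_M[usable],
    inv_conc = 1 / pts$conc_M[usable],
    F0_over_dF = F0 / dF[usable]
  )
  attr(out, "F0") <- F0
  attr(out, "n_dropped") <- n_dropped
  attr(out, "corrected") <- attr(data, "corrected")
  out
}

#' Fit the modified Stern-Volmer model to a titration
#'
#' Ordinary least squares on the transformed points `(1/[Q], F0/dF)`; the
#' intercept is `1/f_a` and the slope is `1/(f_a K)`, so
#' `f_a = 1/intercept`, `K = intercept/slope` and the dissociation constant
#' `K_D = slope/intercept = 1/K`.  This is the graphical procedure used
#' with tyrosine-quenching titrations of Tau; the reciprocal transform
#' inflates the variance of low-concentration points, and the fit is
#' deliberately unweighted to match that procedure.  Standard errors of
#' `f_a` and `K_D` are propagated from the coefficient covariance by the
#' delta method.
#'
#' @inheritParams stern_volmer_points
#' @param linearity_min Minimum r-squared below which the fit is flagged
#'   `"nonlinear"` (default 0.95): strongly curved modified Stern-Volmer
#'   plots preclude a meaningful two-population interpretation.
#' @return An object of class `svq_fit` with elements `f_a`, `K`, `K_D`,
#'   `intercept`, `slope`, their standard errors, `r_squared`, `n_points`,
#'   `n_dropped`, `flags` (character: any of `"fa_above_one"`,
#'   `"uncorrected"`, `"nonlinear"`).  Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' tr <- quench_truth(f_a = 0.12, K = 1 / 2.4e-6, noise_cv = 0, seed = 1)
#' ti <- simulate_titration(tr, c(0, 2, 5, 10, 20, 50, 100) * 1e-6)
#' fit_modified_stern_volmer(ti)
#' @export
fit_modified_stern_volmer <- function(data, inner_filter = TRUE,
                                      linearity_min = 0.95) {
  pts <- stern_volmer_points(data, inner_filter)
  fit <- lm(F0_over_dF ~ inv_conc, data = pts)
  b <- coef(fit)
  intercept <- unname(b[1L]); slope <- unname(b[2L])
  if (intercept <= 0 || slope <= 0) {
    abort("non-physical fit: intercept and slope of the modified Stern-Volmer line must both be positive.")
  }
  vc <- suppressWarnings(vcov(fit))  # perfect fits are a designed use
  se_int <- sqrt(vc[1L, 1L]); se_slope <- sqrt(vc[2L, 2L])
  cov_is <- vc[1L, 2L]
  f_a <- 1 / intercept
  K_D <- slope / intercept
  # delta method: f_a = 1/i; K_D = s/i
  se_fa <- se_int / intercept^2
  grad <- c(-slope / intercept^2, 1 / intercept)
  se_KD <- sqrt(max(0, grad[1]^2 * vc[1, 1] + grad[2]^2 * vc[2, 2] +
                      2 * grad[1] * grad[2] * cov_is))
  r2 <- r_squared_lm(fit)

  flags <- character()
  if (f_a > 1) flags <- c(flags, "fa_above_one")
  if (!attr(pts, "corrected")) flags <- c(flags, "uncorrected")
  if (r2 < linearity_min) flags <- c(flags, "nonlinear")
  if ("fa_above_one" %in% flags) {
    warn(sprintf("fitted accessible fraction f_a = %.3g exceeds 1; result flagged.", f_a))
  }

  new_fit(list(
    f_a = f_a, K = intercept / slope, K_D = K_D,
    intercept = intercept, slope = slope,
    se_f_a = se_fa, se_K_D = se_KD,
    se_intercept = se_int, se_slope = se_slope,
    r_squared = r2, n_points = nrow(pts),
    n_dropped = attr(pts, "n_dropped"),
    corrected = attr(pts, "corrected"),
    flags = flags, points = pts, lm = fit
  ), "svq_fit")
}

#' Fit the regular (single-population) Stern-Volmer model
#'
#' OLS of `F0/F` against `[Q]`, both with a free intercept and with the
#' intercept fixed at its theoretical value 1.  Used as the linearity
#' diagnostic: heterogeneously accessible fluorophores make this plot
#' curved, motivating the modified (two-population) analysis.
#'
#' @inheritParams stern_volmer_points
#' @return An object of class `sv_fit` with `K_free`, `intercept_free`,
#'   `K_fixed`, `r_squared` (free fit) and `n_points`.
#' @export
fit_regular_stern_volmer <- function(data, inner_filter = TRUE) {
  data <- prepare_titration(data, inner_filter)
  F0 <- data$F_corr[data$conc_M == 0][1L]
  pts <- data[data$conc_M > 0, , drop = FALSE]
  y <- F0 / pts$F_corr
  if (all(abs(y - 1) < 1e-12)) abort("no quench: F0/F is 1 at every concentration.")
  fit_free <- lm(y ~ conc_M, data = cbind(pts, y = y))
  fit_fixed <- lm(I(y - 1) ~ 0 + conc_M, data = cbind(pts, y = y))
  slope_free <- unname(coef(fit_free)[2L])
  if (slope_free <= 0) abort("no quench: Stern-Volmer slope is not positive.")
  new_fit(list(
    K_free = slope_free,
    intercept_free = unname(coef(fit_free)[1L]),
    K_fixed = unname(coef(fit_fixed)[1L]),
    r_squared = r_squared_lm(fit_free),
    n_points = nrow(pts)
  ), "sv_fit")
}

#' Nonlinear two-population quench fit (cross-check)
#'
#' Direct nonlinear least squares of the two-population quench model
#' `F([Q]) = f_a F0 / (1 + K [Q]) + (1 - f_a) F0` on the corrected
#' intensities.  Provided as an independent cross-check of the linear
#' transform estimate of [fit_modified_stern_volmer()]; the linear
#' transform is the reference procedure.
#'
#' @inheritParams stern_volmer_points
#' @param start Optional named list with starting values `f_a`, `K`.
#' @return A list with `f_a`, `K`, `K_D`, `converged`.
#' @export
fit_quench_nls <- function(data, inner_filter = TRUE, start = NULL) {
  data <- prepare_titration(data, inner_filter)
  F0 <- data$F_corr[data$conc_M == 0][1L]
  start <- start %||% list(f_a = 0.5, K = 1 / stats::median(data$conc_M[data$conc_M > 0]))
  fit <- minpack.lm::nlsLM(
    F_corr ~ f_a * F0 / (1 + K * conc_M) + (1 - f_a) * F0,
    data = data, start = start,
    lower = c(f_a = 1e-6, K = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- coef(fit)
  list(f_a = unname(cf["f_a"]), K = unname(cf["K"]),
       K_D = 1 / unname(cf["K"]), converged = fit$convInfo$isConv)
}

#' @export
tidy.svq_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope", "f_a", "K_D"),
    estimate = c(x$intercept, x$slope, x$f_a, x$K_D),
    std.error = c(x$se_intercept, x$se_slope, x$se_f_a, x$se_K_D)
  )
}

#' @export
glance.svq_fit <- function(x, ...) {
  tibble::tibble(
    f_a = x$f_a, K = x$K, K_D = x$K_D, r_squared = x$r_squared,
    n_points = x$n_points, n_dropped = x$n_dropped,
    corrected = x$corrected,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @export
glance.sv_fit <- function(x, ...) {
  tibble::tibble(K_free = x$K_free, intercept_free = x$intercept_free,
                 K_fixed = x$K_fixed, r_squared = x$r_squared,
                 n_points = x$n_points)
}

#' Diagnostic plot of a modified Stern-Volmer fit
#'
#' @param object An `svq_fit`.
#' @param ... Ignored.
#' @return A ggplot: transformed points with the fitted line; the
#'   y-intercept is `1/f_a`.
#' @export
autoplot.svq_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$inv_conc, y = .data$F0_over_dF)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression(1 / "[Q]" ~ (M^-1)),
      y = expression(F[0] / Delta * F),
      title = sprintf("Modified Stern-Volmer: f_a = %.3g, K_D = %.3g M",
                      object$f_a, object$K_D)
    )
}
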