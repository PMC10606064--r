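#' Ground truth for a fluorescence-quenching titration
#'
#' Describes a two-population quench model of intrinsic (tyrosine) protein
#' fluorescence: a fraction `f_a` of the unquenched signal is accessible to
#' the ligand and follows Stern-Volmer quenching with association constant
#' `K`, while the remaining `1 - f_a` is buried and unquenched.  The
#' simulated instrument signal is additionally attenuated by the
#' inner-filter effect of total sample absorbance at the excitation and
#' emission wavelengths.
#'
#' @param f_a Accessible fraction of the unquenched fluorescence, in (0, 1].
#' @param K Stern-Volmer association constant (M^-1); the dissociation
#'   constant of the complex is `1/K`.
#' @param F0_total Unquenched total intensity (arbitrary units).
#' @param protein_conc Protein concentration (M).  Default 5e-6 M, a typical
#'   titration concentration for recombinant Tau.
#' @param eps_ex_compound,eps_em_compound Ligand extinction coefficients
#'   (M^-1 cm^-1) at the excitation and emission wavelengths; their product
#'   with `path_length` and ligand concentration drives the inner-filter
#'   attenuation.  Default 0 (no inner filter).
#' @param eps_ex_protein,eps_em_protein Protein extinction coefficients
#'   (M^-1 cm^-1).  Default 7700 at excitation (the Tau value near 280 nm)
#'   and 0 at the 303 nm tyrosine emission.
#' @param path_length Cuvette path length (cm).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   measurement noise.  Default 0.02 (2 %), a typical spectrofluorometer
#'   repeatability; set 0 for noiseless data.
#' @param seed Integer RNG seed (mandatory; generators never touch global
#'   RNG state).
#' @return A `quench_truth` list.
#' @seealso [simulate_titration()]
#' @export
quench_truth <- function(f_a, K, F0_total = 1e6, protein_conc = 5e-6,
                         eps_ex_compound = 0, eps_em_compound = 0,
                         eps_ex_protein = 7700, eps_em_protein = 0,
                         path_length = 1, noise_cv = 0.02, seed) {
  check_number(f_a, "f_a", 0, 1, strict_lower = TRUE)
  check_number(K, "K", 0, strict_lower = TRUE)
  check_number(F0_total, "F0_total", 0, strict_lower = TRUE)
  check_number(protein_conc, "protein_conc", 0)
  check_number(eps_ex_compound, "eps_ex_compound", 0)
  check_number(eps_em_compound, "eps_em_compound", 0)
  check_number(path_length, "path_length", 0, strict_lower = TRUE)
  check_number(noise_cv, "noise_cv", 0)
  structure(
    list(f_a = f_a, K = K, F0_total = F0_total, protein_conc = protein_conc,
         eps_ex_compound = eps_ex_compound, eps_em_compound = eps_em_compound,
         eps_ex_protein = eps_ex_protein, eps_em_protein = eps_em_protein,
         path_length = path_length, noise_cv = noise_cv,
         seed = check_seed(seed)),
    class = "quench_truth"
  )
}

#' Simulate a fluorescence-quenching titration
#'
#' Generates the observed intensity of a protein titrated with increasing
#' ligand (quencher) concentrations.  The true signal follows the
#' two-population quench model
#' `F([Q]) = f_a * F0 / (1 + K * [Q]) + (1 - f_a) * F0`; absorbances grow
#' linearly with ligand concentration on top of the constant protein
#' contribution, and the recorded signal is attenuated by
#' `exp(-(A_ex + A_em) / 2)` — the exact inverse of the inner-filter
#' correction applied at analysis time.
#'
#' @param truth A [quench_truth()] object.
#' @param concentrations Ligand concentrations (M), non-negative and
#'   strictly increasing; the first element may (and for downstream fitting
#'   must) be 0.
#' @param compound Label carried into the output.
#' @return A tibble with columns `compound`, `conc_M`, `F_obs`, `A_ex`,
#'   `A_em` and the noiseless pre-attenuation intensity `F_true`.
#' @examples
#' tr <- quench_truth(f_a = 0.12, K = 1 / 2.4e-6, noise_cv = 0, seed = 1)
#' simulate_titration(tr, c(0, 1, 2, 5, 10, 20) * 1e-6)
#' @export
simulate_titration <- function(truth, concentrations, compound = "compound") {
  stopifnot(inherits(truth, "quench_truth"))
  conc <- as.numeric(concentrations)
  if (any(conc < 0)) abort("`concentrations` must be non-negative.")
  if (anyDuplicated(conc)) abort("duplicate concentrations are not allowed.")
  check_increasing(conc, "concentrations")

  F_true <- truth$f_a * truth$F0_total / (1 + truth$K * conc) +
    (1 - truth$f_a) * truth$F0_total
  A_ex <- truth$path_length *
    (truth$eps_ex_protein * truth$protein_conc + truth$eps_ex_compound * conc)
  A_em <- truth$path_length *
    (truth$eps_em_protein * truth$protein_conc + truth$eps_em_compound * conc)
  F_att <- F_true * exp(-(A_ex + A_em) / 2)
  F_obs <- apply_cv_noise(F_att, truth$noise_cv, truth$seed)

  tibble::tibble(compound = compound, conc_M = conc, F_obs = F_obs,
                 A_ex = A_ex, A_em = A_em, F_true = F_true)
}

#' Ground truth for a thioflavin-S aggregation experiment
#'
#' Encodes the empirical behaviour of heparin-induced Tau filament assembly
#' followed by ThS fluorescence: an exponential approach from `baseline` to
#' a plateau with time constant `tau_rise`, where the plateau is depressed
#' by the compound according to a linear-then-saturating dose law —
#' inhibition grows linearly with the ligand concentration, reaching 50 %
#' at `half_inhibition_conc` and capping at 100 % (full suppression of
#' assembly) at twice that concentration.
#'
#' @param half_inhibition_conc Compound concentration (uM) halving the
#'   assembled plateau.
#' @param plateau_control Untreated plateau intensity (a.u.).
#' @param baseline ThS background intensity (a.u.), also the time-zero
#'   signal.
#' @param tau_rise Assembly time constant (min).  Default 120 min, placing
#'   plateau attainment at roughly 8 h as observed for heparin-induced
#'   full-length Tau.
#' @param tau_conc Tau concentration (uM); default 2 uM, the assay
#'   condition.
#' @param noise_cv Multiplicative noise CV (default 2 %).
#' @param seed Integer RNG seed.
#' @return An `aggregation_truth` list.  The derived field
#'   `full_inhibition_ratio` gives the ligand/Tau ratio at which inhibition
#'   saturates.
#' @export
aggregation_truth <- function(half_inhibition_conc, plateau_control = 1000,
                              baseline = 50, tau_rise = 120, tau_conc = 2,
                              noise_cv = 0.02, seed) {
  check_number(half_inhibition_conc, "half_inhibition_conc", 0, strict_lower = TRUE)
  check_number(plateau_control, "plateau_control", 0, strict_lower = TRUE)
  check_number(baseline, "baseline", 0)
  if (plateau_control <= baseline) {
    abort("`plateau_control` must exceed `baseline`.")
  }
  check_number(tau_rise, "tau_rise", 0, strict_lower = TRUE)
  check_number(tau_conc, "tau_conc", 0, strict_lower = TRUE)
  check_number(noise_cv, "noise_cv", 0)
  structure(
    list(half_inhibition_conc = half_inhibition_conc,
         plateau_control = plateau_control, baseline = baseline,
         tau_rise = tau_rise, tau_conc = tau_conc,
         full_inhibition_ratio = 2 * half_inhibition_conc / tau_conc,
         noise_cv = noise_cv, seed = check_seed(seed)),
    class = "aggregation_truth"
  )
}

#' Default ThS plate-reader time grid
#'
#' Reads every 15 min for 8.75 h: 36 time points starting at 0.
#'
#' @return Numeric vector of times (min).
#' @export
ths_time_grid <- function() seq(0, by = 15, length.out = 36)

# Linear-then-saturating dose law: percent inhibition of plateau assembly.
dose_inhibition <- function(conc, half_inhibition_conc) {
  pmin(100, 50 * conc / half_inhibition_conc)
}

#' Simulate one ThS aggregation time course
#'
#' The noiseless signal is
#' `Y(t) = plateau(C) - (plateau(C) - baseline) * exp(-t / tau_rise)`, with
#' `plateau(C)` depressed from the control plateau according to the linear
#' dose law of [aggregation_truth()].
#'
#' @param truth An [aggregation_truth()] object.
#' @param compound_conc Compound concentration (uM, >= 0).
#' @param times Time grid (min), non-negative increasing; defaults to
#'   [ths_time_grid()].
#' @param compound,well Labels carried into the output.
#' @return A tibble with columns `well`, `compound`, `conc_uM`, `time_min`,
#'   `intensity`.
#' @export
simulate_ths_timecourse <- function(truth, compound_conc,
                                    times = ths_time_grid(),
                                    compound = "compound", well = NULL) {
  stopifnot(inherits(truth, "aggregation_truth"))
  check_number(compound_conc, "compound_conc", 0)
  times <- as.numeric(times)
  if (any(times < 0)) abort("`times` must be non-negative.")
  check_increasing(times, "times")

  inh <- dose_inhibition(compound_conc, truth$half_inhibition_conc)
  plateau <- truth$baseline +
    (truth$plateau_control - truth$baseline) * (1 - inh / 100)
  y <- plateau - (plateau - truth$baseline) * exp(-times / truth$tau_rise)
  # sub-seed per concentration so wells of one panel have independent noise
  sub_seed <- (truth$seed + round(1e3 * compound_conc)) %% .Machine$integer.max
  y <- apply_cv_noise(y, truth$noise_cv, sub_seed)

  well <- well %||% sprintf("%s_%g", compound, compound_conc)
  tibble::tibble(well = well, compound = compound, conc_uM = compound_conc,
                 time_min = times, intensity = y)
}

#' Simulate a ThS dose panel
#'
#' One control well (no compound) plus one well per concentration, all on a
#' common time grid, bound into one long tibble.
#'
#' @inheritParams simulate_ths_timecourse
#' @param concentrations Compound concentrations (uM, > 0).
#' @export
simulate_ths_panel <- function(truth, concentrations,
                               times = ths_time_grid(),
                               compound = "compound") {
  concs <- c(0, sort(as.numeric(concentrations)))
  purrr::map_dfr(concs, function(cc) {
    simulate_ths_timecourse(truth, cc, times = times, compound = compound)
  })
}

#' Recommended concentration panel for log-linear IC50 estimation
#'
#' The percent-inhibition readout is linear in concentration, yet the IC50
#' is read off an ordinary least-squares line fitted against `log10`
#' concentration.  That mismatch carries a curvature bias that grows
#' quadratically with the width of the panel on the log axis: points placed
#' far from the 50 % point systematically pull the fitted crossing away
#' from it.  Concentrations log-symmetric within +/- 0.1 decade of the
#' anticipated half-inhibition point keep the bias near 1 %, which is why
#' this bracket is the package default for recovery-grade panels.
#'
#' @param anticipated_ic50 Centre of the bracket (uM).
#' @param n Number of concentrations (default 6).
#' @param span_decades Total width on the log10 axis (default 0.2, i.e.
#'   +/- 0.1 decade).
#' @return Numeric vector of concentrations (uM).
#' @export
ths_panel_concentrations <- function(anticipated_ic50, n = 6,
                                     span_decades = 0.2) {
  check_number(anticipated_ic50, "anticipated_ic50", 0, strict_lower = TRUE)
  anticipated_ic50 * 10^seq(-span_decades / 2, span_decades / 2,
                            length.out = n)
}

#' Simulate an MTT viability dose-response
#'
#' Viability follows the median-effect model: the affected fraction is
#' `fa(D) = 1 / (1 + (Dm / D)^m)` and viability is `1 - fa`, so viability
#' is exactly 0.5 at `D = Dm`.
#'
#' @param m Median-effect slope (> 0; 1 corresponds to a simple
#'   mass-action dose-effect).
#' @param Dm Median-effect dose, i.e. the IC50 (uM, > 0).
#' @param doses Doses (uM, > 0), strictly increasing.
#' @param noise_cv Multiplicative noise CV applied to viability, which is
#'   then clipped to [0, 1].
#' @param seed Integer RNG seed.
#' @param compound,cell_line Labels carried into the output.
#' @return A tibble with columns `compound`, `cell_line`, `dose_uM`,
#'   `viability`.
#' @export
simulate_viability <- function(m, Dm, doses, noise_cv = 0, seed,
                               compound = "compound", cell_line = "cells") {
  check_number(m, "m", 0, strict_lower = TRUE)
  check_number(Dm, "Dm", 0, strict_lower = TRUE)
  doses <- as.numeric(doses)
  if (any(doses <= 0)) abort("`doses` must be positive.")
  check_increasing(doses, "doses")
  check_number(noise_cv, "noise_cv", 0)
  seed <- check_seed(seed)

  fa <- 1 / (1 + (Dm / doses)^m)
  v <- apply_cv_noise(1 - fa, noise_cv, seed)
  tibble::tibble(compound = compound, cell_line = cell_line,
                 dose_uM = doses, viability = pmin(1, pmax(0, v)))
}

#' Ground truth for simulated cell-migration tracks
#'
#' Parameters of a persistent random walk: headings evolve by
#' wrapped-Gaussian increments whose variance is `2 * dt / persistence_time`,
#' giving step-to-step direction correlation `exp(-dt / persistence_time)`;
#' step lengths are `mean_speed * dt`, either exact (`step_shape = Inf`) or
#' gamma-distributed with shape `step_shape` around that mean.
#'
#' @param mean_speed Mean instantaneous speed (um/min).
#' @param persistence_time Direction decorrelation time (min); `Inf` gives
#'   straight-line motion.
#' @param n_frames Frames per track (default 61).
#' @param total_time Experiment duration (min, default 600).
#' @param step_shape Gamma shape of step-length noise (default 4, i.e. a
#'   50 % per-step CV typical of single-cell speed fluctuation); `Inf` for
#'   noiseless steps.
#' @param seed Integer RNG seed.
#' @export
motility_truth <- function(mean_speed, persistence_time, n_frames = 61,
                           total_time = 600, step_shape = 4, seed) {
  check_number(mean_speed, "mean_speed", 0)
  if (!(is.numeric(persistence_time) && length(persistence_time) == 1L &&
        persistence_time > 0)) {
    abort("`persistence_time` must be a single positive number (Inf allowed).")
  }
  if (!is.numeric(n_frames) || n_frames < 2) abort("`n_frames` must be >= 2.")
  check_number(total_time, "total_time", 0, strict_lower = TRUE)
  if (!(is.numeric(step_shape) && (is.infinite(step_shape) || step_shape > 0))) {
    abort("`step_shape` must be positive or Inf.")
  }
  structure(
    list(mean_speed = mean_speed, persistence_time = persistence_time,
         n_frames = as.integer(n_frames), total_time = total_time,
         step_shape = step_shape, seed = check_seed(seed)),
    class = "motility_truth"
  )
}

#' Simulate persistent-random-walk cell tracks
#'
#' @param truth A [motility_truth()] object.
#' @param n_cells Number of tracks (>= 1).
#' @param group Optional group label column value.
#' @return A tibble with columns `track_id`, `frame`, `time_min`, `x_um`,
#'   `y_um` (and `group` when supplied), `n_frames` rows per track at
#'   uniform intervals spanning `total_time`.
#' @export
simulate_tracks <- function(truth, n_cells, group = NULL) {
  stopifnot(inherits(truth, "motility_truth"))
  if (!is.numeric(n_cells) || n_cells < 1) abort("`n_cells` must be >= 1.")
  n_cells <- as.integer(n_cells)
  nf <- truth$n_frames
  dt <- truth$total_time / (nf - 1)
  n_steps <- nf - 1L
  heading_sd <- sqrt(2 * dt / truth$persistence_time)

  id_prefix <- if (is.null(group)) "track" else as.character(group)
  tracks <- withr::with_seed(truth$seed, {
    purrr::map_dfr(seq_len(n_cells), function(i) {
      theta0 <- runif(1, 0, 2 * pi)
      dtheta <- if (is.finite(truth$persistence_time)) {
        rnorm(n_steps, 0, heading_sd)
      } else {
        rep(0, n_steps)
      }
      theta <- theta0 + cumsum(dtheta)
      len <- if (is.infinite(truth$step_shape)) {
        rep(truth$mean_speed * dt, n_steps)
      } else if (truth$mean_speed == 0) {
        rep(0, n_steps)
      } else {
        rgamma(n_steps, shape = truth$step_shape,
               scale = truth$mean_speed * dt / truth$step_shape)
      }
      tibble::tibble(
        track_id = sprintf("%s_%03d", id_prefix, i),
        frame = seq_len(nf),
        time_min = (seq_len(nf) - 1) * dt,
        x_um = c(0, cumsum(len * cos(theta))),
        y_um = c(0, cumsum(len * sin(theta)))
      )
    })
  })
  if (!is.null(group)) tracks$group <- group
  tracks
}

#' Ground truth for a synthetic two-channel cell image
#'
#' Describes a single-cell field: the actin channel delineates a disk-shaped
#' cell occupying `cell_mask_fraction` of the frame, and the tubulin channel
#' carries a filament-like foreground covering exactly
#' `mt_coverage_of_cell` of the cell mask, at `fg_intensity` over a
#' `bg_intensity` background, plus additive Gaussian noise.
#'
#' @param width,height Frame size in pixels (>= 64).
#' @param cell_mask_fraction Fraction of the frame occupied by the cell
#'   disk (the disk must fit inside the frame).
#' @param mt_coverage_of_cell Fraction of the cell mask covered by the
#'   microtubule foreground, in (0, 1].
#' @param fg_intensity,bg_intensity Foreground/background intensities
#'   (a.u.), `fg_intensity > bg_intensity`.
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.).
#' @param n_filaments Number of straight filament segments used to shape
#'   the tubulin foreground.
#' @param seed Integer RNG seed.
#' @export
image_truth <- function(width = 256, height = 256, cell_mask_fraction = 0.35,
                        mt_coverage_of_cell, fg_intensity = 200,
                        bg_intensity = 50, noise_sd = 0, n_filaments = 30,
                        seed) {
  if (width < 64 || height < 64) abort("image must be at least 64 x 64 pixels.")
  check_number(cell_mask_fraction, "cell_mask_fraction", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(mt_coverage_of_cell, "mt_coverage_of_cell", 0, 1,
               strict_lower = TRUE)
  if (fg_intensity <= bg_intensity) {
    abort("`fg_intensity` must exceed `bg_intensity`.")
  }
  check_number(noise_sd, "noise_sd", 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         cell_mask_fraction = cell_mask_fraction,
         mt_coverage_of_cell = mt_coverage_of_cell,
         fg_intensity = fg_intensity, bg_intensity = bg_intensity,
         noise_sd = noise_sd, n_filaments = as.integer(n_filaments),
         seed = check_seed(seed)),
    class = "image_truth"
  )
}

# Distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorised
# over points.
dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / len2))
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Simulate a two-channel single-cell image with known coverage
#'
#' The tubulin foreground is built from random straight filament segments
#' crossing the cell: every cell pixel is scored by its distance to the
#' nearest filament, and exactly the required number of closest pixels
#' (rounded ground-truth coverage times cell area) become foreground, so
#' coverage is exact by construction at the pixel level.
#'
#' @param truth An [image_truth()] object.
#' @return A `tau_cell_image` list with matrices `tubulin`, `actin` (height
#'   x width), logical ground-truth masks `cell_mask`, `mt_mask`, and the
#'   `truth` used.
#' @export
simulate_cell_image <- function(truth) {
  stopifnot(inherits(truth, "image_truth"))
  w <- truth$width; h <- truth$height
  radius <- sqrt(truth$cell_mask_fraction * w * h / pi)
  if (radius > min(w, h) / 2 - 1) {
    abort("`cell_mask_fraction` too large: the cell disk does not fit in the frame.")
  }
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  cell <- (xs - cx)^2 + (ys - cy)^2 <= radius^2
  n_cell <- sum(cell)
  n_mt <- round(truth$mt_coverage_of_cell * n_cell)
  if (n_mt < 1) {
    abort("requested microtubule coverage is not achievable at this resolution (rounds to zero pixels).")
  }

  out <- withr::with_seed(truth$seed, {
    # filament chords: random points inside the cell joined by segments
    ang <- runif(truth$n_filaments, 0, 2 * pi)
    r0 <- radius * sqrt(runif(truth$n_filaments))
    mx <- cx + r0 * cos(ang); my <- cy + r0 * sin(ang)
    dir <- runif(truth$n_filaments, 0, pi)
    x1 <- mx - radius * cos(dir); y1 <- my - radius * sin(dir)
    x2 <- mx + radius * cos(dir); y2 <- my + radius * sin(dir)

    px <- xs[cell]; py <- ys[cell]
    dmin <- rep(Inf, n_cell)
    for (k in seq_len(truth$n_filaments)) {
      dmin <- pmin(dmin, dist_to_segment(px, py, x1[k], y1[k], x2[k], y2[k]))
    }
    # deterministic tie-break: distance, then pixel order
    sel <- order(dmin, seq_len(n_cell))[seq_len(n_mt)]
    mt <- matrix(FALSE, h, w)
    mt[which(cell)[sel]] <- TRUE

    tubulin <- matrix(truth$bg_intensity, h, w)
    tubulin[mt] <- truth$fg_intensity
    actin <- matrix(truth$bg_intensity, h, w)
    actin[cell] <- truth$fg_intensity
    if (truth$noise_sd > 0) {
      tubulin <- tubulin + matrix(rnorm(h * w, 0, truth$noise_sd), h, w)
      actin <- actin + matrix(rnorm(h * w, 0, truth$noise_sd), h, w)
    }
    list(tubulin = tubulin, actin = actin, cell_mask = cell, mt_mask = mt)
  })
  structure(c(out, list(truth = truth)), class = "tau_cell_image")
}
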