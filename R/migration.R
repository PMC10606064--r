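#' Per-track cell-migration metrics
#'
#' For each track: total distance (sum of Euclidean step lengths), distance
#' to origin (net translocation between first and last position), velocity
#' (total distance divided by the nominal experiment duration — 600 min by
#' convention for a full overnight recording), and directional persistence
#' (distance to origin over total distance).  A track shorter than the
#' nominal duration (cell lost from the field) uses its own elapsed time as
#' the velocity denominator and is flagged; a track that never moves gets
#' persistence 0 with a degenerate flag rather than NaN, keeping population
#' means defined.
#'
#' @param data Tibble with columns `track_id`, `time_min`, `x_um`, `y_um`;
#'   any other columns constant within a track (e.g. `group`) are carried
#'   through.
#' @param total_time Nominal experiment duration (min, default 600) used as
#'   the velocity denominator.
#' @return A tibble with one row per track: `total_distance`,
#'   `distance_to_origin`, `velocity`, `persistence`, `flag_short`,
#'   `flag_degenerate`.
#' @examples
#' tr <- motility_truth(mean_speed = 0.5, persistence_time = 30, seed = 1)
#' track_metrics(simulate_tracks(tr, n_cells = 5))
#' @export
track_metrics <- function(data, total_time = 600) {
  req <- c("track_id", "time_min", "x_um", "y_um")
  if (!all(req %in% names(data))) {
    abort("track data needs columns `track_id`, `time_min`, `x_um`, `y_um`.")
  }
  check_number(total_time, "total_time", 0, strict_lower = TRUE)
  carried <- setdiff(names(data), c(req, "frame"))

  data |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) abort("each track needs at least 2 points.")
      check_increasing(g$time_min, "time_min")
      steps <- sqrt(diff(g$x_um)^2 + diff(g$y_um)^2)
      total <- sum(steps)
      d2o <- sqrt((g$x_um[nrow(g)] - g$x_um[1L])^2 +
                    (g$y_um[nrow(g)] - g$y_um[1L])^2)
      elapsed <- g$time_min[nrow(g)] - g$time_min[1L]
      short <- elapsed < total_time * (1 - 1e-9)
      denom <- if (short) elapsed else total_time
      degenerate <- total == 0
      out <- tibble::tibble(
        total_distance = total,
        distance_to_origin = d2o,
        velocity = total / denom,
        persistence = if (degenerate) 0 else d2o / total,
        flag_short = short,
        flag_degenerate = degenerate
      )
      for (cc in carried) {
        v <- unique(g[[cc]])
        if (length(v) == 1L) out[[cc]] <- v
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Group summaries and pairwise comparison of migration metrics
#'
#' Per-group mean, standard error of the mean and n for each metric, the
#' percent change of every group relative to the reference group, and a
#' Wilcoxon rank-sum p-value against the reference (the conventional
#' nonparametric comparison for per-cell motility data).
#'
#' @param metrics Per-track tibble from [track_metrics()] including a
#'   grouping column.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param reference Reference group label; default the first group in
#'   order of appearance.
#' @param metric_cols Metrics to summarise.
#' @return A tidy tibble with columns `metric`, `group`, `n`, `mean`,
#'   `sem`, `pct_change` (vs reference; NA for the reference itself) and
#'   `p_value` (rank-sum vs reference).
#' @export
population_summary <- function(metrics, group_col = "group",
                               reference = NULL,
                               metric_cols = c("velocity",
                                               "distance_to_origin",
                                               "total_distance",
                                               "persistence")) {
  if (!group_col %in% names(metrics)) {
    abort(sprintf("grouping column `%s` not found.", group_col))
  }
  groups <- unique(metrics[[group_col]])
  if (length(groups) < 2) abort("need at least 2 groups.")
  sizes <- table(metrics[[group_col]])
  if (any(sizes < 5)) abort("each group needs at least 5 tracks.")
  reference <- reference %||% groups[1L]
  if (!reference %in% groups) abort("`reference` is not a group label.")

  long <- metrics |>
    dplyr::select(dplyr::all_of(c(group_col, metric_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric")
  ref <- long[long[[group_col]] == reference, ]

  long |>
    dplyr::group_by(.data$metric, .data[[group_col]]) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::rename(group = dplyr::all_of(group_col)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(
      pct_change = ifelse(
        .data$group == reference, NA_real_,
        100 * (.data$mean - .data$mean[.data$group == reference]) /
          .data$mean[.data$group == reference]),
      p_value = purrr::map2_dbl(.data$metric, .data$group, function(m, g) {
        if (g == reference) return(NA_real_)
        x <- ref$value[ref$metric == m]
        y <- long$value[long$metric == m & long[[group_col]] == g]
        suppressWarnings(wilcox.test(y, x)$p.value)
      })
    ) |>
    dplyr::ungroup()
}

#' Trajectory plot of migration tracks, origin-aligned
#'
#' @param data Track tibble (`track_id`, `x_um`, `y_um`, optional group
#'   column used for facetting).
#' @param group_col Optional facet column.
#' @return A ggplot with every track translated to start at the origin.
#' @export
plot_tracks <- function(data, group_col = NULL) {
  d <- data |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(x_um = .data$x_um - .data$x_um[1L],
                  y_um = .data$y_um - .data$y_um[1L]) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                       group = .data$track_id)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
  if (!is.null(group_col)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data[[group_col]]))
  }
  p
}
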