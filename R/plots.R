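# ggplot2 visualisations for the main result types.

#' Plot a landscape
#'
#' Draws patch outlines coloured by habitat class over the study and city
#' boundaries and the developments layer.
#'
#' @param landscape A `landscape`.
#' @return A ggplot.
#' @export
plot_landscape <- function(landscape) {
  ring_df <- function(ring, id) {
    tibble::tibble(x = ring[, 1], y = ring[, 2], ring_id = id)
  }
  p <- landscape$patches
  pd <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    purrr::map_dfr(seq_along(p$geometry[[i]]), function(j) {
      dplyr::mutate(ring_df(p$geometry[[i]][[j]],
                            paste0(p$patch_id[i], "_", j)),
                    habitat_class = factor(p$habitat_class[i]))
    })
  })
  dev <- purrr::map_dfr(seq_along(landscape$developments), function(j)
    ring_df(landscape$developments[[j]], paste0("dev", j)))
  bd <- dplyr::bind_rows(
    dplyr::mutate(ring_df(landscape$study_boundary, "study"), layer = "study"),
    dplyr::mutate(ring_df(landscape$city_boundary, "city"), layer = "city"))
  g <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = bd,
                          ggplot2::aes(.data$x, .data$y, group = .data$ring_id,
                                       linetype = .data$layer),
                          fill = NA, colour = "grey40") +
    ggplot2::geom_polygon(data = pd,
                          ggplot2::aes(.data$x, .data$y, group = .data$ring_id,
                                       fill = .data$habitat_class),
                          colour = "grey20", linewidth = 0.1)
  if (nrow(dev) > 0)
    g <- g + ggplot2::geom_polygon(data = dev,
                                   ggplot2::aes(.data$x, .data$y,
                                                group = .data$ring_id),
                                   fill = "grey30", alpha = 0.6)
  g + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "habitat class") +
    ggplot2::theme_minimal()
}

#' @describeIn rank_scenarios Bar chart of wins and losses per scenario.
#' @param object A `promethee_ranking`.
#' @export
autoplot.promethee_ranking <- function(object, ...) {
  d <- tidyr::pivot_longer(object$table, c("wins", "losses"),
                           names_to = "direction", values_to = "points")
  ggplot2::ggplot(d, ggplot2::aes(.data$scenario, .data$points,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = sprintf("PROMETHEE ranking (robust: %s)",
                                  object$robust),
                  x = "scenario", y = "points") +
    ggplot2::theme_minimal()
}

#' Plot occupancy against habitat loss
#'
#' Mean occupancy (% of suitable area, after burn-in) against the habitat
#' loss level, one line per scenario, faceted by species; the plot on which
#' habitat-loss thresholds are read.
#'
#' @param occupancy_by_level Tibble with `species`, `scenario`, `level`,
#'   `mean_occupancy_pct` (the `occupancy_by_level` element of
#'   [run_experiment()] output).
#' @return A ggplot.
#' @export
plot_occupancy_curves <- function(occupancy_by_level) {
  d <- occupancy_by_level[occupancy_by_level$scenario != "present" |
                            occupancy_by_level$level == 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$mean_occupancy_pct,
                                  colour = .data$scenario)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "habitat loss (% of present-day area)",
                  y = "mean occupancy after burn-in (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn ifm_simulate Occupancy percentage through time per replicate.
#' @param object An `ifm_trajectories`.
#' @param ... Unused.
#' @export
autoplot.ifm_trajectories <- function(object, ...) {
  d <- dim(object$occ)
  total <- sum(object$area_ha)
  df <- purrr::map_dfr(seq_len(d[1]), function(r) {
    occ_r <- object$occ[r, , , drop = FALSE]
    dim(occ_r) <- d[2:3]
    tibble::tibble(replicate = r, t = 0:(d[2] - 1),
                   occupancy_pct = 100 * as.numeric(occ_r %*% object$area_ha) /
                     total)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$occupancy_pct,
                                   group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "timestep", y = "occupancy (% of suitable area)") +
    ggplot2::theme_minimal()
}
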