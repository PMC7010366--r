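# Landscape-scale sustainability measures computed from IFM trajectories,
# and the habitat-loss threshold detector. Ecological sustainability:
# minimum occupancy %, occupancy % after burn-in (175 timesteps), survival
# probability. Social sustainability: city survival probability (existence
# value of biodiversity for residents) and city green space (access to
# natural space inside the city boundary). When a scenario leaves a species
# no habitat, occupancies are recorded as zero rather than skipped.

#' Percentage of suitable habitat area occupied
#'
#' `100 * (area of occupied patches) / (area of all suitable patches in this
#' landscape)`; 0 for an empty patch set (the zero-habitat rule).
#'
#' @param state Binary occupancy vector.
#' @param area_ha Patch areas, ha (same length).
#' @return A percentage in \[0, 100\].
#' @export
occupancy_pct <- function(state, area_ha) {
  if (length(area_ha) == 0) return(0)
  stopifnot(length(state) == length(area_ha))
  min(100, 100 * sum(area_ha[state == 1]) / sum(area_ha))
}

#' Compute the sustainability measures from trajectories
#'
#' Per replicate: minimum occupancy % over all timesteps t >= 1, occupancy %
#' at the burn-in timestep, survival (any patch occupied at the final
#' timestep) and city survival (any occupied patch whose centroid lies
#' inside the city boundary at the final timestep). City green space - the
#' total area of suitable patches with centroid inside the city - is a
#' landscape-level scalar attached as a column (constant across replicates).
#'
#' @param traj An `ifm_trajectories` from [ifm_simulate()].
#' @param landscape The scenario `landscape` the trajectories were run on
#'   (its species habitat map supplied the patches).
#' @param burn_in Burn-in timestep (default 175); trajectories must cover at
#'   least this many timesteps.
#' @return A tibble with one row per replicate: `replicate`,
#'   `min_occupancy_pct`, `occupancy_pct_t175`, `survival`, `city_survival`,
#'   `city_green_space_ha`.
#' @export
compute_measures <- function(traj, landscape, burn_in = 175) {
  d <- dim(traj$occ)
  reps <- d[1]; T_total <- d[2] - 1; n <- d[3]
  if (T_total < burn_in)
    abort(sprintf("trajectories cover %d timesteps; need >= %d", T_total, burn_in))
  city <- landscape$city_boundary
  if (n == 0) {
    return(tibble::tibble(replicate = seq_len(reps), min_occupancy_pct = 0,
                          occupancy_pct_t175 = 0, survival = 0L,
                          city_survival = 0L, city_green_space_ha = 0))
  }
  p <- landscape$patches[match(traj$patch_id, landscape$patches$patch_id), ,
                         drop = FALSE]
  areas <- traj$area_ha
  in_city <- vapply(seq_len(n), function(i)
    point_in_ring(c(p$cx[i], p$cy[i]), city), logical(1))
  green <- sum(areas[in_city])
  total_area <- sum(areas)
  out <- purrr::map_dfr(seq_len(reps), function(r) {
    occ_r <- traj$occ[r, , , drop = FALSE]
    dim(occ_r) <- d[2:3]
    occ_area <- as.numeric(occ_r %*% areas)
    pct <- pmin(100, 100 * occ_area / total_area)
    final <- occ_r[d[2], ]
    tibble::tibble(
      replicate = r,
      min_occupancy_pct = min(pct[-1]),
      occupancy_pct_t175 = pct[burn_in + 1],
      survival = as.integer(any(final == 1L)),
      city_survival = as.integer(any(final == 1L & in_city))
    )
  })
  out$city_green_space_ha <- green
  out
}

#' Detect a habitat-loss threshold in an occupancy-by-loss series
#'
#' Scans consecutive habitat-loss classes in increasing loss order and
#' returns the first interval in which mean occupancy falls by strictly more
#' than 30% of present-day occupancy - a disproportionate species loss for a
#' 10-point habitat loss.
#'
#' @param occ_by_level Mean occupancy % at each loss level, the 0% (present
#'   day) entry first.
#' @param loss_pct Loss levels matching `occ_by_level` (default 0, 10, ...,
#'   90).
#' @param present_occ Present-day occupancy (default the first entry).
#' @param drop_fraction Threshold fraction of present-day occupancy (default
#'   0.30).
#' @return A one-row tibble: `threshold_found`, `loss_lower_pct`,
#'   `loss_upper_pct`, `occupancy_decrease_pct` (the first qualifying drop
#'   as % of present-day occupancy; `NA`s when no threshold), and
#'   `undefined` (`TRUE` when present-day occupancy is 0 so the statistic
#'   does not exist).
#' @export
detect_threshold <- function(occ_by_level,
                             loss_pct = seq(0, 90, by = 10),
                             present_occ = occ_by_level[1],
                             drop_fraction = 0.30) {
  stopifnot(length(occ_by_level) == length(loss_pct), length(occ_by_level) >= 2)
  none <- tibble::tibble(threshold_found = FALSE, loss_lower_pct = NA_real_,
                         loss_upper_pct = NA_real_,
                         occupancy_decrease_pct = NA_real_, undefined = FALSE)
  if (present_occ <= 0) {
    none$undefined <- TRUE
    return(none)
  }
  for (k in seq_len(length(occ_by_level) - 1)) {
    drop <- occ_by_level[k] - occ_by_level[k + 1]
    if (drop > drop_fraction * present_occ) {
      return(tibble::tibble(threshold_found = TRUE,
                            loss_lower_pct = loss_pct[k],
                            loss_upper_pct = loss_pct[k + 1],
                            occupancy_decrease_pct = 100 * drop / present_occ,
                            undefined = FALSE))
    }
  }
  none
}
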