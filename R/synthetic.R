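# Synthetic landscape and occupancy generator. Emulates the structure the
# pipeline assumes for a mid-sized UK city: a bounded mosaic of
# non-overlapping habitat patches with skewed class abundances, an inner
# city boundary within a buffered study area, a clustered developments
# layer, a 2 x 2 km analysis grid, and multi-year grid-cell occupancy
# records. Shapes are restricted to axis-aligned rectangles and discretised
# circles so that downstream geometric operations (shrinkage in particular)
# have closed-form checks.

#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate a Nottingham-sized study system: a 12 x 12 km study area
#' (city plus external dispersal buffer) on a 2 km grid, 150 habitat patches
#' from 0.05 to 20 ha with class abundances skewed towards improved
#' grassland and arable land, and 8 development polygons clustered in the
#' city centre.
#'
#' @param n_patches Number of habitat patches.
#' @param class_weights Named numeric vector of relative class abundances;
#'   names are habitat class ids.
#' @param patch_area_range Min and max patch area, ha; areas are drawn
#'   log-uniformly between them.
#' @param study_extent Side of the square study area, metres.
#' @param city_fraction Fraction of the extent forming the inner (centred,
#'   square) city boundary.
#' @param n_developments Number of development polygons.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patches = 150,
                         class_weights = c("1" = 0.12, "2" = 0.08, "3" = 0.25,
                                           "4" = 0.30, "5" = 0.07, "6" = 0.06,
                                           "8" = 0.05, "9" = 0.03, "10" = 0.02,
                                           "11" = 0.01, "16" = 0.01),
                         patch_area_range = c(0.05, 20),
                         study_extent = 12000,
                         city_fraction = 0.6,
                         n_developments = 8,
                         seed = 1L) {
  stopifnot(n_patches >= 1, all(class_weights >= 0), sum(class_weights) > 0,
            length(patch_area_range) == 2,
            patch_area_range[1] < patch_area_range[2],
            study_extent > 0, city_fraction > 0, city_fraction < 1,
            n_developments >= 0)
  structure(list(n_patches = as.integer(n_patches),
                 class_weights = class_weights,
                 patch_area_range = as.numeric(patch_area_range),
                 study_extent = as.numeric(study_extent),
                 city_fraction = as.numeric(city_fraction),
                 n_developments = as.integer(n_developments),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic landscape
#'
#' Places `n_patches` non-overlapping patches (half rectangles, half
#' discretised circles) uniformly inside the study square by rejection
#' sampling, assigns habitat classes by the configured weights, centres a
#' square city boundary inside the study area and clusters development
#' rectangles around the city centre. Identical configurations (including
#' seed) produce identical landscapes.
#'
#' @param config A [synth_config()].
#' @return A `landscape`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    ext <- config$study_extent
    study <- rect_ring(ext / 2, ext / 2, ext, ext)
    city_side <- ext * config$city_fraction
    city <- rect_ring(ext / 2, ext / 2, city_side, city_side)
    lo <- log(config$patch_area_range[1]); hi <- log(config$patch_area_range[2])
    cw <- config$class_weights
    cls <- as.integer(sample(names(cw), config$n_patches, replace = TRUE,
                             prob = cw))
    geoms <- vector("list", config$n_patches)
    centers <- matrix(0, 0, 2)
    radii <- numeric(0)
    for (i in seq_len(config$n_patches)) {
      area_m2 <- exp(runif(1, lo, hi)) * 1e4
      placed <- FALSE
      is_circle <- runif(1) < 0.5
      if (is_circle) {
        r <- sqrt(area_m2 / pi)
        r_out <- r
      } else {
        aspect <- exp(runif(1, log(0.5), log(2)))
        w <- sqrt(area_m2 * aspect); h <- area_m2 / w
        r_out <- sqrt(w^2 + h^2) / 2
      }
      for (try in 1:500) {
        cx <- runif(1, r_out, ext - r_out)
        cy <- runif(1, r_out, ext - r_out)
        # conservative non-overlap test on circumscribed circles, 1 m margin
        if (nrow(centers) > 0) {
          dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
          if (any(dd < radii + r_out + 1)) next
        }
        geoms[[i]] <- if (is_circle) list(circle_ring(cx, cy, r))
                      else list(rect_ring(cx, cy, w, h))
        centers <- rbind(centers, c(cx, cy))
        radii <- c(radii, r_out)
        placed <- TRUE
        break
      }
      if (!placed)
        abort("could not place all patches without overlap; increase study_extent or reduce n_patches")
    }
    devs <- list()
    if (config$n_developments > 0) {
      for (k in seq_len(config$n_developments)) {
        side <- runif(1, 100, 400)
        cx <- ext / 2 + stats::rnorm(1, 0, city_side / 6)
        cy <- ext / 2 + stats::rnorm(1, 0, city_side / 6)
        cx <- min(max(cx, side / 2), ext - side / 2)
        cy <- min(max(cy, side / 2), ext - side / 2)
        devs <- c(devs, list(rect_ring(cx, cy, side, side)))
      }
    }
    grid <- grid_spec(origin = c(0, 0), cell_size = 2000,
                      n_cols = ceiling(ext / 2000), n_rows = ceiling(ext / 2000))
    landscape(patch_tbl(geoms, cls), study, city, devs, grid)
  })
}

#' Generate synthetic grid-cell occupancy records
#'
#' Emulates coarse species occurrence records: among the grid cells that
#' contain at least one suitable patch for the species, a fraction
#' `prevalence` (rounded half-up) is marked occupied in year 1; each
#' subsequent year every suitable cell's state flips with probability
#' `flip_prob`, giving mildly varying multi-year records.
#'
#' @param landscape A `landscape` (the present-day landscape).
#' @param profile A species profile row (see [species_profiles()]).
#' @param prevalence Fraction of suitable cells occupied in year 1 (0..1).
#' @param years Number of years of records.
#' @param flip_prob Per-year, per-cell state flip probability (default 0.05).
#' @param seed Integer seed.
#' @return A tibble with columns `cell_id`, `year`, `occupied` covering
#'   every suitable cell and year.
#' @export
generate_cell_occupancy <- function(landscape, profile, prevalence, years = 1,
                                    flip_prob = 0.05, seed = 1L) {
  stopifnot(prevalence >= 0, prevalence <= 1, years >= 1)
  prof <- as.list(profile)
  suit <- unlist(prof$suitable_classes)
  p <- landscape$patches[landscape$patches$habitat_class %in% suit, ,
                         drop = FALSE]
  if (nrow(p) == 0)
    abort("no grid cell contains suitable habitat for this species")
  cells <- sort(unique(assign_patches_to_cells(p, landscape$grid)$cell_id))
  with_seed(seed, {
    n_occ <- round_half_up(prevalence * length(cells))
    occ <- rep(0L, length(cells))
    if (n_occ > 0) occ[sample(seq_along(cells), n_occ)] <- 1L
    out <- tibble::tibble(cell_id = cells, year = 1L, occupied = occ)
    if (years > 1) {
      for (yr in 2:years) {
        flips <- runif(length(cells)) < flip_prob
        occ <- ifelse(flips, 1L - occ, occ)
        out <- dplyr::bind_rows(out, tibble::tibble(cell_id = cells,
                                                    year = as.integer(yr),
                                                    occupied = as.integer(occ)))
      }
    }
    out
  })
}

#' Generate a multi-year patch-occupancy history
#'
#' Produces the analogue of a multi-year patch-occupancy survey by iterating
#' the incidence-function-model transition ([ifm_step()]) from a Bernoulli
#' initial state. Year 1 is the initial state; each later year is one model
#' transition from the year before, so the history's dynamics are exactly
#' those of the simulation engine. Used to exercise and validate parameter
#' fitting.
#'
#' @param patches Patch tibble (`patch_id`, `area_ha`, `cx`, `cy`).
#' @param params An [ifm_params()] object.
#' @param years Number of years (states) to produce.
#' @param initial_prevalence Bernoulli occupancy probability for year 1
#'   (ignored when `initial_state` is given).
#' @param seed Integer seed.
#' @param initial_state Optional explicit binary year-1 state.
#' @param discard Number of initial transitions to run and discard before
#'   recording year 1, letting the chain approach quasi-stationarity.
#' @return An integer matrix of dimension `years x n_patches` with
#'   `patch_id`s as column names.
#' @export
generate_occupancy_history <- function(patches, params, years = 8,
                                       initial_prevalence = 0.5, seed = 1L,
                                       initial_state = NULL, discard = 0L) {
  stopifnot(years >= 1, discard >= 0)
  if (nrow(patches) == 0) abort("cannot generate a history for zero patches")
  validate_ifm_params(params)
  with_seed(seed, {
    n <- nrow(patches)
    K <- ifm_kernel(patches, params$alpha, params$b)
    hist <- matrix(0L, nrow = years, ncol = n,
                   dimnames = list(NULL, patches$patch_id))
    state <- if (is.null(initial_state))
      as.integer(runif(n) < initial_prevalence)
    else as.integer(initial_state)
    for (t in seq_len(discard))
      state <- ifm_step_kernel(state, K, patches$area_ha, params)
    hist[1, ] <- state
    if (years > 1) {
      for (yr in 2:years) {
        state <- ifm_step_kernel(state, K, patches$area_ha, params)
        hist[yr, ] <- state
      }
    }
    hist
  })
}
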