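# End-to-end orchestration: synthetic base landscape -> scenario series ->
# species habitat maps -> downscaled starting conditions -> per-starting-
# condition IFM fit -> simulation -> sustainability measures -> PROMETHEE
# ranking -> habitat-loss thresholds. Every stage's randomness is driven by
# seeds derived deterministically from the single experiment seed, so
# rerunning a config reproduces the bundle exactly.

#' Experiment configuration
#'
#' Defaults mirror the full study design (9 loss levels, 200 starting
#' conditions, 500 timesteps, 100 replicates, burn-in 175, 8-year fitting
#' histories) but every knob is configurable for desk-scale runs.
#'
#' @param species Species names (subset of [species_profiles()]); default
#'   all ten.
#' @param strategies Scenario strategy codes (default all six).
#' @param n_starting_conditions Downscaled occupancy configurations per
#'   species.
#' @param steps,reps,burn_in Simulation length, replicates and burn-in
#'   timestep.
#' @param fit_years Years of synthetic occupancy history fitted per
#'   starting condition.
#' @param fit_discard Transitions run and discarded before the recorded
#'   history so fitting sees near-stationary occupancy.
#' @param prevalence Grid-cell prevalence of the synthetic species records.
#' @param sim_x,sim_ey2 Parameters of the process that generates the
#'   synthetic occupancy histories (the fitting stage re-estimates them).
#' @param levels Loss fractions (default `seq(0.1, 0.9, 0.1)`).
#' @param alpha_level Mann-Whitney significance gate for the MCDA.
#' @param synth A [synth_config()] for the base landscape; by default one
#'   is derived from `seed`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory: when set, [run_experiment()] writes
#'   the result bundle there as CSV/JSON.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(species = species_profiles()$species,
                              strategies = scenario_codes,
                              n_starting_conditions = 200,
                              steps = 500, reps = 100, burn_in = 175,
                              fit_years = 8, fit_discard = 30,
                              prevalence = 0.6,
                              sim_x = 1.0, sim_ey2 = 0.1,
                              levels = seq(0.1, 0.9, by = 0.1),
                              alpha_level = 0.05,
                              synth = NULL, seed = 1L, out_dir = NULL) {
  stopifnot(burn_in < steps, n_starting_conditions >= 1, reps >= 1)
  if (is.null(synth)) synth <- synth_config(seed = child_seed(seed, 1))
  structure(list(species = species, strategies = strategies,
                 n_starting_conditions = n_starting_conditions,
                 steps = steps, reps = reps, burn_in = burn_in,
                 fit_years = fit_years, fit_discard = fit_discard,
                 prevalence = prevalence, sim_x = sim_x, sim_ey2 = sim_ey2,
                 levels = levels, alpha_level = alpha_level, synth = synth,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' @noRd
zero_measures <- function(reps) {
  tibble::tibble(replicate = seq_len(reps), min_occupancy_pct = 0,
                 occupancy_pct_t175 = 0, survival = 0L, city_survival = 0L,
                 city_green_space_ha = 0)
}

#' Run the full scenario-comparison experiment
#'
#' Executes every stage of the workflow on a synthetic study system and
#' returns the complete result bundle. Species whose habitat map on a
#' scenario landscape is empty, or whose recorded grid cells hold no
#' remaining habitat, are not simulated there: their occupancies are
#' recorded as zero. Starting-condition fits that fail (e.g. complete
#' separation in a small history) fall back to the generating parameters;
#' the manifest counts such fallbacks.
#'
#' @param config An [experiment_config()].
#' @return A list of class `landsust_experiment` with elements `measures`
#'   (per-replicate tibble), `ranking`/`total` (overall PROMETHEE result),
#'   `ranking_by_group`, `ranking_by_measure`, `thresholds`,
#'   `occupancy_by_level` (mean occupancy % per species x scenario x loss
#'   level), `base_landscape`, `series` (scenario series by strategy),
#'   `fits` (per species x starting condition parameter tibble) and
#'   `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  profiles <- species_profiles()
  profiles <- profiles[profiles$species %in% config$species, , drop = FALSE]
  if (nrow(profiles) == 0) abort("no matching species in species_profiles()")

  base <- generate_landscape(config$synth)
  series <- setNames(lapply(seq_along(config$strategies), function(k)
    make_scenario_series(base, config$strategies[k],
                         seed = child_seed(seed, 100 + k),
                         levels = config$levels)),
    config$strategies)

  measures <- list()
  fits <- list()
  occ_level0 <- list()
  n_fit_fallback <- 0L

  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    sp <- prof$species
    hm0 <- build_species_habitat_map(base, prof)
    if (nrow(hm0$patches) == 0) {
      for (k in seq_along(config$strategies)) {
        for (l in seq_along(config$levels)) {
          for (sc in seq_len(config$n_starting_conditions)) {
            measures[[length(measures) + 1]] <- dplyr::mutate(
              zero_measures(config$reps), species = sp, group = prof$group,
              scenario = config$strategies[k], level = 100 * config$levels[l],
              starting_condition = sc, .before = 1)
          }
        }
      }
      occ_level0[[sp]] <- rep(0, config$n_starting_conditions)
      next
    }
    cells <- generate_cell_occupancy(base, prof, config$prevalence, years = 1,
                                     seed = child_seed(seed, 200 + i))
    true_params <- ifm_params(alpha = 1 / prof$dispersal_km, x = config$sim_x,
                              ey2 = config$sim_ey2)
    assign0 <- assign_patches_to_cells(hm0$patches, base$grid)
    starts <- sample_starting_conditions(cells, hm0$patches, assign0,
                                         n = config$n_starting_conditions,
                                         base_seed = child_seed(seed, 300 + i))

    # species habitat maps per scenario landscape, shared across starting
    # conditions
    hms <- lapply(config$strategies, function(strat)
      lapply(series[[strat]]$landscapes, build_species_habitat_map,
             profile = prof))
    names(hms) <- config$strategies
    hm_assign <- lapply(hms, function(hl) lapply(hl, function(hm)
      if (nrow(hm$patches) > 0)
        assign_patches_to_cells(hm$patches, hm$grid) else NULL))

    # one fit and one level-0 simulation per starting condition
    sp_fits <- vector("list", config$n_starting_conditions)
    occ0 <- numeric(config$n_starting_conditions)
    for (sc in seq_len(config$n_starting_conditions)) {
      st <- starts$occupied[starts$starting_condition == sc]
      hist <- generate_occupancy_history(
        hm0$patches, true_params, years = config$fit_years,
        seed = child_seed(seed, 1000 * i + sc), initial_state = st,
        discard = config$fit_discard)
      fit_params <- tryCatch(
        fit_ifm(hist, hm0$patches, alpha = true_params$alpha,
                mode = "constrained", species = sp)$params,
        error = function(e) {
          n_fit_fallback <<- n_fit_fallback + 1L
          true_params
        })
      sp_fits[[sc]] <- tibble::tibble(species = sp, starting_condition = sc,
                                      alpha = fit_params$alpha,
                                      x = fit_params$x, ey2 = fit_params$ey2)
      traj0 <- ifm_simulate(st, hm0$patches, fit_params, steps = config$steps,
                            reps = config$reps,
                            seed = child_seed(seed, 2000000 + 1000 * i + sc))
      m0 <- compute_measures(traj0, hm0, burn_in = config$burn_in)
      occ0[sc] <- mean(m0$occupancy_pct_t175)
      measures[[length(measures) + 1]] <- dplyr::mutate(
        m0, species = sp, group = prof$group, scenario = "present", level = 0,
        starting_condition = sc, .before = 1)
      for (k in seq_along(config$strategies)) {
        strat <- config$strategies[k]
        for (l in seq_along(config$levels)) {
          hm <- hms[[strat]][[l]]
          lvl <- 100 * config$levels[l]
          if (nrow(hm$patches) == 0) {
            mm <- zero_measures(config$reps)
          } else {
            assign_l <- hm_assign[[strat]][[l]]
            init <- downscale_occupancy(
              cells, hm$patches, assign_l,
              seed = child_seed(seed, 3e7 + ((i * 20 + k) * 20 + l) * 1e3 + sc))
            if (sum(init$occupied) == 0) {
              # recorded cells hold no remaining habitat: occupancy is zero,
              # but green space is still a property of the landscape
              mm <- zero_measures(config$reps)
              in_city <- vapply(seq_len(nrow(hm$patches)), function(pi_)
                point_in_ring(c(hm$patches$cx[pi_], hm$patches$cy[pi_]),
                              hm$city_boundary), logical(1))
              mm$city_green_space_ha <- sum(hm$patches$area_ha[in_city])
            } else {
              traj <- ifm_simulate(
                init, hm$patches, fit_params, steps = config$steps,
                reps = config$reps,
                seed = child_seed(seed, 6e7 + ((i * 20 + k) * 20 + l) * 1e3 + sc))
              mm <- compute_measures(traj, hm, burn_in = config$burn_in)
            }
          }
          measures[[length(measures) + 1]] <- dplyr::mutate(
            mm, species = sp, group = prof$group, scenario = strat,
            level = lvl, starting_condition = sc, .before = 1)
        }
      }
    }
    fits[[sp]] <- dplyr::bind_rows(sp_fits)
    occ_level0[[sp]] <- occ0
  }

  measures_tbl <- dplyr::bind_rows(measures)
  scen_tbl <- measures_tbl[measures_tbl$scenario != "present", , drop = FALSE]

  overall <- promethee_analysis(scen_tbl, alpha_level = config$alpha_level)
  by_group <- promethee_analysis(scen_tbl, alpha_level = config$alpha_level,
                                 grouping = "group")
  by_measure <- promethee_analysis(scen_tbl, alpha_level = config$alpha_level,
                                   grouping = "measure")

  occ_by_level <- dplyr::summarise(
    dplyr::group_by(measures_tbl, .data$species, .data$scenario, .data$level),
    mean_occupancy_pct = mean(.data$occupancy_pct_t175), .groups = "drop")
  thresholds <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    sp <- profiles$species[i]
    present <- mean(occ_level0[[sp]])
    purrr::map_dfr(config$strategies, function(strat) {
      sub <- occ_by_level[occ_by_level$species == sp &
                            occ_by_level$scenario == strat, , drop = FALSE]
      sub <- sub[order(sub$level), , drop = FALSE]
      res <- detect_threshold(c(present, sub$mean_occupancy_pct),
                              loss_pct = c(0, sub$level),
                              present_occ = present)
      dplyr::mutate(res, species = sp, scenario = strat, .before = 1)
    })
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("landsust")),
    r_version = R.version.string,
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    n_species = nrow(profiles),
    n_strategies = length(config$strategies),
    n_levels = length(config$levels),
    n_starting_conditions = config$n_starting_conditions,
    n_criteria = 5 * length(config$levels) * nrow(profiles) *
      config$n_starting_conditions,
    n_measure_rows = nrow(measures_tbl),
    n_fit_fallback = n_fit_fallback)

  bundle <- structure(list(measures = measures_tbl, total = overall$total,
                           ranking = overall$ranking,
                           ranking_by_group = by_group,
                           ranking_by_measure = by_measure,
                           thresholds = thresholds,
                           occupancy_by_level = occ_by_level,
                           base_landscape = base, series = series,
                           fits = dplyr::bind_rows(fits),
                           manifest = manifest),
                      class = "landsust_experiment")
  if (!is.null(config$out_dir)) write_experiment(bundle, config$out_dir)
  bundle
}

#' @export
print.landsust_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<landsust_experiment> %d species x %d strategies x %d levels x %d starting conditions (%d criteria)\n",
              m$n_species, m$n_strategies, m$n_levels,
              m$n_starting_conditions, m$n_criteria))
  cat("overall ranking (robust:", x$ranking$robust, ")\n")
  print(x$ranking$table)
  invisible(x)
}

#' Write an experiment bundle to disk
#'
#' Writes the tabular outputs (measures, total preference matrix, rankings,
#' thresholds, occupancy curves, fitted parameters) as CSV and the manifest
#' as JSON.
#'
#' @param bundle A `landsust_experiment` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$measures, file.path(dir, "measures.csv"), row.names = FALSE)
  tot <- as.data.frame(bundle$total)
  tot <- cbind(scenario = rownames(bundle$total), tot)
  write.csv(tot, file.path(dir, "total_preference.csv"), row.names = FALSE)
  write.csv(bundle$ranking$table, file.path(dir, "ranking.csv"),
            row.names = FALSE)
  grp <- dplyr::bind_rows(lapply(seq_len(nrow(bundle$ranking_by_group)),
    function(i) dplyr::mutate(bundle$ranking_by_group$ranking[[i]]$table,
                              group = bundle$ranking_by_group$group[i],
                              .before = 1)))
  write.csv(grp, file.path(dir, "ranking_by_group.csv"), row.names = FALSE)
  msr <- dplyr::bind_rows(lapply(seq_len(nrow(bundle$ranking_by_measure)),
    function(i) dplyr::mutate(bundle$ranking_by_measure$ranking[[i]]$table,
                              measure = bundle$ranking_by_measure$group[i],
                              .before = 1)))
  write.csv(msr, file.path(dir, "ranking_by_measure.csv"), row.names = FALSE)
  write.csv(bundle$thresholds, file.path(dir, "thresholds.csv"),
            row.names = FALSE)
  write.csv(bundle$occupancy_by_level, file.path(dir, "occupancy_by_level.csv"),
            row.names = FALSE)
  write.csv(bundle$fits, file.path(dir, "fitted_parameters.csv"),
            row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
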