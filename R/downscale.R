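# Area-weighted downscaling of grid-cell species records to patch-level
# occupancy. The landscape-wide proportion of occupied suitable cells, q, is
# assumed self-similar across scales: within each occupied cell holding m
# suitable patches, max(1, round(q * m)) patches are drawn without
# replacement with probability proportional to patch area and marked
# occupied. Patches in unoccupied cells stay unoccupied.

#' Downscale cell-level records to one patch-occupancy configuration
#'
#' @param cell_occ Year-1 slice of cell records: a data frame with `cell_id`
#'   and `occupied` (0/1); cells absent from it are treated as unoccupied.
#' @param patches Species habitat-map patch tibble (`patch_id`, `area_ha`).
#' @param cell_assignment Patch-to-cell mapping as from
#'   [assign_patches_to_cells()] on the same patches.
#' @param seed Integer seed.
#' @return A tibble with columns `patch_id` and `occupied` (0/1), one row
#'   per patch.
#' @export
downscale_occupancy <- function(cell_occ, patches, cell_assignment, seed = 1L) {
  if (nrow(patches) == 0)
    abort("cannot downscale: the species habitat map has no patches")
  suitable_cells <- unique(cell_assignment$cell_id)
  occ_cells <- unique(cell_occ$cell_id[cell_occ$occupied == 1])
  occ_suit <- intersect(occ_cells, suitable_cells)
  q <- length(occ_suit) / length(suitable_cells)
  with_seed(seed, {
    occupied <- setNames(rep(0L, nrow(patches)), patches$patch_id)
    for (cell in occ_suit) {
      ids <- cell_assignment$patch_id[cell_assignment$cell_id == cell]
      m <- length(ids)
      k <- max(1L, round_half_up(q * m))
      k <- min(k, m)
      w <- patches$area_ha[match(ids, patches$patch_id)]
      pick <- if (m == 1) ids else sample(ids, k, prob = w)
      occupied[as.character(pick)] <- 1L
    }
    tibble::tibble(patch_id = patches$patch_id,
                   occupied = as.integer(occupied[as.character(patches$patch_id)]))
  })
}

#' Draw a set of occupancy starting conditions
#'
#' Repeats [downscale_occupancy()] under seeds derived deterministically
#' from `base_seed`, giving the stochastic ensemble of starting conditions
#' that carries downscaling uncertainty into the simulations (200 in the
#' full design).
#'
#' @inheritParams downscale_occupancy
#' @param n Number of starting conditions.
#' @param base_seed Integer base seed.
#' @return A tibble with columns `starting_condition`, `patch_id`,
#'   `occupied`.
#' @export
sample_starting_conditions <- function(cell_occ, patches, cell_assignment,
                                       n = 200, base_seed = 1L) {
  stopifnot(n >= 1)
  purrr::map_dfr(seq_len(n), function(i) {
    sc <- downscale_occupancy(cell_occ, patches, cell_assignment,
                              seed = child_seed(base_seed, i))
    dplyr::mutate(sc, starting_condition = i, .before = 1)
  })
}
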