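# Landscape container: a patch tibble with list-column geometry plus study /
# city boundaries, a developments layer, a grid specification and the habitat
# class table. Geometry convention: metres, planar; areas in ha; distances
# between patches in km. Patch location for all distance computations is the
# area centroid.

#' Construct a grid specification
#'
#' A regular analysis grid of half-open square cells
#' `[x0 + c*s, x0 + (c+1)*s) x [y0 + r*s, y0 + (r+1)*s)`; a point on an
#' interior cell edge belongs to the cell on the +x/+y side, so the grid
#' partitions the plane deterministically. The default cell size of 2000 m
#' matches the 2 x 2 km resolution at which species occurrence records are
#' typically held.
#'
#' @param origin Numeric length-2, grid origin (x0, y0) in metres.
#' @param cell_size Cell edge length in metres (default 2000).
#' @param n_cols,n_rows Number of columns / rows.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size = 2000, n_cols, n_rows) {
  stopifnot(length(origin) == 2, cell_size > 0, n_cols >= 1, n_rows >= 1)
  structure(list(origin = as.numeric(origin), cell_size = as.numeric(cell_size),
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

# build the patch tibble from a list of geometries (each a list of rings)
#' @noRd
patch_tbl <- function(geometries, habitat_class, patch_id = NULL) {
  n <- length(geometries)
  if (is.null(patch_id)) patch_id <- seq_len(n)
  area_m2 <- vapply(geometries, parts_area, numeric(1))
  cent <- if (n > 0) t(vapply(geometries, parts_centroid, numeric(2)))
          else matrix(numeric(0), ncol = 2)
  tibble::tibble(
    patch_id = as.integer(patch_id),
    habitat_class = as.integer(habitat_class),
    area_ha = area_m2 / 1e4,
    cx = if (n > 0) cent[, 1] else numeric(0),
    cy = if (n > 0) cent[, 2] else numeric(0),
    geometry = geometries
  )
}

#' Construct a landscape
#'
#' Bundles a patch mosaic with its study and city boundaries, a developments
#' layer, an analysis grid and the habitat class table.
#'
#' @param patches A tibble with columns `patch_id`, `habitat_class`,
#'   `area_ha`, `cx`, `cy` and a `geometry` list-column (each element a list
#'   of n x 2 coordinate matrices, metres, counter-clockwise).
#' @param study_boundary,city_boundary Single rings (n x 2 matrices); the
#'   city boundary must lie within the study boundary.
#' @param developments A list of rings for existing/planned developments.
#' @param grid A [grid_spec()].
#' @param classes Habitat class table as from [habitat_classes()].
#' @return An object of class `landscape`.
#' @export
landscape <- function(patches, study_boundary, city_boundary,
                      developments = list(), grid, classes = habitat_classes()) {
  obj <- structure(list(patches = patches, study_boundary = study_boundary,
                        city_boundary = city_boundary,
                        developments = developments, grid = grid,
                        classes = classes),
                   class = "landscape")
  obj
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d patches, %.1f ha habitat, %d habitat classes\n",
              nrow(x$patches), sum(x$patches$area_ha),
              length(unique(x$patches$habitat_class))))
  cat(sprintf("  grid: %d x %d cells of %g m; %d development polygon(s)\n",
              x$grid$n_cols, x$grid$n_rows, x$grid$cell_size,
              length(x$developments)))
  invisible(x)
}

#' Validate a landscape
#'
#' Checks the structural invariants of a landscape: positive patch areas,
#' valid (simple) ring geometry, stored area consistent with geometry, unique
#' patch ids, and (optionally) pairwise non-overlap of patches.
#'
#' @param x A `landscape`.
#' @param check_overlap Also test pairwise patch overlap (O(n^2) with a
#'   bounding-box prefilter); intersection area above `1e-9` of the smaller
#'   patch fails.
#' @return `x` invisibly; aborts with a diagnostic naming the offending
#'   patch on failure.
#' @export
validate_landscape <- function(x, check_overlap = FALSE) {
  p <- x$patches
  if (anyDuplicated(p$patch_id))
    abort("duplicate patch_id in landscape")
  for (i in seq_len(nrow(p))) {
    g <- p$geometry[[i]]
    for (r in g) {
      if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3 || !ring_is_simple(r))
        abort(sprintf("invalid geometry for patch %d", p$patch_id[i]))
    }
    a <- parts_area(g) / 1e4
    if (a <= 0)
      abort(sprintf("non-positive area for patch %d", p$patch_id[i]))
    if (abs(a - p$area_ha[i]) > 1e-6 * max(a, 1e-12))
      abort(sprintf("stored area inconsistent with geometry for patch %d",
                    p$patch_id[i]))
  }
  if (check_overlap && nrow(p) > 1) {
    bb <- lapply(p$geometry, parts_bbox)
    for (i in seq_len(nrow(p) - 1)) {
      for (j in (i + 1):nrow(p)) {
        if (bbox_gap(bb[[i]], bb[[j]]) > 0) next
        inter <- 0
        for (ra in p$geometry[[i]]) for (rb in p$geometry[[j]])
          inter <- inter + convex_intersection_area(ra, rb)
        if (inter > 1e-9 * min(p$area_ha[i], p$area_ha[j]) * 1e4)
          abort(sprintf("patches %d and %d overlap", p$patch_id[i], p$patch_id[j]))
      }
    }
  }
  invisible(x)
}

#' Assign patches to grid cells by centroid
#'
#' Each patch is assigned to the (unique) half-open grid cell containing its
#' area centroid; a centroid exactly on an interior edge goes to the cell on
#' the +x/+y side. A patch spanning several cells is still assigned to
#' exactly one cell - the downscaling stage treats the cell holding the
#' centroid as the patch's cell.
#'
#' @param patches Patch tibble (needs `patch_id`, `cx`, `cy`).
#' @param grid A [grid_spec()].
#' @return A tibble with columns `patch_id`, `cell_col`, `cell_row` (0-based)
#'   and `cell_id` (`"c<col>_r<row>"`).
#' @export
assign_patches_to_cells <- function(patches, grid) {
  col <- floor((patches$cx - grid$origin[1]) / grid$cell_size)
  row <- floor((patches$cy - grid$origin[2]) / grid$cell_size)
  bad <- col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows
  if (any(bad))
    abort(paste0("patch centroid outside grid extent for patch(es): ",
                 paste(patches$patch_id[bad], collapse = ", ")))
  tibble::tibble(patch_id = patches$patch_id,
                 cell_col = as.integer(col), cell_row = as.integer(row),
                 cell_id = sprintf("c%d_r%d", as.integer(col), as.integer(row)))
}

#' Build a species habitat map
#'
#' Restricts a landscape to the patches a species can use: patches whose
#' habitat class is in the species' suitable set are kept, neighbouring
#' suitable patches separated by no more than `gap_m` metres (land-ownership
#' boundaries, habitat-type demarcations, paths and small roads) are
#' dissolved into one patch, and dissolved patches smaller than the species'
#' minimum area requirement are discarded. Dissolving groups patches into
#' connected components under the "boundary distance <= gap_m" relation;
#' because patches never overlap, the merged area is the sum of member areas
#' and the merged geometry keeps every member ring as one multipart patch.
#'
#' @param landscape A `landscape`.
#' @param profile One row of [species_profiles()] (or any list with
#'   `suitable_classes` and `min_area_ha`).
#' @param gap_m Maximum gap bridged by the dissolve, metres (default 3).
#' @return A `landscape` whose patches are the species' habitat patches
#'   (possibly zero rows); each patch records its area, centroid, the class
#'   of its largest member and the member patch ids (`members` list-column).
#' @export
build_species_habitat_map <- function(landscape, profile, gap_m = 3) {
  prof <- as.list(profile)
  suit <- unlist(prof$suitable_classes)
  min_area <- prof$min_area_ha[[1]]
  p <- landscape$patches
  keep <- p$habitat_class %in% suit
  p <- p[keep, , drop = FALSE]
  n <- nrow(p)
  if (n == 0) {
    out <- landscape
    out$patches <- patch_tbl(list(), integer(0))
    out$patches$members <- list()
    return(out)
  }
  for (i in seq_len(n)) {
    for (r in p$geometry[[i]])
      if (!is.matrix(r) || nrow(r) < 3 || !ring_is_simple(r))
        abort(sprintf("invalid geometry for patch %d", p$patch_id[i]))
  }
  # connected components under boundary distance <= gap_m (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  bb <- lapply(p$geometry, parts_bbox)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      if (find(i) == find(j)) next
      if (bbox_gap(bb[[i]], bb[[j]]) > gap_m) next
      if (parts_dist(p$geometry[[i]], p$geometry[[j]], upper = gap_m + 1e-9) <= gap_m)
        parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  geoms <- vector("list", length(groups))
  cls <- integer(length(groups))
  members <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    geoms[[k]] <- do.call(c, p$geometry[idx])
    cls[k] <- p$habitat_class[idx[which.max(p$area_ha[idx])]]
    members[[k]] <- p$patch_id[idx]
  }
  out_p <- patch_tbl(geoms, cls)
  out_p$members <- members
  out_p <- out_p[out_p$area_ha >= min_area, , drop = FALSE]
  out_p$patch_id <- seq_len(nrow(out_p))
  out <- landscape
  out$patches <- out_p
  out
}

# total habitat area (ha) of removable classes
#' @noRd
removable_area <- function(landscape) {
  rem <- landscape$classes$class_id[landscape$classes$removable]
  sum(landscape$patches$area_ha[landscape$patches$habitat_class %in% rem])
}
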