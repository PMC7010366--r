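# Habitat-loss scenario generators. Six rule sets produce nine landscapes
# each at 10-90% cumulative loss of the present-day habitat area:
#   A1  smallest patches lost first
#   A2  largest patches lost first
#   R1  nationally common habitat classes lost first (random within class)
#   R2  locally common classes lost first, rarity re-ranked after each step
#   C   patches nearest developments lost first; removals join the
#       developments layer before the next step (contagion)
#   S   every patch shrunk to (1 - loss) of its area by inward offset
# Freshwater-flagged classes are excluded from both removal and the habitat
# area total. "Remove patches whose area equals f% of the total" cannot hold
# exactly for discrete patches; the minimal-overshoot rule is used: the
# shortest prefix of the ordering whose cumulative area reaches the target.

scenario_codes <- c("A1", "A2", "R1", "R2", "C", "S")

#' Order patches for removal under a scenario strategy
#'
#' Returns the removal order of the removable patches in a landscape under
#' strategies A1, A2, R1, R2 or C (scenario S shrinks rather than removes,
#' so has no ordering). Rarity ranks give 1 to the most common class; R1
#' ranks classes by national coverage, R2 by class area within this
#' landscape. Ties within a rarity class are ordered randomly (seeded); area
#' and distance ties are broken by `patch_id`.
#'
#' @param landscape A `landscape`.
#' @param strategy One of `"A1"`, `"A2"`, `"R1"`, `"R2"`, `"C"`.
#' @param seed Integer seed for within-rarity-class randomisation (R1/R2).
#' @param developments Optional developments layer overriding the
#'   landscape's own (used by the contagion iteration).
#' @return Integer vector of `patch_id`s in removal order.
#' @export
order_patches <- function(landscape, strategy, seed = 1L,
                          developments = NULL) {
  strategy <- match.arg(strategy, c("A1", "A2", "R1", "R2", "C"))
  cls <- landscape$classes
  p <- landscape$patches[landscape$patches$habitat_class %in%
                           cls$class_id[cls$removable], , drop = FALSE]
  if (nrow(p) == 0) abort("landscape has no removable patches")
  if (strategy == "A1") {
    p$patch_id[order(p$area_ha, p$patch_id)]
  } else if (strategy == "A2") {
    p$patch_id[order(-p$area_ha, p$patch_id)]
  } else if (strategy %in% c("R1", "R2")) {
    if (strategy == "R1") {
      if (any(is.na(cls$national_cover_ha)))
        abort("R1 requires national_cover_ha for every habitat class")
      cover <- setNames(cls$national_cover_ha, cls$class_id)
    } else {
      local <- tapply(p$area_ha, p$habitat_class, sum)
      cover <- setNames(as.numeric(local), names(local))
    }
    # rank 1 = most common; only classes present in the landscape compete
    present <- as.character(sort(unique(p$habitat_class)))
    rk <- rank(-cover[present], ties.method = "first")
    rarity <- setNames(rk, present)
    with_seed(seed, {
      jitter <- runif(nrow(p))
      p$patch_id[order(rarity[as.character(p$habitat_class)], jitter)]
    })
  } else { # C
    devs <- if (is.null(developments)) landscape$developments else developments
    if (length(devs) == 0) abort("contagion strategy requires a developments layer")
    dist_dev <- vapply(p$geometry, function(g)
      parts_dist(g, devs), numeric(1))
    p$patch_id[order(dist_dev, p$patch_id)]
  }
}

#' Select the removal prefix reaching a target area
#'
#' Implements the minimal-overshoot rule: removes the shortest prefix of an
#' ordered patch set whose cumulative area is at least `target_area`.
#'
#' @param ordered A tibble/data frame with `patch_id` and `area_ha` in
#'   removal order, or a numeric vector of areas.
#' @param target_area Target cumulative area, ha (0 removes nothing).
#' @return A list with `removed` and `retained` (patch ids, or indices when
#'   `ordered` is a bare vector) and `removed_area`.
#' @export
remove_to_target <- function(ordered, target_area) {
  if (is.numeric(ordered)) {
    areas <- ordered; ids <- seq_along(ordered)
  } else {
    areas <- ordered$area_ha; ids <- ordered$patch_id
  }
  stopifnot(target_area >= 0)
  if (target_area > sum(areas) + 1e-9)
    abort("target_area exceeds total available area")
  cum <- cumsum(areas)
  n_rm <- if (target_area <= 1e-12) 0L else which(cum >= target_area - 1e-9)[1]
  list(removed = ids[seq_len(n_rm)],
       retained = if (n_rm < length(ids)) ids[(n_rm + 1):length(ids)] else ids[0],
       removed_area = if (n_rm > 0) cum[n_rm] else 0)
}

#' Shrink a patch to a fraction of its area by inward offset
#'
#' Finds, by bisection, the inward offset distance at which the patch's area
#' equals `retained_fraction` of its original area (relative tolerance
#' `tol`), and returns the offset geometry. For a circle of radius r the
#' result is the circle of radius `r * sqrt(f)`; for a square of side s, the
#' square of side `s * sqrt(f)`. Multipart patches are offset by a common
#' distance chosen on the total area. Returns `NULL` in the degenerate case
#' where the geometry vanishes before the target is reached.
#'
#' @param geometry A patch geometry: list of convex rings.
#' @param retained_fraction Fraction of area to retain, in (0, 1).
#' @param tol Relative area tolerance of the bisection (default 1e-4).
#' @param max_iter Maximum bisection iterations (default 100).
#' @return The shrunk geometry (list of rings), or `NULL`.
#' @export
shrink_patch <- function(geometry, retained_fraction, tol = 1e-4,
                         max_iter = 100L) {
  stopifnot(retained_fraction > 0, retained_fraction < 1)
  a0 <- parts_area(geometry)
  if (a0 <= 0) abort("cannot shrink a degenerate polygon")
  target <- retained_fraction * a0
  # bracket: grow hi until the geometry's area falls below target
  lo <- 0
  hi <- sqrt(a0)
  for (k in 1:60) {
    g <- parts_inward_offset(geometry, hi)
    if (is.null(g) || parts_area(g) < target) break
    lo <- hi
    hi <- hi * 2
  }
  g <- parts_inward_offset(geometry, hi)
  if (!is.null(g) && parts_area(g) >= target)
    return(NULL) # could not bracket: geometry never reaches the target
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g <- parts_inward_offset(geometry, mid)
    a <- if (is.null(g)) 0 else parts_area(g)
    if (abs(a - target) <= tol * a0) {
      if (is.null(g)) return(NULL)
      return(g)
    }
    if (a > target) lo <- mid else hi <- mid
  }
  g <- parts_inward_offset(geometry, (lo + hi) / 2)
  g
}

#' Generate a nine-level habitat-loss scenario series
#'
#' Produces the nine scenario landscapes of one strategy at cumulative
#' losses of 10%, 20%, ..., 90% of the present-day removable habitat area.
#' A1, A2, R1 and C fix removals as nested prefixes of an ordering (C
#' recomputes the ordering each step after adding the removed patches to the
#' developments layer; R2 re-ranks local rarity each step); S shrinks every
#' removable patch independently per level to `1 - level` of its area.
#' Non-removable (freshwater-flagged) patches are carried through unchanged.
#'
#' @param landscape The present-day `landscape`.
#' @param strategy One of `"A1"`, `"A2"`, `"R1"`, `"R2"`, `"C"`, `"S"`.
#' @param seed Integer seed (R1/R2 within-class randomisation; for R1 the
#'   random within-class order is fixed once for the whole series).
#' @param levels Loss fractions (default `seq(0.1, 0.9, by = 0.1)`).
#' @return A list of class `scenario_series` with elements `strategy`,
#'   `levels`, `landscapes` (list of `landscape`), `removal_log` (tibble:
#'   `level`, `patch_id` removed at that level, or shrink fractions for S)
#'   and `total_area_ha` (present-day removable area).
#' @export
make_scenario_series <- function(landscape, strategy, seed = 1L,
                                 levels = seq(0.1, 0.9, by = 0.1)) {
  strategy <- match.arg(strategy, scenario_codes)
  cls <- landscape$classes
  removable_ids <- landscape$patches$patch_id[
    landscape$patches$habitat_class %in% cls$class_id[cls$removable]]
  fixed <- landscape$patches[!landscape$patches$patch_id %in% removable_ids, ,
                             drop = FALSE]
  total <- removable_area(landscape)
  out <- list(strategy = strategy, levels = levels,
              landscapes = vector("list", length(levels)),
              removal_log = tibble::tibble(level = numeric(0),
                                           patch_id = integer(0)),
              emptied = rep(FALSE, length(levels)),
              total_area_ha = total)

  subset_landscape <- function(keep_ids) {
    l <- landscape
    l$patches <- dplyr::bind_rows(
      landscape$patches[landscape$patches$patch_id %in% keep_ids, , drop = FALSE],
      fixed)
    l$patches <- l$patches[order(l$patches$patch_id), , drop = FALSE]
    l
  }

  if (strategy %in% c("A1", "A2", "R1")) {
    ord <- order_patches(landscape, strategy, seed = seed)
    areas <- landscape$patches$area_ha[match(ord, landscape$patches$patch_id)]
    prev_removed <- integer(0)
    for (k in seq_along(levels)) {
      sel <- remove_to_target(tibble::tibble(patch_id = ord, area_ha = areas),
                              levels[k] * total)
      out$landscapes[[k]] <- subset_landscape(setdiff(removable_ids, sel$removed))
      new_rm <- setdiff(sel$removed, prev_removed)
      out$removal_log <- dplyr::bind_rows(
        out$removal_log,
        tibble::tibble(level = levels[k], patch_id = as.integer(new_rm)))
      prev_removed <- sel$removed
    }
  } else if (strategy %in% c("R2", "C")) {
    removed <- integer(0)
    devs <- landscape$developments
    for (k in seq_along(levels)) {
      current <- subset_landscape(setdiff(removable_ids, removed))
      step_target <- levels[k] * total - sum(
        landscape$patches$area_ha[landscape$patches$patch_id %in% removed])
      remaining <- setdiff(removable_ids, removed)
      if (length(remaining) > 0 && step_target > 1e-9) {
        avail <- sum(landscape$patches$area_ha[
          landscape$patches$patch_id %in% remaining])
        if (step_target >= avail) {
          new_rm <- remaining # insufficient removable area: level emptied
          out$emptied[k] <- TRUE
        } else {
          ord <- order_patches(current, strategy, seed = child_seed(seed, k),
                               developments = if (strategy == "C") devs else NULL)
          areas <- current$patches$area_ha[match(ord, current$patches$patch_id)]
          sel <- remove_to_target(tibble::tibble(patch_id = ord, area_ha = areas),
                                  step_target)
          new_rm <- sel$removed
        }
      } else new_rm <- integer(0)
      removed <- c(removed, new_rm)
      if (strategy == "C" && length(new_rm) > 0) {
        for (id in new_rm) {
          g <- landscape$patches$geometry[[
            which(landscape$patches$patch_id == id)]]
          devs <- c(devs, g)
        }
      }
      out$landscapes[[k]] <- subset_landscape(setdiff(removable_ids, removed))
      if (strategy == "C") out$landscapes[[k]]$developments <- devs
      out$removal_log <- dplyr::bind_rows(
        out$removal_log,
        tibble::tibble(level = levels[k], patch_id = as.integer(new_rm)))
    }
  } else { # S
    out$removal_log <- tibble::tibble(level = numeric(0), patch_id = integer(0),
                                      retained_fraction = numeric(0))
    for (k in seq_along(levels)) {
      f <- 1 - levels[k]
      l <- landscape
      keep <- logical(nrow(l$patches))
      for (i in seq_len(nrow(l$patches))) {
        if (!l$patches$patch_id[i] %in% removable_ids) { keep[i] <- TRUE; next }
        g <- shrink_patch(l$patches$geometry[[i]], f)
        if (is.null(g)) { keep[i] <- FALSE; next }
        keep[i] <- TRUE
        l$patches$geometry[[i]] <- g
        l$patches$area_ha[i] <- parts_area(g) / 1e4
        cc <- parts_centroid(g)
        l$patches$cx[i] <- cc[1]; l$patches$cy[i] <- cc[2]
      }
      l$patches <- l$patches[keep, , drop = FALSE]
      out$landscapes[[k]] <- l
      out$removal_log <- dplyr::bind_rows(
        out$removal_log,
        tibble::tibble(level = levels[k],
                       patch_id = landscape$patches$patch_id[!keep],
                       retained_fraction = f))
    }
  }
  structure(out, class = "scenario_series")
}

#' @export
print.scenario_series <- function(x, ...) {
  cat(sprintf("<scenario_series %s> %d levels (%.0f%%-%.0f%% loss), present-day habitat %.1f ha\n",
              x$strategy, length(x$levels), 100 * min(x$levels),
              100 * max(x$levels), x$total_area_ha))
  invisible(x)
}
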