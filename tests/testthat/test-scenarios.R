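# Habitat-loss scenario engine.

area_side <- function(ha) sqrt(ha * 1e4) # square side for a given area

# landscape with known patch areas (well separated squares)
areas_landscape <- function(areas_ha, classes = rep(1L, length(areas_ha)),
                            developments = list()) {
  n <- length(areas_ha)
  geoms <- lapply(seq_len(n), function(i)
    square_geom(500 + ((i - 1) %% 8) * 900, 500 + ((i - 1) %/% 8) * 900,
                area_side(areas_ha[i]))[[1]])
  make_test_landscape(lapply(geoms, list), classes, extent = 8000,
                      developments = developments)
}

test_that("A1/A2 order by area with patch_id tie-breaks", {
  L <- areas_landscape(c(5, 1, 3))
  expect_identical(order_patches(L, "A1"), c(2L, 3L, 1L))
  expect_identical(order_patches(L, "A2"), c(1L, 3L, 2L))
  L_tie <- areas_landscape(c(2, 2, 1))
  expect_identical(order_patches(L_tie, "A1"), c(3L, 1L, 2L))
})

test_that("contagion ordering puts the patch touching a development first", {
  dev <- square_geom(500, 500, area_side(1))
  L <- areas_landscape(c(1, 1, 1), developments = dev) # patch 1 at distance 0
  ord <- order_patches(L, "C")
  expect_identical(ord[1], 1L)
  # distances increase along the row of patches
  expect_identical(ord, c(1L, 2L, 3L))
  expect_error(order_patches(areas_landscape(1), "C"), "developments")
})

test_that("R2 ranks by local commonness; R1 requires national cover", {
  L <- areas_landscape(c(30, 30, 15, 15, 10), c(1L, 1L, 2L, 2L, 3L))
  # class areas: 1 -> 60, 2 -> 30, 3 -> 10; commonest first
  ord <- order_patches(L, "R2", seed = 1)
  expect_identical(L$patches$habitat_class[match(ord, L$patches$patch_id)],
                   c(1L, 1L, 2L, 2L, 3L))
  # same seed, same order; different seed may permute within class
  expect_identical(order_patches(L, "R2", seed = 1), ord)
  L_na <- L
  L_na$classes$national_cover_ha <- NA_real_
  expect_error(order_patches(L_na, "R1"), "national_cover")
})

test_that("R1 uses the national commonness ranking", {
  # class 4 (improved grassland) is nationally commoner than class 1
  # (broadleaved woodland), which is commoner than class 9
  L <- areas_landscape(c(1, 1, 1), c(9L, 4L, 1L))
  ord <- order_patches(L, "R1", seed = 2)
  expect_identical(L$patches$habitat_class[match(ord, L$patches$patch_id)],
                   c(4L, 1L, 9L))
})

test_that("remove_to_target implements minimal overshoot", {
  sel <- remove_to_target(c(1, 2, 3, 4, 10), 2.0)
  expect_identical(sel$removed, 1:2) # cumulative 3.0 >= 2.0
  expect_equal(sel$removed_area, 3.0)
  expect_identical(remove_to_target(c(1, 2, 3), 0)$removed, integer(0))
  expect_error(remove_to_target(c(1, 2), 10), "exceeds")
})

test_that("removal prefix matches a cumulative-sum oracle on random patches", {
  set.seed(21)
  for (rep in 1:5) {
    areas <- exp(runif(200, log(0.05), log(20)))
    target <- 0.35 * sum(areas)
    sel <- remove_to_target(areas, target)
    cum <- cumsum(areas)
    n_or <- which(cum >= target)[1] # independent oracle
    expect_identical(length(sel$removed), as.integer(n_or))
    expect_gte(sum(areas[sel$removed]), target)
    expect_lt(sum(areas[sel$removed]) - areas[sel$removed[n_or]], target)
    expect_setequal(c(sel$removed, sel$retained), seq_along(areas))
  }
})

test_that("shrinkage reproduces circle and square closed forms", {
  circ <- circle_geom(0, 0, 10)
  g <- shrink_patch(circ, 0.81)
  a0 <- landsust:::parts_area(circ)
  expect_equal(landsust:::parts_area(g) / a0, 0.81, tolerance = 2e-4)
  # effective radius ~ 0.9 r (discretised-circle apothem scales the same way)
  r_eff <- mean(sqrt(g[[1]][, 1]^2 + g[[1]][, 2]^2))
  expect_equal(r_eff / 10, 0.9, tolerance = 1e-2)

  sq <- square_geom(0, 0, 2)
  g2 <- shrink_patch(sq, 0.25)
  expect_equal(landsust:::parts_area(g2), 1, tolerance = 1e-3)
  bb <- landsust:::parts_bbox(g2)
  expect_equal(bb[3] - bb[1], 1, tolerance = 1e-3) # side 1 = inward offset 0.5
})

test_that("shrinkage hits the target on random convex polygons", {
  set.seed(31)
  for (rep in 1:10) {
    pts <- cbind(runif(12, -50, 50), runif(12, -50, 50))
    hull <- pts[rev(grDevices::chull(pts)), ] # CCW convex ring
    g <- shrink_patch(list(hull), 0.5)
    expect_equal(landsust:::parts_area(g) / landsust:::ring_area(hull), 0.5,
                 tolerance = 2e-4)
  }
})

test_that("series have nine nested landscapes with conserved area (A1)", {
  set.seed(41)
  areas <- exp(runif(200, log(0.05), log(20)))
  # well-separated grid of squares
  geoms <- lapply(seq_along(areas), function(i)
    square_geom(600 + ((i - 1) %% 15) * 1200, 600 + ((i - 1) %/% 15) * 1200,
                area_side(areas[i]))[[1]])
  L <- make_test_landscape(lapply(geoms, list),
                           rep(1L, length(areas)), extent = 18000)
  ser <- make_scenario_series(L, "A1")
  expect_length(ser$landscapes, 9L)
  total <- ser$total_area_ha
  removed_prev <- integer(0)
  for (k in seq_along(ser$levels)) {
    lvl <- ser$levels[k]
    ids_k <- ser$landscapes[[k]]$patches$patch_id
    removed_k <- setdiff(L$patches$patch_id, ids_k)
    expect_true(all(removed_prev %in% removed_k)) # nested removals
    rem_area <- sum(ser$landscapes[[k]]$patches$area_ha)
    # conservation
    expect_equal(rem_area + sum(L$patches$area_ha[removed_k]), total,
                 tolerance = 1e-9)
    # overshoot bounds: ((1-f) total - max removed, (1-f) total]
    expect_lte(rem_area, (1 - lvl) * total + 1e-9)
    expect_gt(rem_area, (1 - lvl) * total -
                max(L$patches$area_ha[removed_k]) - 1e-9)
    removed_prev <- removed_k
  }
})

test_that("A2 at 90% loss retains only the smallest patches", {
  L <- areas_landscape(exp(seq(log(0.1), log(8), length.out = 20)))
  ser <- make_scenario_series(L, "A2")
  l9 <- ser$landscapes[[9]]
  removed <- setdiff(L$patches$patch_id, l9$patches$patch_id)
  expect_true(max(l9$patches$area_ha) <=
                min(L$patches$area_ha[removed]) + 1e-12)
})

test_that("rarity scenarios never remove rarer classes while commoner remain", {
  set.seed(51)
  L <- areas_landscape(runif(24, 0.5, 3),
                       classes = rep(c(4L, 1L, 9L), each = 8))
  for (strat in c("R1", "R2")) {
    ser <- make_scenario_series(L, strat, seed = 5)
    log1 <- ser$removal_log[ser$removal_log$level == 0.1, ]
    cls_rm <- L$patches$habitat_class[match(log1$patch_id, L$patches$patch_id)]
    # first removals come from the commonest class only
    common <- if (strat == "R1") 4L else
      as.integer(names(which.max(tapply(L$patches$area_ha,
                                        L$patches$habitat_class, sum))))
    expect_true(all(cls_rm == common))
  }
  # seed determinism of the randomised within-class order
  s1 <- make_scenario_series(L, "R1", seed = 9)$removal_log
  s2 <- make_scenario_series(L, "R1", seed = 9)$removal_log
  expect_identical(s1, s2)
})

test_that("contagion adds removals to the developments layer", {
  dev <- square_geom(500, 500, 100)
  L <- areas_landscape(rep(1, 10), developments = dev)
  ser <- make_scenario_series(L, "C")
  n_dev <- vapply(ser$landscapes, function(l) length(l$developments),
                  integer(1))
  expect_true(all(diff(n_dev) >= 0))
  expect_gt(n_dev[9], length(dev))
})

test_that("scenario S shrinks every patch to 1 - level of its area", {
  L <- areas_landscape(c(0.5, 2, 5))
  ser <- make_scenario_series(L, "S")
  for (k in c(1, 5, 9)) {
    lk <- ser$landscapes[[k]]
    expect_identical(nrow(lk$patches), 3L) # no patch vanishes here
    ratio <- lk$patches$area_ha /
      L$patches$area_ha[match(lk$patches$patch_id, L$patches$patch_id)]
    expect_true(all(abs(ratio - (1 - ser$levels[k])) <= 1.5e-4))
  }
})

test_that("freshwater patches are exempt from loss and from the total", {
  L <- areas_landscape(c(2, 2, 2, 2), c(1L, 1L, 1L, 16L))
  ser <- make_scenario_series(L, "A1")
  expect_equal(ser$total_area_ha, 6) # class 16 excluded
  for (l in ser$landscapes)
    expect_true(16L %in% l$patches$habitat_class)
  ser_s <- make_scenario_series(L, "S")
  fw <- ser_s$landscapes[[9]]$patches
  expect_equal(fw$area_ha[fw$habitat_class == 16L], 2, tolerance = 1e-9)
})
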