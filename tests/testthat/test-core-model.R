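# Domain types, habitat-map construction, grid assignment, GeoJSON IO.

test_that("polygon primitives match closed forms", {
  sq <- square_geom(10, 10, 4)[[1]]
  expect_equal(landsust:::ring_area(sq), 16)
  expect_equal(landsust:::ring_centroid(sq), c(10, 10))
  # discretised circle area: (n/2) r^2 sin(2 pi / n)
  circ <- circle_geom(0, 0, 5, n = 48)[[1]]
  expect_equal(landsust:::ring_area(circ), 48 / 2 * 25 * sin(2 * pi / 48),
               tolerance = 1e-12)
  expect_true(landsust:::point_in_ring(c(10, 10), sq))
  expect_false(landsust:::point_in_ring(c(13, 10), sq))
  # boundary distance between two unit squares 3 m apart
  a <- square_geom(0, 0, 2)[[1]]; b <- square_geom(5, 0, 2)[[1]]
  expect_equal(landsust:::ring_ring_dist(a, b), 3)
})

test_that("habitat map filters unsuitable classes", {
  L <- make_test_landscape(square_geom(1000, 1000, sqrt(5e4)), classes = 3L)
  prof <- list(species = "sp", dispersal_km = 1,
               suitable_classes = list(c(1L, 2L)), min_area_ha = 0.32)
  hm <- build_species_habitat_map(L, prof)
  expect_identical(nrow(hm$patches), 0L)
})

test_that("adjacent suitable patches dissolve additively and pass min area", {
  side <- sqrt(2000) # 0.20 ha squares
  geoms <- c(rect_geom(1000, 1000, side, side),
             rect_geom(1000 + side, 1000, side, side)) # share an edge
  L <- make_test_landscape(geoms, classes = c(1L, 2L))
  prof <- list(species = "sp", dispersal_km = 1,
               suitable_classes = list(c(1L, 2L)), min_area_ha = 0.32)
  hm <- build_species_habitat_map(L, prof)
  expect_identical(nrow(hm$patches), 1L)
  expect_equal(hm$patches$area_ha, 0.40, tolerance = 1e-9)
  # alone, each 0.20 ha patch fails the 0.32 ha minimum
  L1 <- make_test_landscape(rect_geom(1000, 1000, side, side), classes = 1L)
  expect_identical(nrow(build_species_habitat_map(L1, prof)$patches), 0L)
})

test_that("dissolve bridges gaps up to 3 m but not beyond", {
  side <- sqrt(2000)
  prof <- list(species = "sp", dispersal_km = 1,
               suitable_classes = list(1L), min_area_ha = 0.01)
  near <- c(rect_geom(1000, 1000, side, side),
            rect_geom(1000 + side + 2.5, 1000, side, side))
  far <- c(rect_geom(1000, 1000, side, side),
           rect_geom(1000 + side + 3.5, 1000, side, side))
  expect_identical(nrow(build_species_habitat_map(
    make_test_landscape(near, c(1L, 1L)), prof)$patches), 1L)
  expect_identical(nrow(build_species_habitat_map(
    make_test_landscape(far, c(1L, 1L)), prof)$patches), 2L)
})

test_that("dissolved area equals suitable input area minus discarded patches", {
  # 50 random non-overlapping suitable patches on a jittered grid
  set.seed(42)
  geoms <- list(); classes <- integer(0)
  k <- 0
  for (gx in 1:8) for (gy in 1:7) {
    if (k >= 50) break
    k <- k + 1
    side <- sqrt(runif(1, 100, 4e4))
    geoms <- c(geoms, rect_geom(gx * 900 + runif(1, -80, 80),
                                gy * 900 + runif(1, -80, 80),
                                side, side * runif(1, 0.6, 1.4)))
    classes <- c(classes, sample(1:3, 1))
  }
  L <- make_test_landscape(geoms, classes)
  prof <- list(species = "sp", dispersal_km = 1,
               suitable_classes = list(c(1L, 2L)), min_area_ha = 0.32)
  hm <- build_species_habitat_map(L, prof)
  # oracle: patches are pairwise disjoint, so the union area of the suitable
  # set equals its summed area; output must equal that minus what the
  # min-area rule discarded
  suit_total <- sum(L$patches$area_ha[L$patches$habitat_class %in% c(1, 2)])
  discarded <- suit_total - sum(hm$patches$area_ha)
  expect_gte(discarded, 0)
  hm_all <- build_species_habitat_map(
    L, list(species = "sp", dispersal_km = 1,
            suitable_classes = list(c(1L, 2L)), min_area_ha = 1e-9))
  expect_equal(sum(hm_all$patches$area_ha), suit_total, tolerance = 1e-9)
  small <- hm_all$patches$area_ha < 0.32
  expect_equal(sum(hm_all$patches$area_ha[small]), discarded, tolerance = 1e-9)
})

test_that("dissolve is idempotent", {
  set.seed(7)
  geoms <- lapply(1:25, function(i)
    rect_geom(runif(1, 200, 7800), runif(1, 200, 7800),
              runif(1, 20, 120), runif(1, 20, 120))[[1]])
  geoms <- lapply(geoms, list)
  L <- make_test_landscape(geoms, sample(1:2, 25, replace = TRUE))
  prof <- list(species = "sp", dispersal_km = 1,
               suitable_classes = list(c(1L, 2L)), min_area_ha = 0.01)
  hm1 <- build_species_habitat_map(L, prof)
  hm2 <- build_species_habitat_map(hm1, prof)
  expect_identical(nrow(hm2$patches), nrow(hm1$patches))
  expect_equal(sort(hm2$patches$area_ha), sort(hm1$patches$area_ha),
               tolerance = 1e-12)
})

test_that("grid assignment follows the half-open centroid convention", {
  g <- grid_spec(c(0, 0), 2000, 4, 4)
  p <- tibble::tibble(patch_id = 1:3, cx = c(1000, 2000, 3999.999),
                      cy = c(1000, 2000, 0))
  a <- assign_patches_to_cells(p, g)
  expect_identical(a$cell_col, c(0L, 1L, 1L)) # edge point goes +x side
  expect_identical(a$cell_row, c(0L, 1L, 0L))
  # outside the grid -> error naming the patch
  p_bad <- tibble::tibble(patch_id = 99L, cx = 8000, cy = 100)
  expect_error(assign_patches_to_cells(p_bad, g), "99")
})

test_that("grid assignment matches a floor-division oracle and partitions", {
  set.seed(11)
  g <- grid_spec(c(-500, 300), 1250, 10, 10)
  p <- tibble::tibble(patch_id = 1:100,
                      cx = runif(100, -500, -500 + 12500),
                      cy = runif(100, 300, 300 + 12500))
  a <- assign_patches_to_cells(p, g)
  expect_identical(a$cell_col, as.integer(floor((p$cx + 500) / 1250)))
  expect_identical(a$cell_row, as.integer(floor((p$cy - 300) / 1250)))
  expect_identical(nrow(a), 100L) # every patch in exactly one cell
  expect_false(anyDuplicated(a$patch_id) > 0)
})

test_that("GeoJSON write/read round-trips a landscape", {
  geoms <- c(square_geom(1000, 1000, 100), circle_geom(3000, 3000, 80),
             rect_geom(5000, 2000, 150, 60))
  L <- make_test_landscape(geoms, c(1L, 2L, 3L),
                           developments = list(square_geom(4000, 4000, 200)[[1]]))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_landscape(L, f)
  L2 <- read_landscape(f)
  expect_identical(nrow(L2$patches), 3L)
  expect_identical(L2$patches$habitat_class, L$patches$habitat_class)
  expect_equal(L2$patches$area_ha, L$patches$area_ha, tolerance = 1e-9)
  expect_equal(L2$grid$cell_size, 2000)
  expect_identical(length(L2$developments), 1L)
  # writing the reread landscape reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_landscape(L2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("GeoJSON reader rejects malformed features with diagnostics", {
  L <- make_test_landscape(square_geom(1000, 1000, 100), 1L)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_landscape(L, f)
  doc <- jsonlite::read_json(f)
  doc$features[[1]]$properties$habitat_class <- NULL
  f_bad <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(doc, f_bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_landscape(f_bad), "habitat_class")
  doc2 <- jsonlite::read_json(f)
  doc2$features[[1]]$geometry$type <- "Point"
  jsonlite::write_json(doc2, f_bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_landscape(f_bad), "non-polygon")
})

test_that("areas recomputed on read agree with a geometry oracle", {
  set.seed(5)
  geoms <- lapply(1:20, function(i) {
    if (i %% 2 == 0) circle_geom(runif(1, 500, 7500), runif(1, 500, 7500),
                                 runif(1, 20, 100))[[1]]
    else rect_geom(runif(1, 500, 7500), runif(1, 500, 7500),
                   runif(1, 30, 200), runif(1, 30, 200))[[1]]
  })
  L <- make_test_landscape(lapply(geoms, list), rep(1L, 20))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_landscape(L, f)
  L2 <- read_landscape(f)
  expect_equal(sum(L2$patches$area_ha), sum(L$patches$area_ha),
               tolerance = 1e-9)
})

test_that("landscape validation flags inconsistent and invalid patches", {
  L <- make_test_landscape(square_geom(1000, 1000, 100), 1L)
  expect_silent(validate_landscape(L, check_overlap = TRUE))
  L_bad <- L
  L_bad$patches$area_ha[1] <- 99
  expect_error(validate_landscape(L_bad), "inconsistent")
  # self-intersecting bowtie
  L_bow <- L
  L_bow$patches$geometry[[1]] <- list(cbind(c(0, 100, 0, 100), c(0, 100, 100, 0)))
  expect_error(validate_landscape(L_bow), "invalid geometry")
  # overlapping patches detected
  L_ov <- make_test_landscape(c(square_geom(1000, 1000, 100),
                                square_geom(1040, 1000, 100)), c(1L, 1L))
  expect_error(validate_landscape(L_ov, check_overlap = TRUE), "overlap")
})

test_that("species profile reader parses classes and validates rows", {
  profs <- species_profiles()
  expect_identical(nrow(profs), 10L)
  expect_identical(profs$suitable_classes[[7]], c(1L, 2L)) # jay: woodland only
  expect_equal(profs$min_area_ha[profs$species == "Poecile palustris"], 2.10)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,dispersal_km,classes,min_area_ha",
               "bad,-1,1;2,0.5"), f)
  expect_error(read_species_profiles(f), "bad")
})
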