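# Shared fixtures and independent oracles.

# -- geometry builders --------------------------------------------------------

square_geom <- function(cx, cy, side) {
  list(cbind(c(cx - side / 2, cx + side / 2, cx + side / 2, cx - side / 2),
             c(cy - side / 2, cy - side / 2, cy + side / 2, cy + side / 2)))
}

rect_geom <- function(cx, cy, w, h) {
  list(cbind(c(cx - w / 2, cx + w / 2, cx + w / 2, cx - w / 2),
             c(cy - h / 2, cy - h / 2, cy + h / 2, cy + h / 2)))
}

circle_geom <- function(cx, cy, r, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(cbind(cx + r * cos(th), cy + r * sin(th)))
}

# patch tibble from geometries (areas/centroids recomputed like the package);
# a bare matrix element is treated as a single-part geometry
make_patches <- function(geoms, classes = rep(1L, length(geoms)),
                         ids = seq_along(geoms)) {
  geoms <- lapply(geoms, function(g) if (is.matrix(g)) list(g) else g)
  shoelace <- function(xy) {
    n <- nrow(xy); j <- c(2:n, 1)
    abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2)
  }
  area <- vapply(geoms, function(g) sum(vapply(g, shoelace, numeric(1))),
                 numeric(1))
  cent <- t(vapply(geoms, function(g) {
    a <- vapply(g, shoelace, numeric(1))
    cs <- t(vapply(g, function(r) colMeans(r), numeric(2)))
    c(sum(cs[, 1] * a), sum(cs[, 2] * a)) / sum(a)
  }, numeric(2)))
  tibble::tibble(patch_id = as.integer(ids), habitat_class = as.integer(classes),
                 area_ha = area / 1e4, cx = cent[, 1], cy = cent[, 2],
                 geometry = geoms)
}

# note: centroid via colMeans is exact for the symmetric shapes used here

make_test_landscape <- function(geoms, classes, extent = 8000,
                                developments = list(),
                                classes_tbl = habitat_classes()) {
  landscape(make_patches(geoms, classes),
            study_boundary = square_geom(extent / 2, extent / 2, extent)[[1]],
            city_boundary = square_geom(extent / 2, extent / 2, extent * 0.5)[[1]],
            developments = developments,
            grid = grid_spec(c(0, 0), 2000, ceiling(extent / 2000),
                             ceiling(extent / 2000)),
            classes = classes_tbl)
}

# dimensionless point patches for IFM tests (geometry never touched)
point_patches <- function(areas, x_km, y_km = rep(0, length(x_km))) {
  tibble::tibble(patch_id = seq_along(areas), habitat_class = 1L,
                 area_ha = areas, cx = x_km * 1000, cy = y_km * 1000,
                 geometry = vector("list", length(areas)))
}

# -- exact Markov-chain oracle for small IFM systems --------------------------
# States are subsets of patches encoded 0..2^n-1 (bit i = patch i occupied).
# Per-patch probabilities written out from the model formulas, independent of
# the package's transition code.

ifm_exact_chain <- function(patches, params) {
  n <- nrow(patches)
  A <- patches$area_ha
  d_km <- as.matrix(dist(cbind(patches$cx, patches$cy))) / 1000
  n_states <- 2^n
  P <- matrix(0, n_states, n_states)
  for (s in 0:(n_states - 1)) {
    occ <- as.integer(intToBits(s))[1:n]
    S <- vapply(1:n, function(i)
      sum(occ[-i] * exp(-params$alpha * d_km[i, -i]) * A[-i]^params$b),
      numeric(1))
    C <- S^2 / (S^2 + params$y^2)
    E <- pmin(1, (params$ey2 / params$y^2) / A^params$x)
    Ee <- if (params$rescue) E * (1 - C) else E
    p_occ_next <- ifelse(occ == 1, 1 - Ee, C) # P(patch occupied next step)
    for (t in 0:(n_states - 1)) {
      occ_t <- as.integer(intToBits(t))[1:n]
      P[s + 1, t + 1] <- prod(ifelse(occ_t == 1, p_occ_next, 1 - p_occ_next))
    }
  }
  P
}

# quasi-stationary distribution: normalised left eigenvector of the chain
# restricted to transient (non-empty) states
ifm_qsd <- function(P) {
  Q <- P[-1, -1, drop = FALSE]
  e <- eigen(t(Q))
  k <- which.max(Re(e$values))
  v <- abs(Re(e$vectors[, k]))
  v / sum(v)
}

# -- exact Mann-Whitney oracle ------------------------------------------------
# Brute-force enumeration of the U distribution over all assignments of the
# pooled sample (no ties assumed), with the two-sided doubling convention.

exact_u_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_stat(x, y)
  combos <- combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# independent partial-preference decision: exact-U gate, mean direction
oracle_partial_preference <- function(samples, alpha_level = 0.05) {
  nms <- names(samples)
  k <- length(samples)
  m <- matrix(0L, k, k, dimnames = list(nms, nms))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      p <- exact_u_pvalue(samples[[a]], samples[[b]])
      if (p < alpha_level) {
        if (mean(samples[[a]]) > mean(samples[[b]])) m[a, b] <- 1L
        else if (mean(samples[[b]]) > mean(samples[[a]])) m[b, a] <- 1L
      }
    }
  }
  m
}

# -- parameter-recovery harness ----------------------------------------------
# 400 patches scattered over a 55 x 55 km plane with areas 0.25-15 ha; the
# generating process uses x = 0.8, e*y^2 = 0.3, alpha = 1; 80 discarded
# transitions bring the chain near quasi-stationarity before the recorded
# 20-year history.

recovery_rep <- function(seed, years = 20, mode = "constrained") {
  set.seed(seed)
  n <- 400
  patches <- point_patches(exp(runif(n, log(0.25), log(15))),
                           x_km = runif(n, 0, 55), y_km = runif(n, 0, 55))
  truth <- ifm_params(alpha = 1, x = 0.8, ey2 = 0.3)
  h <- generate_occupancy_history(patches, truth, years = years,
                                  initial_prevalence = 0.7, seed = seed,
                                  discard = 80)
  fit <- fit_ifm(h, patches, alpha = 1, mode = mode)
  list(x = fit$params$x, lney2 = log(fit$params$ey2),
       coef_lnS = unname(fit$params$fitted_coefs["coef_lnS"]))
}
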