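# Planar geometry utilities for convex patch polygons.
#
# Geometries are stored as "parts": a list of N x 2 numeric matrices, each an
# open (last vertex != first), counter-clockwise ring in projected metre
# coordinates. Generated patches are rectangles and discretised circles, so
# every part is convex; dissolved patches are multipart.

#' @noRd
ring_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' @noRd
ring_area <- function(xy) abs(ring_area_signed(xy))

#' @noRd
ring_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# ensure counter-clockwise orientation
#' @noRd
ring_ccw <- function(xy) {
  if (ring_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' @noRd
parts_area <- function(parts) sum(vapply(parts, ring_area, numeric(1)))

# area-weighted centroid of a multipart geometry
#' @noRd
parts_centroid <- function(parts) {
  a <- vapply(parts, ring_area, numeric(1))
  cs <- t(vapply(parts, ring_centroid, numeric(2)))
  c(sum(cs[, 1] * a), sum(cs[, 2] * a)) / sum(a)
}

#' @noRd
ring_bbox <- function(xy) c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))

#' @noRd
parts_bbox <- function(parts) {
  bb <- vapply(parts, ring_bbox, numeric(4))
  c(min(bb[1, ]), min(bb[2, ]), max(bb[3, ]), max(bb[4, ]))
}

#' @noRd
bbox_gap <- function(a, b) {
  dx <- max(a[1] - b[3], b[1] - a[3], 0)
  dy <- max(a[2] - b[4], b[2] - a[4], 0)
  sqrt(dx^2 + dy^2)
}

# even-odd ray casting; points on the boundary count as inside
#' @noRd
point_in_ring <- function(pt, xy) {
  x <- pt[1]; y <- pt[2]
  vx <- xy[, 1]; vy <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j[i]]; yj <- vy[j[i]]
    if ((yi > y) != (yj > y)) {
      xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xint) inside <- !inside
    }
  }
  inside
}

#' @noRd
point_in_parts <- function(pt, parts) {
  for (p in parts) if (point_in_ring(pt, p)) return(TRUE)
  FALSE
}

# squared distances from every point of P (n x 2) to every segment
# (S1[k, ] -> S2[k, ]); returns an n x m matrix
#' @noRd
points_segs_dist2 <- function(P, S1, S2) {
  dx <- S2[, 1] - S1[, 1]; dy <- S2[, 2] - S1[, 2]
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- 1e-300
  tx <- outer(P[, 1], S1[, 1], "-")
  ty <- outer(P[, 2], S1[, 2], "-")
  tt <- sweep(sweep(tx, 2, dx, "*") + sweep(ty, 2, dy, "*"), 2, len2, "/")
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  qx <- tx - sweep(tt, 2, dx, "*")
  qy <- ty - sweep(tt, 2, dy, "*")
  qx * qx + qy * qy
}

#' @noRd
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# minimum boundary-to-boundary distance between two convex rings (0 on
# overlap). For disjoint segment sets the minimum is attained at a vertex of
# one ring and an edge of the other; crossing/containment cases are caught
# by the point-in-ring and intersection-area checks.
#' @noRd
ring_ring_dist <- function(a, b) {
  if (point_in_ring(a[1, ], b) || point_in_ring(b[1, ], a)) return(0)
  na <- nrow(a); nb <- nrow(b)
  a2 <- a[c(2:na, 1), , drop = FALSE]
  b2 <- b[c(2:nb, 1), , drop = FALSE]
  d <- sqrt(min(points_segs_dist2(a, b, b2), points_segs_dist2(b, a, a2)))
  if (d > 0 && bbox_gap(ring_bbox(a), ring_bbox(b)) == 0 &&
      convex_intersection_area(a, b) > 0) return(0)
  d
}

# minimum distance between two multipart geometries, with bbox short-circuit
#' @noRd
parts_dist <- function(pa, pb, upper = Inf) {
  dmin <- Inf
  for (a in pa) {
    ba <- ring_bbox(a)
    for (b in pb) {
      if (bbox_gap(ba, ring_bbox(b)) >= min(dmin, upper)) next
      d <- ring_ring_dist(a, b)
      if (d < dmin) dmin <- d
      if (dmin == 0) return(0)
    }
  }
  dmin
}

# Sutherland-Hodgman clip of a ring by the half-plane n . x <= c
# (vectorised: candidate rows are vertices interleaved with edge crossings)
#' @noRd
clip_halfplane <- function(xy, nrm, cc) {
  n <- nrow(xy)
  s <- as.numeric(xy %*% nrm) - cc
  jj <- c(2:n, 1)
  ci <- s <= 1e-12
  cross <- ci != ci[jj]
  t <- ifelse(cross, s / (s - s[jj]), 0)
  inter <- xy + t * (xy[jj, , drop = FALSE] - xy)
  keep <- c(rbind(ci, cross))
  cand <- matrix(0, 2 * n, 2)
  cand[seq(1, 2 * n, by = 2), ] <- xy
  cand[seq(2, 2 * n, by = 2), ] <- inter
  out <- cand[keep, , drop = FALSE]
  if (nrow(out) < 3) return(NULL)
  out
}

# inward offset of a convex CCW ring by distance d (>= 0); NULL if it vanishes
#' @noRd
ring_inward_offset <- function(xy, d) {
  if (d <= 0) return(xy)
  out <- xy
  n <- nrow(xy)
  j <- c(2:n, 1)
  for (i in seq_len(n)) {
    e <- xy[j[i], ] - xy[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(e[2], -e[1]) / len  # outward normal for CCW ring
    out <- clip_halfplane(out, nrm, sum(nrm * xy[i, ]) - d)
    if (is.null(out)) return(NULL)
  }
  out
}

#' @noRd
parts_inward_offset <- function(parts, d) {
  out <- list()
  for (p in parts) {
    q <- ring_inward_offset(p, d)
    if (!is.null(q)) out <- c(out, list(q))
  }
  if (length(out) == 0) NULL else out
}

# intersection area of two convex rings (clip a by b's edges)
#' @noRd
convex_intersection_area <- function(a, b) {
  out <- a
  n <- nrow(b)
  j <- c(2:n, 1)
  for (i in seq_len(n)) {
    e <- b[j[i], ] - b[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(e[2], -e[1]) / len
    out <- clip_halfplane(out, nrm, sum(nrm * b[i, ]))
    if (is.null(out)) return(0)
  }
  ring_area(out)
}

# simple-polygon check: no two non-adjacent edges intersect
#' @noRd
ring_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      if (k == i || j[k] == i || j[i] == k) next
      if (segments_intersect(xy[i, ], xy[j[i], ], xy[k, ], xy[j[k], ])) return(FALSE)
    }
  }
  TRUE
}

#' @noRd
rect_ring <- function(cx, cy, w, h) {
  ring_ccw(cbind(
    c(cx - w / 2, cx + w / 2, cx + w / 2, cx - w / 2),
    c(cy - h / 2, cy - h / 2, cy + h / 2, cy + h / 2)
  ))
}

#' @noRd
circle_ring <- function(cx, cy, r, n = 48L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
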