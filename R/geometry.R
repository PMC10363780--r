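# Planar geometry primitives shared by the landscape and simulation code.
# Polygons are n x 2 matrices of vertices (open rings: the closing edge
# last -> first is implicit). Polylines are n x 2 matrices of waypoints.

#' Shoelace area of a polygon
#' @param poly n x 2 matrix of vertices.
#' @return Area in squared input units (always positive).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorised over points. Points exactly on an edge may fall on either
#' side; callers that care about boundaries test distances instead.
#'
#' @param px,py Point coordinates.
#' @param poly n x 2 vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xj <- x[c(n, seq_len(n - 1L))]; yj <- y[c(n, seq_len(n - 1L))]
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (yj[i] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) * (xj[i] - x[i]) / (yj[i] - y[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

# distance from each point to one segment (a,b); vectorised over points
.dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Distance from points to a polyline
#' @param px,py Point coordinates.
#' @param line n x 2 waypoint matrix.
#' @return Numeric vector of Euclidean distances (same units as input).
#' @export
dist_to_polyline <- function(px, py, line) {
  if (nrow(line) == 1L) return(sqrt((px - line[1, 1])^2 + (py - line[1, 2])^2))
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1L)) {
    d <- pmin(d, .dist_point_segment(px, py, line[i, 1], line[i, 2],
                                     line[i + 1, 1], line[i + 1, 2]))
  }
  d
}

#' Distance from points to a polygon boundary
#' @inheritParams dist_to_polyline
#' @param poly n x 2 vertex matrix (ring closed implicitly).
#' @return Numeric vector of distances to the nearest boundary point.
#' @export
dist_to_ring <- function(px, py, poly) {
  dist_to_polyline(px, py, rbind(poly, poly[1, , drop = FALSE]))
}

#' Repair a self-intersecting ring
#'
#' Rings whose signed shoelace area is degenerate (bow-ties) are replaced by
#' their convex hull, which preserves the covered extent for the small
#' building/patch footprints this pipeline consumes. Valid rings are
#' returned unchanged.
#'
#' @param poly n x 2 vertex matrix.
#' @return List with elements `poly` (repaired matrix) and `repaired` flag.
#' @export
repair_ring <- function(poly) {
  if (.ring_self_intersects(poly)) {
    h <- grDevices::chull(poly[, 1], poly[, 2])
    list(poly = poly[h, , drop = FALSE], repaired = TRUE)
  } else {
    list(poly = poly, repaired = FALSE)
  }
}

.seg_intersects <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) && ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

.ring_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      if (.seg_intersects(poly[idx[i, 1], ], poly[idx[i, 2], ],
                          poly[idx[j, 1], ], poly[idx[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

#' Axis-aligned rectangle as a polygon matrix
#' @param cx,cy Centre. @param w,h Width and height. @param angle Rotation (radians).
#' @return 4 x 2 vertex matrix.
#' @export
rect_poly <- function(cx, cy, w, h, angle = 0) {
  base <- cbind(c(-w, w, w, -w) / 2, c(-h, -h, h, h) / 2)
  if (angle != 0) {
    rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
    base <- base %*% t(rot)
  }
  cbind(base[, 1] + cx, base[, 2] + cy)
}
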