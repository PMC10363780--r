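# Landscape covariates. Villages are derived from building footprints by a
# 50 m morphological closing (dilate, merge, erode), implemented on a fine
# raster with exact Euclidean distance transforms: buildings closer than
# 100 m end up in one cluster, the closing fills the spaces between them,
# and any resulting cluster larger than 1.5 ha counts as a village. Roads
# are filtered to the five traffic-bearing categories; dense vegetation is
# a binary point-in-patch covariate.

ROAD_CATEGORIES <- c("motorway", "trunk", "primary", "secondary", "tertiary")

#' Filter a road layer to traffic-bearing categories
#'
#' Keeps motorway, trunk, primary, secondary and tertiary roads; drops
#' residential roads, tracks and anything unrecognised (with a message).
#'
#' @param roads List of `list(coords, category)` road lines
#'   (from [load_landscape_layers()] or the simulator).
#' @return Filtered list of the same structure.
#' @export
filter_roads <- function(roads) {
  cats <- vapply(roads, function(r) r$category, character(1))
  keep <- cats %in% ROAD_CATEGORIES
  dropped <- unique(cats[!keep])
  if (length(dropped))
    message("dropped road categories: ", paste(dropped, collapse = ", "))
  out <- roads[keep]
  if (!length(out)) warning("road network empty after category filtering")
  out
}

.rasterize_polys <- function(polys, x0, y0, nx, ny, res) {
  m <- matrix(FALSE, nx, ny)
  xs <- x0 + (seq_len(nx) - 1) * res
  ys <- y0 + (seq_len(ny) - 1) * res
  for (p in polys) {
    ix <- which(xs >= min(p[, 1]) - res & xs <= max(p[, 1]) + res)
    iy <- which(ys >= min(p[, 2]) - res & ys <= max(p[, 2]) + res)
    if (!length(ix) || !length(iy)) next
    gx <- rep(xs[ix], times = length(iy))
    gy <- rep(ys[iy], each = length(ix))
    inside <- point_in_polygon(gx, gy, p)
    m[ix, iy] <- m[ix, iy] | matrix(inside, length(ix), length(iy))
  }
  m
}

# distance (map units) from every cell to the TRUE region of mask
.dist_to_mask <- function(mask, res) {
  d <- EBImage::distmap(1 - mask)  # background pixels: distance to mask
  as.matrix(d) * res
}

#' Derive village polygons from building footprints
#'
#' Morphological closing of the building layer with a disc of
#' `buffer_m`: buildings whose footprints come within `2 * buffer_m` of
#' each other are merged into one cluster, the space between them is
#' filled, and the cluster edge is shrunk back to the peripheral
#' buildings. Clusters with closed area strictly greater than
#' `min_area_m2` are villages.
#'
#' Implemented on a raster of resolution `res` via Euclidean distance
#' transforms (dilation = distance-to-buildings <= buffer; erosion =
#' distance-to-outside >= buffer). Buildings are always contained in the
#' result.
#'
#' @param buildings List of building polygons (n x 2 matrices, planar m).
#' @param buffer_m Closing radius (default 50).
#' @param min_area_m2 Minimum closed-cluster area (default 15000 = 1.5 ha).
#' @param res Raster resolution in meters (default 2).
#' @param pad Extent padding around the building bounding box (default
#'   `2 * buffer_m + 4 * res`).
#' @return Object of class `villages`: raster origin/resolution, a label
#'   matrix (0 = outside), per-village areas, boundary cell centres, and
#'   contour polygons for plotting.
#' @export
derive_villages <- function(buildings, buffer_m = 50, min_area_m2 = 15000,
                            res = 2, pad = NULL) {
  if (!length(buildings)) {
    warning("empty building layer: no villages")
    return(structure(list(x0 = 0, y0 = 0, res = res, labels = matrix(0L, 0, 0),
                          areas_m2 = numeric(), n = 0L,
                          boundary = cbind(x = numeric(), y = numeric()),
                          polygons = list(), buffer_m = buffer_m,
                          min_area_m2 = min_area_m2), class = "villages"))
  }
  if (is.null(pad)) pad <- 2 * buffer_m + 4 * res
  allb <- do.call(rbind, buildings)
  x0 <- floor(min(allb[, 1]) - pad); y0 <- floor(min(allb[, 2]) - pad)
  nx <- ceiling((max(allb[, 1]) + pad - x0) / res) + 1L
  ny <- ceiling((max(allb[, 2]) + pad - y0) / res) + 1L
  A <- .rasterize_polys(buildings, x0, y0, nx, ny, res)
  dil <- A | (.dist_to_mask(A, res) <= buffer_m)
  # cluster identity comes from the dilated (merged-buffer) layer
  lab_dil <- EBImage::bwlabel(dil * 1)
  d_out <- as.matrix(EBImage::distmap(dil)) * res  # inside dil: dist to outside
  closed <- (d_out >= buffer_m) | A
  labels <- matrix(0L, nx, ny)
  labels[closed] <- as.integer(as.matrix(lab_dil))[closed]
  areas <- tabulate(labels[labels > 0]) * res^2
  keep <- which(areas > min_area_m2)
  relab <- integer(length(areas)); relab[keep] <- seq_along(keep)
  labels[] <- ifelse(labels > 0, relab[labels], 0L)
  if (!length(keep)) warning("no building cluster exceeds the village area threshold")
  bnd <- .boundary_cells(labels > 0)
  structure(list(
    x0 = x0, y0 = y0, res = res, labels = labels,
    areas_m2 = areas[keep], n = length(keep),
    boundary = cbind(x = x0 + (bnd[, 1] - 1) * res, y = y0 + (bnd[, 2] - 1) * res),
    polygons = .label_contours(labels, x0, y0, res),
    buffer_m = buffer_m, min_area_m2 = min_area_m2), class = "villages")
}

# indices (i, j) of TRUE cells with a FALSE/edge 4-neighbour
.boundary_cells <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  if (!any(mask)) return(cbind(integer(), integer()))
  padded <- matrix(FALSE, nx + 2, ny + 2)
  padded[2:(nx + 1), 2:(ny + 1)] <- mask
  core <- padded[2:(nx + 1), 2:(ny + 1)]
  nb <- padded[1:nx, 2:(ny + 1)] & padded[3:(nx + 2), 2:(ny + 1)] &
    padded[2:(nx + 1), 1:ny] & padded[2:(nx + 1), 3:(ny + 2)]
  which(core & !nb, arr.ind = TRUE)
}

.label_contours <- function(labels, x0, y0, res) {
  if (!any(labels > 0)) return(list())
  oc <- EBImage::ocontour(EBImage::Image(labels))
  lapply(oc, function(m) cbind(x = x0 + m[, 1] * res, y = y0 + m[, 2] * res))
}

#' @export
print.villages <- function(x, ...) {
  cat(sprintf("%d village(s); areas (ha): %s\n", x$n,
              paste(sprintf("%.2f", x$areas_m2 / 1e4), collapse = ", ")))
  invisible(x)
}

#' Signed distance to the nearest village edge
#'
#' Positive outside, negative inside, zero on the edge: the convention
#' makes "distance to village" a single continuous covariate across the
#' village boundary.
#'
#' @param px,py Point coordinates (planar meters).
#' @param villages A [derive_villages()] object with at least one village.
#' @return Numeric vector of signed distances (meters, raster-accurate to
#'   about one cell).
#' @export
signed_distance_to_village <- function(px, py, villages) {
  if (villages$n == 0) stop("village layer is empty: distance undefined")
  ix <- round((px - villages$x0) / villages$res) + 1
  iy <- round((py - villages$y0) / villages$res) + 1
  ok <- ix >= 1 & ix <= nrow(villages$labels) & iy >= 1 & iy <= ncol(villages$labels)
  inside <- logical(length(px))
  inside[ok] <- villages$labels[cbind(ix[ok], iy[ok])] > 0
  b <- villages$boundary
  d <- numeric(length(px))
  chunk <- max(1L, floor(5e6 / max(1, nrow(b))))
  for (s in seq(1, length(px), by = chunk)) {
    e <- min(s + chunk - 1L, length(px))
    dx <- outer(px[s:e], b[, 1], "-"); dy <- outer(py[s:e], b[, 2], "-")
    d[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  ifelse(inside, -d, d)
}

#' Distance to the nearest retained road
#'
#' @param px,py Point coordinates (planar meters).
#' @param roads Filtered road list from [filter_roads()].
#' @return Numeric vector of distances (meters).
#' @export
distance_to_road <- function(px, py, roads) {
  if (!length(roads)) stop("road layer is empty: distance undefined")
  d <- rep(Inf, length(px))
  for (r in roads) d <- pmin(d, dist_to_polyline(px, py, r$coords))
  d
}

#' Dense-vegetation indicator
#'
#' @param px,py Point coordinates (planar meters).
#' @param vegetation List of vegetation-patch polygons.
#' @return Integer vector: 1 inside a dense-vegetation patch, else 0.
#' @export
vegetation_class <- function(px, py, vegetation) {
  inside <- logical(length(px))
  for (p in vegetation) {
    cand <- which(!inside & px >= min(p[, 1]) & px <= max(p[, 1]) &
                    py >= min(p[, 2]) & py <= max(p[, 2]))
    if (length(cand)) inside[cand] <- point_in_polygon(px[cand], py[cand], p)
  }
  as.integer(inside)
}

#' Evaluate the standard covariate triple at points
#'
#' @param px,py Coordinates. @param villages A `villages` object.
#' @param roads Filtered roads. @param vegetation Vegetation polygons.
#' @return Data frame `veg`, `d_village`, `d_road` (meters).
#' @export
landscape_covariates <- function(px, py, villages, roads, vegetation) {
  data.frame(veg = vegetation_class(px, py, vegetation),
             d_village = signed_distance_to_village(px, py, villages),
             d_road = distance_to_road(px, py, roads))
}
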