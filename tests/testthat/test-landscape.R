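test_that("road filtering keeps the five traffic categories only", {
  roads <- list(list(coords = cbind(0:1, 0), category = "motorway"),
                list(coords = cbind(0:1, 1), category = "residential"),
                list(coords = cbind(0:1, 2), category = "track"),
                list(coords = cbind(0:1, 3), category = "tertiary"))
  kept <- suppressMessages(filter_roads(roads))
  expect_equal(vapply(kept, `[[`, "", "category"), c("motorway", "tertiary"))
  expect_warning(suppressMessages(filter_roads(roads[2:3])), "empty")
})

test_that("village closing merges at 90 m, splits at 110 m, keeps buildings", {
  # one isolated 20x20 building: closing is the identity, area < 1.5 ha
  b1 <- list(rect_poly(0, 0, 20, 20))
  expect_warning(v0 <- derive_villages(b1, res = 1), "threshold")
  expect_equal(v0$n, 0)
  v1 <- derive_villages(b1, res = 1, min_area_m2 = 1)
  expect_equal(v1$n, 1)
  # identity on a convex building, up to one raster cell along the edge
  expect_lt(abs(v1$areas_m2 - 400), 4 * 20 * 1)
  # two 10x20 buildings, nearest edges 90 m apart: buffers overlap -> merge
  mk_pair <- function(gap) list(rect_poly(0, 0, 10, 20),
                                rect_poly(10 + gap, 0, 10, 20))
  v90 <- derive_villages(mk_pair(90), res = 1, min_area_m2 = 1)
  expect_equal(v90$n, 1)
  # same buildings 110 m apart: two separate components
  v110 <- derive_villages(mk_pair(110), res = 1, min_area_m2 = 1)
  expect_equal(v110$n, 2)
  # at the 1.5 ha default neither small component survives
  expect_warning(v110b <- derive_villages(mk_pair(110), res = 1), "threshold")
  expect_equal(v110b$n, 0)
  # a dense cluster closes into one village above 1.5 ha, containing
  # every building footprint
  set.seed(5)
  bl <- lapply(1:30, function(i) rect_poly(runif(1, -100, 100),
                                           runif(1, -100, 100), 15, 15))
  vc <- derive_villages(bl, res = 2)
  expect_equal(vc$n, 1)
  expect_gt(vc$areas_m2, 15000)
  ctr <- t(vapply(bl, colMeans, numeric(2)))
  expect_true(all(signed_distance_to_village(ctr[, 1], ctr[, 2], vc) < 0))
})

test_that("village closing is idempotent", {
  set.seed(6)
  bl <- lapply(1:25, function(i) rect_poly(runif(1, -90, 90),
                                           runif(1, -90, 90), 18, 18))
  v1 <- derive_villages(bl, res = 2)
  v2 <- derive_villages(v1$polygons, res = 2)
  expect_equal(v2$n, v1$n)
  expect_lt(abs(v2$areas_m2 - v1$areas_m2) / v1$areas_m2, 0.02)
})

test_that("signed village distance: sign convention, oracle, continuity", {
  # a single square 'village': force acceptance with min_area 1
  sq <- rect_poly(0, 0, 200, 200)
  v <- derive_villages(list(sq), res = 1, min_area_m2 = 1)
  expect_equal(v$n, 1)
  d_in <- signed_distance_to_village(c(0, 80), c(0, 0), v)
  expect_lt(d_in[1], 0)
  expect_lt(abs(d_in[1] + 100), 2.5)  # centre is 100 m inside
  expect_lt(abs(d_in[2] + 20), 2.5)   # 20 m inside the east edge
  # brute-force oracle for an outside point: distance to the square ring
  p <- c(400, 30)
  oracle <- dist_to_ring(p[1], p[2], sq)
  got <- signed_distance_to_village(p[1], p[2], v)
  expect_lt(abs(got - oracle), 2.5)
  # continuity across the boundary on a transect
  xs <- seq(90, 110, by = 0.5)
  sd_t <- signed_distance_to_village(xs, rep(0, length(xs)), v)
  expect_lt(max(abs(diff(sd_t))), 2.5)  # no jump beyond raster accuracy
  expect_lt(min(abs(sd_t)), 1.5)        # passes through ~0
  # empty village layer is an error for the covariate
  expect_warning(v_empty <- derive_villages(list()), "empty")
  expect_error(signed_distance_to_village(0, 0, v_empty), "empty")
})

test_that("road distance and vegetation class behave on constructed layers", {
  roads <- list(list(coords = cbind(c(-100, 100), c(0, 0)), category = "primary"))
  expect_equal(distance_to_road(0, 0, roads), 0)
  expect_equal(distance_to_road(c(0, 50), c(30, -40), roads), c(30, 40))
  # beyond the segment end the distance is to the endpoint
  expect_equal(distance_to_road(130, 40, roads), 50)
  expect_error(distance_to_road(0, 0, list()), "empty")
  veg <- list(rect_poly(0, 0, 100, 100))
  expect_equal(vegetation_class(c(0, 200), c(0, 0), veg), c(1L, 0L))
  expect_equal(vegetation_class(0, 0, list()), 0L)
  cov <- landscape_covariates(c(0, 80), c(10, 10),
                              derive_villages(list(rect_poly(500, 0, 200, 200)),
                                              res = 2, min_area_m2 = 1),
                              roads, veg)
  expect_equal(cov$veg, c(1L, 0L))
  expect_equal(cov$d_road, c(10, 10))
  expect_true(all(cov$d_village > 0))
})
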