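# Descriptor formulas against closed forms, and geometry primitives against
# independent pixel/boundary oracles.

test_that("area and perimeter match closed forms on analytic shapes", {
  d <- raster_disc(100)
  ap <- measure_area_perimeter(d)
  expect_lt(abs(ap$area_mm2 / (pi * 100^2) - 1), 0.01)
  expect_lt(abs(ap$perimeter_mm / (2 * pi * 100) - 1), 0.02)

  one_px <- binary_mask(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2), 0.5)
  expect_equal(measure_area_perimeter(one_px)$area_mm2, 0.25)

  sq <- raster_square(100)
  expect_lt(abs(measure_area_perimeter(sq)$perimeter_mm / 400 - 1), 0.02)

  expect_error(measure_area_perimeter(binary_mask(matrix(FALSE, 3, 3), 1)),
               class = "phenoscreen_empty_mask")
})

test_that("perimeter estimators are calibrated against a boundary-walk oracle", {
  for (seed in 1:40) {
    m <- random_blob(seed)
    walk <- chain_walk_perimeter(m)
    est <- measure_area_perimeter(m)$perimeter_mm
    # smoothed-contour estimate removes staircase bias, so it sits at or
    # just below the raw chain length
    expect_lt(est / walk, 1.02)
    expect_gt(est / walk, 0.85)
    expect_equal(measure_area_perimeter(m)$area_mm2, sum(m$grid))
  }
})

test_that("convex hull uses the outer-corner convention", {
  sq <- raster_square(10)
  h <- compute_hull(sq)
  expect_equal(h$hull_area, 100)
  expect_equal(h$hull_perimeter, 40)
  # hull vertices form a convex ring: all cross products share one sign
  poly <- h$hull_polygon
  n <- nrow(poly)
  cr <- vapply(seq_len(n), function(i) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1, ]; c_ <- poly[((i + 1) %% n) + 1, ]
    (b[1] - a[1]) * (c_[2] - b[2]) - (b[2] - a[2]) * (c_[1] - b[1])
  }, numeric(1))
  expect_true(all(cr >= 0) || all(cr <= 0))

  # non-convex plus shape: hull is strictly larger than the region
  g <- matrix(FALSE, 90, 90)
  g[31:60, 1:90] <- TRUE; g[1:90, 31:60] <- TRUE
  p <- binary_mask(g, 1)
  expect_gt(compute_hull(p)$hull_area, measure_area_perimeter(p)$area_mm2)
  expect_equal(compactness(measure_area_perimeter(p)$area_mm2,
                           compute_hull(p)$hull_area), 5 / 7, tolerance = 1e-10)

  collinear <- binary_mask({g <- matrix(FALSE, 5, 9); g[3, 2:8] <- TRUE; g}, 1)
  expect_error(compute_hull(collinear), class = "phenoscreen_degenerate_hull")
})

test_that("skeleton length follows path-sum oracles", {
  bar <- binary_mask({g <- matrix(FALSE, 7, 105); g[4, 3:103] <- TRUE; g}, 1)
  expect_equal(compute_skeleton_length(bar), 100, tolerance = 0.02)

  # L-shape: two bars joined at a right angle, length ~ sum of arms
  g <- matrix(FALSE, 80, 80)
  g[10:70, 10] <- TRUE; g[70, 10:60] <- TRUE
  ell <- binary_mask(g, 1)
  expect_equal(compute_skeleton_length(ell), (61 - 1) + (51 - 1), tolerance = 0.05)

  # disc skeleton degenerates toward the center: far shorter than perimeter
  d <- raster_disc(40)
  expect_lt(compute_skeleton_length(d), 0.25 * measure_area_perimeter(d)$perimeter_mm)

  # mm scaling
  bar2 <- binary_mask(bar$grid, 0.5)
  expect_equal(compute_skeleton_length(bar2), 50, tolerance = 0.02)
})

test_that("roundness family matches closed forms", {
  r <- 57.3
  expect_equal(roundness(pi * r^2, 2 * pi * r), 1)
  expect_equal(roundness(4^2, 4 * 4), pi / 4, tolerance = 1e-12)
  expect_equal(roundness(10 * 1, 22), 4 * pi * 10 / 484, tolerance = 1e-12)
  expect_error(roundness(-1, 5))
  # equilateral triangle hull, side s: A = sqrt(3)/4 s^2, P = 3 s
  s <- 2
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  expect_equal(roundness2(polygon_area(tri), polygon_perimeter(tri)),
               pi * sqrt(3) / 9, tolerance = 1e-12)
})

test_that("eccentricity matches moment closed forms and invariances", {
  expect_equal(eccentricity(raster_disc(100)), 0, tolerance = 0.02)
  e <- raster_ellipse(100, 50)
  expect_equal(eccentricity(e), sqrt(3) / 2, tolerance = 0.005)
  expect_equal(eccentricity(binary_mask(t(e$grid), 1)), eccentricity(e))
  one_px <- binary_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), 1)
  expect_equal(eccentricity(one_px), 0)
})

test_that("rms agrees with the grid-sampling overlap oracle", {
  # square hull vs equal-area disc (frozen from the oracle: 0.19912)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  v <- rms(sq, c(0.5, 0.5))
  expect_lt(abs(v - rms_grid_oracle(sq, c(0.5, 0.5))), 2e-3)
  expect_equal(v, 0.19912, tolerance = 2e-4)
  # centered regular 64-gon is nearly a disc: rms ~ 0
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  gon <- cbind(cos(th), sin(th))
  expect_lt(rms(gon, c(0, 0)), 1e-2)
  # translation invariance
  expect_equal(rms(sq + 10, c(10.5, 10.5)), v, tolerance = 1e-12)
  # irregular convex hulls vs oracle
  for (seed in 1:10) {
    set.seed(seed)
    pts <- cbind(runif(12), runif(12) * 2)
    hull <- pts[grDevices::chull(pts), ]
    ctr <- colMeans(hull)
    expect_lt(abs(rms(hull, ctr) - rms_grid_oracle(hull, ctr)), 4e-3)
  }
})

test_that("isotropy of regular polygons matches closed forms", {
  hexagon <- cbind(cos(seq(0, 2 * pi, length.out = 7)[-7]),
                   sin(seq(0, 2 * pi, length.out = 7)[-7]))
  # regular hexagon: 4*pi*A/P^2 = pi*sqrt(3)/6
  expect_equal(isotropy(hexagon), pi * sqrt(3) / 6, tolerance = 1e-12)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  expect_equal(isotropy(cbind(cos(th), sin(th))), 1, tolerance = 1e-3)
  expect_error(isotropy(cbind(1:2, 1:2)))
})

test_that("describe is deterministic, symmetric, and correct on a disc", {
  d <- raster_disc(100, scale = 0.5)
  a <- describe(d)
  expect_identical(a, describe(d))
  # reflection invariance of every descriptor
  mir <- binary_mask(d$grid[, ncol(d$grid):1], 0.5)
  b <- describe(mir)
  expect_equal(as.numeric(a[descriptor_names()]), as.numeric(b[descriptor_names()]))
  expect_equal(a$roundness, 1, tolerance = 0.02)
  expect_lt(a$eccentricity, 0.02)
  expect_equal(a$compactness, 1, tolerance = 0.02)
  expect_lt(a$rms, 0.02)
  # empty mask flagged, not crashed
  e <- describe(binary_mask(matrix(FALSE, 4, 4), 1, plant_id = "p9", day = 12))
  expect_true(all(is.na(e[descriptor_names()])))
  expect_match(e$qc_flags, "empty-mask")
})

test_that("roundness2 strictly dominates roundness on rosette-like silhouettes", {
  # the hull isoperimetric ratio exceeds the region's own whenever the
  # silhouette is genuinely concave (petioles, separated blades)
  for (seed in 1:20) {
    model <- rosette_model(seed = seed)
    for (d in c(11, 15, 19)) {
      ds <- describe(render_rosette(model, d, size_px = 300, mm_per_px = 0.33))
      expect_gt(ds$roundness2, ds$roundness)
    }
  }
})

test_that("descriptor invariants hold over a random blob suite", {
  for (seed in 1:60) {
    m <- random_blob(seed)
    ds <- describe(m)
    # raster tolerance: near-convex blobs can cross by estimator error only
    expect_gte(ds$roundness2, ds$roundness - 0.05)
    expect_lte(ds$compactness, 1)
    expect_gt(ds$sol, 0)
    # scale covariance: doubling mm/px quadruples area, doubles perimeter,
    # leaves dimensionless descriptors unchanged
    m2 <- binary_mask(m$grid, 2)
    ds2 <- describe(m2)
    expect_equal(ds2$area, 4 * ds$area)
    expect_equal(ds2$perimeter, 2 * ds$perimeter, tolerance = 1e-9)
    for (p in c("roundness", "roundness2", "eccentricity", "compactness", "sol")) {
      expect_equal(ds2[[p]], ds[[p]], tolerance = 1e-9)
    }
  }
})

test_that("raster-exact symmetries leave every descriptor unchanged", {
  m <- random_blob(101, n = 80)
  ds <- describe(m)
  rot90 <- binary_mask(t(m$grid)[ncol(m$grid):1, ], 1)
  rot180 <- binary_mask(m$grid[nrow(m$grid):1, ncol(m$grid):1], 1)
  for (other in list(rot90, rot180)) {
    dso <- describe(other)
    expect_equal(as.numeric(dso[descriptor_names()]),
                 as.numeric(ds[descriptor_names()]), tolerance = 1e-9)
  }
})

test_that("mask io round-trips and multi-component masks are cleaned", {
  m <- random_blob(7)
  p <- tempfile(fileext = ".png")
  write_mask(m, p)
  m2 <- read_mask(p, mm_per_px = 1)
  expect_identical(m$grid, m2$grid)
  # add a distant speck: largest_component drops it and describe flags it
  g <- m$grid
  g[2, 2] <- TRUE
  spotted <- binary_mask(g, 1)
  lc <- largest_component(spotted)
  expect_identical(lc$mask$grid, m$grid)
  expect_equal(lc$n_dropped, 1L)
  expect_match(describe(spotted)$qc_flags, "multi-component")
})
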