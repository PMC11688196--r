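test_that("alpha hull reduces to the convex hull and respects containment", {
  sq <- square_poly(0, 0, 2)
  hull <- alpha_hull(sq, 0)
  expect_equal(polygon_area(hull), 4)

  set.seed(41)
  pts <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  ch_area <- polygon_area(pts[grDevices::chull(pts), ])
  expect_equal(polygon_area(alpha_hull(pts, 0)), ch_area)
  # loose alpha stays close to the convex hull and contains every point
  h <- alpha_hull(pts, 0.01)
  expect_lte(polygon_area(h), ch_area + 1e-9)
  expect_true(all(points_in_polygon(pts[, 1], pts[, 2], h)))

  expect_error(alpha_hull(cbind(c(0, 1), c(0, 0)), 0.1), "degenerate")
  expect_error(alpha_hull(cbind(0:5, 0:5), 0.1), "collinear")
})

test_that("concave point clouds yield sub-convex hull areas", {
  # dense ring: suitable alpha respects the annulus outline
  set.seed(42)
  th <- runif(2000, 0, 2 * pi)
  r <- runif(2000, 40, 50)
  ring <- cbind(50 + r * cos(th), 50 + r * sin(th))
  h <- alpha_hull(ring, 0.1)
  ch_area <- polygon_area(ring[grDevices::chull(ring), ])
  expect_lt(polygon_area(h), ch_area)

  # L-shaped cloud through select_alpha: concavity captured, no rejections
  set.seed(43)
  nL <- 1500
  xy <- cbind(runif(nL, 0, 90), runif(nL, 0, 90))
  keep <- xy[, 1] <= 30 | xy[, 2] <= 30
  L <- xy[keep, ]
  sel <- select_alpha(L, c(0.01, 0.05, 0.1, 0.2))
  expect_equal(sel$n_rejected, 0L)
  ch_L <- polygon_area(L[grDevices::chull(L), ])
  expect_lt(sel$area_um2, ch_L)
  expect_true(all(points_in_polygon(L[, 1], L[, 2], sel$polygon)))
})

test_that("hull area is monotone non-increasing as alpha tightens", {
  set.seed(44)
  pts <- cbind(runif(1200, 0, 200), runif(1200, 0, 100))
  alphas <- c(0, 0.02, 0.05, 0.1)
  areas <- sapply(alphas, function(a) polygon_area(alpha_hull(pts, a)))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("select_alpha falls back to the convex hull when nothing encloses", {
  set.seed(45)
  pts <- cbind(runif(40, 0, 1000), runif(40, 0, 1000)) # far too sparse
  expect_warning(sel <- select_alpha(pts, c(0.5, 1)), "convex hull")
  expect_equal(sel$alpha, 0)
})

test_that("layer densities: arithmetic and Poisson slab recovery", {
  # 500 cells, known hull: density = n / (area * thickness)
  set.seed(46)
  n <- 500
  cells <- toy_cells(runif(n, 0, 1000), runif(n, 0, 100), layer = "LIV")
  ld <- layer_density(cells, thickness_um = 50)
  expect_equal(ld$density_cells_mm3,
               ld$n_cells / (ld$area_um2 * 50 * 1e-9))
  expect_equal(ld$volume_mm3, ld$area_um2 * 50 * 1e-9)

  # homogeneous Poisson slab: recovered within 3 SE of the count plus the
  # hull-erosion bias budget (< 5 % at >= 2,000 cells)
  rho <- 103016
  set.seed(47)
  n2 <- rpois(1, rho * 1000 * 500 * 50 * 1e-9)
  slab <- toy_cells(runif(n2, 0, 1000), runif(n2, 0, 500), layer = "LIV")
  ld2 <- layer_density(slab, thickness_um = 50)
  expect_lt(abs(ld2$density_cells_mm3 - rho) / rho, 0.05 + 3 / sqrt(n2))
  expect_gte(ld2$density_cells_mm3, rho * 0.98) # boundary erosion biases high
})

test_that("Layer I uses the looser alpha and hulls keep their cells", {
  spec <- small_spec(seed = 48, width = 1200)
  cells <- sample_cells(spec)
  ld <- layer_density(cells)
  expect_equal(ld$alpha[ld$layer_label == "LI"], 0.005)
  expect_equal(ld$alpha[ld$layer_label != "LI"], rep(0.05, 2))
  for (i in seq_len(nrow(ld))) {
    sel <- cells$layer_label == ld$layer_label[i]
    inside <- points_in_polygon(cells$x_um[sel], cells$y_um[sel],
                                ld$polygon[[i]])
    # the reported count is exactly the number of cells in the polygon
    expect_equal(ld$n_cells[i], sum(inside))
    # the alpha-selection contract guarantees zero rejected cells
    pts <- cbind(cells$x_um[sel], cells$y_um[sel])
    chosen <- select_alpha(pts, c(0.005, 0.02, 0.05))
    expect_equal(chosen$n_rejected, 0L)
    expect_true(all(points_in_polygon(pts[, 1], pts[, 2], chosen$polygon)))
  }
})

test_that("layer heights recover the generating bands", {
  spec <- small_spec(seed = 49, width = 1500)
  col <- simulate_column(spec)
  cells <- filter_in_polygon(col$cells, col$regions)
  grid <- build_depth_grid(col$regions)
  lh <- layer_heights(cells, grid)
  layers <- small_layers()
  # mean inter-cell spacing along depth within one grid column
  spacing <- sum(layers$height_um) / (nrow(cells) / 10)
  for (i in seq_len(nrow(layers))) {
    est <- lh$mean_height_um[lh$layer_label == layers$label[i]]
    expect_lt(abs(est - layers$height_um[i]), max(3 * spacing, 12))
  }
  total <- attr(lh, "total_height_um")
  expect_lt(abs(total - sum(layers$height_um)), 10)
  # additivity: per-layer means sum to the total column height
  expect_lt(abs(sum(lh$mean_height_um) - total), 1e-6)
})

test_that("single-layer column height equals its depth extent; shuffled labels alarm", {
  spec <- column_spec(small_layers()[2, ], column_width_um = 800, seed = 50)
  col <- simulate_column(spec)
  cells <- filter_in_polygon(col$cells, col$regions)
  grid <- build_depth_grid(col$regions)
  lh <- layer_heights(cells, grid)
  expect_equal(nrow(lh), 1)
  expect_equal(lh$mean_height_um, 150, tolerance = 0.05)

  # label shuffling must not crash, and the spread blows up
  spec3 <- small_spec(seed = 51, width = 1500)
  col3 <- simulate_column(spec3)
  cells3 <- filter_in_polygon(col3$cells, col3$regions)
  grid3 <- build_depth_grid(col3$regions)
  lh_ok <- layer_heights(cells3, grid3)
  shuf <- cells3
  set.seed(52)
  shuf$layer_label <- sample(shuf$layer_label)
  lh_bad <- layer_heights(shuf, grid3)
  expect_gt(mean(lh_bad$sd_height_um), 2 * mean(lh_ok$sd_height_um))
})
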