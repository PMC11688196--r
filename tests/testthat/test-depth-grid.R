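rect_regions <- function(w = 1000, h = 400) {
  region_set(
    square_poly(0, 0, 1) * cbind(rep(w, 4), rep(h, 4)),
    outside_pia = cbind(c(0, w), c(0, 0)),
    corners = list(tl = c(0, 0), tr = c(w, 0), bl = c(0, h), br = c(w, h))
  )
}

test_that("point-in-polygon filter matches the ray-casting oracle", {
  # unit square basics, boundary retained
  cells <- toy_cells(c(0.5, 2, 0), c(0.5, 2, 0.5))
  kept <- filter_in_polygon(cells, square_poly(0, 0, 1))
  expect_equal(kept$cell_id, c("c001", "c003"))

  # irregular polygon vs oracle on random points
  set.seed(23)
  poly <- cbind(c(0, 4, 5, 3, 4, 1, 0.5), c(0, 0.5, 3, 2.5, 5, 4, 2))
  x <- runif(400, -1, 6); y <- runif(400, -1, 6)
  mine <- points_in_polygon(x, y, poly)
  oracle <- ray_cast_inside(x, y, poly)
  expect_identical(mine, oracle)
})

test_that("corner convexity check distinguishes convex and dart shapes", {
  expect_true(check_convex(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  expect_false(check_convex(rbind(c(0, 0), c(2, 0), c(1, 0.2), c(1, 1))))
  # collinear degenerate corner allowed
  expect_true(check_convex(rbind(c(0, 0), c(1, 0), c(2, 0), c(1, 1))))
  expect_error(check_convex(rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 1))),
               "repeated")
})

test_that("rectangle grid degenerates to congruent rectangular bins", {
  grid <- build_depth_grid(rect_regions(1000, 400))
  expect_equal(nrow(grid$bins), 200)
  expect_equal(grid$bins$area_um2, rep(1000 * 400 / 200, 200), tolerance = 1e-9)
  expect_equal(sum(grid$bins$area_um2) / grid$s1hl_area_um2, 1, tolerance = 5e-3)
})

test_that("rectangle binning equals the direct half-open binning oracle", {
  regions <- rect_regions(1000, 400)
  grid <- build_depth_grid(regions)
  set.seed(3)
  n <- 2000
  cells <- toy_cells(runif(n, 0, 1000), runif(n, 0, 400))
  g <- bin_densities(grid, cells)
  oracle_col <- pmin(floor(cells$x_um / 100) + 1, 10)
  oracle_row <- pmin(floor(cells$y_um / 20) + 1, 20)
  oracle <- table(factor(paste(oracle_col, oracle_row),
                         levels = paste(g$bins$col, g$bins$row)))
  expect_equal(g$bins$count, as.numeric(oracle))
  expect_equal(sum(g$bins$count), n)
})

test_that("curved-band grid conserves counts and areas", {
  spec <- small_spec(seed = 12, width = 800, curvature = 35)
  col <- simulate_column(spec)
  grid <- build_depth_grid(col$regions)
  expect_equal(sum(grid$bins$area_um2) / grid$s1hl_area_um2, 1, tolerance = 5e-3)
  cells <- filter_in_polygon(col$cells, col$regions)
  g <- bin_densities(grid, cells)
  expect_equal(sum(g$bins$count), nrow(cells))
})

test_that("concave corner quadrilateral is refused", {
  poly <- cbind(c(0, 500, 1000, 500), c(0, 150, 0, 400))
  bad <- region_set(poly, corners = list(
    tl = c(0, 0), tr = c(1000, 0), bl = c(500, 150), br = c(500, 400)
  ))
  expect_error(build_depth_grid(bad), "concave S1HL")
})

test_that("densities: arithmetic, exclusion weighting and Poisson recovery", {
  regions <- rect_regions(1000, 400)
  grid <- build_depth_grid(regions)
  # one bin is 100 x 20 um = 0.002 mm^2; put 100 cells into bin (1,1)
  cells <- toy_cells(runif(100, 0, 99.9), runif(100, 0, 19.9))
  g <- bin_densities(grid, cells, thickness_um = 50)
  b11 <- g$bins[g$bins$col == 1 & g$bins$row == 1, ]
  expect_equal(b11$volume_mm3, 100 * 20 * 50 * 1e-9)
  expect_equal(b11$density_cells_mm3, 100 / (100 * 20 * 50 * 1e-9))

  # zero exclusion probabilities leave densities untouched
  fake_ex <- structure(list(per_cell_exclusion_probability = rep(0, 100),
                            n_cells = 100), class = "exclusion_result")
  g2 <- bin_densities(grid, cells, thickness_um = 50, exclusion = fake_ex)
  expect_equal(g2$bins$density_cells_mm3, g$bins$density_cells_mm3)

  # homogeneous Poisson: mean per-bin density unbiased within 2 %
  rho <- 80000 # cells/mm^3
  set.seed(9)
  vol <- 1000 * 400 * 50 * 1e-9
  n <- rpois(1, rho * vol)
  cells_p <- toy_cells(runif(n, 0, 1000), runif(n, 0, 400))
  gp <- bin_densities(grid, cells_p, thickness_um = 50)
  expect_equal(mean(gp$bins$density_cells_mm3), rho,
               tolerance = 0.02 + 3 * sqrt(rho / vol) / rho / sqrt(200))
})

test_that("depth profile averages within image then across images", {
  regions <- rect_regions(1000, 400)
  grid <- build_depth_grid(regions)
  mk <- function(n, seed) {
    set.seed(seed)
    bin_densities(grid, toy_cells(runif(n, 0, 1000), runif(n, 0, 400)))
  }
  # two synthetic images with uniform densities 100k and 120k
  vol <- 1000 * 400 * 50 * 1e-9
  prof <- depth_profile(list(mk(round(1e5 * vol), 1), mk(round(1.2e5 * vol), 2)))
  expect_equal(nrow(prof), 20)
  expect_equal(prof$depth_percent, seq(2.5, 97.5, by = 5))
  expect_equal(mean(prof$mean_density), 110000, tolerance = 0.03)
  expect_true(all(prof$sd_density >= 0))

  # single image: zero SD, flagged by n_images
  p1 <- depth_profile(list(mk(2000, 3)))
  expect_equal(p1$sd_density, rep(0, 20))
  expect_equal(unique(p1$n_images), 1)

  # exact arithmetic: constant densities 100k/120k per image
  t1 <- tibble::tibble(col = rep(1:10, 20), row = rep(1:20, each = 10),
                       density_cells_mm3 = 1e5)
  t2 <- dplyr::mutate(t1, density_cells_mm3 = 1.2e5)
  p2 <- depth_profile(list(t1, t2))
  expect_equal(p2$mean_density, rep(110000, 20))
  expect_equal(p2$sd_density, rep(sd(c(1e5, 1.2e5)), 20))
})

test_that("profile recovers the generating layer densities on synthetic columns", {
  spec <- small_spec(seed = 30, width = 2000)
  col <- simulate_column(spec)
  grid <- build_depth_grid(col$regions)
  g <- bin_densities(grid, filter_in_polygon(col$cells, col$regions))
  prof <- depth_profile(list(g))
  layers <- small_layers()
  bounds <- c(0, cumsum(layers$height_um)) / sum(layers$height_um) * 100
  for (i in seq_len(nrow(layers))) {
    interior <- prof$depth_percent > bounds[i] + 5 &
      prof$depth_percent < bounds[i + 1] - 5
    if (!any(interior)) next
    plateau <- mean(prof$mean_density[interior])
    rho <- layers$density_cells_mm3[i]
    n_bin <- rho * (2000 * sum(layers$height_um) / 200) * 50 * 1e-9
    se <- rho / sqrt(n_bin * sum(interior) * 10)
    expect_lt(abs(plateau - rho), 4 * se)
  }
})
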