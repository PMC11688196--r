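test_that("diameter from area inverts the circular-area formula", {
  expect_equal(diameter_from_area(pi), 2)
  expect_equal(diameter_from_area(78.5398), 10, tolerance = 1e-5)
  a <- runif(20, 1, 500)
  expect_equal(pi * (diameter_from_area(a) / 2)^2, a, tolerance = 1e-9)
  expect_error(diameter_from_area(c(1, 0)), "non-positive")
})

test_that("mixture fit recovers simulated parameters and matches mclust", {
  set.seed(55)
  n <- 5000
  x <- ifelse(runif(n) < 0.5, rnorm(n, 5.20, 1.20), rnorm(n, 8.14, 2.33))
  fit <- fit_diameter_mixture(x, seed = 55)
  se <- 1.20 / sqrt(n / 2) # small-population mean SE scale
  expect_lt(abs(fit$means[1] - 5.20), 3 * 0.05)
  expect_lt(abs(fit$means[2] - 8.14), 3 * 0.1)
  expect_true(fit$converged)
  expect_true(all(diff(fit$means) >= 0))
  expect_equal(sum(fit$weights), 1)

  # independent EM implementation agrees on the component means
  library(mclust)
  m <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means, sort(as.numeric(m$parameters$mean)), tolerance = 0.02)
  expect_equal(fit$log_likelihood, m$loglik, tolerance = 1e-4)
})

test_that("mixture fit flags unimodal data and is scale-equivariant", {
  set.seed(56)
  x <- rnorm(2000, 7, 1.5)
  fit <- fit_diameter_mixture(x, seed = 56)
  expect_lt(fit$overlap, 1.5) # near-identical components flagged by overlap
  expect_lt(abs(diff(fit$means)), 3)

  set.seed(57)
  y <- ifelse(runif(3000) < 0.5, rnorm(3000, 5, 1), rnorm(3000, 10, 2))
  f1 <- fit_diameter_mixture(y, seed = 1)
  f2 <- fit_diameter_mixture(2 * y, seed = 1)
  expect_equal(f2$means, 2 * f1$means, tolerance = 0.02)
  expect_error(fit_diameter_mixture(1:5), "at least 10")
})

test_that("Welch t-test matches the closed-form hand computation", {
  r <- welch_ttest(c(1, 2, 3), c(2, 3, 4))
  # means 2 and 3, each variance 1: t = -1 / sqrt(1/3 + 1/3)
  expect_equal(r$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4, tolerance = 1e-9)
  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  degen <- welch_ttest(c(2, 2), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("Welch and Kruskal-Wallis hold their nominal type-I error", {
  set.seed(58)
  n_sim <- 1000
  rej_w <- logical(n_sim)
  rej_k <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    a <- rnorm(8); b <- rnorm(8, sd = 2)
    rej_w[s] <- welch_ttest(a, b)$significant
    dens <- tibble::tibble(
      layer_label = rep(layer_levels(), each = 5),
      density_cells_mm3 = rnorm(35)
    )
    rej_k[s] <- density_across_layers(dens)$significant
  }
  # binomial 3-sigma band around 5 %
  band <- 3 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(rej_w) - 0.05), band + 0.01)
  expect_lt(abs(mean(rej_k) - 0.05), band + 0.015)
})

test_that("Kruskal-Wallis detects layered densities and handles total ties", {
  set.seed(59)
  layers <- default_layer_spec()
  dens <- tibble::tibble(
    layer_label = rep(layers$label, each = 6),
    density_cells_mm3 = rnorm(42, rep(layers$density_cells_mm3, each = 6), 2000)
  )
  r <- density_across_layers(dens)
  expect_lt(r$p_value, 0.001)
  expect_equal(r$df, 6)

  ties <- tibble::tibble(layer_label = rep(layer_levels(), each = 2),
                         density_cells_mm3 = 1)
  rt <- density_across_layers(ties)
  expect_true(rt$degenerate)
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 1)

  # two-group large-sample relationship with the rank-sum z statistic
  set.seed(60)
  a <- rnorm(300); b <- rnorm(300, 0.3)
  two <- tibble::tibble(layer_label = rep(c("LI", "LII"), each = 300),
                        density_cells_mm3 = c(a, b))
  h <- density_across_layers(two)$statistic
  w <- stats::wilcox.test(a, b, correct = FALSE)
  z2 <- stats::qnorm(w$p.value / 2)^2
  expect_equal(h, z2, tolerance = 0.02)
})

test_that("adjacent-layer tests use the Bonferroni-adjusted alpha", {
  set.seed(61)
  layers <- default_layer_spec()
  dens <- tibble::tibble(
    layer_label = rep(layers$label, each = 8),
    density_cells_mm3 = rnorm(56, rep(layers$density_cells_mm3, each = 8), 1500)
  )
  res <- adjacent_layer_tests(dens)
  expect_equal(nrow(res), 6)
  expect_equal(unique(res$alpha_used), 0.05 / 6, tolerance = 1e-12)
  expect_true(all(res$significant))

  # missing layer: both pairs involving it are skipped with warnings
  w <- testthat::capture_warnings(
    res2 <- adjacent_layer_tests(dplyr::filter(dens, layer_label != "LIV"))
  )
  expect_length(w, 2)
  expect_true(all(grepl("skipping pair", w)))
  expect_equal(nrow(res2), 4)

  # identical distributions keep the family-wise error controlled
  set.seed(62)
  fwe <- replicate(300, {
    null <- tibble::tibble(layer_label = rep(layers$label, each = 5),
                           density_cells_mm3 = rnorm(35))
    any(suppressWarnings(adjacent_layer_tests(null))$significant)
  })
  expect_lt(mean(fwe), 0.09)
})

test_that("per-image aggregation compares the two populations", {
  set.seed(63)
  fits <- tidyr::expand_grid(layer_label = c("LI", "LIV"),
                             image_id = sprintf("im%d", 1:6)) |>
    dplyr::mutate(pop1_mean_um = rnorm(12, 5.2, 0.1),
                  pop2_mean_um = rnorm(12, 9.8, 0.2))
  agg <- aggregate_mixtures(fits)
  expect_equal(nrow(agg), 2)
  expect_true(all(agg$significant))
  expect_true(all(agg$p_value < 1e-6))
  expect_true(all(agg$pop1_mean_um < agg$pop2_mean_um))

  # identical fits: degenerate, not significant
  const <- dplyr::mutate(fits, pop1_mean_um = 5, pop2_mean_um = 5)
  agg2 <- aggregate_mixtures(const)
  expect_true(all(agg2$degenerate))
  expect_false(any(agg2$significant))

  # single image: aggregation without a test
  one <- dplyr::filter(fits, image_id == "im1")
  agg3 <- aggregate_mixtures(one)
  expect_true(all(is.na(agg3$p_value)))
})

test_that("test results are invariant to sample order", {
  set.seed(64)
  a <- rnorm(20); b <- rnorm(20, 1)
  r1 <- welch_ttest(a, b)
  r2 <- welch_ttest(sample(a), sample(b))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})
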