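# Soma-diameter morphometry: diameter from area, two-component Gaussian
# mixture fits, across-image aggregation, and the statistical battery.

#' Equivalent circular diameter from soma area
#'
#' `d = 2 * sqrt(area / pi)` under the assumption of a perfectly circular
#' soma.
#'
#' @param area_um2 Soma areas (um^2), strictly positive.
#' @return Diameters (um).
#' @export
diameter_from_area <- function(area_um2) {
  if (any(area_um2 <= 0, na.rm = TRUE)) {
    stop("non-positive soma area", call. = FALSE)
  }
  2 * sqrt(area_um2 / pi)
}

em_gauss2 <- function(x, mu, sg, w, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  sd_floor <- max(sd(x), 1e-6) * 1e-4
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w * dnorm(x, mu[1], sg[1])
    d2 <- (1 - w) * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sg <- c(sqrt(sum(r * (x - mu[1])^2) / n1),
            sqrt(sum((1 - r) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, sd_floor)
    w <- n1 / n
  }
  list(mu = mu, sg = sg, w = w, loglik = ll_old, converged = converged)
}

#' Fit a two-component Gaussian mixture to soma diameters
#'
#' Maximum-likelihood fit via expectation-maximisation. The first start
#' splits the sample at its median (the small-cell and large-cell halves
#' initialise the two components); the remaining `n_restarts - 1` starts are
#' random, seed-controlled perturbations. The best log-likelihood is kept
#' and components are sorted by ascending mean.
#'
#' @param diameters Numeric sample of soma diameters (um), `n >= 10`.
#' @param n_components Only 2 is supported (the small/large soma dichotomy).
#' @param n_restarts Number of EM starts (default 5).
#' @param seed Integer seed for the random restarts.
#' @return An object of class `mixture_fit` with `means`, `sds`, `weights`
#'   (ascending-mean order), `n`, `log_likelihood`, `converged`, and an
#'   `overlap` diagnostic (Bhattacharyya-style separation
#'   `|mu2 - mu1| / sqrt(sd1 * sd2)`; values below 1 flag near-identical
#'   components).
#' @export
fit_diameter_mixture <- function(diameters, n_components = 2, n_restarts = 5,
                                 seed = NULL) {
  if (n_components != 2) stop("only 2-component mixtures are supported", call. = FALSE)
  x <- diameters[is.finite(diameters)]
  if (length(x) < 10) stop("need at least 10 diameters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (!length(hi)) hi <- lo
  starts <- list(list(mu = c(mean(lo), mean(hi)),
                      sg = pmax(c(sd(lo), sd(hi)), 1e-3, na.rm = TRUE),
                      w = 0.5))
  for (i in seq_len(max(0, n_restarts - 1))) {
    q <- sort(runif(2, 0.05, 0.95))
    starts[[i + 1]] <- list(
      mu = as.numeric(quantile(x, q)),
      sg = rep(max(sd(x) * runif(1, 0.3, 1), 1e-3), 2),
      w = runif(1, 0.25, 0.75)
    )
  }
  best <- NULL
  for (s in starts) {
    fit <- em_gauss2(x, s$mu, s$sg, s$w)
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  ord <- order(best$mu)
  means <- best$mu[ord]
  sds <- best$sg[ord]
  weights <- c(best$w, 1 - best$w)[ord]
  structure(
    list(
      means = means, sds = sds, weights = weights,
      n = length(x), log_likelihood = best$loglik,
      converged = best$converged,
      overlap = abs(diff(means)) / sqrt(prod(sds))
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> n =", x$n, if (!x$converged) "(not converged)", "\n")
  cat(sprintf("  pop 1: %.2f +- %.2f um (w = %.2f)\n",
              x$means[1], x$sds[1], x$weights[1]))
  cat(sprintf("  pop 2: %.2f +- %.2f um (w = %.2f)\n",
              x$means[2], x$sds[2], x$weights[2]))
  invisible(x)
}

#' @rdname fit_diameter_mixture
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(
    component = c("pop1", "pop2"),
    mean_um = x$means, sd_um = x$sds, weight = x$weights
  )
}

#' @rdname fit_diameter_mixture
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, log_likelihood = x$log_likelihood, converged = x$converged,
    separation = x$overlap
  )
}

stat_result <- function(test_name, statistic, p_value, df = NA_real_,
                        alpha_used = 0.05, degenerate = FALSE, label = NA_character_) {
  tibble::tibble(
    test_name = test_name, label = label, statistic = statistic, df = df,
    p_value = p_value, alpha_used = alpha_used,
    significant = !is.na(p_value) & p_value < alpha_used,
    degenerate = degenerate
  )
}

#' Welch's two-sample t-test
#'
#' Two-sided comparison of two sample means without assuming equal
#' variances (Welch-Satterthwaite degrees of freedom). Samples with zero
#' variance on both sides and equal means report `t = 0, p = 1` by
#' convention instead of failing.
#'
#' @param sample_a,sample_b Numeric samples, each of size at least 2.
#' @param alpha Significance threshold recorded in the result.
#' @param var_equal If `TRUE`, the pooled-variance Student t-test is used
#'   instead.
#' @return A one-row tibble: `test_name`, `statistic`, `df`, `p_value`,
#'   `alpha_used`, `significant`, `degenerate`.
#' @export
welch_ttest <- function(sample_a, sample_b, alpha = 0.05, var_equal = FALSE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  name <- if (var_equal) "two_sample_t" else "welch_t"
  if (var(sample_a) == 0 && var(sample_b) == 0) {
    same <- mean(sample_a) == mean(sample_b)
    return(stat_result(name, statistic = if (same) 0 else Inf,
                       p_value = if (same) 1 else 0,
                       alpha_used = alpha, degenerate = TRUE))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
  stat_result(name, statistic = unname(ht$statistic),
              df = unname(ht$parameter), p_value = ht$p.value,
              alpha_used = alpha)
}

#' Aggregate per-image mixture fits by layer
#'
#' Given per-image two-component fits (one row per image and layer), computes
#' the unweighted across-image mean and SD of each population mean and tests
#' whether the two population means differ within each layer with a
#' two-sample t-test (Welch-flavoured by default).
#'
#' @param fits A tibble with columns `layer_label`, `image_id`,
#'   `pop1_mean_um`, `pop2_mean_um` (e.g. built from
#'   [fit_diameter_mixture()] tidies).
#' @param alpha Significance threshold (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A tibble with one row per layer: population summaries, test
#'   statistic and p-value. Layers with fewer than 2 images aggregate
#'   without a test; identical fits across images are flagged degenerate and
#'   not significant.
#' @export
aggregate_mixtures <- function(fits, alpha = 0.05, var_equal = FALSE) {
  fits |>
    dplyr::group_by(.data$layer_label) |>
    dplyr::group_modify(function(df, key) {
      out <- tibble::tibble(
        n_images = nrow(df),
        pop1_mean_um = mean(df$pop1_mean_um),
        pop1_sd_um = if (nrow(df) > 1) sd(df$pop1_mean_um) else 0,
        pop2_mean_um = mean(df$pop2_mean_um),
        pop2_sd_um = if (nrow(df) > 1) sd(df$pop2_mean_um) else 0
      )
      if (nrow(df) >= 2) {
        ht <- welch_ttest(df$pop1_mean_um, df$pop2_mean_um, alpha = alpha,
                          var_equal = var_equal)
        out$statistic <- ht$statistic
        out$p_value <- ht$p_value
        out$significant <- ht$significant & !ht$degenerate
        out$degenerate <- ht$degenerate
      } else {
        out$statistic <- NA_real_
        out$p_value <- NA_real_
        out$significant <- FALSE
        out$degenerate <- TRUE
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Kruskal-Wallis test of density differences across layers
#'
#' H statistic with tie correction; p-value from the chi-square distribution
#' with `k - 1` degrees of freedom. When every observation is identical the
#' statistic is 0 and `p = 1` by convention (flagged degenerate).
#'
#' @param densities A tibble with columns `layer_label` and
#'   `density_cells_mm3` (one row per image and layer).
#' @param alpha Significance threshold.
#' @return A one-row stat-result tibble.
#' @export
density_across_layers <- function(densities, alpha = 0.05) {
  groups <- split(densities$density_cells_mm3, densities$layer_label)
  if (length(groups) < 2) stop("need at least 2 layers", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each layer needs at least 2 density values", call. = FALSE)
  }
  vals <- unlist(groups)
  if (length(unique(vals)) == 1) {
    return(stat_result("kruskal_wallis", statistic = 0, p_value = 1,
                       df = length(groups) - 1, alpha_used = alpha,
                       degenerate = TRUE))
  }
  ht <- stats::kruskal.test(groups)
  stat_result("kruskal_wallis", statistic = unname(ht$statistic),
              df = unname(ht$parameter), p_value = ht$p.value,
              alpha_used = alpha)
}

#' Bonferroni-adjusted adjacent-layer density tests
#'
#' Two-sample t-tests between each of the six adjacent layer pairs in
#' anatomical order, with the significance threshold divided by the number
#' of comparisons (`0.05 / 6 = 0.0083` for the seven-layer column).
#'
#' @param densities A tibble with columns `layer_label` and
#'   `density_cells_mm3`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param var_equal Use pooled-variance t-tests instead of Welch.
#' @return A stat-result tibble with one row per adjacent pair tested;
#'   pairs with a missing layer are skipped with a warning.
#' @export
adjacent_layer_tests <- function(densities, alpha = 0.05, var_equal = FALSE) {
  ord <- layer_ordering(unique(densities$layer_label))
  pairs <- cbind(ord[-length(ord)], ord[-1])
  m <- nrow(pairs)
  alpha_used <- alpha / m
  rows <- list()
  for (i in seq_len(m)) {
    a <- densities$density_cells_mm3[densities$layer_label == pairs[i, 1]]
    b <- densities$density_cells_mm3[densities$layer_label == pairs[i, 2]]
    lab <- paste(pairs[i, 1], "vs", pairs[i, 2])
    if (length(a) < 2 || length(b) < 2) {
      warning("skipping pair ", lab, ": missing layer data", call. = FALSE)
      next
    }
    ht <- welch_ttest(a, b, alpha = alpha_used, var_equal = var_equal)
    ht$label <- lab
    rows[[length(rows) + 1]] <- ht
  }
  dplyr::bind_rows(rows)
}

#' Per-image, per-layer mixture fits
#'
#' Convenience wrapper: computes the equivalent circular diameter from soma
#' area and fits the two-component mixture for every image x layer group
#' with at least `min_n` cells.
#'
#' @param cells A labeled cell tibble.
#' @param min_n Minimum group size to attempt a fit (default 50).
#' @param n_restarts,seed Passed to [fit_diameter_mixture()].
#' @return A tibble with `image_id`, `layer_label`, `n`, `pop1_mean_um`,
#'   `pop1_sd_um`, `pop2_mean_um`, `pop2_sd_um`, `pop1_weight`, `converged`.
#' @export
fit_mixtures_by_layer <- function(cells, min_n = 50, n_restarts = 5, seed = 1L) {
  d <- diameter_from_area(cells$area_um2)
  grp <- dplyr::tibble(image_id = cells$image_id,
                       layer_label = cells$layer_label, diameter_um = d) |>
    dplyr::filter(.data$layer_label != "none")
  grp |>
    dplyr::group_by(.data$image_id, .data$layer_label) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_n) return(tibble::tibble())
      fit <- fit_diameter_mixture(df$diameter_um, n_restarts = n_restarts,
                                  seed = seed)
      tibble::tibble(
        n = fit$n,
        pop1_mean_um = fit$means[1], pop1_sd_um = fit$sds[1],
        pop2_mean_um = fit$means[2], pop2_sd_um = fit$sds[2],
        pop1_weight = fit$weights[1], converged = fit$converged
      )
    }) |>
    dplyr::ungroup()
}
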