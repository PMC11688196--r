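# Virtual-z stereology: since consecutive 50-um sections count every cell,
# overcounting across the slice surfaces is corrected by assigning each cell
# a random virtual depth and excluding cells whose estimated soma would
# protrude through the upper surface.

#' Assign a virtual z coordinate to each cell
#'
#' Draws `z_um ~ Uniform(0, thickness_um)` independently per cell,
#' deterministic given `seed`.
#'
#' @param cells A cell tibble.
#' @param thickness_um Slice thickness (um).
#' @param seed Integer seed.
#' @return The cell tibble with a `z_um` column.
#' @export
assign_virtual_z <- function(cells, thickness_um = 50, seed = NULL) {
  stopifnot(thickness_um > 0)
  if (!is.null(seed)) set.seed(seed)
  cells$z_um <- runif(nrow(cells), 0, thickness_um)
  cells
}

# k nearest neighbours (excluding self) within one coordinate set, blocked to
# keep the distance matrix small. Returns the mean of `values` over each
# point's k neighbours.
knn_mean_value <- function(x, y, values, k) {
  n <- length(x)
  out <- numeric(n)
  block <- max(1L, min(n, as.integer(4e6 / n)))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    for (r in seq_along(idx)) {
      v <- d2[r, ]
      v[idx[r]] <- Inf # the cell itself is not its own neighbour
      cut <- sort(v, partial = k)[k]
      nb <- which(v <= cut)
      if (length(nb) > k) nb <- nb[order(v[nb])][seq_len(k)]
      out[idx[r]] <- mean(values[nb])
    }
  }
  out
}

#' Neighbour-based soma diameter estimate
#'
#' For each cell, the mean representative diameter of its `k` nearest
#' neighbouring cells (2-D Euclidean distance on centroids, per image; the
#' cell's own diameter is not included). The representative diameter of a
#' cell is the mean of its maximum and minimum diameters.
#'
#' @param cells A cell tibble.
#' @param k Number of neighbours (default 6).
#' @return Numeric vector of estimated diameters (um), aligned with rows of
#'   `cells`.
#' @export
neighbor_diameter <- function(cells, k = 6) {
  rep_d <- (cells$d_max_um + cells$d_min_um) / 2
  out <- numeric(nrow(cells))
  for (img in unique(cells$image_id)) {
    sel <- which(cells$image_id == img)
    if (length(sel) < k + 1) {
      stop("image '", img, "' has fewer than k+1 = ", k + 1, " cells",
           call. = FALSE)
    }
    out[sel] <- knn_mean_value(cells$x_um[sel], cells$y_um[sel], rep_d[sel], k)
  }
  out
}

#' Upper-surface exclusion rule
#'
#' A cell is excluded when its virtual depth plus half its estimated diameter
#' strictly exceeds the slice thickness, i.e. the soma would protrude through
#' the upper surface. A soma touching the surface exactly counts as inside.
#'
#' @param cells A cell tibble carrying `z_um`.
#' @param diam_est Estimated diameters (um), e.g. from [neighbor_diameter()].
#' @param thickness_um Slice thickness (um).
#' @return Logical vector, `TRUE` for excluded cells.
#' @export
exclude_upper_surface <- function(cells, diam_est, thickness_um = 50) {
  if (is.null(cells$z_um)) stop("assign_virtual_z() first: no z_um column", call. = FALSE)
  cells$z_um + diam_est / 2 > thickness_um
}

#' Bootstrap the stereological exclusion fraction
#'
#' Repeats the virtual-z draw and upper-surface exclusion `n_iterations`
#' times (neighbour diameters are estimated once; the in-plane geometry does
#' not change between iterations) and aggregates the excluded fraction and
#' per-cell exclusion probabilities.
#'
#' @param cells A cell tibble.
#' @param thickness_um Slice thickness (um).
#' @param n_iterations Number of bootstrap iterations (default 100).
#' @param seed Integer seed.
#' @param diam_est Optional pre-computed diameter estimates; defaults to
#'   [neighbor_diameter()] with 6 neighbours.
#' @return An object of class `exclusion_result` with fields
#'   `per_iteration_excluded_fraction`, `mean_fraction`, `sd_fraction`,
#'   `per_cell_exclusion_probability`, `last_z_um`, `n_iterations`,
#'   `thickness_um`, `n_cells`.
#' @export
bootstrap_exclusion <- function(cells, thickness_um = 50, n_iterations = 100,
                                seed = NULL, diam_est = NULL) {
  if (n_iterations < 2) stop("n_iterations must be at least 2", call. = FALSE)
  if (is.null(diam_est)) diam_est <- neighbor_diameter(cells)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cells)
  frac <- numeric(n_iterations)
  excl_count <- numeric(n)
  z <- NULL
  for (it in seq_len(n_iterations)) {
    z <- runif(n, 0, thickness_um)
    ex <- z + diam_est / 2 > thickness_um
    frac[it] <- mean(ex)
    excl_count <- excl_count + ex
  }
  structure(
    list(
      per_iteration_excluded_fraction = frac,
      mean_fraction = mean(frac),
      sd_fraction = sd(frac),
      per_cell_exclusion_probability = excl_count / n_iterations,
      diam_est_um = diam_est,
      last_z_um = z,
      n_iterations = n_iterations,
      thickness_um = thickness_um,
      n_cells = n
    ),
    class = "exclusion_result"
  )
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat("<exclusion_result> ", x$n_cells, " cells, ", x$n_iterations,
      " iterations, thickness ", x$thickness_um, " um\n", sep = "")
  cat(sprintf("  excluded fraction: %.4f +- %.4f (%.2f%%)\n",
              x$mean_fraction, x$sd_fraction, 100 * x$mean_fraction))
  invisible(x)
}

#' @rdname bootstrap_exclusion
#' @param x An `exclusion_result`.
#' @param ... Unused.
#' @export
tidy.exclusion_result <- function(x, ...) {
  tibble::tibble(
    iteration = seq_len(x$n_iterations),
    excluded_fraction = x$per_iteration_excluded_fraction
  )
}

#' @rdname bootstrap_exclusion
#' @export
glance.exclusion_result <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    n_iterations = x$n_iterations,
    thickness_um = x$thickness_um,
    mean_fraction = x$mean_fraction,
    sd_fraction = x$sd_fraction
  )
}

#' @rdname bootstrap_exclusion
#' @param object An `exclusion_result`.
#' @export
autoplot.exclusion_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$excluded_fraction)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_fraction, linetype = 2) +
    ggplot2::labs(x = "excluded fraction per iteration", y = "iterations",
                  title = sprintf("Stereological exclusion: %.2f%% +- %.2f%%",
                                  100 * object$mean_fraction,
                                  100 * object$sd_fraction)) +
    ggplot2::theme_minimal()
}
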