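# Nonlinear depth grid: 10 columns x 20 rows fitted inside the cortical-band
# polygon, rows following the pia and white-matter outlines so that each row
# is a constant fraction of cortical depth.

#' Filter cells to a polygon
#'
#' Retains cells whose centroid lies inside or on the boundary of the
#' polygon.
#'
#' @param cells A cell tibble.
#' @param polygon An n x 2 polygon matrix, or a [region_set()] (its S1HL
#'   polygon is used).
#' @return The filtered cell tibble.
#' @export
filter_in_polygon <- function(cells, polygon) {
  if (inherits(polygon, "region_set")) polygon <- polygon$s1hl
  keep <- points_in_polygon(cells$x_um, cells$y_um, polygon)
  cells[keep, , drop = FALSE]
}

#' Convexity check for the band's corner quadrilateral
#'
#' Rows of the nonlinear grid are only well-ordered in depth when the
#' quadrilateral spanned by the four corner reference points is convex;
#' concave bands are refused upstream (mirroring the exclusion of concave
#' slices from density analysis).
#'
#' @param corners Either a 4 x 2 matrix ordered TL, TR, BR, BL or a named
#'   list with `tl`, `tr`, `bl`, `br` (as stored in a [region_set()]).
#' @return `TRUE` iff the quadrilateral is convex (zero cross products, i.e.
#'   collinear degeneracies, are allowed).
#' @export
check_convex <- function(corners) {
  if (is.list(corners) && !is.null(corners$tl)) {
    corners <- rbind(corners$tl, corners$tr, corners$br, corners$bl)
  }
  corners <- as_xy_matrix(corners)
  if (nrow(corners) != 4) stop("need exactly 4 corner points", call. = FALSE)
  if (anyDuplicated(paste(corners[, 1], corners[, 2]))) {
    stop("repeated corner points", call. = FALSE)
  }
  nxt <- c(2, 3, 4, 1)
  e <- corners[nxt, ] - corners
  cr <- e[, 1] * e[nxt, 2] - e[, 2] * e[nxt, 1]
  all(cr >= 0) || all(cr <= 0)
}

# Split the S1HL ring into the top (pia-side, TL -> TR) and bottom
# (white-matter-side, BL -> BR) polylines using the corner points.
split_band_boundary <- function(regions) {
  poly <- regions$s1hl
  corners <- regions$corners
  if (is.null(corners)) stop("region set has no corner points", call. = FALSE)
  n <- nrow(poly)
  near <- function(p) which.min((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
  idx <- vapply(corners[c("tl", "tr", "bl", "br")], near, integer(1))
  walk <- function(from, to, forward) {
    if (forward) {
      if (from <= to) from:to else c(from:n, 1:to)
    } else {
      if (from >= to) from:to else c(from:1, n:to)
    }
  }
  path_avoiding <- function(from, to, avoid) {
    fwd <- walk(from, to, TRUE)
    bwd <- walk(from, to, FALSE)
    if (!any(avoid %in% fwd)) fwd
    else if (!any(avoid %in% bwd)) bwd
    else if (length(fwd) <= length(bwd)) fwd else bwd
  }
  top_idx <- path_avoiding(idx["tl"], idx["tr"], idx[c("bl", "br")])
  bot_idx <- path_avoiding(idx["bl"], idx["br"], idx[c("tl", "tr")])
  list(top = poly[top_idx, , drop = FALSE], bottom = poly[bot_idx, , drop = FALSE])
}

#' Build the nonlinear depth grid inside the cortical band
#'
#' The pia-side and white-matter-side outlines are resampled uniformly in
#' arc length; intermediate row polylines at depth fraction `t` are the
#' pointwise linear blend `(1 - t) * top + t * bottom`; columns are cut by
#' the straight segments joining top and bottom points at matching
#' arc-length fractions. Bins are the cells of this curvilinear lattice and
#' tile the band exactly in the rectangular (zero-curvature) limit.
#'
#' @param regions A [region_set()] with corner points.
#' @param n_cols,n_rows Grid size (default 10 x 20).
#' @return An object of class `depth_grid` with a `bins` tibble (`col`,
#'   `row`, `polygon` list-column, `area_um2`), row 1 at the pia.
#' @export
build_depth_grid <- function(regions, n_cols = 10, n_rows = 20) {
  stopifnot(inherits(regions, "region_set"))
  if (!check_convex(regions$corners)) {
    stop("concave S1HL: the corner quadrilateral is not convex; ",
         "this slice must be excluded from depth-density analysis",
         call. = FALSE)
  }
  halves <- split_band_boundary(regions)
  pts_per_col <- 20L
  m <- n_cols * pts_per_col + 1L
  top <- resample_polyline(halves$top, m)
  bot <- resample_polyline(halves$bottom, m)
  blend <- function(t) (1 - t) * top + t * bot
  t_cuts <- seq(0, 1, length.out = n_rows + 1)
  row_lines <- lapply(t_cuts, blend)
  bins <- vector("list", n_cols * n_rows)
  k <- 0
  for (r in seq_len(n_rows)) {
    upper <- row_lines[[r]]; lower <- row_lines[[r + 1]]
    for (cc in seq_len(n_cols)) {
      sel <- ((cc - 1) * pts_per_col + 1):(cc * pts_per_col + 1)
      poly <- rbind(upper[sel, , drop = FALSE],
                    lower[rev(sel), , drop = FALSE])
      k <- k + 1
      bins[[k]] <- tibble::tibble(col = cc, row = r, polygon = list(poly),
                                  area_um2 = polygon_area(poly))
    }
  }
  bins <- dplyr::bind_rows(bins)
  structure(
    list(bins = bins, n_cols = n_cols, n_rows = n_rows,
         s1hl_area_um2 = polygon_area(regions$s1hl)),
    class = "depth_grid"
  )
}

#' @export
print.depth_grid <- function(x, ...) {
  cat("<depth_grid> ", x$n_cols, " cols x ", x$n_rows, " rows; bin areas sum ",
      format(sum(x$bins$area_um2), big.mark = ","), " um^2 (band ",
      format(x$s1hl_area_um2, big.mark = ","), " um^2)\n", sep = "")
  invisible(x)
}

#' @rdname build_depth_grid
#' @param x A `depth_grid`.
#' @param ... Unused.
#' @export
tidy.depth_grid <- function(x, ...) {
  dplyr::select(x$bins, -"polygon")
}

# Assign each cell to exactly one bin. Boundary ties resolve to the larger
# (col, row) index, reproducing half-open binning in the rectangular limit;
# in-polygon cells that fall between bins numerically go to the nearest bin
# centroid.
assign_bins <- function(grid, cells) {
  n <- nrow(cells)
  bin_col <- rep(NA_integer_, n)
  bin_row <- rep(NA_integer_, n)
  bins <- grid$bins
  ord <- order(bins$col, bins$row) # ascending; later hits overwrite
  for (b in ord) {
    poly <- bins$polygon[[b]]
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    cand <- which(cells$x_um >= xr[1] - 1e-9 & cells$x_um <= xr[2] + 1e-9 &
                  cells$y_um >= yr[1] - 1e-9 & cells$y_um <= yr[2] + 1e-9)
    if (!length(cand)) next
    hit <- cand[points_in_polygon(cells$x_um[cand], cells$y_um[cand], poly)]
    bin_col[hit] <- bins$col[b]
    bin_row[hit] <- bins$row[b]
  }
  lost <- which(is.na(bin_col))
  if (length(lost)) {
    cx <- vapply(bins$polygon, function(p) mean(p[, 1]), numeric(1))
    cy <- vapply(bins$polygon, function(p) mean(p[, 2]), numeric(1))
    for (i in lost) {
      b <- which.min((cx - cells$x_um[i])^2 + (cy - cells$y_um[i])^2)
      bin_col[i] <- bins$col[b]; bin_row[i] <- bins$row[b]
    }
  }
  tibble::tibble(bin_col = bin_col, bin_row = bin_row)
}

#' Per-bin counts and densities
#'
#' Counts the cells assigned to each grid bin (effective, probability-
#' weighted counts when a stereological [bootstrap_exclusion()] result is
#' supplied: each cell contributes `1 - exclusion probability`) and converts
#' to densities using the bin volume `area_um2 * thickness_um` (reported in
#' cells/mm^3). Zero-area bins report a missing density, never infinity.
#'
#' @param grid A `depth_grid`.
#' @param cells Cells already filtered to the band polygon
#'   ([filter_in_polygon()]).
#' @param thickness_um Slice thickness (um).
#' @param exclusion Optional `exclusion_result` aligned with `cells` rows.
#' @return The `depth_grid` with `count`, `volume_mm3` and
#'   `density_cells_mm3` columns added to its `bins` tibble.
#' @export
bin_densities <- function(grid, cells, thickness_um = 50, exclusion = NULL) {
  stopifnot(inherits(grid, "depth_grid"))
  w <- rep(1, nrow(cells))
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "exclusion_result"),
              exclusion$n_cells == nrow(cells))
    w <- 1 - exclusion$per_cell_exclusion_probability
  }
  asg <- assign_bins(grid, cells)
  key <- paste(asg$bin_col, asg$bin_row)
  counts <- tapply(w, key, sum)
  bins <- grid$bins
  bins$count <- as.numeric(counts[paste(bins$col, bins$row)])
  bins$count[is.na(bins$count)] <- 0
  bins$volume_mm3 <- bins$area_um2 * thickness_um * 1e-9
  bins$density_cells_mm3 <- ifelse(bins$volume_mm3 > 0,
                                   bins$count / bins$volume_mm3, NA_real_)
  grid$bins <- bins
  grid$thickness_um <- thickness_um
  grid
}

#' Cell-density depth profile across images
#'
#' For each image, bin densities are first averaged over the grid columns
#' within each row; the per-row across-image mean and standard deviation
#' (n - 1 denominator) then form the density-versus-percent-depth profile.
#'
#' @param per_image Either a list of `depth_grid`s processed by
#'   [bin_densities()] or a list of tibbles with `row` and
#'   `density_cells_mm3` columns.
#' @param n_rows Number of depth rows (default 20; bin centers at 2.5%,
#'   7.5%, ..., 97.5% depth).
#' @return A tibble of class `depth_profile` with `depth_percent`,
#'   `mean_density`, `sd_density`, `n_images`. With a single image the SD is
#'   reported as 0 and `n_images = 1` flags it.
#' @export
depth_profile <- function(per_image, n_rows = 20) {
  if (inherits(per_image, "depth_grid")) per_image <- list(per_image)
  stopifnot(length(per_image) >= 1)
  row_means <- lapply(per_image, function(g) {
    b <- if (inherits(g, "depth_grid")) g$bins else tibble::as_tibble(g)
    if (is.null(b$density_cells_mm3)) {
      stop("run bin_densities() first: no density column", call. = FALSE)
    }
    if (max(b$row) != n_rows) {
      stop("inconsistent row count: expected ", n_rows, ", got ", max(b$row),
           call. = FALSE)
    }
    out <- tapply(b$density_cells_mm3, b$row, mean, na.rm = TRUE)
    as.numeric(out[as.character(seq_len(n_rows))])
  })
  mat <- do.call(cbind, row_means)
  n_images <- ncol(mat)
  out <- tibble::tibble(
    depth_percent = (seq_len(n_rows) - 0.5) / n_rows * 100,
    mean_density = rowMeans(mat, na.rm = TRUE),
    sd_density = if (n_images > 1) apply(mat, 1, sd, na.rm = TRUE) else rep(0, n_rows),
    n_images = n_images
  )
  class(out) <- c("depth_profile", class(out))
  out
}

#' @rdname depth_profile
#' @param object A `depth_profile`.
#' @param ... Unused.
#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_percent,
                                       y = .data$mean_density)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_density - .data$sd_density,
                                      ymax = .data$mean_density + .data$sd_density),
                         fill = "lightblue") +
    ggplot2::geom_line(colour = "darkblue", linewidth = 0.8) +
    ggplot2::labs(x = "cortical depth (%)", y = "cell density (cells/mm³)") +
    ggplot2::theme_minimal()
}
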