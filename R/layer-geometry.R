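# Alpha-concave hulls per layer, alpha selection, per-layer densities and
# layer heights.

# union-find over triangle indices
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Connected components of triangles sharing an edge; returns component id per
# triangle.
tri_components <- function(tri) {
  m <- nrow(tri)
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  owner <- rep(seq_len(m), 3)
  parent <- seq_len(m)
  sp <- split(owner, key)
  for (grp in sp) {
    if (length(grp) < 2) next
    r1 <- uf_find(parent, grp[1])
    for (g in grp[-1]) {
      r2 <- uf_find(parent, g)
      if (r1 != r2) parent[r2] <- r1
    }
  }
  vapply(seq_len(m), function(i) uf_find(parent, i), integer(1))
}

# Outer boundary polygon of a set of triangles. Triangles are oriented
# positively so their boundary edges (those used by exactly one triangle)
# carry the region on their left; loops are walked along these directed
# edges, resolving pinch vertices (several outgoing edges) by taking the
# sharpest right turn, which keeps each loop on one face. The loop with the
# largest signed area is the outer boundary (holes come out negative).
tri_boundary_polygon <- function(pts, tri) {
  # orient each triangle counter-clockwise (positive shoelace)
  det <- (pts[tri[, 2], 1] - pts[tri[, 1], 1]) *
    (pts[tri[, 3], 2] - pts[tri[, 1], 2]) -
    (pts[tri[, 3], 1] - pts[tri[, 1], 1]) *
    (pts[tri[, 2], 2] - pts[tri[, 1], 2])
  flip <- det < 0
  tmp <- tri[flip, 2]
  tri[flip, 2] <- tri[flip, 3]
  tri[flip, 3] <- tmp
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  be <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
  if (nrow(be) < 3) stop("degenerate hull boundary", call. = FALSE)
  out_map <- split(seq_len(nrow(be)), be[, 1])
  used <- rep(FALSE, nrow(be))
  loops <- list()
  for (e0 in seq_len(nrow(be))) {
    if (used[e0]) next
    loop <- be[e0, 1]
    e <- e0
    repeat {
      used[e] <- TRUE
      u <- be[e, 1]; v <- be[e, 2]
      loop <- c(loop, v)
      cand <- out_map[[as.character(v)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1) {
        # continue around the same face: smallest counter-clockwise angle
        # from the reversed incoming direction (sharpest right turn), which
        # keeps the exterior ring outside any hole meeting it at the pinch
        rin <- atan2(pts[u, 2] - pts[v, 2], pts[u, 1] - pts[v, 1])
        ang <- atan2(pts[be[cand, 2], 2] - pts[v, 2],
                     pts[be[cand, 2], 1] - pts[v, 1])
        turn <- (ang - rin) %% (2 * pi)
        cand <- cand[which.min(turn)]
      }
      e <- cand[1]
    }
    loops[[length(loops) + 1]] <- loop[-length(loop)] # drop closing vertex
  }
  areas <- vapply(loops, function(l) signed_area(pts[l, , drop = FALSE]),
                  numeric(1))
  ensure_ccw(pts[loops[[which.max(areas)]], , drop = FALSE])
}

#' Alpha-concave hull of a point set
#'
#' Computes the alpha-shape boundary in the inverse characteristic-scale
#' convention: a Delaunay triangle is kept when its circumradius is below
#' `1 / alpha`, so `alpha = 0` yields the convex hull and larger values
#' tighten the outline. When the kept triangles split into several connected
#' regions, the boundary of the largest (by area) is returned.
#'
#' @param points An n x 2 matrix (or data frame) of points.
#' @param alpha Non-negative tightness parameter (1/um).
#' @return A simple polygon (n x 2 matrix, counter-clockwise in shoelace
#'   orientation).
#' @export
alpha_hull <- function(points, alpha) {
  points <- as_xy_matrix(points)
  uniq <- points[!duplicated(paste(points[, 1], points[, 2])), , drop = FALSE]
  if (nrow(uniq) < 3) stop("degenerate geometry: need at least 3 distinct points",
                           call. = FALSE)
  ch <- grDevices::chull(uniq)
  if (polygon_area(uniq[ch, , drop = FALSE]) <= 0) {
    stop("degenerate geometry: points are collinear", call. = FALSE)
  }
  if (alpha <= 0) return(ensure_ccw(uniq[ch, , drop = FALSE]))
  tri <- delaunay_triangulation(points)
  keep <- tri_circumradius(points, tri) < 1 / alpha
  if (!any(keep)) {
    stop("alpha too large: no triangle has circumradius below 1/alpha",
         call. = FALSE)
  }
  kept <- tri[keep, , drop = FALSE]
  comp <- tri_components(kept)
  comp_area <- tapply(tri_area(points, kept), comp, sum)
  main <- as.integer(names(comp_area)[which.max(comp_area)])
  tri_boundary_polygon(points, kept[comp == main, , drop = FALSE])
}

#' Select an alpha value that rejects no points
#'
#' Among the candidate alphas, returns the one whose hull has minimal area
#' subject to enclosing every input point (points on the hull boundary count
#' as inside). If no candidate encloses all points the convex hull
#' (`alpha = 0`) is returned with a warning.
#'
#' @param points An n x 2 matrix of points.
#' @param candidate_alphas Numeric vector of candidate tightness values.
#' @return A list with `alpha`, `polygon`, `area_um2`, `n_rejected`.
#' @export
select_alpha <- function(points, candidate_alphas = c(0.005, 0.01, 0.02, 0.05, 0.1)) {
  points <- as_xy_matrix(points)
  candidate_alphas <- sort(candidate_alphas)
  best <- NULL
  for (a in candidate_alphas) {
    hull <- tryCatch(alpha_hull(points, a), error = function(e) NULL)
    if (is.null(hull)) next
    outside <- sum(!points_in_polygon(points[, 1], points[, 2], hull))
    if (outside > 0) next
    area <- polygon_area(hull)
    if (is.null(best) || area < best$area_um2) {
      best <- list(alpha = a, polygon = hull, area_um2 = area, n_rejected = 0L)
    }
  }
  if (is.null(best)) {
    warning("no candidate alpha encloses all points; falling back to the convex hull",
            call. = FALSE)
    hull <- alpha_hull(points, 0)
    best <- list(alpha = 0, polygon = hull, area_um2 = polygon_area(hull),
                 n_rejected = 0L)
  }
  best
}

#' Per-layer alpha-hull volumes and densities
#'
#' For each layer present in the labeled cells, computes the alpha-concave
#' hull of that layer's centroids (the sparse Layer I uses its own, looser
#' alpha: one tenth of the common value), the hull volume at the given slice
#' thickness, the (effective) cell count inside the hull and the resulting
#' density in cells/mm^3.
#'
#' @param cells A labeled cell tibble (`layer_label` set).
#' @param thickness_um Slice thickness (um).
#' @param alpha Tightness used for all layers except Layer I (1/um).
#' @param alpha_layer1 Tightness for Layer I.
#' @param exclusion Optional `exclusion_result` aligned with `cells`; counts
#'   become probability-weighted effective counts.
#' @return A tibble of class `layer_hulls`: `layer_label`, `alpha`,
#'   `polygon` (list-column), `area_um2`, `volume_mm3`, `n_cells`,
#'   `density_cells_mm3`.
#' @export
layer_density <- function(cells, thickness_um = 50, alpha = 0.05,
                          alpha_layer1 = 0.005, exclusion = NULL) {
  w <- rep(1, nrow(cells))
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "exclusion_result"),
              exclusion$n_cells == nrow(cells))
    w <- 1 - exclusion$per_cell_exclusion_probability
  }
  present <- intersect(.layer_levels, unique(cells$layer_label))
  present <- setdiff(present, "none")
  rows <- lapply(present, function(lay) {
    sel <- cells$layer_label == lay
    pts <- cbind(cells$x_um[sel], cells$y_um[sel])
    a <- if (lay == "LI") alpha_layer1 else alpha
    hull <- alpha_hull(pts, a)
    inside <- points_in_polygon(pts[, 1], pts[, 2], hull)
    area <- polygon_area(hull)
    if (area <= 0) stop("zero-area hull for layer ", lay, call. = FALSE)
    vol <- area * thickness_um * 1e-9
    n_eff <- sum(w[sel][inside])
    tibble::tibble(
      layer_label = lay, alpha = a, polygon = list(hull), area_um2 = area,
      volume_mm3 = vol, n_cells = n_eff, density_cells_mm3 = n_eff / vol
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("layer_hulls", class(out))
  out
}

#' @rdname layer_density
#' @param x A `layer_hulls` tibble.
#' @param ... Unused.
#' @export
tidy.layer_hulls <- function(x, ...) {
  out <- dplyr::select(tibble::as_tibble(x), -"polygon")
  class(out) <- setdiff(class(out), "layer_hulls")
  out
}

#' @rdname layer_density
#' @param object A `layer_hulls` tibble.
#' @export
autoplot.layer_hulls <- function(object, ...) {
  polys <- purrr::map2_dfr(object$polygon, object$layer_label, function(p, l) {
    tibble::tibble(x = p[, 1], y = p[, 2], layer = l)
  })
  ggplot2::ggplot(polys, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$layer)) +
    ggplot2::geom_polygon(alpha = 0.5, colour = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

layer_ordering <- function(labels) {
  if ("LII/III" %in% labels) layer_levels(merged = TRUE) else layer_levels()
}

# Depth at which the predicted label switches between two adjacent layers in
# one grid column: among candidate splits between consecutive sorted cells,
# the one minimising the number of misordered cells (upper-layer cells below
# the split plus lower-layer cells above). Reduces to the midpoint between
# the last upper cell and the first lower cell in the noise-free case.
boundary_depth <- function(depth, is_upper) {
  ord <- order(depth)
  depth <- depth[ord]; is_upper <- is_upper[ord]
  n <- length(depth)
  cand <- (depth[-n] + depth[-1]) / 2
  # err(k): split between cell k and k+1
  upper_above <- rev(cumsum(rev(is_upper)))[-1]   # upper cells deeper than split k
  lower_below <- cumsum(!is_upper)[-n]            # lower cells above split k
  err <- upper_above + lower_below
  cand[which.min(err)]
}

#' Layer heights from labeled cells and a depth grid
#'
#' For each grid column, the boundary depth between each pair of adjacent
#' layers is the depth at which the predicted label switches (the split
#' minimising label misordering along the column's depth axis, which is the
#' midpoint between the last cell of the upper layer and the first of the
#' lower in the noise-free limit). A layer's height in a column is the
#' distance between its two boundaries; the pia (depth 0) tops the first
#' layer and the deepest cell of the last layer bottoms the column. Columns
#' missing a layer contribute no estimate for it.
#'
#' @param cells A labeled cell tibble (filtered to the band).
#' @param grid A `depth_grid` built for the same image.
#' @return A tibble of class `layer_heights`: per layer `mean_height_um`,
#'   `sd_height_um`, `n_columns`; the attribute `per_column` holds the
#'   per-column detail and `total_height_um`/`total_sd_um` the pia-to-bottom
#'   column height across columns.
#' @export
layer_heights <- function(cells, grid) {
  stopifnot(inherits(grid, "depth_grid"))
  ord <- layer_ordering(unique(cells$layer_label))
  asg <- assign_bins(grid, cells)
  per_col <- list()
  for (cc in sort(unique(asg$bin_col))) {
    sel <- which(asg$bin_col == cc & cells$layer_label %in% ord)
    if (!length(sel)) next
    d <- cells$dist_pia_um[sel]
    lab <- cells$layer_label[sel]
    present <- ord[ord %in% unique(lab)]
    if (!length(present)) next
    bnd <- numeric(length(present) + 1)
    bnd[1] <- 0
    if (length(present) > 1) {
      for (i in seq_len(length(present) - 1)) {
        pair <- lab %in% c(present[i], present[i + 1])
        bnd[i + 1] <- boundary_depth(d[pair], lab[pair] == present[i])
      }
    }
    bnd[length(present) + 1] <- max(d[lab == present[length(present)]])
    per_col[[length(per_col) + 1]] <- tibble::tibble(
      column = cc, layer_label = present,
      top_um = bnd[-length(bnd)], bottom_um = bnd[-1],
      height_um = diff(bnd)
    )
  }
  detail <- dplyr::bind_rows(per_col)
  if (nrow(detail) == 0) stop("no labeled cells in any grid column", call. = FALSE)
  out <- detail |>
    dplyr::group_by(.data$layer_label) |>
    dplyr::summarise(
      mean_height_um = mean(.data$height_um),
      sd_height_um = if (dplyr::n() > 1) sd(.data$height_um) else 0,
      n_columns = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$layer_label, ord))
  totals <- detail |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(total = max(.data$bottom_um), .groups = "drop")
  attr(out, "per_column") <- detail
  attr(out, "total_height_um") <- mean(totals$total)
  attr(out, "total_sd_um") <- if (nrow(totals) > 1) sd(totals$total) else 0
  class(out) <- c("layer_heights", class(out))
  out
}
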