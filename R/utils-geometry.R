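# Planar geometry helpers. Polygons are n x 2 numeric matrices of vertices in
# order, open rings (the closing edge last->first is implicit). Coordinates are
# micrometres in the image frame: y increases downward.

as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, 1:2])
  p <- unname(as.matrix(p))
  storage.mode(p) <- "double"
  if (ncol(p) != 2) stop("polygon/polyline must have two columns (x, y)", call. = FALSE)
  # drop an explicitly closed ring's duplicate end vertex
  n <- nrow(p)
  if (n > 1 && isTRUE(all(p[1, ] == p[n, ]))) p <- p[-n, , drop = FALSE]
  p
}

signed_area <- function(poly) {
  poly <- as_xy_matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area (shoelace)
#' @param poly n x 2 matrix of vertices (open ring).
#' @return Area in squared input units, orientation-invariant.
#' @export
polygon_area <- function(poly) abs(signed_area(poly))

# exterior ring counter-clockwise in a y-down frame means negative signed area
# in the usual y-up convention; normalize to positive shoelace orientation so
# that orientation is deterministic after I/O round-trips.
ensure_ccw <- function(poly) {
  poly <- as_xy_matrix(poly)
  if (signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Test points against a simple polygon
#'
#' Boundary points count as inside, matching the convention that cells
#' sitting exactly on the region outline are retained.
#'
#' @param x,y Point coordinates.
#' @param poly Polygon as an n x 2 matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- as_xy_matrix(poly)
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

polyline_seg_lengths <- function(line) {
  line <- as.matrix(line)
  sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
}

polyline_length <- function(line) sum(polyline_seg_lengths(line))

# Resample a polyline to m points uniformly spaced in arc length.
resample_polyline <- function(line, m) {
  line <- as.matrix(line)
  if (nrow(line) < 2) stop("polyline needs at least 2 vertices", call. = FALSE)
  s <- c(0, cumsum(polyline_seg_lengths(line)))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate zero-length polyline", call. = FALSE)
  target <- seq(0, total, length.out = m)
  cbind(
    stats::approx(s, line[, 1], xout = target, ties = "ordered")$y,
    stats::approx(s, line[, 2], xout = target, ties = "ordered")$y
  )
}

# Minimum distance from each point to a polyline (vectorized over points).
dist_to_polyline <- function(x, y, line) {
  line <- as.matrix(line)
  n <- nrow(line)
  if (n == 1) return(sqrt((x - line[1, 1])^2 + (y - line[1, 2])^2))
  best <- rep(Inf, length(x))
  for (i in seq_len(n - 1)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    dx <- line[i + 1, 1] - ax; dy <- line[i + 1, 2] - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2)) else 0
    d2 <- (x - (ax + t * dx))^2 + (y - (ay + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Sutherland-Hodgman clipping: subject polygon clipped by a convex polygon.
# Returns the (possibly empty) intersection polygon.
clip_polygon_convex <- function(subject, clip) {
  subject <- ensure_ccw(subject)
  clip <- ensure_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inside <- function(p) (ex * (p[2] - a[2]) - ey * (p[1] - a[1])) >= -1e-12
    res <- matrix(numeric(0), ncol = 2)
    np <- nrow(out)
    for (j in seq_len(np)) {
      p <- out[j, ]; q <- out[if (j == np) 1 else j + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) res <- rbind(res, p)
      if (xor(pin, qin)) {
        denom <- ex * (q[2] - p[2]) - ey * (q[1] - p[1])
        if (abs(denom) > 1e-15) {
          t <- (ex * (a[2] - p[2]) - ey * (a[1] - p[1])) / denom
          t <- min(1, max(0, t))
          res <- rbind(res, p + t * (q - p))
        }
      }
    }
    out <- res
  }
  unname(out)
}

polygon_intersection_area <- function(a, b) {
  a <- as_xy_matrix(a); b <- as_xy_matrix(b)
  # Sutherland-Hodgman needs a convex clip polygon; clip by whichever input is
  # convex, preferring b. Near-convex soma outlines make this exact in
  # practice; use mode = "raster" in polygon_iou() for arbitrary shapes.
  if (is_convex_polygon(b)) {
    inter <- clip_polygon_convex(a, b)
  } else if (is_convex_polygon(a)) {
    inter <- clip_polygon_convex(b, a)
  } else {
    return(raster_intersection_area(a, b))
  }
  if (nrow(inter) < 3) 0 else polygon_area(inter)
}

is_convex_polygon <- function(poly, tol = 1e-9) {
  poly <- as_xy_matrix(poly)
  n <- nrow(poly)
  if (n < 4) return(TRUE)
  nxt <- c(2:n, 1)
  e <- poly[nxt, , drop = FALSE] - poly
  cr <- e[, 1] * e[nxt, 2] - e[, 2] * e[nxt, 1]
  scale <- max(abs(cr), 1)
  all(cr >= -tol * scale) || all(cr <= tol * scale)
}

raster_grid <- function(polys, pixel) {
  bb <- do.call(rbind, polys)
  list(
    x = seq(min(bb[, 1]) - pixel, max(bb[, 1]) + pixel, by = pixel),
    y = seq(min(bb[, 2]) - pixel, max(bb[, 2]) + pixel, by = pixel)
  )
}

rasterize_polygon <- function(poly, grid) {
  g <- expand.grid(x = grid$x, y = grid$y)
  matrix(points_in_polygon(g$x, g$y, poly), nrow = length(grid$x))
}

raster_intersection_area <- function(a, b, pixel = 0.346) {
  grid <- raster_grid(list(a, b), pixel)
  ra <- rasterize_polygon(a, grid); rb <- rasterize_polygon(b, grid)
  sum(ra & rb) * pixel^2
}

#' Intersection-over-union of two polygons
#'
#' @param a,b Simple polygons (n x 2 matrices).
#' @param mode `"area"` computes exact vector areas (requires at least one of
#'   the two polygons to be convex, else falls back to rasterisation);
#'   `"raster"` rasterises both polygons on a common pixel grid.
#' @param pixel Pixel edge (micrometres) for rasterised mode; the default
#'   matches 20x slide scans at 0.346 um/pixel.
#' @return IoU in `[0, 1]`.
#' @export
polygon_iou <- function(a, b, mode = c("area", "raster"), pixel = 0.346) {
  mode <- match.arg(mode)
  a <- as_xy_matrix(a); b <- as_xy_matrix(b)
  if (mode == "raster") {
    grid <- raster_grid(list(a, b), pixel)
    ra <- rasterize_polygon(a, grid); rb <- rasterize_polygon(b, grid)
    inter <- sum(ra & rb); uni <- sum(ra | rb)
    return(if (uni == 0) 0 else inter / uni)
  }
  inter <- polygon_intersection_area(a, b)
  uni <- polygon_area(a) + polygon_area(b) - inter
  if (uni <= 0) 0 else min(1, max(0, inter / uni))
}

# Delaunay triangulation of a 2-D point set (duplicate points collapsed).
# Returns list(triangles = m x 3 index matrix into the *original* rows,
# kept = indices of unique rows used).
delaunay_triangulation <- function(pts) {
  pts <- as_xy_matrix(pts)
  key <- paste(pts[, 1], pts[, 2])
  keep <- !duplicated(key)
  idx <- which(keep)
  up <- pts[keep, , drop = FALSE]
  if (nrow(up) < 3) stop("need at least 3 distinct points", call. = FALSE)
  tri <- delaunay_cpp(up)
  tri[] <- idx[tri]
  tri
}

tri_circumradius <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  a <- sqrt((bx - cx)^2 + (by - cy)^2)
  b <- sqrt((ax - cx)^2 + (ay - cy)^2)
  cc <- sqrt((ax - bx)^2 + (ay - by)^2)
  area2 <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
  r <- a * b * cc / (2 * pmax(area2, .Machine$double.xmin))
  r[area2 <= 0] <- Inf
  r
}

tri_area <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}
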