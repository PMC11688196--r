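# Shared fixtures, built in code.

# Small three-layer column spec for fast tests.
small_layers <- function() {
  tibble::tribble(
    ~label, ~height_um, ~density_cells_mm3,
    ~pop1_mean_um, ~pop1_sd_um, ~pop2_mean_um, ~pop2_sd_um,
    "LI",  100, 40000, 5.0, 1.0, 8.0, 2.0,
    "LIV", 150, 100000, 6.0, 1.4, 10.0, 2.0,
    "LVIb", 120, 70000, 4.8, 1.0, 9.0, 2.5
  ) |> dplyr::mutate(pop1_weight = 0.5)
}

small_spec <- function(seed = 1, width = 400, curvature = 0) {
  column_spec(small_layers(), column_width_um = width,
              curvature_um = curvature, seed = seed)
}

# A hand-rolled ray-casting point-in-polygon oracle (even-odd rule), kept
# independent of the package implementation.
ray_cast_inside <- function(x, y, poly) {
  n <- nrow(poly)
  out <- logical(length(x))
  for (p in seq_along(x)) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      # on-edge check: treat boundary as inside
      if (on_segment(x[p], y[p], xi, yi, xj, yj)) {
        inside <- TRUE
        break
      }
      if ((yi > y[p]) != (yj > y[p])) {
        xint <- xi + (y[p] - yi) * (xj - xi) / (yj - yi)
        if (x[p] < xint) inside <- !inside
      }
      j <- i
    }
    out[p] <- inside
  }
  out
}

on_segment <- function(px, py, x1, y1, x2, y2, tol = 1e-9) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > tol * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  px >= min(x1, x2) - tol && px <= max(x1, x2) + tol &&
    py >= min(y1, y2) - tol && py <= max(y1, y2) + tol
}

# All permutations of 1:n as rows (n small).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))
  }))
}

# Axis-aligned square polygon helper for segmentation tests.
square_poly <- function(x0, y0, side = 1) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# Minimal valid cell tibble.
toy_cells <- function(x, y, d = 10, image_id = "img1", layer = "none") {
  n <- length(x)
  tibble::tibble(
    image_id = image_id, cell_id = sprintf("c%03d", seq_len(n)),
    x_um = x, y_um = y,
    d_max_um = rep_len(d, n), d_min_um = rep_len(d, n),
    dist_pia_um = y, layer_label = rep_len(layer, n)
  )
}
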