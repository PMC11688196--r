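# Synthetic layered cortical columns: geometry, Poisson cell point patterns,
# bimodal soma-diameter draws and layer labels, in the same formats the
# readers ingest.

#' Default layer specification for the juvenile rat S1HL column
#'
#' Per-layer mean thicknesses, Nissl-positive cell densities and
#' two-component soma-diameter mixture parameters for the seven-layer
#' somatosensory column (pia to white matter). Mixture weights are an even
#' split: the source measurements report per-population means and spreads but
#' no weights, so 0.5 is the neutral default and can be overridden.
#'
#' @return A tibble with one row per layer: `label`, `height_um`,
#'   `density_cells_mm3`, `pop1_mean_um`, `pop1_sd_um`, `pop2_mean_um`,
#'   `pop2_sd_um`, `pop1_weight`.
#' @export
default_layer_spec <- function() {
  tibble::tribble(
    ~label, ~height_um, ~density_cells_mm3,
    ~pop1_mean_um, ~pop1_sd_um, ~pop2_mean_um, ~pop2_sd_um,
    "LI",   129, 32568, 5.20, 1.20,  8.14, 2.33,
    "LII",  129, 90226, 5.96, 1.38, 10.33, 2.11,
    "LIII", 373, 85094, 6.09, 1.52, 10.74, 2.18,
    "LIV",  152, 103016, 6.04, 1.40, 10.14, 1.91,
    "LV",   517, 72005, 5.35, 1.03, 10.51, 3.00,
    "LVIa", 452, 89198, 5.36, 1.18, 10.01, 1.83,
    "LVIb", 165, 71153, 4.80, 0.99,  9.12, 2.69
  ) |>
    dplyr::mutate(pop1_weight = 0.5)
}

# Minimum physical soma diameter (um) used to truncate mixture draws; matches
# the smallest observed soma in the reference measurements.
.min_diameter_um <- 0.39

#' Specify a synthetic cortical column
#'
#' @param layers Tibble of per-layer parameters as in [default_layer_spec()],
#'   ordered pia to white matter.
#' @param column_width_um Width of the simulated band (um).
#' @param curvature_um Sagitta (bow amplitude) of the pia; 0 gives a straight
#'   pia and an axis-aligned rectangular column. A bowed pia is modelled as a
#'   circular arc so that the layer bands are concentric constant-depth
#'   offsets; the sagitta must be small enough that the arc radius exceeds
#'   the total column depth.
#' @param thickness_um Slice thickness (um); 50 matches sagittal cryostat
#'   sections.
#' @param seed Integer seed driving all draws; per-layer sub-streams are
#'   derived from it so edits to the layer list do not reshuffle other
#'   layers.
#' @return An object of class `column_spec`.
#' @export
column_spec <- function(layers = default_layer_spec(), column_width_um = 1000,
                        curvature_um = 0, thickness_um = 50, seed = 1L) {
  layers <- tibble::as_tibble(layers)
  need <- c("label", "height_um", "density_cells_mm3", "pop1_mean_um",
            "pop1_sd_um", "pop2_mean_um", "pop2_sd_um", "pop1_weight")
  missing <- setdiff(need, names(layers))
  if (length(missing)) {
    stop("layer spec missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(layers) < 1) stop("need at least one layer", call. = FALSE)
  stopifnot(all(layers$height_um > 0), all(layers$density_cells_mm3 >= 0),
            all(layers$pop1_sd_um > 0), all(layers$pop2_sd_um > 0),
            all(layers$pop1_weight >= 0 & layers$pop1_weight <= 1),
            column_width_um > 0, thickness_um > 0, curvature_um >= 0)
  total <- sum(layers$height_um)
  if (curvature_um > 0) {
    radius <- (column_width_um^2 / 4 + curvature_um^2) / (2 * curvature_um)
    if (radius <= total) {
      stop("curvature too strong: arc radius ", round(radius),
           " um must exceed total depth ", round(total), " um", call. = FALSE)
    }
  }
  structure(
    list(layers = layers, column_width_um = column_width_um,
         curvature_um = curvature_um, thickness_um = thickness_um,
         seed = as.integer(seed)),
    class = "column_spec"
  )
}

# Pia polyline for a spec: straight segment or circular arc with the given
# sagitta, sampled densely enough for downstream arc-length resampling.
pia_polyline <- function(spec, n_pts = 101) {
  w <- spec$column_width_um
  if (spec$curvature_um <= 0) {
    return(cbind(seq(0, w, length.out = n_pts), 0))
  }
  a <- spec$curvature_um
  r <- (w^2 / 4 + a^2) / (2 * a)
  cx <- w / 2; cy <- r - a # center below the chord (y increases downward)
  half <- asin((w / 2) / r)
  th <- seq(-half, half, length.out = n_pts)
  cbind(cx + r * sin(th), cy - r * cos(th))
}

# Constant-depth offset of the pia: concentric arc (or parallel line).
offset_polyline <- function(spec, depth, n_pts = 101) {
  w <- spec$column_width_um
  if (spec$curvature_um <= 0) {
    return(cbind(seq(0, w, length.out = n_pts), depth))
  }
  a <- spec$curvature_um
  r <- (w^2 / 4 + a^2) / (2 * a)
  cx <- w / 2; cy <- r - a
  half <- asin((w / 2) / r)
  th <- seq(-half, half, length.out = n_pts)
  rd <- r - depth
  cbind(cx + rd * sin(th), cy - rd * cos(th))
}

band_polygon <- function(spec, depth_top, depth_bottom, n_pts = 101) {
  top <- offset_polyline(spec, depth_top, n_pts)
  bot <- offset_polyline(spec, depth_bottom, n_pts)
  rbind(top, bot[rev(seq_len(nrow(bot))), , drop = FALSE])
}

#' Build the annotation geometry of a synthetic column
#'
#' Produces the pia polyline (`Outside Pia`), the cortical-band polygon whose
#' top edge is the pia and whose bottom edge is its constant-depth offset by
#' the summed layer heights, and the four corner reference points. With zero
#' curvature the band is an axis-aligned rectangle.
#'
#' @param spec A [column_spec()].
#' @return A [region_set()].
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "column_spec"))
  total <- sum(spec$layers$height_um)
  top <- pia_polyline(spec)
  bot <- offset_polyline(spec, total)
  poly <- rbind(top, bot[rev(seq_len(nrow(bot))), , drop = FALSE])
  corners <- list(
    tl = top[1, ], tr = top[nrow(top), ],
    bl = bot[1, ], br = bot[nrow(bot), ]
  )
  region_set(poly, outside_pia = top, corners = corners,
             metadata = list(analyze = TRUE))
}

layer_substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 2654435L + h * 97L) %% 2147483647L)
}

sample_uniform_in_polygon <- function(n, poly, seed_state = NULL) {
  if (n == 0) return(cbind(numeric(0), numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(2L * (n - length(out_x)), 32L)
    x <- runif(m, xr[1], xr[2]); y <- runif(m, yr[1], yr[2])
    keep <- points_in_polygon(x, y, poly)
    out_x <- c(out_x, x[keep]); out_y <- c(out_y, y[keep])
  }
  cbind(out_x[seq_len(n)], out_y[seq_len(n)])
}

# Truncated draw from the layer's two-component diameter mixture.
sample_diameters <- function(n, layer_row) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 32L)
    comp <- runif(m) < layer_row$pop1_weight
    d <- ifelse(comp,
                rnorm(m, layer_row$pop1_mean_um, layer_row$pop1_sd_um),
                rnorm(m, layer_row$pop2_mean_um, layer_row$pop2_sd_um))
    out <- c(out, d[d >= .min_diameter_um])
  }
  out[seq_len(n)]
}

#' Sample a synthetic cell table from a column specification
#'
#' Per layer, the cell count is Poisson with mean
#' `density * band_area * thickness` (unit-consistent: um^2 x um converted to
#' mm^3); positions are uniform in the layer band; soma diameters are drawn
#' from the layer's two-component Gaussian mixture truncated at the minimum
#' physical size; `dist_pia_um` is the Euclidean distance from the centroid
#' to the pia polyline, and `layer_label` records the generating layer.
#' Deterministic given the spec's seed.
#'
#' @param spec A [column_spec()].
#' @param geometry Optional [region_set()] from [make_geometry()] (rebuilt if
#'   omitted).
#' @param image_id Image identifier stamped on every row.
#' @param label_noise_um Optional boundary-uncertainty emulation: layer
#'   labels are re-assigned from a depth jittered by this Gaussian standard
#'   deviation (um), so labels near boundaries overlap as they do in human
#'   annotations. 0 (default) keeps exact generating labels.
#' @return A validated cell tibble (see [read_cell_table()]).
#' @export
sample_cells <- function(spec, geometry = NULL, image_id = "synthetic_1",
                         label_noise_um = 0) {
  stopifnot(inherits(spec, "column_spec"))
  if (is.null(geometry)) geometry <- make_geometry(spec)
  pia <- geometry$outside_pia
  layers <- spec$layers
  bounds <- c(0, cumsum(layers$height_um))
  rows <- vector("list", nrow(layers))
  for (i in seq_len(nrow(layers))) {
    lr <- layers[i, ]
    set.seed(layer_substream_seed(spec$seed, lr$label))
    band <- band_polygon(spec, bounds[i], bounds[i + 1])
    volume_mm3 <- polygon_area(band) * spec$thickness_um * 1e-9
    n <- rpois(1, lr$density_cells_mm3 * volume_mm3)
    if (n == 0) next
    xy <- sample_uniform_in_polygon(n, band)
    d <- sample_diameters(n, lr)
    ecc <- runif(n, 0.75, 1) # d_min/d_max ratio; geometric mean kept at d
    rows[[i]] <- tibble::tibble(
      image_id = image_id,
      layer_label = lr$label,
      x_um = xy[, 1], y_um = xy[, 2],
      d_max_um = d / sqrt(ecc), d_min_um = d * sqrt(ecc),
      area_um2 = pi * (d / 2)^2,
      dist_pia_um = dist_to_polyline(xy[, 1], xy[, 2], pia)
    )
  }
  cells <- dplyr::bind_rows(rows)
  if (nrow(cells) == 0) {
    return(validate_cell_table(tibble::tibble(
      image_id = character(), cell_id = character(), x_um = numeric(),
      y_um = numeric(), d_max_um = numeric(), d_min_um = numeric(),
      area_um2 = numeric(), dist_pia_um = numeric(), layer_label = character()
    )))
  }
  if (label_noise_um > 0) {
    set.seed(layer_substream_seed(spec$seed, "boundary-jitter"))
    jit <- cells$dist_pia_um + rnorm(nrow(cells), 0, label_noise_um)
    idx <- pmin(findInterval(jit, bounds, all.inside = TRUE), nrow(layers))
    cells$layer_label <- layers$label[idx]
  }
  cells$cell_id <- sprintf("cell_%06d", seq_len(nrow(cells)))
  cells$area_backfilled <- FALSE
  validate_cell_table(cells)
}

#' Read a column specification from a JSON document
#'
#' The packaged default (`system.file("extdata", "default_column_spec.json",
#' package = "nisslcolumn")`) carries the seven-layer defaults of
#' [default_layer_spec()].
#'
#' @param path Path to a JSON column specification; `NULL` loads the
#'   packaged default.
#' @return A [column_spec()].
#' @export
read_column_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_column_spec.json",
                        package = "nisslcolumn")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  column_spec(
    layers = tibble::as_tibble(doc$layers),
    column_width_um = doc$column_width_um %||% 1000,
    curvature_um = doc$curvature_um %||% 0,
    thickness_um = doc$thickness_um %||% 50,
    seed = doc$seed %||% 1L
  )
}

#' Simulate a full synthetic column
#'
#' Convenience wrapper producing both the annotation geometry and the cell
#' table for one column.
#'
#' @inheritParams sample_cells
#' @param spec A [column_spec()].
#' @return A list with elements `spec`, `regions` and `cells`.
#' @export
simulate_column <- function(spec, image_id = "synthetic_1", label_noise_um = 0) {
  geometry <- make_geometry(spec)
  cells <- sample_cells(spec, geometry, image_id = image_id,
                        label_noise_um = label_noise_um)
  list(spec = spec, regions = geometry, cells = cells)
}
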