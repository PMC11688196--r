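# Region annotations: named geometries in GeoJSON (planar, micrometres).

#' Construct a region set
#'
#' Bundles the named annotation geometries of one image: the cortical-band
#' polygon (`s1hl`), the pia outline (`outside_pia`), the optional slice
#' contour, and the four corner reference points of the band (top-left /
#' top-right on the pia side, bottom-left / bottom-right on the white-matter
#' side).
#'
#' @param s1hl Simple polygon (n x 2 matrix) delimiting the cortical band.
#' @param outside_pia Polyline along the pia surface (optional).
#' @param corners Named list with elements `tl`, `tr`, `bl`, `br`, each a
#'   length-2 numeric, or `NULL`.
#' @param slice_contour Optional polygon of the whole slice.
#' @param metadata List of pass-through metadata (e.g.
#'   `distance_to_midline_mm`, `analyze`).
#' @return An object of class `region_set`.
#' @export
region_set <- function(s1hl, outside_pia = NULL, corners = NULL,
                       slice_contour = NULL, metadata = list()) {
  s1hl <- ensure_ccw(as_xy_matrix(s1hl))
  if (!is_simple_polygon(s1hl)) {
    stop("S1HL polygon is self-intersecting", call. = FALSE)
  }
  if (!is.null(outside_pia)) outside_pia <- as_xy_matrix(outside_pia)
  if (!is.null(slice_contour)) slice_contour <- ensure_ccw(as_xy_matrix(slice_contour))
  if (!is.null(corners)) {
    need <- c("tl", "tr", "bl", "br")
    if (!all(need %in% names(corners))) {
      stop("corners must be a named list with tl, tr, bl, br", call. = FALSE)
    }
    corners <- lapply(corners[need], function(p) as.numeric(p)[1:2])
    d <- vapply(corners, function(p) {
      dist_to_polyline(p[1], p[2], rbind(s1hl, s1hl[1, ]))
    }, numeric(1))
    if (any(d > 1)) {
      warning("corner point(s) ", paste(names(corners)[d > 1], collapse = ", "),
              " are more than 1 um from the S1HL boundary", call. = FALSE)
    }
  }
  structure(
    list(s1hl = s1hl, outside_pia = outside_pia, corners = corners,
         slice_contour = slice_contour, metadata = metadata),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>\n")
  cat("  S1HL polygon: ", nrow(x$s1hl), " vertices, area ",
      format(polygon_area(x$s1hl), big.mark = ","), " um^2\n", sep = "")
  if (!is.null(x$outside_pia)) {
    cat("  Outside Pia polyline: ", nrow(x$outside_pia), " vertices\n", sep = "")
  }
  if (!is.null(x$corners)) cat("  corner points: tl, tr, bl, br\n")
  if (!is.null(x$slice_contour)) {
    cat("  slice contour: ", nrow(x$slice_contour), " vertices\n", sep = "")
  }
  invisible(x)
}

# Simple-polygon test: no two non-adjacent edges intersect.
is_simple_polygon <- function(poly) {
  poly <- as_xy_matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  p1 <- poly; p2 <- poly[nxt, , drop = FALSE]
  for (i in seq_len(n - 2)) {
    j <- seq(i + 2, n)
    j <- j[!(i == 1 & j == n)] # skip edges adjacent through the closure
    if (!length(j)) next
    if (any(segments_cross(p1[i, ], p2[i, ], p1[j, , drop = FALSE],
                           p2[j, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

# Does segment a-b properly cross any of the segments c[k,]-d[k,]?
segments_cross <- function(a, b, c, d) {
  o <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  o1 <- o(a[1], a[2], b[1], b[2], c[, 1], c[, 2])
  o2 <- o(a[1], a[2], b[1], b[2], d[, 1], d[, 2])
  o3 <- o(c[, 1], c[, 2], d[, 1], d[, 2], a[1], a[2])
  o4 <- o(c[, 1], c[, 2], d[, 1], d[, 2], b[1], b[2])
  o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0
}

.region_names <- c(
  s1hl = "S1HL",
  outside_pia = "Outside Pia",
  slice_contour = "SliceContour",
  tl = "S1HL top-left point",
  tr = "S1HL top-right point",
  bl = "S1HL bottom-left point",
  br = "S1HL bottom-right point"
)

classify_region_name <- function(nm) {
  key <- normalize_header(nm)
  if (key == "s1hl") return("s1hl")
  if (grepl("outsidepia|^pia$", key)) return("outside_pia")
  if (grepl("slicecontour", key)) return("slice_contour")
  if (grepl("top.*left|topleft", key)) return("tl")
  if (grepl("top.*right|topright", key)) return("tr")
  if (grepl("bottom.*left|bottomleft", key)) return("bl")
  if (grepl("bottom.*right|bottomright", key)) return("br")
  NA_character_
}

feature_name <- function(props) {
  nm <- props$classification$name
  if (is.null(nm)) nm <- props$name
  if (is.null(nm)) NA_character_ else as.character(nm)
}

#' Read region annotations from GeoJSON
#'
#' Parses an RFC 7946 FeatureCollection with non-geographic planar
#' coordinates (micrometres). The classification name of each feature is
#' looked up in `properties.classification.name`, then `properties.name`.
#'
#' @param path Path to a GeoJSON file.
#' @return A [region_set()].
#' @export
read_regions <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  got <- list()
  meta <- list()
  for (f in doc$features) {
    nm <- feature_name(f$properties)
    if (is.na(nm)) next
    slot <- classify_region_name(nm)
    if (is.na(slot)) next
    geom <- f$geometry
    coords <- switch(geom$type,
      Polygon = do.call(rbind, lapply(geom$coordinates[[1]], function(p) unlist(p)[1:2])),
      LineString = do.call(rbind, lapply(geom$coordinates, function(p) unlist(p)[1:2])),
      Point = matrix(unlist(geom$coordinates)[1:2], nrow = 1),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    got[[slot]] <- coords
    if (slot == "s1hl" && !is.null(f$properties$distance_to_midline_mm)) {
      meta$distance_to_midline_mm <- as.numeric(f$properties$distance_to_midline_mm)
    }
    if (slot == "s1hl" && !is.null(f$properties$analyze)) {
      meta$analyze <- isTRUE(f$properties$analyze)
    }
  }
  if (is.null(got$s1hl)) stop("named region missing: S1HL", call. = FALSE)
  corners <- NULL
  if (all(c("tl", "tr", "bl", "br") %in% names(got))) {
    corners <- lapply(got[c("tl", "tr", "bl", "br")], function(m) as.numeric(m[1, ]))
  }
  region_set(got$s1hl, outside_pia = got$outside_pia, corners = corners,
             slice_contour = got$slice_contour, metadata = meta)
}

geojson_feature <- function(name, type, coords, extra_props = list()) {
  props <- c(list(classification = list(name = name)), extra_props)
  list(type = "Feature", properties = props,
       geometry = list(type = type, coordinates = coords))
}

ring_coords <- function(poly) {
  poly <- ensure_ccw(poly)
  closed <- rbind(poly, poly[1, ])
  list(lapply(seq_len(nrow(closed)), function(i) as.numeric(closed[i, ])))
}

line_coords <- function(line) {
  lapply(seq_len(nrow(line)), function(i) as.numeric(line[i, ]))
}

#' Write region annotations to GeoJSON
#'
#' @param regions A [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  feats <- list()
  extra <- list()
  if (!is.null(regions$metadata$distance_to_midline_mm)) {
    extra$distance_to_midline_mm <- regions$metadata$distance_to_midline_mm
  }
  if (!is.null(regions$metadata$analyze)) extra$analyze <- regions$metadata$analyze
  feats[[length(feats) + 1]] <-
    geojson_feature("S1HL", "Polygon", ring_coords(regions$s1hl), extra)
  if (!is.null(regions$outside_pia)) {
    feats[[length(feats) + 1]] <-
      geojson_feature("Outside Pia", "LineString", line_coords(regions$outside_pia))
  }
  if (!is.null(regions$slice_contour)) {
    feats[[length(feats) + 1]] <-
      geojson_feature("SliceContour", "Polygon", ring_coords(regions$slice_contour))
  }
  if (!is.null(regions$corners)) {
    for (k in c("tl", "tr", "bl", "br")) {
      feats[[length(feats) + 1]] <- geojson_feature(
        .region_names[[k]], "Point", as.numeric(regions$corners[[k]])
      )
    }
  }
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read cell outline polygons from GeoJSON
#'
#' Reads a FeatureCollection of Polygon features (e.g. exported segmentation
#' masks) into a list of n x 2 matrices, for use with the segmentation
#' evaluation functions.
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of polygons (exterior rings, open).
#' @export
read_polygons <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  polys <- list()
  for (f in doc$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    nm <- feature_name(f$properties)
    m <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(p) unlist(p)[1:2]))
    polys[[length(polys) + 1]] <- as_xy_matrix(m)
    names(polys)[length(polys)] <-
      if (is.na(nm)) paste0("object_", length(polys)) else nm
  }
  polys
}

#' Write cell outline polygons to GeoJSON
#'
#' @param polys List of polygons (n x 2 matrices); names become feature names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polys, path) {
  nms <- names(polys)
  if (is.null(nms)) nms <- paste0("object_", seq_along(polys))
  feats <- lapply(seq_along(polys), function(i) {
    geojson_feature(nms[i], "Polygon", ring_coords(polys[[i]]))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
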