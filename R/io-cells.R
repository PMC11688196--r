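# Detection-measurement table I/O (QuPath-export dialect, tab-separated).

.canonical_cols <- c(
  "image_id", "cell_id", "x_um", "y_um", "d_max_um", "d_min_um",
  "area_um2", "dist_pia_um", "layer_label", "z_um", "excluded"
)
.mandatory_cols <- c(
  "image_id", "cell_id", "x_um", "y_um", "d_max_um", "d_min_um", "dist_pia_um"
)
.export_headers <- c(
  image_id = "Image",
  cell_id = "Name",
  x_um = "Centroid X um",
  y_um = "Centroid Y um",
  d_max_um = "Cell: Max diameter um",
  d_min_um = "Cell: Min diameter um",
  area_um2 = "Cell: Area um^2",
  dist_pia_um = "Distance to annotation with Outside Pia um",
  layer_label = "Layer",
  z_um = "Z um",
  excluded = "Excluded"
)

# Header normalization: exports differ in case, whitespace, punctuation and
# mu-vs-u spelling; compare on a stripped-down key.
normalize_header <- function(h) {
  h <- tolower(h)
  h <- gsub("µ|μ", "u", h)
  gsub("[^a-z0-9]+", "", h)
}

match_canonical <- function(headers) {
  key <- normalize_header(headers)
  out <- rep(NA_character_, length(headers))
  exact <- normalize_header(.export_headers)
  for (i in seq_along(exact)) out[key == exact[i]] <- names(exact)[i]
  pattern_map <- list(
    image_id = "^image$",
    cell_id = "^(name|objectid|cellid)$",
    x_um = "centroid.*x|^x(um)?$",
    y_um = "centroid.*y|^y(um)?$",
    d_max_um = "max.*diam|diam.*max",
    d_min_um = "min.*diam|diam.*min",
    area_um2 = "area",
    dist_pia_um = "dist.*pia|pia.*dist",
    layer_label = "^(layer|class|classification|predictedlayer|layerlabel)",
    z_um = "^z(um)?$|virtualz",
    excluded = "^excluded$"
  )
  for (canon in names(pattern_map)) {
    if (canon %in% out) next
    hit <- which(is.na(out) & grepl(pattern_map[[canon]], key))
    if (length(hit)) out[hit[1]] <- canon
  }
  out
}

#' Validate a cell table
#'
#' Checks the per-cell invariants: finite coordinates, `d_min_um <= d_max_um`,
#' non-negative distance to pia, positive areas when present, and layer labels
#' drawn from the closed vocabulary. A missing `area_um2` column is back-filled
#' under a circular-soma assumption from the mean of the two diameters,
#' `pi * ((d_max + d_min) / 4)^2`, and flagged in `area_backfilled`.
#'
#' @param cells A data frame with the canonical cell columns.
#' @return The validated tibble (invisibly modified: canonical column order
#'   first, extras preserved).
#' @export
validate_cell_table <- function(cells) {
  cells <- tibble::as_tibble(cells)
  missing <- setdiff(.mandatory_cols, names(cells))
  if (length(missing)) {
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c("x_um", "y_um", "d_max_um", "d_min_um", "area_um2",
                          "dist_pia_um", "z_um"), names(cells))
  for (cl in num_cols) cells[[cl]] <- as.numeric(cells[[cl]])
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um))) {
    stop("non-finite centroid coordinates", call. = FALSE)
  }
  if (any(cells$d_min_um > cells$d_max_um + 1e-9, na.rm = TRUE)) {
    stop("d_min_um exceeds d_max_um for some cells", call. = FALSE)
  }
  if (any(cells$dist_pia_um < 0, na.rm = TRUE)) {
    stop("negative dist_pia_um", call. = FALSE)
  }
  if (!"layer_label" %in% names(cells)) cells$layer_label <- "none"
  cells$layer_label <- as.character(cells$layer_label)
  cells$layer_label[is.na(cells$layer_label) | cells$layer_label == ""] <- "none"
  bad <- setdiff(unique(cells$layer_label), .layer_levels)
  if (length(bad)) {
    stop("unknown layer label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"area_um2" %in% names(cells) || all(is.na(cells$area_um2))) {
    cells$area_um2 <- pi * ((cells$d_max_um + cells$d_min_um) / 4)^2
    cells$area_backfilled <- TRUE
  } else if (is.null(cells[["area_backfilled"]])) {
    fill <- is.na(cells$area_um2)
    cells$area_backfilled <- fill
    cells$area_um2[fill] <-
      pi * ((cells$d_max_um[fill] + cells$d_min_um[fill]) / 4)^2
  }
  if (any(cells$area_um2 <= 0, na.rm = TRUE)) {
    stop("non-positive area_um2", call. = FALSE)
  }
  front <- intersect(c(.canonical_cols, "area_backfilled"), names(cells))
  dplyr::relocate(cells, dplyr::all_of(front))
}

#' Read a detection-measurement table
#'
#' Reads the tab-separated per-cell export dialect (one row per segmented
#' cell: image, name, centroid x/y, max/min diameter, distance to the
#' Outside Pia annotation, in micrometres). Header matching is
#' case-insensitive and tolerant to whitespace, punctuation and mu-vs-u
#' spelling differences; unrecognised columns are preserved verbatim.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param strict If `TRUE` (default) a non-numeric coordinate is an error; if
#'   `FALSE` such rows are dropped with a message stating the count.
#' @return A tibble with canonical columns (`image_id`, `cell_id`, `x_um`,
#'   `y_um`, `d_max_um`, `d_min_um`, `area_um2`, `dist_pia_um`,
#'   `layer_label`, optional `z_um`/`excluded`) followed by any extra columns.
#' @export
read_cell_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  canon <- match_canonical(names(raw))
  missing <- setdiff(.mandatory_cols, canon)
  if (length(missing)) {
    stop("missing mandatory column(s): ",
         paste(.export_headers[missing], collapse = "; "), call. = FALSE)
  }
  names(raw)[!is.na(canon)] <- canon[!is.na(canon)]
  num_cols <- intersect(c("x_um", "y_um", "d_max_um", "d_min_um", "area_um2",
                          "dist_pia_um", "z_um"), names(raw))
  for (cl in num_cols) {
    v <- raw[[cl]]
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(parsed)
    if (any(bad)) {
      if (strict) {
        stop("non-numeric value in column '", cl, "' at data row(s) ",
             paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
      }
      parsed[bad] <- NA
    }
    raw[[cl]] <- parsed
  }
  essential <- intersect(c("x_um", "y_um", "d_max_um", "d_min_um", "dist_pia_um"),
                         names(raw))
  drop <- rowSums(is.na(raw[essential])) > 0
  if (any(drop)) {
    if (strict) {
      stop("unparseable coordinate/measurement in ", sum(drop), " row(s)",
           call. = FALSE)
    }
    message("dropped ", sum(drop), " row(s) with unparseable values")
    raw <- raw[!drop, , drop = FALSE]
  }
  if ("excluded" %in% names(raw)) {
    raw$excluded <- tolower(raw$excluded) %in% c("true", "t", "1", "yes")
  }
  validate_cell_table(raw)
}

#' Write a detection-measurement table
#'
#' Tab-separated, header first, UTF-8, `.` decimal separator. The layer label
#' `"none"` is serialised as an empty cell; extra columns are written
#' verbatim after the canonical ones.
#'
#' @param cells A cell table (see [read_cell_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  cells <- if (nrow(cells)) validate_cell_table(cells) else tibble::as_tibble(cells)
  out <- cells
  if ("layer_label" %in% names(out)) {
    out$layer_label[out$layer_label == "none"] <- ""
  }
  hdr <- names(out)
  known <- hdr %in% names(.export_headers)
  hdr[known] <- .export_headers[hdr[known]]
  names(out) <- hdr
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
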