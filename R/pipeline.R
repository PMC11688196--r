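# End-to-end orchestration: stereology -> depth densities -> (optional)
# classifier -> layer hulls/heights -> morphometry, with a single config and
# seeded, idempotent outputs.

#' Default pipeline configuration
#'
#' All defaults mirror the study constants: 50-um slices, 100 stereology
#' iterations, a 10 x 20 depth grid, 10-fold image-grouped CV, alpha 0.05
#' (0.005 for Layer I), and Bonferroni over the six adjacent-layer
#' comparisons.
#'
#' @param ... Overrides, echoed into the run log.
#' @return A nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    thickness_um = 50,
    stereology = list(iters = 100, seed = 1L),
    grid = list(n_cols = 10, n_rows = 20),
    classifier = list(model = "rf", folds = 10, seed = 1L,
                      paradigm = "separated"),
    alpha = list(general = 0.05, layer1 = 0.005),
    stats = list(alpha = 0.05, bonferroni_m = 6)
  )
  utils::modifyList(cfg, list(...))
}

pipeline_log <- function(run_dir, msg) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", msg)
  message(line)
  cat(line, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

#' Run the full quantification pipeline on one image
#'
#' Executes, in order: stereological bootstrap exclusion, depth-grid
#' densities, layer classification (training and prediction when annotated
#' images are supplied, otherwise the existing labels are used), per-layer
#' alpha-hull densities and heights, and the diameter-mixture morphometry.
#' All stage outputs are written to `run_dir` (`profile.csv`, `layers.json`,
#' `morph.json`, `report.json` plus a timestamped log); a stage failure
#' aborts with the stage name and leaves a `FAILED` marker.
#'
#' @param cells A cell tibble (or path readable by [read_cell_table()]).
#' @param regions A [region_set()] (or GeoJSON path).
#' @param run_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(cells, regions, run_dir = tempfile("nissl_run_"),
                         config = pipeline_config()) {
  if (is.character(cells)) cells <- read_cell_table(cells)
  if (is.character(regions)) regions <- read_regions(regions)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(run_dir, "FAILED"))
  res <- list(config = config)
  stage <- function(name, expr) {
    pipeline_log(run_dir, paste0("stage ", name, " start"))
    out <- tryCatch(expr, error = function(e) {
      file.create(file.path(run_dir, "FAILED"))
      pipeline_log(run_dir, paste0("stage ", name, " FAILED: ",
                                   conditionMessage(e)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    pipeline_log(run_dir, paste0("stage ", name, " done"))
    out
  }

  cells <- stage("filter", filter_in_polygon(cells, regions))
  res$exclusion <- stage("stereology", bootstrap_exclusion(
    cells, thickness_um = config$thickness_um,
    n_iterations = config$stereology$iters, seed = config$stereology$seed
  ))
  grid <- stage("depth_density", {
    g <- build_depth_grid(regions, config$grid$n_cols, config$grid$n_rows)
    bin_densities(g, cells, thickness_um = config$thickness_um,
                  exclusion = res$exclusion)
  })
  res$grid <- grid
  res$profile <- depth_profile(list(grid), n_rows = config$grid$n_rows)
  readr::write_csv(res$profile, file.path(run_dir, "profile.csv"))

  labeled <- any(cells$layer_label != "none")
  if (labeled) {
    n_img <- length(unique(cells$image_id[cells$layer_label != "none"]))
    if (n_img >= config$classifier$folds) {
      feats <- stage("features", assemble_features(cells, regions))
      res$report <- stage("train", train_evaluate(
        feats, model_kind = config$classifier$model,
        folds = config$classifier$folds, seed = config$classifier$seed
      ))
    }
  } else {
    pipeline_log(run_dir, "no layer labels: skipping classifier training")
  }

  res$hulls <- stage("layer_geometry", layer_density(
    cells, thickness_um = config$thickness_um,
    alpha = config$alpha$general, alpha_layer1 = config$alpha$layer1,
    exclusion = res$exclusion
  ))
  res$heights <- stage("layer_heights", layer_heights(cells, res$grid))
  jsonlite::write_json(
    list(
      hulls = tidy(res$hulls),
      heights = tibble::as_tibble(res$heights),
      total_height_um = attr(res$heights, "total_height_um"),
      total_sd_um = attr(res$heights, "total_sd_um")
    ),
    file.path(run_dir, "layers.json"), auto_unbox = TRUE, digits = NA
  )

  res$mixtures <- stage("morphometry", fit_mixtures_by_layer(
    cells, seed = config$stereology$seed
  ))
  jsonlite::write_json(res$mixtures, file.path(run_dir, "morph.json"),
                       auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(
      config = config,
      n_cells = nrow(cells),
      exclusion = glance(res$exclusion),
      layers = tidy(res$hulls),
      classifier = if (!is.null(res$report)) glance(res$report)
    ),
    file.path(run_dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  pipeline_log(run_dir, "run complete")
  invisible(res)
}
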