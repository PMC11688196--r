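# Cell-level cortical-layer classification: feature assembly with 50-um
# spatial smoothing, permutation-importance selection, random-forest and
# distance-weighted KNN models with image-grouped cross-validation, and
# macro-averaged evaluation.

.base_feature_names <- c(
  "x_um", "y_um", "dist_pia_um", "area_um2", "d_max_um", "d_min_um",
  "aspect", "perimeter_um", "circularity"
)
.smoothed_feature_names <- c(
  "dist_pia_um", "area_um2", "d_max_um", "d_min_um", "aspect", "circularity"
)

# Mean of each feature over all cells (self included) within radius, per
# image; implemented as a masked matrix product in row blocks.
radius_smooth <- function(x, y, feats, radius) {
  n <- length(x)
  p <- ncol(feats)
  out <- matrix(NA_real_, n, p)
  r2 <- radius^2
  block <- max(1L, min(n, as.integer(4e6 / n)))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    w <- (d2 <= r2) * 1
    cnt <- rowSums(w)
    out[idx, ] <- (w %*% feats) / cnt
  }
  out
}

#' Assemble the classification feature table
#'
#' Builds per-cell base features (position, distance to pia, soma area and
#' diameters, aspect ratio, an elliptical perimeter estimate and
#' circularity) plus their spatially smoothed counterparts: the unweighted
#' mean over all cells, self included, within `radius_um` of the cell in the
#' same image. A spatially constant feature is therefore unchanged by
#' smoothing, and an isolated cell keeps its own value.
#'
#' @param cells A cell tibble.
#' @param regions Optional [region_set()]; used to compute `dist_pia_um`
#'   from the pia polyline when the column is absent.
#' @param radius_um Smoothing radius (um), default 50.
#' @return A tibble with `image_id`, `layer_label` and numeric feature
#'   columns (smoothed features prefixed `smoothed_`); the feature names are
#'   stored in the `feature_names` attribute.
#' @export
assemble_features <- function(cells, regions = NULL, radius_um = 50) {
  has_dist <- !is.null(cells[["dist_pia_um"]]) && !all(is.na(cells$dist_pia_um))
  if (!has_dist && !is.null(regions) && !is.null(regions$outside_pia)) {
    cells$dist_pia_um <- dist_to_polyline(cells$x_um, cells$y_um,
                                          regions$outside_pia)
  }
  cells <- validate_cell_table(cells)
  a <- cells$d_max_um / 2
  b <- cells$d_min_um / 2
  h <- ((a - b) / (a + b))^2
  h[!is.finite(h)] <- 0
  perimeter <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  ft <- tibble::tibble(
    image_id = cells$image_id,
    layer_label = if (is.null(cells$layer_label)) "none" else cells$layer_label,
    x_um = cells$x_um, y_um = cells$y_um,
    dist_pia_um = cells$dist_pia_um,
    area_um2 = cells$area_um2,
    d_max_um = cells$d_max_um, d_min_um = cells$d_min_um,
    aspect = ifelse(cells$d_max_um > 0, cells$d_min_um / cells$d_max_um, 1),
    perimeter_um = perimeter,
    circularity = ifelse(perimeter > 0,
                         pmin(1, 4 * pi * cells$area_um2 / perimeter^2), 1)
  )
  for (img in unique(ft$image_id)) {
    sel <- which(ft$image_id == img)
    sm <- radius_smooth(ft$x_um[sel], ft$y_um[sel],
                        as.matrix(ft[sel, .smoothed_feature_names]), radius_um)
    for (j in seq_along(.smoothed_feature_names)) {
      col <- paste0("smoothed_", .smoothed_feature_names[j])
      if (is.null(ft[[col]])) ft[[col]] <- NA_real_
      ft[[col]][sel] <- sm[, j]
    }
  }
  attr(ft, "feature_names") <-
    c(.base_feature_names, paste0("smoothed_", .smoothed_feature_names))
  ft
}

feature_names_of <- function(features) {
  fn <- attr(features, "feature_names")
  if (is.null(fn)) {
    fn <- setdiff(names(features), c("image_id", "layer_label", "cell_id"))
  }
  fn
}

default_hyper <- function(model_kind) {
  switch(model_kind,
    rf = list(num_trees = 500),
    knn = list(k = 15),
    stop("unknown model kind: ", model_kind, call. = FALSE)
  )
}

fit_model <- function(X, y, model_kind, hyper, seed = 1L) {
  y <- factor(y)
  if (model_kind == "rf") {
    fit <- ranger::ranger(
      x = X, y = y, num.trees = hyper$num_trees, probability = TRUE,
      seed = seed, num.threads = 1
    )
    list(kind = "rf", fit = fit, classes = levels(y))
  } else {
    mu <- colMeans(X)
    sg <- apply(X, 2, sd)
    sg[sg == 0] <- 1
    list(kind = "knn", train = scale(X, mu, sg), y = y, mu = mu, sg = sg,
         k = hyper$k, classes = levels(y))
  }
}

predict_model <- function(model, X) {
  if (nrow(X) == 0) {
    return(list(label = character(0),
                prob = matrix(numeric(0), 0, length(model$classes),
                              dimnames = list(NULL, model$classes))))
  }
  if (model$kind == "rf") {
    prob <- stats::predict(model$fit, data = X, num.threads = 1)$predictions
    lab <- model$classes[max.col(prob, ties.method = "first")]
    return(list(label = lab, prob = prob))
  }
  Xs <- scale(as.matrix(X), model$mu, model$sg)
  tr <- model$train
  k <- min(model$k, nrow(tr))
  n <- nrow(Xs)
  prob <- matrix(0, n, length(model$classes),
                 dimnames = list(NULL, model$classes))
  block <- max(1L, min(n, as.integer(4e6 / nrow(tr))))
  tr_sq <- rowSums(tr^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(Xs[idx, , drop = FALSE]^2), tr_sq, "+") -
      2 * Xs[idx, , drop = FALSE] %*% t(tr)
    d2[d2 < 0] <- 0
    for (r in seq_along(idx)) {
      v <- d2[r, ]
      cut <- sort(v, partial = k)[k]
      nb <- which(v <= cut)
      if (length(nb) > k) nb <- nb[order(v[nb])][seq_len(k)]
      w <- 1 / (sqrt(v[nb]) + 1e-6)
      votes <- tapply(w, model$y[nb], sum)
      votes[is.na(votes)] <- 0
      prob[idx[r], names(votes)] <- votes / sum(votes)
    }
  }
  lab <- model$classes[max.col(prob, ties.method = "first")]
  list(label = lab, prob = prob)
}

#' Permutation-importance feature selection
#'
#' A model is fitted on a (image-grouped) training split; the importance of
#' each feature is the mean drop in held-out accuracy over `n_repeats`
#' independent permutations of that feature's column. Only features with a
#' positive mean importance are retained.
#'
#' @param features A feature tibble from [assemble_features()], labeled rows
#'   (`layer_label != "none"`) are used.
#' @param model_kind `"rf"` or `"knn"`.
#' @param n_repeats Permutations per feature (default 5).
#' @param seed Integer seed.
#' @param holdout_frac Fraction of images held out for importance
#'   measurement (default 0.25, at least one image).
#' @param hyper Optional hyperparameter overrides.
#' @return A tibble: `feature`, `importance`, `sd`, `retained`, sorted by
#'   descending importance. The baseline held-out accuracy is stored in the
#'   `baseline_accuracy` attribute.
#' @export
select_features <- function(features, model_kind = c("rf", "knn"),
                            n_repeats = 5, seed = 1L, holdout_frac = 0.25,
                            hyper = NULL) {
  model_kind <- match.arg(model_kind)
  hyper <- utils::modifyList(default_hyper(model_kind), hyper %||% list())
  lab <- features$layer_label
  features <- features[lab != "none", , drop = FALSE]
  if (length(unique(features$layer_label)) < 2) {
    stop("need at least two label classes", call. = FALSE)
  }
  fn <- feature_names_of(features)
  set.seed(seed)
  imgs <- sample(unique(features$image_id))
  n_hold <- max(1L, round(holdout_frac * length(imgs)))
  if (n_hold >= length(imgs)) stop("need at least 2 labeled images", call. = FALSE)
  hold <- features$image_id %in% imgs[seq_len(n_hold)]
  model <- fit_model(as.matrix(features[!hold, fn]),
                     features$layer_label[!hold], model_kind, hyper, seed)
  X_hold <- as.matrix(features[hold, fn])
  y_hold <- features$layer_label[hold]
  baseline <- mean(predict_model(model, X_hold)$label == y_hold)
  imp <- matrix(NA_real_, length(fn), n_repeats, dimnames = list(fn, NULL))
  for (f in fn) {
    for (r in seq_len(n_repeats)) {
      Xp <- X_hold
      Xp[, f] <- sample(Xp[, f])
      imp[f, r] <- baseline - mean(predict_model(model, Xp)$label == y_hold)
    }
  }
  out <- tibble::tibble(
    feature = fn,
    importance = rowMeans(imp),
    sd = apply(imp, 1, sd)
  ) |>
    dplyr::mutate(retained = .data$importance > 0) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  attr(out, "baseline_accuracy") <- baseline
  out
}

#' Per-class and macro classification metrics
#'
#' Computes the pooled confusion matrix (rows = truth, columns =
#' prediction) and, per class, precision, recall, F1 and one-vs-rest
#' accuracy; macro metrics are the unweighted means over classes with
#' defined values, so classes with different supports contribute equally.
#'
#' @param truth,pred Character/factor vectors of true and predicted labels.
#' @param classes Optional class ordering (defaults to anatomical layer
#'   order of the classes present).
#' @return A list: `confusion` (K x K integer matrix), `per_class` tibble,
#'   `macro` one-row tibble (includes `micro_accuracy`, the trace over the
#'   total).
#' @export
classification_metrics <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) {
    present <- union(unique(as.character(truth)), unique(as.character(pred)))
    classes <- intersect(c(.layer_levels, sort(setdiff(present, .layer_levels))),
                         present)
  }
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  confusion <- table(truth = truth, pred = pred)
  total <- sum(confusion)
  per_class <- purrr::map_dfr(classes, function(k) {
    tp <- confusion[k, k]
    fp <- sum(confusion[, k]) - tp
    fn <- sum(confusion[k, ]) - tp
    tn <- total - tp - fp - fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    tibble::tibble(
      class = k, support = tp + fn,
      precision = precision, recall = recall, f1 = f1,
      accuracy = (tp + tn) / total
    )
  })
  macro <- tibble::tibble(
    macro_accuracy = mean(per_class$accuracy, na.rm = TRUE),
    macro_precision = mean(per_class$precision, na.rm = TRUE),
    macro_recall = mean(per_class$recall, na.rm = TRUE),
    macro_f1 = mean(per_class$f1, na.rm = TRUE),
    micro_accuracy = sum(diag(confusion)) / total
  )
  list(confusion = unclass(confusion), per_class = per_class, macro = macro)
}

#' Cross-validated training and evaluation of a layer classifier
#'
#' Folds are split by image so that all cells of an image stay together
#' (cells within an image are spatially dependent; splitting them would leak
#' position information across folds). Per fold the model is fitted on the
#' remaining images and predicts the held-out cells; the confusion matrix is
#' pooled over folds and macro-averaged metrics computed.
#'
#' @param features A feature tibble from [assemble_features()] (labeled rows
#'   used).
#' @param model_kind `"rf"` (random forest) or `"knn"` (distance-weighted
#'   k-nearest-neighbour).
#' @param folds Number of cross-validation folds (default 10); requires at
#'   least that many labeled images.
#' @param seed Integer seed (fold shuffling and model fitting).
#' @param feature_names Optional subset of feature columns (e.g. the
#'   retained set from [select_features()]).
#' @param hyper Optional hyperparameter overrides (`num_trees` for rf, `k`
#'   for knn).
#' @return An object of class `layer_classifier_report`.
#' @export
train_evaluate <- function(features, model_kind = c("rf", "knn"), folds = 10,
                           seed = 1L, feature_names = NULL, hyper = NULL) {
  model_kind <- match.arg(model_kind)
  hyper <- utils::modifyList(default_hyper(model_kind), hyper %||% list())
  features <- features[features$layer_label != "none", , drop = FALSE]
  fn <- feature_names %||% feature_names_of(features)
  imgs <- unique(features$image_id)
  if (length(imgs) < folds) {
    stop("need at least ", folds, " labeled images for ", folds,
         "-fold image-grouped cross-validation", call. = FALSE)
  }
  set.seed(seed)
  imgs <- sample(imgs)
  fold_of <- setNames(rep_len(seq_len(folds), length(imgs)), imgs)
  classes <- intersect(.layer_levels, unique(features$layer_label))
  truth <- character(0); pred <- character(0)
  for (f in seq_len(folds)) {
    hold <- fold_of[features$image_id] == f
    y_train <- features$layer_label[!hold]
    absent <- setdiff(classes, unique(y_train))
    if (length(absent)) {
      warning("class(es) ", paste(absent, collapse = ", "),
              " absent from training data of fold ", f, call. = FALSE)
    }
    model <- fit_model(as.matrix(features[!hold, fn]), y_train, model_kind,
                       hyper, seed + f)
    p <- predict_model(model, as.matrix(features[hold, fn]))
    truth <- c(truth, features$layer_label[hold])
    pred <- c(pred, p$label)
  }
  metrics <- classification_metrics(truth, pred, classes)
  structure(
    c(metrics,
      list(model_kind = model_kind, cv_folds = folds, seed = seed,
           hyper = hyper, feature_names = fn,
           paradigm = if ("LII/III" %in% classes) "merged" else "separated")),
    class = "layer_classifier_report"
  )
}

#' @export
print.layer_classifier_report <- function(x, ...) {
  cat("<layer_classifier_report> ", toupper(x$model_kind), ", ", x$cv_folds,
      "-fold image-grouped CV (", x$paradigm, " LII/LIII)\n", sep = "")
  cat(sprintf("  macro accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f\n",
              x$macro$macro_accuracy, x$macro$macro_precision,
              x$macro$macro_recall, x$macro$macro_f1))
  invisible(x)
}

#' @rdname train_evaluate
#' @param x A `layer_classifier_report`.
#' @param ... Unused.
#' @export
tidy.layer_classifier_report <- function(x, ...) x$per_class

#' @rdname train_evaluate
#' @export
glance.layer_classifier_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model_kind = x$model_kind, cv_folds = x$cv_folds,
                   paradigm = x$paradigm),
    x$macro
  )
}

#' @rdname train_evaluate
#' @param object A `layer_classifier_report`.
#' @export
autoplot.layer_classifier_report <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("truth", "pred", "n")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted layer", y = "annotated layer") +
    ggplot2::theme_minimal()
}

#' Fit a final layer classifier on all labeled cells
#'
#' @inheritParams train_evaluate
#' @return An object of class `layer_classifier` usable with [predict()].
#' @export
fit_layer_classifier <- function(features, model_kind = c("rf", "knn"),
                                 seed = 1L, feature_names = NULL, hyper = NULL) {
  model_kind <- match.arg(model_kind)
  hyper <- utils::modifyList(default_hyper(model_kind), hyper %||% list())
  features <- features[features$layer_label != "none", , drop = FALSE]
  fn <- feature_names %||% feature_names_of(features)
  model <- fit_model(as.matrix(features[, fn]), features$layer_label,
                     model_kind, hyper, seed)
  structure(list(model = model, feature_names = fn, model_kind = model_kind,
                 hyper = hyper),
            class = "layer_classifier")
}

#' Predict layer labels for new cells
#'
#' @param object A fitted `layer_classifier`.
#' @param newdata A feature tibble with the model's feature columns.
#' @param ... Unused.
#' @return Character vector of predicted layer labels, with the class
#'   probability matrix attached as the `prob` attribute.
#' @export
predict.layer_classifier <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    stop("feature mismatch: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- predict_model(object$model, as.matrix(newdata[, object$feature_names]))
  structure(p$label, prob = p$prob)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
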