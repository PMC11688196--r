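# Shared fixture: 12 small three-layer columns (image-grouped CV needs >= 10
# labeled images). Sizes kept modest so the whole file runs in seconds.
cls_cols <- lapply(1:12, function(i) {
  simulate_column(small_spec(seed = 400 + i, width = 250),
                  image_id = sprintf("img_%02d", i))
})
cls_cells <- dplyr::bind_rows(lapply(cls_cols, `[[`, "cells"))
cls_feats <- assemble_features(cls_cells)

test_that("spatial smoothing matches hand values and the radius-scan oracle", {
  # constant feature is unchanged
  cells <- toy_cells(runif(50, 0, 40), runif(50, 0, 40), d = 8)
  ft <- assemble_features(cells, radius_um = 50)
  expect_equal(ft$smoothed_d_max_um, ft$d_max_um)

  # two cells 10 um apart with values 0 and 10 smooth to 5
  two <- toy_cells(c(0, 10), c(0, 0))
  two$d_max_um <- c(0, 10); two$d_min_um <- c(0, 10)
  two$area_um2 <- c(1, 1)
  ft2 <- assemble_features(two, radius_um = 50)
  expect_equal(ft2$smoothed_d_max_um, c(5, 5))

  # random pattern vs brute-force radius scan
  set.seed(71)
  n <- 150
  cells_r <- toy_cells(runif(n, 0, 200), runif(n, 0, 200))
  cells_r$d_max_um <- runif(n, 5, 15)
  cells_r$d_min_um <- cells_r$d_max_um
  ftr <- assemble_features(cells_r, radius_um = 50)
  oracle <- sapply(seq_len(n), function(i) {
    d2 <- (cells_r$x_um - cells_r$x_um[i])^2 + (cells_r$y_um - cells_r$y_um[i])^2
    mean(cells_r$d_max_um[d2 <= 50^2])
  })
  expect_equal(ftr$smoothed_d_max_um, oracle, tolerance = 1e-12)

  # an isolated cell keeps its own value
  iso <- toy_cells(c(0, 1000), c(0, 0))
  iso$d_max_um <- c(3, 9); iso$d_min_um <- c(3, 9)
  fti <- assemble_features(iso, radius_um = 50)
  expect_equal(fti$smoothed_d_max_um, c(3, 9))
})

test_that("permutation importance retains informative features, drops noise", {
  set.seed(5)
  n <- 1200
  f_signal <- runif(n, 0, 100)
  f_noise <- rnorm(n)
  feats <- tibble::tibble(
    image_id = rep(sprintf("im%d", 1:8), length.out = n),
    layer_label = ifelse(f_signal < 50, "LI", "LIV"),
    signal = f_signal, noise = f_noise
  )
  attr(feats, "feature_names") <- c("signal", "noise")
  sel <- select_features(feats, model_kind = "knn", n_repeats = 5, seed = 2)
  imp <- setNames(sel$importance, sel$feature)
  expect_gt(imp["signal"], 0.2)
  expect_lt(abs(imp["noise"]), 0.05)
  expect_true(sel$retained[sel$feature == "signal"])
  expect_error(
    select_features(dplyr::mutate(feats, layer_label = "LI"), "knn"),
    "two label classes"
  )
})

test_that("separable synthetic layers are classified nearly perfectly", {
  rep_rf <- train_evaluate(cls_feats, "rf", folds = 10, seed = 3,
                           hyper = list(num_trees = 60))
  expect_gte(rep_rf$macro$macro_accuracy, 0.99)
  expect_gte(rep_rf$macro$micro_accuracy, 0.97)
  # errors, if any, confined to adjacent layers
  cm <- rep_rf$confusion
  expect_equal(cm["LI", "LVIb"] + cm["LVIb", "LI"], 0)
  # confusion row sums equal class supports
  expect_equal(as.numeric(rowSums(cm)),
               as.numeric(table(factor(cls_feats$layer_label, rownames(cm)))))
})

test_that("shuffled labels drop performance to chance", {
  set.seed(8)
  shuf <- cls_feats
  shuf$layer_label <- sample(shuf$layer_label)
  rep_s <- train_evaluate(shuf, "knn", folds = 10, seed = 8)
  k <- length(unique(shuf$layer_label))
  expect_lt(rep_s$macro$macro_recall, 2 / k)
  expect_gt(rep_s$macro$macro_recall, 0.5 / k)
})

test_that("macro metrics treat classes equally (support invariance)", {
  set.seed(9)
  truth <- sample(c("LI", "LIV", "LVIb"), 600, TRUE, prob = c(0.6, 0.3, 0.1))
  pred <- ifelse(runif(600) < 0.8, truth,
                 sample(c("LI", "LIV", "LVIb"), 600, TRUE))
  m1 <- classification_metrics(truth, pred)
  dup <- c(seq_along(truth), which(truth == "LVIb"))
  m2 <- classification_metrics(truth[dup], pred[dup])
  # per-class recall and macro recall are exactly support-independent
  expect_equal(m2$per_class$recall, m1$per_class$recall, tolerance = 1e-12)
  expect_equal(m2$macro$macro_recall, m1$macro$macro_recall, tolerance = 1e-12)
  # micro accuracy equals trace over total
  expect_equal(m1$macro$micro_accuracy,
               sum(diag(m1$confusion)) / sum(m1$confusion))
})

test_that("prediction is row-order invariant, schema-checked, empty-safe", {
  model <- fit_layer_classifier(cls_feats, "knn", seed = 4)
  idx <- sample(nrow(cls_feats))
  p1 <- predict(model, cls_feats)
  p2 <- predict(model, cls_feats[idx, ])
  expect_equal(as.character(p2), as.character(p1)[idx])
  # trained-on-self reproduces the labels on separable data
  expect_gt(mean(p1 == cls_feats$layer_label), 0.995)
  expect_length(predict(model, cls_feats[0, ]), 0)
  expect_error(predict(model, cls_feats[, 1:3]), "feature mismatch")
  expect_equal(dim(attr(p1, "prob")), c(nrow(cls_feats), 3))
})

test_that("merged LII/III paradigm is supported and reported", {
  merged <- cls_cells
  merged$layer_label[merged$layer_label == "LIV"] <- "LII/III"
  fm <- assemble_features(merged)
  rep_m <- train_evaluate(fm, "knn", folds = 10, seed = 5)
  expect_equal(rep_m$paradigm, "merged")
  expect_true("LII/III" %in% rownames(rep_m$confusion))
  g <- glance(rep_m)
  expect_equal(g$model_kind, "knn")
  expect_true(all(unlist(g[, c("macro_accuracy", "macro_precision",
                               "macro_recall", "macro_f1")]) <= 1))
})

test_that("grouped CV refuses too few images and warns on absent classes", {
  few <- cls_feats[cls_feats$image_id %in% sprintf("img_%02d", 1:5), ]
  expect_error(train_evaluate(few, "knn", folds = 10), "at least 10")
  # a class confined to one image disappears from that fold's training set
  one_img <- cls_cells
  one_img$layer_label[one_img$layer_label == "LVIb"] <- "LI"
  one_img$layer_label[one_img$image_id == "img_01" &
                        one_img$layer_label == "LI"] <- "LVIb"
  f1 <- assemble_features(one_img)
  expect_warning(train_evaluate(f1, "knn", folds = 10, seed = 1),
                 "absent from training")
})
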