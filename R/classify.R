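#' DAB-positivity rule
#'
#' A nucleus is called Ki-67 positive when its mean nucleus DAB optical
#' density reaches the threshold. The default threshold of 0.15 nucleus
#' DAB OD mean was calibrated against a pathologist's visual perception of
#' positive staining; the comparison is inclusive (`>=`).
#'
#' @param threshold Positive threshold on `nucleus_dab_od_mean`
#'   (default 0.15).
#' @param feature Feature column the rule reads.
#' @return A `positivity_rule` object.
#' @export
positivity_rule <- function(threshold = 0.15,
                            feature = "nucleus_dab_od_mean") {
  stopifnot(threshold > 0)
  structure(list(threshold = threshold, feature = feature),
            class = "positivity_rule")
}

#' Call Ki-67 positivity on detections
#'
#' Applies the positivity rule to every detection regardless of class
#' (tumour-cell filtering happens downstream in scoring).
#'
#' @param detections Detection tibble carrying the rule's feature column.
#' @param rule A [positivity_rule()].
#' @return The detections with a logical `ki67_positive` column.
#' @export
call_positivity <- function(detections, rule = positivity_rule()) {
  stopifnot(inherits(rule, "positivity_rule"))
  if (!rule$feature %in% names(detections))
    stop("detections lack the positivity feature `", rule$feature, "`")
  detections$ki67_positive <- detections[[rule$feature]] >= rule$threshold
  detections
}

# Columns never used as classifier features.
non_feature_cols <- function() {
  c("id", "x_um", "y_um", "class_label", "truth_id", "truth_class",
    "truth_positive", "ki67_positive", "valid", "increment_rank",
    "case_id")
}

#' Feature columns available for classification
#' @param detections A detection tibble.
#' @return Character vector of numeric feature column names.
#' @export
feature_columns <- function(detections) {
  num <- names(detections)[vapply(detections, is.numeric, logical(1))]
  setdiff(num, non_feature_cols())
}

#' Train the two-class tumour / non-tumour nucleus classifier
#'
#' Trains an ensemble of randomized decision trees (random forest) to
#' separate epithelial tumour-cell nuclei from all other nuclei, using an
#' equally spaced train/test split: with a training fraction of 0.67,
#' every third object (by row index, with a seeded offset) is held out,
#' and the held-out accuracy is stored in the model metadata.
#'
#' @param labeled Detection tibble with a `class_label` column holding
#'   exactly two classes (canonically `"tumour"` and `"other"`).
#' @param features Feature columns; default [feature_columns()].
#' @param split_fraction Training fraction (default 0.67).
#' @param seed Integer seed (controls the split offset and the forest).
#' @param num_trees Number of trees (default 200).
#' @return A `ki67_classifier` object.
#' @export
train_classifier <- function(labeled, features = NULL,
                             split_fraction = 0.67, seed = 1L,
                             num_trees = 200) {
  if (!"class_label" %in% names(labeled))
    stop("`labeled` must carry a `class_label` column")
  labeled <- labeled[!is.na(labeled$class_label), , drop = FALSE]
  classes <- sort(unique(labeled$class_label))
  if (length(classes) < 2)
    stop("training data holds a single class (", classes,
         "); two classes are required")
  if (is.null(features)) features <- feature_columns(labeled)
  if (length(features) == 0) stop("no feature columns available")
  keep <- stats::complete.cases(labeled[features])
  labeled <- labeled[keep, , drop = FALSE]
  n <- nrow(labeled)
  if (n < 100) stop("need at least 100 labeled objects, got ", n)

  k <- max(2L, round(1 / (1 - split_fraction)))
  offset <- with_local_seed(seed, sample.int(k, 1))
  test_idx <- seq_len(n)[((seq_len(n) - offset) %% k) == 0]
  train_idx <- setdiff(seq_len(n), test_idx)

  df <- labeled[features]
  df$.class <- factor(labeled$class_label, levels = classes)
  fit <- ranger::ranger(
    dependent.variable.name = ".class",
    data = df[train_idx, , drop = FALSE],
    num.trees = num_trees, seed = seed,
    importance = "impurity"
  )
  pred <- stats::predict(fit, data = df[test_idx, , drop = FALSE])$predictions
  acc <- mean(pred == df$.class[test_idx])

  structure(
    list(fit = fit, features = features, classes = classes,
         training = labeled[c(features, "class_label")],
         metadata = list(n_objects = n, split_fraction = split_fraction,
                         seed = seed, num_trees = num_trees,
                         holdout_accuracy = acc,
                         n_train = length(train_idx),
                         n_test = length(test_idx))),
    class = "ki67_classifier"
  )
}

#' @export
print.ki67_classifier <- function(x, ...) {
  m <- x$metadata
  cat("Two-class nucleus classifier (", m$num_trees, " randomized trees)\n",
      "classes: ", paste(x$classes, collapse = " vs "), "\n",
      "objects: ", m$n_objects, " (", m$n_train, " train / ", m$n_test,
      " test, equally spaced)\n",
      "held-out accuracy: ", sprintf("%.1f%%", 100 * m$holdout_accuracy),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a nucleus classifier: variable importance
#' @param x A `ki67_classifier`.
#' @param ... Unused.
#' @return A tibble with `feature` and `importance`, sorted decreasing.
#' @export
tidy.ki67_classifier <- function(x, ...) {
  imp <- ranger::importance(x$fit)
  tibble::tibble(feature = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Glance at a nucleus classifier
#' @param x A `ki67_classifier`.
#' @param ... Unused.
#' @return One-row tibble with training metadata and held-out accuracy.
#' @export
glance.ki67_classifier <- function(x, ...) {
  m <- x$metadata
  tibble::tibble(n_objects = m$n_objects, n_train = m$n_train,
                 n_test = m$n_test, split_fraction = m$split_fraction,
                 num_trees = m$num_trees,
                 holdout_accuracy = m$holdout_accuracy)
}

#' Classify detections as tumour or other nuclei
#'
#' @param detections Detection tibble carrying all of the model's features.
#' @param model A `ki67_classifier` from [train_classifier()].
#' @return The detections with a `class_label` column.
#' @export
classify_nuclei <- function(detections, model) {
  stopifnot(inherits(model, "ki67_classifier"))
  if (nrow(detections) == 0) {
    detections$class_label <- character()
    return(detections)
  }
  miss <- setdiff(model$features, names(detections))
  if (length(miss))
    stop("detections lack model feature(s): ", paste(miss, collapse = ", "))
  df <- detections[model$features]
  df[is.na(df)] <- 0
  pred <- stats::predict(model$fit, data = df)$predictions
  detections$class_label <- as.character(pred)
  detections
}

#' Save / load a trained nucleus classifier
#'
#' Serializes the model (ensemble, feature list, stored training objects
#' and metadata) to a single RDS archive.
#'
#' @param model A `ki67_classifier`.
#' @param path File path (conventionally `.rds`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "ki67_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ki67_classifier"))
    stop("file does not contain a nucleus classifier: ", path)
  model
}

#' Add annotations to a trained classifier and retrain
#'
#' Mirrors incremental annotation: the new labeled objects are pooled with
#' the stored training objects and the classifier is retrained with the
#' same split rule and seed.
#'
#' @param model A `ki67_classifier`.
#' @param new_labeled Additional labeled detections (may be empty).
#' @param seed Seed for retraining; defaults to the stored seed.
#' @return A retrained `ki67_classifier`.
#' @export
augment_training <- function(model, new_labeled, seed = NULL) {
  stopifnot(inherits(model, "ki67_classifier"))
  seed <- seed %||% model$metadata$seed
  pooled <- model$training
  if (!is.null(new_labeled) && nrow(new_labeled) > 0) {
    add <- new_labeled[intersect(names(pooled), names(new_labeled))]
    miss <- setdiff(names(pooled), names(add))
    if (length(miss))
      stop("new labeled objects lack column(s): ",
           paste(miss, collapse = ", "))
    pooled <- dplyr::bind_rows(pooled, add)
  }
  train_classifier(pooled, features = model$features,
                   split_fraction = model$metadata$split_fraction,
                   seed = seed, num_trees = model$metadata$num_trees)
}
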