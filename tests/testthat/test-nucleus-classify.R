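test_that("a separable feature yields perfect held-out accuracy", {
  lab <- fx_separable(n = 300, gap = 50)
  m <- train_classifier(lab, seed = 1)
  expect_equal(m$metadata$holdout_accuracy, 1.0)
  expect_s3_class(glance(m), "tbl_df")
  expect_true(all(tidy(m)$importance >= 0))
})

test_that("permuted labels give chance-level held-out accuracy", {
  lab <- fx_separable(n = 600, gap = 3, seed = 2)
  lab$class_label <- withr::with_seed(99, sample(lab$class_label))
  m <- train_classifier(lab, seed = 1)
  n_test <- m$metadata$n_test
  se <- sqrt(0.25 / n_test)
  expect_lt(abs(m$metadata$holdout_accuracy - 0.5), 3 * se)
})

test_that("training validates its inputs", {
  lab <- fx_separable(n = 300)
  one <- lab[lab$class_label == "tumour", ]
  expect_error(train_classifier(one), "single class")
  both <- lab[c(1:25, 151:175), ]   # two classes, too few objects
  expect_error(train_classifier(both), "at least 100")
})

test_that("the equally spaced split is disjoint and exhaustive", {
  lab <- fx_separable(n = 300)
  m <- train_classifier(lab, split_fraction = 0.67, seed = 3)
  expect_equal(m$metadata$n_train + m$metadata$n_test, m$metadata$n_objects)
  expect_equal(m$metadata$n_test, floor(300 / 3), tolerance = 0.02)
})

test_that("classification is deterministic and order-invariant", {
  lab <- fx_separable(n = 400, gap = 4)
  m <- train_classifier(lab, seed = 5)
  out1 <- classify_nuclei(lab, m)
  out2 <- classify_nuclei(lab, m)
  expect_identical(out1$class_label, out2$class_label)
  perm <- withr::with_seed(7, sample(nrow(lab)))
  out3 <- classify_nuclei(lab[perm, ], m)
  expect_identical(out3$class_label[order(perm)], out1$class_label)
})

test_that("classification handles empty input and missing features", {
  lab <- fx_separable(n = 300)
  m <- train_classifier(lab, seed = 1)
  expect_equal(nrow(classify_nuclei(lab[0, ], m)), 0)
  bad <- lab; bad$f1 <- NULL
  expect_error(classify_nuclei(bad, m), "f1")
})

test_that("applying a model to its own scene meets the held-out floor", {
  lab <- fx_separable(n = 1000, gap = 3, seed = 4)
  m <- train_classifier(lab, seed = 1)
  pred <- classify_nuclei(lab, m)
  agree <- mean(pred$class_label == lab$class_label)
  expect_gte(agree, m$metadata$holdout_accuracy - 0.05)
})

test_that("positivity calling applies the inclusive 0.15 threshold", {
  det <- tibble::tibble(id = 1:4,
                        nucleus_dab_od_mean = c(0.15, 0.1499, 0, 0.9))
  out <- call_positivity(det, positivity_rule())
  expect_identical(out$ki67_positive, c(TRUE, FALSE, FALSE, TRUE))

  # monotone in the feature
  v <- sort(runif(100, 0, 0.4))
  flags <- call_positivity(tibble::tibble(nucleus_dab_od_mean = v),
                           positivity_rule())$ki67_positive
  expect_true(all(diff(as.integer(flags)) >= 0))

  expect_error(call_positivity(tibble::tibble(x = 1), positivity_rule()),
               "nucleus_dab_od_mean")
})

test_that("positivity on a bimodal rendered scene matches ground truth", {
  s <- fx_scene()
  md <- match_truth(call_positivity(s$detections), s$truth)
  ok <- !is.na(md$truth_id)
  expect_true(all(md$ki67_positive[ok] == md$truth_positive[ok]))
})

test_that("a saved classifier predicts identically after reloading", {
  lab <- fx_separable(n = 300, gap = 4)
  m <- train_classifier(lab, seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  expect_identical(classify_nuclei(lab, m2)$class_label,
                   classify_nuclei(lab, m)$class_label)
  expect_equal(glance(m2), glance(m))

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_classifier(bad), "classifier")
})

test_that("augmenting with no new data reproduces the model", {
  lab <- fx_separable(n = 400, gap = 3)
  m <- train_classifier(lab, seed = 6)
  m2 <- augment_training(m, lab[0, ])
  expect_equal(m2$metadata$holdout_accuracy, m$metadata$holdout_accuracy)
  expect_equal(m2$metadata$n_objects, m$metadata$n_objects)
})

test_that("augmentation with shifted examples improves on that distribution", {
  base <- fx_separable(n = 600, gap = 3, seed = 10)
  shifted <- fx_separable(n = 500, gap = 3, seed = 11)
  shifted$f1 <- shifted$f1 + 8   # same classes, displaced feature scale
  m <- train_classifier(base, seed = 1)
  acc_before <- mean(classify_nuclei(shifted, m)$class_label ==
                       shifted$class_label)
  m2 <- augment_training(m, shifted)
  expect_equal(m2$metadata$n_objects,
               m$metadata$n_objects + nrow(shifted))
  acc_after <- mean(classify_nuclei(shifted, m2)$class_label ==
                      shifted$class_label)
  expect_gt(acc_after, acc_before)
})

test_that("detections classified on a rendered scene recover truth classes", {
  s <- fx_scene()
  md <- match_truth(s$detections, s$truth)
  labeled <- md[!is.na(md$truth_class), ]
  labeled$class_label <- ifelse(labeled$truth_class == "tumour",
                                "tumour", "other")
  m <- train_classifier(labeled, seed = 2)
  expect_gte(m$metadata$holdout_accuracy, 0.8)
  pred <- classify_nuclei(labeled, m)
  expect_gte(mean(pred$class_label == labeled$class_label),
             m$metadata$holdout_accuracy - 0.05)
})
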