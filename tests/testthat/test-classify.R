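test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c("a", "b"), c("a", "b")), 1)
  # constant majority prediction over two classes scores 0.5
  expect_equal(balanced_accuracy(c("a", "a", "a", "b"), rep("a", 4)), 0.5)
  expect_equal(balanced_accuracy(c("A", "A", "B", "B"),
                                 c("A", "B", "B", "B")), 0.75)
  expect_error(balanced_accuracy(c("a"), c("a", "b")), "length")
})

test_that("class weights are inverse-frequency with mean 1", {
  w <- class_weights(c("a", "a", "b", "b"))
  expect_equal(unname(w), c(1, 1))
  w2 <- class_weights(c("A", "A", "A", "B"))
  expect_equal(unname(w2[["B"]] / w2[["A"]]), 3)
  expect_equal(mean(w2), 1)
  expect_equal(unname(class_weights(rep("x", 5))), 1)
})

test_that("random stratified partitions balance folds and classes", {
  df <- fx_planted(n = 100L)
  part <- make_partition(df, "random_stratified", k = 5, seed = 2)
  expect_equal(sort(unique(part$fold)), 1:5)
  expect_equal(unname(tabulate(part$fold, 5)), rep(20L, 5))
  # union of folds is everything, pairwise disjoint by construction
  expect_equal(length(part$fold), 100L)
  # stratification: each fold has both classes in near-equal counts
  for (f in 1:5) {
    tab <- table(df$label[part$fold == f])
    expect_true(max(tab) - min(tab) <= 1)
  }
})

test_that("grouped partitions never split an image across folds", {
  tab <- fx_table150()
  m <- merge_labels(tab$features, tab$labels)
  for (seed in c(1, 7, 42)) {
    part <- make_partition(m$labeled, "image_grouped_stratified", k = 5,
                           seed = seed)
    spread <- tapply(part$fold, m$labeled$image_id,
                     function(f) length(unique(f)))
    expect_true(all(spread == 1L))
  }
  # grouped mode needs at least k distinct images
  small <- m$labeled[m$labeled$image_id %in% unique(m$labeled$image_id)[1:2], ]
  expect_error(make_partition(small, "image_grouped_stratified", k = 5),
               "distinct images")
})

test_that("automl recovers a planted single-feature signal", {
  run <- fx_planted_run()
  res <- run$res; test <- run$test
  expect_equal(nrow(res$history), 18L)
  expect_equal(res$bundle$cv_balanced_accuracy, max(res$history$mean_score))
  # held-out balanced accuracy and importance ranking
  pred <- predict_unlabeled(res$bundle, test,
                            data.frame(cell_id = character(0),
                                       label = character(0)))
  expect_gte(balanced_accuracy(test$label, pred$predicted_label), 0.95)
  imp <- importance(res$bundle)
  expect_equal(names(imp)[1], "planted")
  expect_equal(unname(imp[1]), 1.0)
  expect_true(all(imp >= 0 & imp <= 1))
  expect_true(all(diff(imp) <= 1e-12))
})

test_that("the search is reproducible under a fixed seed", {
  df <- fx_planted(n = 60L, seed = 3L)
  part <- make_partition(df, "random_stratified", k = 5, seed = 1)
  a <- automl(df, part, trials_per_family = 3L, seed = 5)
  b <- automl(df, part, trials_per_family = 3L, seed = 5)
  expect_identical(a$history$params, b$history$params)
  expect_identical(a$history$mean_score, b$history$mean_score)
  expect_identical(a$bundle$family, b$bundle$family)
  expect_identical(a$bundle$importances, b$bundle$importances)
})

test_that("median imputation constants are stored and applied", {
  df <- fx_planted(n = 80L, seed = 2L)
  df$noise_1[c(3, 10, 20)] <- NA
  part <- make_partition(df, "random_stratified", k = 5, seed = 1)
  res <- automl(df, part, trials_per_family = 2L, seed = 1)
  expect_true("noise_1" %in% names(res$bundle$impute_medians))
  expect_false(anyNA(res$bundle$impute_medians))
  # prediction works on rows with missing values
  df2 <- df; df2$noise_1 <- NA_real_
  out <- predict_unlabeled(res$bundle, df2[, -match("label", names(df2))],
                           data.frame(cell_id = character(0),
                                      label = character(0)))
  expect_equal(nrow(out), nrow(df2))
  expect_true(all(out$predicted_label %in% c("pos", "neg")))
})

test_that("predicted output keeps expert labels on annotated rows", {
  df <- fx_planted(n = 60L, seed = 4L)
  part <- make_partition(df, "random_stratified", k = 5, seed = 1)
  res <- automl(df, part, trials_per_family = 2L, seed = 1)
  features <- df[, -match("label", names(df))]
  labels <- data.frame(cell_id = df$cell_id[1:20], label = df$label[1:20],
                       stringsAsFactors = FALSE)
  out <- predict_unlabeled(res$bundle, features, labels)
  expect_equal(nrow(out), 60L)
  expect_equal(sum(out$label_source == "annotated"), 20L)
  expect_equal(out$predicted_label[1:20], df$label[1:20])
  expect_true(all(out$predicted_label %in% c("pos", "neg")))

  # schema mismatch is an explicit error
  expect_error(predict_unlabeled(res$bundle, features[, 1:5], labels),
               "lacks training columns")
})

test_that("degenerate single-class data is rejected", {
  df <- fx_planted(n = 40L)
  df$label <- "same"
  part <- list(fold = rep(1:5, 8), k = 5L)
  expect_error(automl(df, part), "two classes")
})
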