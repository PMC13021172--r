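test_that("metrics match hand-computed confusion-matrix quadruples", {
  cm <- matrix(c(5, 0, 0, 5), 2, dimnames = list(c("0", "1"), c("0", "1")))
  m <- classification_metrics(cm)
  expect_equal(as.numeric(m), c(1, 1, 1, 1))
  # TP=3 FP=1 FN=1 TN=5 for positive class "1":
  cm2 <- matrix(c(5, 1, 1, 3), 2, byrow = TRUE,
                dimnames = list(c("0", "1"), c("0", "1")))
  m2 <- classification_metrics(cm2, positive = "1")
  expect_equal(unname(m2["accuracy"]), 0.8)
  expect_equal(unname(m2["precision"]), 0.75)
  expect_equal(unname(m2["recall"]), 0.75)
  expect_equal(unname(m2["f_measure"]), 0.75)
  # constant predictor on balanced data
  cm3 <- confusion_counts(rep(c("a", "b"), 5), rep("a", 10))
  m3 <- classification_metrics(cm3, positive = "b")
  expect_equal(unname(m3["accuracy"]), 0.5)
  expect_equal(unname(m3["recall"]), 0)
  expect_equal(unname(m3["f_measure"]), 0)
  expect_true("b" %in% attr(m3, "undefined"))
})

test_that("macro averaging covers multi-class matrices", {
  cm <- matrix(c(4, 1, 0, 0, 3, 1, 0, 0, 1), 3, byrow = TRUE,
               dimnames = list(letters[1:3], letters[1:3]))
  m <- classification_metrics(cm, averaging = "macro")
  expect_equal(unname(m["accuracy"]), 8 / 10)
  prec <- mean(c(4 / 4, 3 / 4, 1 / 2))
  rec <- mean(c(4 / 5, 3 / 4, 1 / 1))
  expect_equal(unname(m["precision"]), prec)
  expect_equal(unname(m["recall"]), rec)
})

test_that("stratified folds balance classes and reproduce from the seed", {
  y <- rep(c("a", "b"), each = 50)
  f1 <- sgadt:::stratified_folds(y, 5, seed = 3)
  f2 <- sgadt:::stratified_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  expect_equal(as.integer(table(f1)), rep(20L, 5))
  for (k in 1:5)
    expect_equal(as.integer(table(y[f1 == k])), c(10L, 10L))
  expect_warning(sgadt:::stratified_folds(c("a", rep("b", 9)), 5, 1),
                 "fewer than k")
})

test_that("kfold_eval evaluates frameworks fold-hygienically", {
  sd <- gen_numeric(synthetic_spec(n = 100, n_numeric = 4, rate = 0.15,
                                   seed = 8))
  r <- kfold_eval(sd$masked, "mean", k = 5, seed = 2)
  expect_equal(nrow(r$per_fold), 5)
  expect_true(all(r$per_fold$accuracy >= 0 & r$per_fold$accuracy <= 1))
  expect_true(all(vapply(r$audit, function(a)
    length(intersect(a$fit_rows, a$test_rows)) == 0, logical(1))))
  # every row appears in exactly one test fold
  all_test <- sort(unlist(lapply(r$audit, `[[`, "test_rows")))
  expect_equal(all_test, 1:100)
})

test_that("framework comparison shares folds and includes all frameworks", {
  sd <- gen_numeric(synthetic_spec(n = 90, n_numeric = 3, rate = 0.12,
                                   seed = 9))
  fw <- c("drop", "mean", "median", "knn", "lr")
  cmp <- compare_frameworks(sd$masked, fw, k = 3, seed = 7)
  expect_length(cmp$reports, length(fw))
  expect_equal(cmp$summary$framework, fw)
  folds <- lapply(cmp$reports, function(r)
    lapply(r$audit, `[[`, "test_rows"))
  for (i in seq_along(folds)[-1]) expect_identical(folds[[i]], folds[[1]])
  # identical seed reproduces the table
  cmp2 <- compare_frameworks(sd$masked, fw, k = 3, seed = 7)
  expect_equal(cmp$summary, cmp2$summary)
})

test_that("the sweep emits one row per framework and level", {
  sd <- gen_numeric(synthetic_spec(n = 90, n_numeric = 3, rate = 0,
                                   seed = 10))
  sw <- missingness_sweep(sd$complete, c("mean", "knn"),
                          levels = c(0.1, 0.3), k = 3, seed = 4)
  expect_equal(nrow(sw), 4)
  expect_equal(sort(unique(sw$level)), c(0.1, 0.3))
  expect_error(missingness_sweep(sd$complete, "mean",
                                 levels = c(0.5, 0.1)),
               "strictly increasing")
  masked <- inject_mar(sd$complete, mar_spec(0.2, seed = 1))
  expect_error(missingness_sweep(masked, "mean"), "complete input")
})
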