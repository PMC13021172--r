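test_that("pearson matches closed forms and flags degeneracy", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_true(is.na(pearson(c(1, 1, 1), c(1, 2, 3))))
  # computed over mutually observed pairs only
  expect_equal(pearson(c(1, 2, 3, NA), c(2, 4, 6, 100)), 1)
})

test_that("correlation filter drops rho <= 0 and falls back when empty", {
  set.seed(5)
  n <- 60
  t <- rnorm(n)
  df <- data.frame(pos = t + rnorm(n, 0, 0.3),
                   neg = -t + rnorm(n, 0, 0.3),
                   const = rep(1, n),
                   target = t, y = rep(0:1, n / 2))
  df$target[1:5] <- NA
  ds <- dataset(df, class_attr = "y")
  cf <- correlation_filter(ds, "target")
  expect_equal(cf$predictor, "pos")
  expect_false(attr(cf, "fallback"))
  # all-negative candidates trigger the |rho| fallback
  df2 <- data.frame(neg1 = -t, neg2 = -t + rnorm(n, 0, 0.5), target = t,
                    y = rep(0:1, n / 2))
  df2$target[1:5] <- NA
  cf2 <- correlation_filter(dataset(df2, class_attr = "y"), "target")
  expect_true(attr(cf2, "fallback"))
  expect_equal(nrow(cf2), 2)
})

test_that("standard SVR imputation recovers a perfect-copy target", {
  df <- linear_toy(30)
  df$x2[c(4, 11, 20)] <- NA
  ds <- dataset(df, class_attr = "class")
  frag <- impute_standard_svr(ds, "x2",
                              svr_config("linear", C = 500,
                                         epsilon = 0.001))
  expect_complete(frag$dataset)
  got <- frag$dataset$values$x2[c(4, 11, 20)]
  want <- 2 * df$x1[c(4, 11, 20)]
  expect_true(all(abs(got - want) < 0.05))
  # observed cells untouched
  obs <- !ds$mask[, "x2"]
  expect_identical(frag$dataset$values$x2[obs], df$x2[obs])
})

test_that("imputing a target with no missing cells is a no-op", {
  ds <- dataset(linear_toy(12), class_attr = "class")
  frag <- impute_standard_svr(ds, "x2")
  expect_identical(frag$dataset$values, ds$values)
  expect_equal(frag$diagnostics$iterations, 0)
})

test_that("iterative SVR with infinite tolerance equals the standard pass", {
  df <- linear_toy(30, seed = 2)
  df$x2[c(2, 9, 15, 22, 28)] <- NA
  ds <- dataset(df, class_attr = "class")
  cfg <- svr_config("rbf", C = 10, gamma = 0.5, epsilon = 0.05)
  std <- impute_standard_svr(ds, "x2", cfg)
  it <- impute_iterative_svr(ds, "x2", cfg, tol = Inf)
  expect_equal(it$diagnostics$iterations, 1)
  expect_equal(it$dataset$values$x2, std$dataset$values$x2)
})

test_that("iterative refinement settles: final change below the first", {
  deltas <- vapply(1:5, function(s) {
    sd <- gen_numeric(synthetic_spec(n = 150, n_numeric = 4, rate = 0.2,
                                     seed = s))
    frag <- impute_iterative_svr(sd$masked, "x02",
                                 svr_config("rbf", C = 10, gamma = 0.3,
                                            epsilon = 0.01),
                                 tol = 1e-6, max_iter = 6)
    ch <- attr(frag$diagnostics, "changes")
    if (length(ch) < 2) 0 else ch[length(ch)] - ch[1]
  }, numeric(1))
  expect_true(all(deltas <= 1e-8))
})

test_that("knn imputation averages neighbours and majority-votes categories", {
  # two clear clusters; masked row 1 sits in the first cluster whose donor
  # targets are 4 and 6 -> k=2 mean is 5
  df <- data.frame(
    a = c(0, 0.1, -0.1, 5, 5.2, 4.9),
    b = c(0, 0.1, -0.1, 5, 5.2, 4.9),
    t = c(NA, 4, 6, 40, 44, 48),
    y = rep(0:1, 3))
  ds <- dataset(df, class_attr = "y")
  out <- knn_initial_impute(ds, "t", k = 2)
  expect_equal(out$dataset$values$t[1], 5)
  out1 <- knn_initial_impute(ds, "t", k = 1)
  expect_true(out1$dataset$values$t[1] %in% c(4, 6))
  # categorical target: majority vote among {a, a, b}
  dfc <- df
  dfc$t <- c(NA, "a", "a", "b", "b", "b")
  dsc <- dataset(dfc, class_attr = "y")
  outc <- knn_initial_impute(dsc, "t", k = 3)
  expect_equal(outc$dataset$values$t[1], "a")
})

test_that("SVR refinement improves on the raw KNN stage", {
  cfg <- svr_config("rbf", C = 10, gamma = 0.2, epsilon = 0.01)
  wins <- 0; r1s <- c(); r2s <- c()
  for (s in 1:10) {
    sd <- gen_numeric(synthetic_spec(n = 150, n_numeric = 5, rate = 0.3,
                                     seed = 100 + s))
    stage1 <- knn_initial_impute(sd$masked, "x02", k = 5)$dataset
    stage2 <- impute_knn_svr(sd$masked, "x02", cfg, k = 5)$dataset
    mask <- sd$masked$mask[, "x02", drop = FALSE]
    r1 <- sqrt(mean((stage1$values$x02[mask] - sd$truth$x02[mask])^2))
    r2 <- sqrt(mean((stage2$values$x02[mask] - sd$truth$x02[mask])^2))
    r1s <- c(r1s, r1); r2s <- c(r2s, r2)
  }
  expect_lt(mean(r2s), mean(r1s))
})

test_that("the adaptive driver dispatches by regime and is non-destructive", {
  set.seed(7)
  n <- 100
  t <- rnorm(n)
  df <- data.frame(a = t + rnorm(n, 0, 0.2), b = t + rnorm(n, 0, 0.2),
                   c = t + rnorm(n, 0, 0.2), y = rep(0:1, n / 2))
  df$a[1:5] <- NA    # lambda 0.05 -> low -> standard
  df$b[1:30] <- NA   # lambda 0.30 -> high -> knn_svr
  ds <- dataset(df, class_attr = "y")
  res <- impute_dataset(ds, ga = NULL)
  expect_complete(res$dataset)
  d <- res$diagnostics
  expect_equal(d$strategy[d$attribute == "a"], "standard_svr")
  expect_equal(d$strategy[d$attribute == "b"], "knn_svr")
  # ascending-lambda processing order
  expect_equal(d$attribute, c("a", "b"))
  # originally observed cells bit-identical
  for (nm in c("a", "b", "c")) {
    obs <- !ds$mask[, nm]
    expect_identical(res$dataset$values[[nm]][obs], df[[nm]][obs])
  }
})

test_that("a complete dataset passes through the driver untouched", {
  ds <- dataset(linear_toy(12), class_attr = "class")
  res <- impute_dataset(ds, ga = NULL)
  expect_identical(res$dataset$values, ds$values)
  expect_equal(nrow(res$diagnostics), 0)
})

test_that("imputed categorical cells always decode to existing categories", {
  set.seed(3)
  n <- 80
  t <- rnorm(n)
  df <- data.frame(a = t + rnorm(n, 0, 0.3),
                   g = ifelse(t > 0, "hi", "lo"),
                   y = rep(0:1, n / 2))
  df$g[sample(n, 12)] <- NA
  ds <- dataset(df, class_attr = "y")
  res <- impute_dataset(ds, ga = NULL)
  expect_complete(res$dataset)
  expect_true(all(res$dataset$values$g %in% c("hi", "lo")))
})

test_that("baseline imputers match their closed-form fills", {
  df <- data.frame(num = c(1, NA, 3, 8), cat = c("a", "a", "b", NA),
                   y = rep(0:1, 2))
  ds <- dataset(df, class_attr = "y")
  expect_equal(baseline_impute(ds, "mean")$values$num[2], 4)
  expect_equal(baseline_impute(ds, "median")$values$num[2], 3)
  expect_equal(baseline_impute(ds, "mode")$values$cat[4], "a")
  dr <- baseline_impute(ds, "drop")
  expect_equal(nrow(dr$values), 2)
})

test_that("every non-drop baseline completes without touching observed cells", {
  sd <- gen_numeric(synthetic_spec(n = 80, n_numeric = 4, rate = 0.2,
                                   seed = 6))
  ds <- sd$masked
  for (m in c("mean", "mode", "median", "knn", "lr", "nn")) {
    out <- baseline_impute(ds, m, seed = 1)
    expect_complete(out)
    for (nm in predictor_attrs(ds)) {
      obs <- !ds$mask[, nm]
      expect_identical(out$values[[nm]][obs], ds$values[[nm]][obs])
    }
  }
  expect_lt(nrow(baseline_impute(ds, "drop")$values), nrow(ds$values))
})
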