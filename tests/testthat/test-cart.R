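test_that("gini index matches worked examples and bounds", {
  expect_equal(round(gini_index(c(93, 1)), 3), 0.021)
  expect_equal(round(gini_index(c(16, 2)), 3), 0.198)
  expect_equal(gini_index(c(10, 0)), 0)
  expect_equal(gini_index(c(7, 7)), 0.5)
  expect_error(gini_index(c(0, 0)), "undefined")
  # 0 <= GI <= 1 - 1/k, zero iff pure
  set.seed(1)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    counts <- rmultinom(1, 40, rep(1, k))[, 1]
    if (sum(counts > 0) == 0) next
    g <- gini_index(counts)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / k + 1e-12)
    if (sum(counts > 0) == 1) expect_equal(g, 0)
  }
})

test_that("weighted split impurity matches its closed form", {
  expect_equal(gini_split(c(2, 0), c(0, 2)), 0)
  # children copying the parent distribution change nothing
  expect_equal(gini_split(c(6, 2), c(3, 1)), gini_index(c(9, 3)))
  expect_equal(gini_index(c(2, 2)) - gini_split(c(2, 0), c(0, 2)), 0.5)
  expect_error(gini_split(c(0, 0), c(1, 1)), "empty side|undefined")
})

test_that("best_split finds the known threshold on a textbook example", {
  x <- data.frame(x = c(1, 2, 3, 4))
  y <- c("A", "A", "B", "B")
  sp <- best_split(x, y)
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$reduction, 0.5)
  # identical features, mixed labels: no valid split
  expect_null(best_split(data.frame(x = rep(1, 4)), y))
})

test_that("split search equals exhaustive enumeration on random tiny data", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(4:8, 1); p <- sample(1:3, 1)
    x <- as.data.frame(replicate(p, sample(1:4, n, replace = TRUE)))
    names(x) <- paste0("v", seq_len(p))
    if (p >= 2 && runif(1) < 0.5)
      x[[p]] <- sample(letters[1:3], n, replace = TRUE)
    y <- sample(c("u", "w"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("u", "w"), y[1])
    sp <- best_split(x, y)
    oracle <- oracle_best_reduction(x, y)
    if (is.null(sp)) expect_lte(oracle, 1e-12)
    else expect_equal(sp$reduction, oracle, tolerance = 1e-10)
  }
})

test_that("tree induction handles base cases and memorizes distinct rows", {
  one <- dataset(data.frame(a = 1, y = "p"), class_attr = "y")
  tr1 <- induce_tree(one)
  expect_equal(tr1$n_leaves, 1)
  expect_equal(predict(tr1, data.frame(a = 99)), "p")
  # linearly separable clusters -> a single split, perfect training accuracy
  df <- data.frame(a = c(rnorm(20, -3), rnorm(20, 3)), b = rnorm(40),
                   y = rep(c("neg", "pos"), each = 20))
  tr2 <- induce_tree(dataset(df, class_attr = "y"))
  expect_equal(tr2$depth, 1)
  expect_equal(predict(tr2, df[, 1:2]), df$y)
  # distinct-featured rows are memorized by the unpruned tree
  set.seed(30)
  df3 <- data.frame(a = runif(25), b = runif(25),
                    y = sample(c("u", "w"), 25, replace = TRUE))
  tr3 <- induce_tree(dataset(df3, class_attr = "y"))
  expect_equal(mean(predict(tr3, df3[, 1:2]) == df3$y), 1)
  expect_error(induce_tree(df3[0, ]), "empty|zero")
})

test_that("prediction routes thresshold ties left and refuses missing cells", {
  df <- data.frame(a = c(1, 2, 3, 4), y = c("A", "A", "B", "B"))
  tr <- induce_tree(dataset(df, class_attr = "y"))
  expect_equal(predict(tr, data.frame(a = 2.5)), "A")  # <= goes left
  expect_equal(predict(tr, data.frame(a = 2.50001)), "B")
  expect_error(predict(tr, data.frame(a = NA_real_)), "missing value")
})

test_that("cost-complexity pruning is monotone and has the right limits", {
  set.seed(31)
  n <- 200
  df <- data.frame(a = rnorm(n), b = rnorm(n))
  df$y <- ifelse(df$a + 0.5 * df$b + rnorm(n, 0, 0.6) > 0, "pos", "neg")
  ds <- dataset(df, class_attr = "y")
  tr <- induce_tree(ds)
  alphas <- c(0, 0.003, 0.007, 0.05)
  leaves <- c(); accs <- c()
  for (a in alphas) {
    pr <- ccp_prune(tr, a)
    leaves <- c(leaves, pr$n_leaves)
    accs <- c(accs, mean(predict(pr, df[, 1:2]) == df$y))
    expect_lte(pr$n_leaves, tr$n_leaves)
  }
  expect_true(all(diff(leaves) <= 0))
  expect_true(all(diff(accs) <= 1e-12))
  inf <- ccp_prune(tr, Inf)
  expect_equal(inf$n_leaves, 1)
  expect_equal(inf$root$label, names(which.max(table(df$y))))
})

test_that("rules cover each training row exactly once and carry gini", {
  df <- data.frame(a = c(1, 2, 3, 4), y = c("A", "A", "B", "B"))
  tr <- induce_tree(dataset(df, class_attr = "y"))
  rules <- export_rules(tr)
  expect_length(rules, tr$n_leaves)
  expect_length(rules, 2)
  # a leaf with counts (16, 2) annotates gini 0.198
  leaf <- sgadt:::new_leaf(c(16, 2), c("malignant", "benign"))
  fake <- structure(list(root = leaf, classes = c("malignant", "benign"),
                         n_leaves = 1, depth = 0, ccp_alpha = 0),
                    class = "sga_tree")
  expect_match(export_rules(fake), "gini = 0.198")
  js <- tree_to_json(tr)
  expect_true(jsonlite::validate(js))
})
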