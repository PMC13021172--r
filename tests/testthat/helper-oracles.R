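# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately re-derive quantities from first principles and
# never call the package code paths they are used to check.

# Exhaustive enumeration of every binary split (numeric midpoints, all
# nominal subsets) returning the maximum achievable impurity reduction.
oracle_best_reduction <- function(x, y, kinds = NULL) {
  if (is.null(kinds))
    kinds <- ifelse(vapply(x, is.numeric, logical(1)), "numeric",
                    "categorical")
  gini <- function(labs) {
    p <- table(labs) / length(labs)
    1 - sum(p^2)
  }
  parent <- gini(y)
  best <- -Inf
  for (j in seq_along(x)) {
    v <- x[[j]]
    parts <- list()
    if (kinds[j] == "numeric") {
      sv <- sort(unique(v))
      if (length(sv) < 2) next
      mids <- (sv[-1] + sv[-length(sv)]) / 2
      parts <- lapply(mids, function(t) v <= t)
    } else {
      cats <- unique(v)
      if (length(cats) < 2) next
      for (m in 1:(2^(length(cats) - 1) - 1)) {
        sel <- cats[as.logical(bitwAnd(m, 2^(seq_along(cats) - 1)))]
        parts <- c(parts, list(v %in% sel))
      }
    }
    for (inL in parts) {
      if (!any(inL) || all(inL)) next
      w <- mean(inL)
      red <- parent - (w * gini(y[inL]) + (1 - w) * gini(y[!inL]))
      if (red > best) best <- red
    }
  }
  best
}

# A small data.frame with one numeric target linearly tied to a predictor,
# for exact-recovery style checks.
linear_toy <- function(n = 30, seed = 1) {
  set.seed(seed)
  x1 <- seq(-1, 1, length.out = n)
  data.frame(x1 = x1, x2 = 2 * x1, x3 = rnorm(n),
             class = as.integer(x1 > 0))
}

# Write a dataset to a temporary csv and return the path.
tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  path
}

expect_complete <- function(ds) {
  expect_s3_class(ds, "sga_dataset")
  expect_equal(n_missing(ds), 0)
  expect_false(anyNA(ds$values))
}
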