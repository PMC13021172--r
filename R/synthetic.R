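#' Specify a synthetic tabular dataset
#'
#' Gaussian latent-factor generator: every attribute loads on one shared
#' factor (so all pairwise correlations are positive, which the correlation
#' filter expects of informative predictors) plus one of `n_factors` group
#' factors, with additive Gaussian noise. The binary class is a thresholded
#' linear score of the latent factors with label-noise flips. MAR missingness
#' at the configured rate is injected by [inject_mar()] into every non-class
#' attribute except the first numeric one, which is held out as the fully
#' observed driver the masking probabilities depend on.
#'
#' @param n Instances (>= 10).
#' @param n_numeric Numeric attribute count.
#' @param n_categorical Categorical attribute count.
#' @param cardinalities Category counts (recycled over categorical
#'   attributes; each >= 2). Categoricals are quantile-discretized latent
#'   scores.
#' @param n_factors Latent group factors.
#' @param shared_loading,group_loading,noise_sd Loadings of the shared and
#'   group factors and the noise scale.
#' @param label_noise Probability a class label is flipped.
#' @param rate MAR missing-cell rate per attribute (0 disables masking).
#' @param seed Integer seed; the full (complete, masked, truth) triple is
#'   reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 1000, n_numeric = 10, n_categorical = 0,
                           cardinalities = 3, n_factors = 3,
                           shared_loading = 0.4, group_loading = 0.8,
                           noise_sd = 0.4, label_noise = 0.05,
                           rate = 0.2, seed = 1) {
  stopifnot(n >= 10, rate >= 0, rate < 1, all(cardinalities >= 2),
            n_numeric + n_categorical >= 1, label_noise >= 0,
            label_noise < 0.5)
  structure(list(n = n, n_numeric = n_numeric,
                 n_categorical = n_categorical,
                 cardinalities = rep_len(cardinalities,
                                         max(1, n_categorical)),
                 n_factors = n_factors, shared_loading = shared_loading,
                 group_loading = group_loading, noise_sd = noise_sd,
                 label_noise = label_noise, rate = rate, seed = seed),
            class = "synthetic_spec")
}

#' Presets mirroring the two benchmark synthetic datasets
#'
#' `spec_synthetic1()`: 5000 instances, 15 numeric attributes, 27.6% MAR
#' missingness (the high-missingness regime benchmark).
#' `spec_synthetic2()`: 15000 instances, 30 mixed attributes (20 numeric +
#' 10 categorical), 10% MAR missingness (the moderate-missingness mixed-type
#' benchmark).
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
spec_synthetic1 <- function(seed = 1) {
  synthetic_spec(n = 5000, n_numeric = 15, n_categorical = 0,
                 rate = 0.276, seed = seed)
}

#' @rdname spec_synthetic1
#' @export
spec_synthetic2 <- function(seed = 1) {
  synthetic_spec(n = 15000, n_numeric = 20, n_categorical = 10,
                 cardinalities = c(2, 3, 4), rate = 0.10, seed = seed)
}

gen_latent <- function(spec) {
  k <- spec$n_factors
  p <- spec$n_numeric + spec$n_categorical
  Z <- matrix(rnorm(spec$n * k), spec$n, k)
  shared <- rnorm(spec$n)
  group <- rep_len(seq_len(k), p)
  scores <- sapply(seq_len(p), function(j)
    spec$shared_loading * shared + spec$group_loading * Z[, group[j]] +
      spec$noise_sd * rnorm(spec$n))
  lin <- shared + rowSums(Z) / sqrt(k)
  y <- as.integer(lin > 0)
  flip <- runif(spec$n) < spec$label_noise
  y[flip] <- 1L - y[flip]
  list(scores = scores, y = y)
}

build_synthetic <- function(spec) {
  with_seed(spec$seed, {
    lat <- gen_latent(spec)
    p <- spec$n_numeric + spec$n_categorical
    vals <- as.data.frame(lat$scores)
    names(vals) <- sprintf("x%02d", seq_len(p))
    if (spec$n_categorical > 0) {
      cat_idx <- (spec$n_numeric + 1):p
      for (ii in seq_along(cat_idx)) {
        j <- cat_idx[ii]
        card <- spec$cardinalities[ii]
        br <- quantile(vals[[j]], probs = seq(0, 1, length.out = card + 1))
        br[1] <- -Inf; br[length(br)] <- Inf
        vals[[j]] <- paste0("c", as.integer(cut(vals[[j]], breaks = br)))
        names(vals)[j] <- sprintf("f%02d", j)
      }
    }
    vals$class <- lat$y
    vals
  })
}

#' Generate a numeric synthetic dataset with known ground truth
#'
#' Builds the complete table from the latent-factor model of
#' [synthetic_spec()], then injects MAR missingness at the spec's rate into
#' every non-class attribute. The pre-mask truth is returned so imputation
#' error (RMSE) against ground truth can be scored.
#'
#' @param spec A [synthetic_spec()] with `n_categorical = 0`.
#' @return List with `complete` (`sga_dataset`, no missing cells), `masked`
#'   (same rows with MAR-masked cells) and `truth` (the complete value
#'   table).
#' @examples
#' sd1 <- gen_numeric(synthetic_spec(n = 200, n_numeric = 5, rate = 0.2))
#' imputation_rmse(baseline_impute(sd1$masked, "mean"), sd1$truth,
#'                 sd1$masked$mask)
#' @export
gen_numeric <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$n_categorical == 0)
  gen_any(spec)
}

#' Generate a mixed-type synthetic dataset
#'
#' As [gen_numeric()] but with categorical attributes obtained by
#' quantile-discretizing latent scores into the spec'd cardinalities; MAR
#' masking applies to both attribute kinds.
#'
#' @param spec A [synthetic_spec()] with both attribute kinds present.
#' @return As [gen_numeric()].
#' @export
gen_mixed <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$n_categorical > 0,
            spec$n_numeric > 0)
  gen_any(spec)
}

gen_any <- function(spec) {
  vals <- build_synthetic(spec)
  complete <- dataset(vals, class_attr = "class")
  masked <- if (spec$rate > 0) {
    # the first numeric attribute is held out as the fully observed MAR
    # driver; masking probabilities depend on its observed values, never on
    # the class label (a class-driven mask would itself carry class signal)
    drv <- predictor_attrs(complete)[1]
    targets <- setdiff(predictor_attrs(complete), drv)
    inject_mar(complete, mar_spec(spec$rate, drivers = drv,
                                  seed = derive_seed(spec$seed, 99)),
               targets = targets)
  } else complete
  list(complete = complete, masked = masked, truth = complete$values)
}

#' RMSE of imputed values against ground truth
#'
#' Root-mean-square error over the originally masked numeric cells, plus the
#' disagreement rate over originally masked categorical cells, of an imputed
#' dataset against the pre-mask truth.
#'
#' @param imputed A completed `sga_dataset` (or an `sga_imputation`).
#' @param truth The truth table from the generator.
#' @param mask Logical matrix of originally masked cells; defaults to the
#'   one recorded when the imputed dataset still carried it (pass the masked
#'   dataset's mask when scoring externally completed tables).
#' @return Named vector `rmse` (numeric cells; `NA` when none) and
#'   `cat_error` (categorical cells; `NA` when none).
#' @export
imputation_rmse <- function(imputed, truth, mask = NULL) {
  if (inherits(imputed, "sga_imputation")) imputed <- imputed$dataset
  if (is.null(mask)) mask <- attr(imputed, "orig_mask")
  if (is.null(mask)) stop("supply the original missingness mask", call. = FALSE)
  vals <- imputed$values
  kinds <- attr_kind(imputed)
  sq <- c(); wrong <- c()
  for (nm in colnames(mask)) {
    m <- mask[, nm]
    if (!any(m)) next
    if (kinds[nm] == "numeric") {
      sq <- c(sq, (vals[[nm]][m] - truth[[nm]][m])^2)
    } else {
      wrong <- c(wrong, vals[[nm]][m] != truth[[nm]][m])
    }
  }
  c(rmse = if (length(sq)) sqrt(mean(sq)) else NA_real_,
    cat_error = if (length(wrong)) mean(wrong) else NA_real_)
}

#' A tiny hand-checkable fixture dataset
#'
#' Twelve rows, three numeric predictors with simple monotone relationships,
#' one masked column (`x2`, three masked cells) and a binary class; small
#' enough for exhaustive oracle comparisons and unit tests. Serializes to
#' well under 1 KB of CSV.
#'
#' @param seed Integer seed.
#' @return An `sga_dataset`.
#' @export
gen_tiny_fixture <- function(seed = 1) {
  with_seed(seed, {
    x1 <- seq(-1.1, 1.1, length.out = 12)
    x2 <- 2 * x1 + rnorm(12, 0, 0.1)
    x3 <- x1 + rnorm(12, 0, 0.3)
    y <- as.integer(x1 + x3 > 0)
    df <- data.frame(x1 = round(x1, 3), x2 = round(x2, 3),
                     x3 = round(x3, 3), class = y)
    hide <- sample(12, 3)
    df$x2[hide] <- NA
    dataset(df, class_attr = "class")
  })
}
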