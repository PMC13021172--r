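#' Pearson correlation over mutually observed entries
#'
#' Product-moment correlation computed on the rows where both vectors are
#' observed. Returns `NA` (an undefined-correlation signal) when fewer than
#' two complete pairs exist or either vector is constant on them; the
#' correlation filter treats that as zero.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A number in \[-1, 1\], or `NA`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
}

#' Correlation-based predictor filtering
#'
#' Retains every non-class attribute (other than the target) whose Pearson
#' correlation with the target, computed over mutually observed rows, is
#' strictly positive; candidates with correlation <= 0 (or undefined) are
#' removed so weakly or negatively related attributes do not degrade the SVR
#' fit. If the filter removes everything, the top 3 candidates by absolute
#' correlation are retained instead and the result is flagged (attribute
#' `"fallback"`), since the regressor needs at least one predictor.
#'
#' @param ds An `sga_dataset` (categoricals are label-encoded internally).
#' @param target A non-class attribute name.
#' @return data.frame with columns `predictor`, `rho`, ordered by decreasing
#'   `rho`; attribute `fallback` is `TRUE` when the fallback rule fired.
#' @export
correlation_filter <- function(ds, target) {
  enc <- encode_categoricals(ds)$dataset
  cands <- setdiff(predictor_attrs(ds), target)
  if (!target %in% predictor_attrs(ds))
    stop("'", target, "' is not a non-class attribute", call. = FALSE)
  ty <- enc$values[[target]]
  if (sum(!is.na(ty)) < 2)
    stop("target '", target, "' has fewer than 2 observed values",
         call. = FALSE)
  rho <- vapply(cands, function(nm) pearson(enc$values[[nm]], ty),
                numeric(1))
  keep <- !is.na(rho) & rho > 0
  fallback <- FALSE
  if (!any(keep)) {
    fallback <- TRUE
    ord <- order(-abs(ifelse(is.na(rho), 0, rho)))
    keep_idx <- ord[seq_len(min(3, length(ord)))]
  } else {
    keep_idx <- which(keep)
  }
  out <- data.frame(predictor = cands[keep_idx], rho = rho[keep_idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$rho), 0, out$rho)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fallback") <- fallback
  out
}

# Numeric design matrix of predictor columns with remaining NAs filled by the
# column means of `ref` rows (temporary scaffolding for the fit only; filled
# values are never written back into the dataset).
fill_design <- function(vals, predictors, ref_rows = NULL) {
  m <- as.matrix(vals[, predictors, drop = FALSE])
  storage.mode(m) <- "double"
  ref <- if (is.null(ref_rows)) m else m[ref_rows, , drop = FALSE]
  mu <- colMeans(ref, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (any(na)) m[na, j] <- mu[j]
  }
  m
}

# Snap regression predictions for a label-encoded categorical target onto the
# nearest observed code, so imputed cells always decode to a real category.
snap_to_codes <- function(pred, codes) {
  codes <- sort(unique(codes[!is.na(codes)]))
  codes[max.col(-abs(outer(pred, codes, "-")), ties.method = "first")]
}

is_categorical <- function(ds, nm) {
  ds$schema$kind[match(nm, ds$schema$name)] == "categorical"
}

# One SVR imputation pass over a label-encoded working dataset: fit on rows
# with the target observed (design NAs mean-filled), predict the masked rows.
svr_pass <- function(vals, mask, target, predictors, cfg, categorical) {
  train <- which(!mask[, target])
  test <- which(mask[, target])
  x <- fill_design(vals, predictors, ref_rows = train)
  model <- fit_svr(x[train, , drop = FALSE], vals[[target]][train], cfg)
  pred <- predict(model, x[test, , drop = FALSE])
  if (categorical) pred <- snap_to_codes(pred, vals[[target]][train])
  list(pred = pred, test = test, model = model)
}

impute_fragment <- function(ds, target, filled, strategy, cfg, iterations,
                            flags = character(0)) {
  vals <- ds$values; mask <- ds$mask
  vals[[target]][mask[, target]] <- filled
  mask[, target] <- FALSE
  out <- structure(list(values = vals, mask = mask, schema = ds$schema),
                   class = "sga_dataset")
  diag <- data.frame(attribute = target, strategy = strategy,
                     kernel = if (is.null(cfg)) NA_character_ else cfg$kernel,
                     C = if (is.null(cfg)) NA_real_ else cfg$C,
                     gamma = if (is.null(cfg)) NA_real_ else cfg$gamma,
                     epsilon = if (is.null(cfg)) NA_real_ else cfg$epsilon,
                     degree = if (is.null(cfg)) NA_integer_ else cfg$degree,
                     iterations = iterations,
                     flags = paste(flags, collapse = ";"),
                     stringsAsFactors = FALSE)
  list(dataset = out, diagnostics = diag)
}

#' Single-pass SVR imputation (low-missingness strategy)
#'
#' Fits an epsilon-SVR of the target on its correlation-filtered predictors
#' using the rows where the target is observed, then replaces the masked
#' target cells with the fitted predictions. Categorical targets are
#' regressed on their integer codes and snapped to the nearest valid code.
#'
#' @param ds An `sga_dataset`.
#' @param target Non-class attribute to impute.
#' @param cfg An [svr_config()].
#' @param predictors Optional predictor names; default
#'   [correlation_filter()].
#' @return List with the updated `dataset` (target mask all-`FALSE`) and a
#'   one-row `diagnostics` data.frame.
#' @export
impute_standard_svr <- function(ds, target, cfg = svr_config(),
                                predictors = NULL) {
  enc <- encode_categoricals(ds)
  e <- enc$dataset
  if (!any(e$mask[, target]))
    return(impute_fragment(ds, target, numeric(0), "standard_svr", cfg, 0L))
  if (is.null(predictors)) predictors <- correlation_filter(ds, target)$predictor
  p <- svr_pass(e$values, e$mask, target, predictors, cfg,
                is_categorical(ds, target))
  frag <- impute_fragment(e, target, p$pred, "standard_svr", cfg, 1L)
  frag$dataset <- decode_categoricals(frag$dataset, enc$codebook)
  frag$model <- p$model
  frag
}

#' Iterative SVR imputation (medium-missingness strategy)
#'
#' Pass 0 is a standard SVR imputation; each later pass refits the regressor
#' with the previous round's estimates standing in for the missing predictor
#' cells and updates only the originally missing target cells. Iteration
#' stops when the largest absolute change of any imputed value (on the
#' standardized target scale) drops below `tol`, or after `max_iter` passes
#' (flagged `non_converged` in the diagnostics).
#'
#' @inheritParams impute_standard_svr
#' @param tol Convergence tolerance on the standardized scale.
#' @param max_iter Maximum number of passes.
#' @param train_on_imputed If `TRUE`, later passes also train on rows whose
#'   target value was itself imputed in the previous pass; the default trains
#'   only on originally observed target rows (with imputed predictor cells).
#' @return As [impute_standard_svr()]; `diagnostics$iterations` records the
#'   number of passes run.
#' @export
impute_iterative_svr <- function(ds, target, cfg = svr_config(),
                                 predictors = NULL, tol = 1e-3,
                                 max_iter = 10, train_on_imputed = FALSE) {
  enc <- encode_categoricals(ds)
  e <- enc$dataset
  if (!any(e$mask[, target]))
    return(impute_fragment(ds, target, numeric(0), "iterative_svr", cfg, 0L))
  if (is.null(predictors)) predictors <- correlation_filter(ds, target)$predictor
  categorical <- is_categorical(ds, target)
  vals <- e$values
  orig_mask <- e$mask
  train0 <- which(!orig_mask[, target])
  ysd <- sd(vals[[target]][train0]); if (!is.finite(ysd) || ysd == 0) ysd <- 1
  one_pass <- function(cur) {
    work <- vals
    if (!is.null(cur)) work[[target]][orig_mask[, target]] <- cur
    mask_it <- orig_mask
    if (!is.null(cur) && train_on_imputed) mask_it[, target] <- FALSE
    p <- svr_pass(work, mask_it, target, predictors, cfg, categorical)
    pred <- if (train_on_imputed && !is.null(cur)) {
      # predict the originally missing cells from the full-table fit
      x <- fill_design(work, predictors)
      pr <- predict(p$model, x[orig_mask[, target], , drop = FALSE])
      if (categorical) snap_to_codes(pr, work[[target]]) else pr
    } else p$pred
    list(pred = pred, model = p$model)
  }
  p <- one_pass(NULL)   # pass 1 == standard SVR imputation
  cur <- p$pred; model <- p$model
  iters <- 1L; flags <- character(0); converged <- max_iter <= 1L
  changes <- numeric(0)
  while (iters < max_iter) {
    p <- one_pass(cur)
    delta <- max(abs(p$pred - cur)) / ysd
    changes <- c(changes, delta)
    if (delta < tol) { converged <- TRUE; break }  # keep the converged iterate
    cur <- p$pred; model <- p$model
    iters <- iters + 1L
  }
  if (!converged) flags <- c(flags, "non_converged")
  frag <- impute_fragment(e, target, cur, "iterative_svr", cfg, iters, flags)
  attr(frag$diagnostics, "changes") <- changes
  frag$dataset <- decode_categoricals(frag$dataset, enc$codebook)
  frag$model <- model
  frag
}

#' KNN bootstrap imputation
#'
#' Fills the masked cells of `target` with the mean (numeric) or majority
#' category (categorical) of the `k` nearest rows that have the target
#' observed. Distances are standardized Euclidean over the other non-class
#' attributes, averaged over the entries observed in both rows. With fewer
#' than `k` eligible neighbours all of them are used; with none, the column
#' mean/mode is substituted (both cases flagged).
#'
#' @inheritParams impute_standard_svr
#' @param k Number of neighbours.
#' @return List with `dataset` (target completed) and `flags`.
#' @export
knn_initial_impute <- function(ds, target, k = 5) {
  stopifnot(k >= 1)
  enc <- encode_categoricals(ds)
  e <- enc$dataset
  miss <- which(e$mask[, target])
  if (!length(miss)) return(list(dataset = ds, flags = character(0)))
  feats <- setdiff(predictor_attrs(ds), target)
  z <- as.matrix(e$values[, feats, drop = FALSE])
  storage.mode(z) <- "double"
  mu <- colMeans(z, na.rm = TRUE); mu[!is.finite(mu)] <- 0
  sg <- apply(z, 2, sd, na.rm = TRUE); sg[!is.finite(sg) | sg == 0] <- 1
  z <- sweep(sweep(z, 2, mu, "-"), 2, sg, "/")
  donors <- which(!e$mask[, target])
  yv <- e$values[[target]]
  categorical <- is_categorical(ds, target)
  flags <- character(0)
  if (length(donors) == 0) {
    flags <- "no_donors_fallback"
    fill <- if (categorical) NA else mean(yv, na.rm = TRUE)
    if (categorical || !is.finite(fill))
      stop("no rows with observed target and no fallback value", call. = FALSE)
    filled <- rep(fill, length(miss))
  } else {
    if (length(donors) < k) flags <- "fewer_donors_than_k"
    zd <- z[donors, , drop = FALSE]
    filled <- vapply(miss, function(i) {
      d2 <- (zd - matrix(z[i, ], nrow(zd), ncol(zd), byrow = TRUE))^2
      dist <- sqrt(rowMeans(d2, na.rm = TRUE))
      dist[!is.finite(dist)] <- Inf
      nb <- donors[order(dist)[seq_len(min(k, length(donors)))]]
      if (categorical) {
        tab <- sort(table(yv[nb]), decreasing = TRUE)
        as.numeric(names(tab)[1])
      } else mean(yv[nb])
    }, numeric(1))
  }
  frag <- impute_fragment(e, target, filled, "knn", NULL, 1L, flags)
  list(dataset = decode_categoricals(frag$dataset, enc$codebook),
       flags = flags)
}

#' KNN-initialized SVR refinement (high-missingness strategy)
#'
#' Stage 1 fills the target and any incomplete predictor column by KNN
#' imputation so the table becomes structurally complete; stage 2 refits an
#' SVR on that table and overwrites the originally missing target cells with
#' the refined predictions. Originally observed cells are untouched.
#'
#' @inheritParams impute_standard_svr
#' @param k Neighbours for the KNN stage.
#' @return As [impute_standard_svr()].
#' @export
impute_knn_svr <- function(ds, target, cfg = svr_config(), predictors = NULL,
                           k = 5) {
  if (is.null(predictors)) predictors <- correlation_filter(ds, target)$predictor
  if (!any(ds$mask[, target]))
    return(impute_fragment(ds, target, numeric(0), "knn_svr", cfg, 0L))
  stage1 <- knn_initial_impute(ds, target, k)$dataset
  for (nm in predictors)
    if (any(stage1$mask[, nm]))
      stage1 <- knn_initial_impute(stage1, nm, k)$dataset
  enc <- encode_categoricals(stage1)
  e <- enc$dataset
  categorical <- is_categorical(ds, target)
  train <- which(!ds$mask[, target])   # originally observed rows only
  test <- which(ds$mask[, target])
  x <- fill_design(e$values, predictors)
  model <- fit_svr(x[train, , drop = FALSE], e$values[[target]][train], cfg)
  pred <- predict(model, x[test, , drop = FALSE])
  if (categorical) pred <- snap_to_codes(pred, e$values[[target]][train])
  e$values[[target]][test] <- pred
  frag <- impute_fragment(
    structure(list(values = e$values, mask = ds$mask, schema = ds$schema),
              class = "sga_dataset"),
    target, pred, "knn_svr", cfg, 2L)
  frag$dataset <- decode_categoricals(frag$dataset, enc$codebook)
  frag$model <- model
  frag
}

#' Adaptive GA-optimized imputation of a whole dataset
#'
#' The full imputation driver. Incomplete non-class attributes are processed
#' one at a time in ascending order of missing fraction (ties by column
#' order), so the most reliable targets are completed first and become
#' available as predictors for later ones. For each target the strategy is
#' dispatched by its missingness regime (standard SVR when
#' `lambda <= tau1`, iterative SVR when `tau1 < lambda <= tau2`, KNN-then-SVR
#' when `lambda > tau2`), and the SVR kernel and hyperparameters are chosen
#' by the genetic search of [evolve()] minimizing 5-fold cross-validated MSE
#' on the observed target values.
#'
#' @param ds An `sga_dataset`; missingness must be confined to non-class
#'   attributes (enforced by the class).
#' @param ga A [ga_config()], or `NULL` to skip the genetic search and use
#'   `cfg` for every attribute.
#' @param tau1,tau2 Regime thresholds (defaults 0.10, 0.25).
#' @param k Neighbours for the KNN stage.
#' @param tol,max_iter Iterative-SVR controls.
#' @param eps_acc Acceptability half-width used for the within-threshold
#'   diagnostic (fraction of held-out standardized residuals with absolute
#'   value at most `eps_acc`).
#' @param cfg Fallback [svr_config()] when `ga` is `NULL`.
#' @param keep_models Also return the fitted per-attribute SVR models (used
#'   by the cross-validation harness to impute held-out folds without
#'   refitting).
#' @return An `sga_imputation`: list with `dataset` (all-observed) and
#'   `diagnostics` (one row per imputed attribute: lambda, regime, strategy,
#'   chosen config, iterations, cross-validated MSE, within-threshold
#'   fraction).
#' @examples
#' ds <- gen_tiny_fixture(1)
#' res <- impute_dataset(ds, ga = NULL)
#' res$diagnostics
#' @export
impute_dataset <- function(ds, ga = ga_config(), tau1 = 0.10, tau2 = 0.25,
                           k = 5, tol = 1e-3, max_iter = 10, eps_acc = 0.05,
                           cfg = svr_config(), keep_models = FALSE) {
  prof <- missingness_profile(ds, tau1, tau2)$attributes
  todo <- prof[prof$lambda > 0, , drop = FALSE]
  if (any(todo$lambda >= 1))
    stop("unimputable attribute (all values missing): ",
         paste(todo$name[todo$lambda >= 1], collapse = ", "), call. = FALSE)
  todo <- todo[order(todo$lambda, match(todo$name, prof$name)), ,
               drop = FALSE]
  work <- ds
  diags <- NULL
  models <- list()
  for (i in seq_len(nrow(todo))) {
    target <- todo$name[i]
    lam <- todo$lambda[i]; reg <- todo$regime[i]
    cf <- correlation_filter(work, target)
    predictors <- cf$predictor
    fit_mse <- NA_real_; within <- NA_real_
    use_cfg <- cfg
    if (!is.null(ga)) {
      enc <- encode_categoricals(work)$dataset
      train <- which(!enc$mask[, target])
      x <- fill_design(enc$values, predictors, ref_rows = train)
      ga_i <- ga
      ga_i$seed <- derive_seed(if (is.null(ga$seed)) 0 else ga$seed, i)
      ev <- evolve(x[train, , drop = FALSE], enc$values[[target]][train], ga_i)
      use_cfg <- ev$best
      fit_mse <- ev$best_fitness
      within <- ga_within_eps(x[train, , drop = FALSE],
                              enc$values[[target]][train], use_cfg,
                              ga_i, eps_acc)
    }
    frag <- switch(reg,
      low = impute_standard_svr(work, target, use_cfg, predictors),
      medium = impute_iterative_svr(work, target, use_cfg, predictors,
                                    tol = tol, max_iter = max_iter),
      high = impute_knn_svr(work, target, use_cfg, predictors, k = k))
    work <- frag$dataset
    if (keep_models)
      models[[target]] <- list(strategy = frag$diagnostics$strategy,
                               predictors = predictors, model = frag$model,
                               cfg = use_cfg)
    row <- frag$diagnostics
    row$lambda <- lam; row$regime <- reg
    row$cv_mse <- fit_mse; row$within_eps <- within
    if (attr(cf, "fallback"))
      row$flags <- paste(c(row$flags[row$flags != ""], "predictor_fallback"),
                         collapse = ";")
    diags <- rbind(diags, row)
  }
  if (is.null(diags))
    diags <- data.frame(attribute = character(0), strategy = character(0))
  out <- structure(list(dataset = work, diagnostics = diags),
                   class = "sga_imputation")
  if (keep_models) out$models <- models
  out
}

# Encode a dataset against a fixed codebook (fitted on other data): unseen
# categories become masked cells so downstream imputation handles them.
encode_with_codebook <- function(ds, codebook) {
  vals <- ds$values; mask <- ds$mask
  for (nm in names(codebook)) {
    code <- as.numeric(match(vals[[nm]], codebook[[nm]]) - 1L)
    unseen <- !is.na(vals[[nm]]) & is.na(code)
    mask[unseen, nm] <- TRUE
    vals[[nm]] <- code
  }
  structure(list(values = vals, mask = mask, schema = ds$schema),
            class = "sga_dataset")
}

#' @export
print.sga_imputation <- function(x, ...) {
  cat(sprintf("<sga_imputation> %d attribute(s) imputed; %d missing cells remain\n",
              nrow(x$diagnostics), n_missing(x$dataset)))
  if (nrow(x$diagnostics))
    print(x$diagnostics[, intersect(c("attribute", "lambda", "regime",
                                      "strategy", "kernel", "iterations",
                                      "cv_mse"), names(x$diagnostics))],
          row.names = FALSE)
  invisible(x)
}

#' Baseline imputers
#'
#' The seven reference treatments paired with the decision tree in the
#' benchmarking harness: `drop` removes every row with a masked cell;
#' `mean`/`median` fill numeric columns with the column statistic over
#' observed cells (categorical columns fall back to the mode so the result
#' is complete); `mode` fills any column with its most frequent observed
#' value; `knn` applies [knn_initial_impute()] column by column; `lr` fits
#' ordinary least squares of each incomplete attribute on its
#' correlation-filtered predictors; `nn` fits a single-hidden-layer (16
#' unit) neural network on the same design.
#'
#' @param ds An `sga_dataset`.
#' @param method One of `"drop"`, `"mean"`, `"mode"`, `"median"`, `"knn"`,
#'   `"lr"`, `"nn"`.
#' @param k Neighbours for `knn`.
#' @param seed Seed for the `nn` weight initialization.
#' @return An `sga_dataset`; complete for every method except `drop`, which
#'   returns the surviving-row subset.
#' @export
baseline_impute <- function(ds, method = c("drop", "mean", "mode", "median",
                                           "knn", "lr", "nn"),
                            k = 5, seed = 1) {
  method <- match.arg(method)
  if (method == "drop") {
    keep <- rowSums(ds$mask) == 0
    if (!any(keep)) stop("drop imputation removed every row", call. = FALSE)
    return(structure(list(values = ds$values[keep, , drop = FALSE],
                          mask = ds$mask[keep, , drop = FALSE],
                          schema = ds$schema), class = "sga_dataset"))
  }
  imp <- fit_imputer(method, ds, k = k, seed = seed)
  apply_imputer(imp, ds)
}

column_mode <- function(col) {
  obs <- col[!is.na(col)]
  tab <- table(obs)
  val <- names(tab)[which.max(tab)]  # ties: first level in table order
  if (is.numeric(col)) as.numeric(val) else val
}
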