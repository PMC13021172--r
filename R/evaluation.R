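#' Confusion counts
#'
#' k x k matrix of (true class, predicted class) counts; rows are truth,
#' columns are predictions.
#'
#' @param truth,pred Vectors of true and predicted labels.
#' @param classes Optional class ordering; default: sorted union.
#' @return Integer matrix with class dimnames.
#' @export
confusion_counts <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

#' Accuracy, precision, recall and F-measure from a confusion matrix
#'
#' Accuracy is `trace / total`. In `binary` mode precision and recall are
#' those of the designated positive class; in `macro` mode they are
#' unweighted means over classes. A class never predicted (or never present)
#' contributes precision (or recall) 0, flagged in the `undefined` attribute.
#' `F = 2PR / (P + R)`, defined as 0 when `P + R = 0`. The default `auto`
#' mode uses binary metrics for two classes (positive = second class in sort
#' order unless given) and macro otherwise.
#'
#' @param cm Confusion matrix from [confusion_counts()].
#' @param averaging `"auto"`, `"binary"` or `"macro"`.
#' @param positive Positive class label (binary mode).
#' @return Named numeric vector `accuracy`, `precision`, `recall`,
#'   `f_measure`.
#' @examples
#' cm <- confusion_counts(c(1,1,1,1,0,0,0,0,0,0), c(1,1,1,0,1,0,0,0,0,0))
#' classification_metrics(cm)
#' @export
classification_metrics <- function(cm, averaging = c("auto", "binary",
                                                     "macro"),
                                   positive = NULL) {
  averaging <- match.arg(averaging)
  cm <- as.matrix(cm)
  k <- nrow(cm)
  total <- sum(cm)
  stopifnot(total > 0)
  acc <- sum(diag(cm)) / total
  pred_tot <- colSums(cm); true_tot <- rowSums(cm)
  prec_c <- ifelse(pred_tot > 0, diag(cm) / pred_tot, 0)
  rec_c <- ifelse(true_tot > 0, diag(cm) / true_tot, 0)
  undefined <- rownames(cm)[pred_tot == 0 | true_tot == 0]
  if (averaging == "auto") averaging <- if (k == 2) "binary" else "macro"
  if (averaging == "binary") {
    if (is.null(positive)) positive <- rownames(cm)[min(2, k)]
    p <- prec_c[[positive]]; r <- rec_c[[positive]]
  } else {
    p <- mean(prec_c); r <- mean(rec_c)
  }
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  out <- c(accuracy = acc, precision = unname(p), recall = unname(r),
           f_measure = f)
  attr(out, "undefined") <- undefined
  out
}

# Stratified fold assignment: shuffle within class, deal round-robin. Falls
# back to plain k-fold (with a warning) when some class has < k members.
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  stopifnot(k >= 2, n >= k)
  tab <- table(y)
  with_seed(seed, {
    if (any(tab < k)) {
      warning("class with fewer than k members; plain k-fold used")
      return(sample(rep_len(seq_len(k), n)))
    }
    folds <- integer(n)
    for (cl in names(tab)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

canonical_svr_config <- function(p) {
  # neutral un-tuned baseline: rbf, C = 1, epsilon = 0.1, gamma = 1/p on
  # standardized predictors (the usual scale heuristic)
  svr_config("rbf", C = 1, epsilon = 0.1,
             gamma = min(10, max(1e-5, 1 / max(1, p))))
}

FRAMEWORKS <- c("drop", "mean", "mode", "median", "knn", "lr", "nn", "svr",
                "sga")

#' Fit an imputer on training data
#'
#' Builds the per-attribute fill rules or regression models of one framework
#' from the training rows only, so held-out data can later be completed by
#' [apply_imputer()] without touching it during fitting. Frameworks: the
#' seven baselines of [baseline_impute()] plus `svr` (canonical fixed-config
#' SVR, rbf kernel, C = 1, epsilon = 0.1, scale-heuristic gamma) and `sga`
#' (the adaptive GA-optimized imputer of [impute_dataset()]).
#'
#' @param method Framework name (not `drop`, which has no fitting stage).
#' @param ds Training `sga_dataset`.
#' @param k Neighbours for KNN-based stages.
#' @param seed Seed for stochastic components.
#' @param ga [ga_config()] for the `sga` framework.
#' @param row_ids Original row indices of `ds` (recorded for leakage
#'   auditing).
#' @return An `sga_imputer`.
#' @export
fit_imputer <- function(method, ds, k = 5, seed = 1, ga = ga_config(),
                        row_ids = seq_len(nrow(ds$values))) {
  method <- match.arg(method, setdiff(FRAMEWORKS, "drop"))
  enc <- encode_categoricals(ds)
  e <- enc$dataset
  kinds <- attr_kind(ds)
  imp <- list(method = method, codebook = enc$codebook, schema = ds$schema,
              k = k, seed = seed, rows_touched = row_ids)
  # unconditional fallback fills (train column mean / mode)
  imp$fills <- lapply(setNames(nm = predictor_attrs(ds)), function(nm) {
    col <- ds$values[[nm]]
    if (all(is.na(col))) stop("attribute '", nm, "' fully missing",
                              call. = FALSE)
    switch(method,
           median = if (kinds[nm] == "numeric")
             median(col, na.rm = TRUE) else column_mode(col),
           mode = column_mode(col),
           if (kinds[nm] == "numeric") mean(col, na.rm = TRUE)
           else column_mode(col))
  })
  if (method %in% c("mean", "median", "mode")) return(structure(imp, class = "sga_imputer"))
  if (method == "knn") {
    imp$pool <- e
    return(structure(imp, class = "sga_imputer"))
  }
  if (method == "sga") {
    ga$seed <- derive_seed(seed, 31)
    res <- impute_dataset(ds, ga = ga, k = k, keep_models = TRUE)
    imp$models <- res$models
    imp$order <- names(res$models)
    imp$train_completed <- res$dataset
    imp$diagnostics <- res$diagnostics
    imp$pool <- encode_categoricals(res$dataset)$dataset
    imp$fill_mu <- colMeans(as.matrix(
      imp$pool$values[, predictor_attrs(ds), drop = FALSE]))
    return(structure(imp, class = "sga_imputer"))
  }
  # lr / nn / svr: one regression model per incomplete attribute
  lam <- colMeans(e$mask)
  todo <- names(lam)[lam > 0]
  todo <- todo[order(lam[todo], match(todo, names(lam)))]
  mu <- colMeans(as.matrix(e$values[, predictor_attrs(ds), drop = FALSE]),
                 na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  models <- list()
  for (nm in todo) {
    predictors <- correlation_filter(ds, nm)$predictor
    train <- which(!e$mask[, nm])
    x <- fill_design(e$values, predictors, ref_rows = train)[train, ,
                                                             drop = FALSE]
    y <- e$values[[nm]][train]
    fit <- switch(method,
      lr = {
        df <- as.data.frame(x); df$.y <- y
        list(type = "lm", fit = lm(.y ~ ., data = df))
      },
      nn = with_seed(derive_seed(seed, match(nm, todo)), {
        list(type = "nn",
             fit = nnet::nnet(x, matrix(y), size = 16, linout = TRUE,
                              decay = 1e-3, maxit = 200, trace = FALSE),
             xnames = colnames(x))
      }),
      svr = list(type = "svr",
                 fit = fit_svr(x, y, canonical_svr_config(ncol(x)))))
    fit$predictors <- predictors
    fit$codes <- if (kinds[nm] == "categorical") sort(unique(y)) else NULL
    models[[nm]] <- fit
  }
  imp$models <- models
  imp$order <- todo
  imp$fill_mu <- mu
  structure(imp, class = "sga_imputer")
}

predict_imputer_model <- function(m, x) {
  switch(m$type %||% "svr",
         lm = as.numeric(predict(m$fit, newdata = as.data.frame(x))),
         nn = as.numeric(predict(m$fit, x)),
         svr = predict(m$fit, x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# KNN fill of one target column of `e` using donor rows from `pool` (both
# label-encoded against the same codebook).
knn_fill_from_pool <- function(e, pool, target, k, kinds) {
  miss <- which(e$mask[, target])
  if (!length(miss)) return(e)
  feats <- setdiff(colnames(e$mask)[colnames(e$mask) != target],
                   e$schema$name[e$schema$role == "class"])
  zp <- as.matrix(pool$values[, feats, drop = FALSE])
  zq <- as.matrix(e$values[, feats, drop = FALSE])
  storage.mode(zp) <- "double"; storage.mode(zq) <- "double"
  mu <- colMeans(zp, na.rm = TRUE); mu[!is.finite(mu)] <- 0
  sg <- apply(zp, 2, sd, na.rm = TRUE); sg[!is.finite(sg) | sg == 0] <- 1
  zp <- sweep(sweep(zp, 2, mu, "-"), 2, sg, "/")
  zq <- sweep(sweep(zq, 2, mu, "-"), 2, sg, "/")
  donors <- which(!pool$mask[, target])
  yv <- pool$values[[target]]
  categorical <- kinds[target] == "categorical"
  zd <- zp[donors, , drop = FALSE]
  for (i in miss) {
    d2 <- (zd - matrix(zq[i, ], nrow(zd), ncol(zd), byrow = TRUE))^2
    dist <- sqrt(rowMeans(d2, na.rm = TRUE))
    dist[!is.finite(dist)] <- Inf
    nb <- donors[order(dist)[seq_len(min(k, length(donors)))]]
    v <- if (categorical) {
      tab <- sort(table(yv[nb]), decreasing = TRUE)
      as.numeric(names(tab)[1])
    } else mean(yv[nb])
    e$values[[target]][i] <- v
    e$mask[i, target] <- FALSE
  }
  e
}

#' Complete a dataset with a fitted imputer
#'
#' Applies the fill rules / models fitted by [fit_imputer()] to `ds` (which
#' may be the training data itself or held-out rows). Model-based frameworks
#' process attributes in the fitting order, make each completed attribute
#' available to later ones, temporarily mean-fill remaining design gaps with
#' the training column means, and snap categorical predictions to valid
#' codes. Attributes incomplete here but complete during fitting fall back to
#' the training mean/mode.
#'
#' @param imp An `sga_imputer`.
#' @param ds An `sga_dataset`.
#' @return A complete `sga_dataset`.
#' @export
apply_imputer <- function(imp, ds) {
  kinds <- attr_kind(ds)
  if (imp$method %in% c("mean", "median", "mode")) {
    vals <- ds$values
    for (nm in predictor_attrs(ds)) {
      na <- ds$mask[, nm]
      if (any(na)) vals[[nm]][na] <- imp$fills[[nm]]
    }
    return(dataset(vals, class_attr = class_attr(ds), schema = ds$schema))
  }
  e <- encode_with_codebook(ds, imp$codebook)
  if (imp$method == "knn") {
    for (nm in predictor_attrs(ds))
      if (any(e$mask[, nm]))
        e <- knn_fill_from_pool(e, imp$pool, nm, imp$k, kinds)
  } else {
    for (nm in imp$order) {
      miss <- which(e$mask[, nm])
      if (!length(miss)) next
      m <- imp$models[[nm]]
      predictors <- m$predictors
      x <- as.matrix(e$values[, predictors, drop = FALSE])
      storage.mode(x) <- "double"
      for (j in seq_along(predictors)) {  # design gaps -> training means
        gap <- is.na(x[, j])
        if (any(gap)) x[gap, j] <- imp$fill_mu[[predictors[j]]]
      }
      pred <- if (imp$method == "sga") predict(m$model, x[miss, , drop = FALSE])
              else predict_imputer_model(m, x[miss, , drop = FALSE])
      if (kinds[nm] == "categorical") {
        codes <- if (imp$method == "sga")
          sort(unique(imp$pool$values[[nm]])) else m$codes
        pred <- snap_to_codes(pred, codes)
      }
      e$values[[nm]][miss] <- pred
      e$mask[miss, nm] <- FALSE
    }
    # attributes with no fitted model (complete at fit time): training fill
    for (nm in predictor_attrs(ds)) {
      miss <- which(e$mask[, nm])
      if (!length(miss)) next
      fill <- if (!is.null(imp$fill_mu) && kinds[nm] == "numeric")
        imp$fill_mu[[nm]] else {
          f <- imp$fills[[nm]]
          if (kinds[nm] == "categorical")
            as.numeric(match(f, imp$codebook[[nm]]) - 1L) else f
        }
      if (kinds[nm] == "categorical")
        fill <- snap_to_codes(fill, sort(unique(e$values[[nm]][!is.na(e$values[[nm]])])))
      e$values[[nm]][miss] <- fill
      e$mask[miss, nm] <- FALSE
    }
  }
  out <- decode_categoricals(e, imp$codebook)
  dataset(out$values, class_attr = class_attr(ds), schema = ds$schema)
}

#' Cross-validated evaluation of one imputer-classifier framework
#'
#' Stratified k-fold protocol with strict fold hygiene: within each fold the
#' imputer is fitted on the training rows only, the CART tree is induced on
#' the completed training fold, and the completed test fold (imputed by the
#' training-fold-fitted imputer) is scored. For the `drop` framework,
#' incomplete rows are deleted within each fold independently and test
#' metrics are computed over the surviving test rows.
#'
#' @param ds An `sga_dataset`.
#' @param framework One of `"drop"`, `"mean"`, `"mode"`, `"median"`,
#'   `"knn"`, `"lr"`, `"nn"`, `"svr"`, `"sga"`.
#' @param k Folds (>= 2).
#' @param seed Seed for fold assignment and stochastic imputers.
#' @param ccp_alpha Cost-complexity pruning penalty for the tree.
#' @param knn_k Neighbours for KNN stages.
#' @param ga [ga_config()] for the `sga` framework.
#' @param folds Optional precomputed fold assignment (used by
#'   [compare_frameworks()] so every framework sees identical folds).
#' @return An `eval_report`: list with `framework`, `per_fold` (metrics per
#'   fold), `means`, `seed`, and an `audit` element recording, per fold, the
#'   original row indices used for imputer fitting and the test rows.
#' @export
kfold_eval <- function(ds, framework, k = 5, seed = 1, ccp_alpha = 0,
                       knn_k = 5, ga = ga_config(), folds = NULL) {
  framework <- match.arg(framework, FRAMEWORKS)
  y <- ds$values[[class_attr(ds)]]
  stopifnot(k >= 2, nrow(ds$values) >= k)
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  subset_ds <- function(rows)
    structure(list(values = ds$values[rows, , drop = FALSE],
                   mask = ds$mask[rows, , drop = FALSE],
                   schema = ds$schema), class = "sga_dataset")
  per_fold <- NULL
  audit <- list()
  for (f in seq_len(k)) {
    tr_idx <- which(folds != f); te_idx <- which(folds == f)
    train <- subset_ds(tr_idx); test <- subset_ds(te_idx)
    if (framework == "drop") {
      fit_rows <- tr_idx[rowSums(train$mask) == 0]
      train_c <- baseline_impute(train, "drop")
      keep_te <- rowSums(test$mask) == 0
      test_c <- subset_ds(te_idx[keep_te])
    } else {
      imp <- fit_imputer(framework, train, k = knn_k,
                         seed = derive_seed(seed, f), ga = ga,
                         row_ids = tr_idx)
      fit_rows <- imp$rows_touched
      train_c <- if (framework == "sga") imp$train_completed
                 else apply_imputer(imp, train)
      test_c <- apply_imputer(imp, test)
    }
    tree <- induce_tree(train_c)
    if (ccp_alpha > 0) tree <- ccp_prune(tree, ccp_alpha)
    if (nrow(test_c$values) == 0) {
      met <- c(accuracy = NA_real_, precision = NA_real_,
               recall = NA_real_, f_measure = NA_real_)
    } else {
      pred <- predict(tree, test_c$values[, predictor_attrs(ds),
                                          drop = FALSE])
      cm <- confusion_counts(test_c$values[[class_attr(ds)]], pred,
                             classes = sort(unique(y)))
      met <- classification_metrics(cm)
    }
    per_fold <- rbind(per_fold, data.frame(fold = f, t(met)))
    audit[[f]] <- list(fit_rows = fit_rows, train_rows = tr_idx,
                       test_rows = te_idx)
  }
  structure(list(framework = framework,
                 per_fold = per_fold,
                 means = colMeans(per_fold[, -1, drop = FALSE],
                                  na.rm = TRUE),
                 seed = seed, audit = audit),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> framework = %s (%d folds)\n", x$framework,
              nrow(x$per_fold)))
  print(round(x$means, 4))
  invisible(x)
}

#' Compare imputer-classifier frameworks on identical folds
#'
#' Runs [kfold_eval()] for each framework with one shared stratified fold
#' assignment, so differences reflect the imputation treatment only.
#'
#' @inheritParams kfold_eval
#' @param frameworks Character vector of framework names.
#' @return A `framework_comparison`: list with `reports` (named
#'   `eval_report`s) and `summary` (one row of mean metrics per framework).
#' @export
compare_frameworks <- function(ds, frameworks = FRAMEWORKS, k = 5, seed = 1,
                               ccp_alpha = 0, knn_k = 5, ga = ga_config()) {
  frameworks <- vapply(frameworks, match.arg, character(1),
                       choices = FRAMEWORKS)
  y <- ds$values[[class_attr(ds)]]
  folds <- stratified_folds(y, k, seed)
  reports <- lapply(frameworks, function(fw)
    kfold_eval(ds, fw, k = k, seed = seed, ccp_alpha = ccp_alpha,
               knn_k = knn_k, ga = ga, folds = folds))
  names(reports) <- frameworks
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(framework = r$framework, t(r$means))))
  rownames(summary) <- NULL
  structure(list(reports = reports, summary = summary, seed = seed),
            class = "framework_comparison")
}

#' @export
print.framework_comparison <- function(x, ...) {
  cat("<framework_comparison>\n")
  print(transform(x$summary,
                  accuracy = round(accuracy, 4),
                  precision = round(precision, 4),
                  recall = round(recall, 4),
                  f_measure = round(f_measure, 4)), row.names = FALSE)
  invisible(x)
}

#' Missingness sweep experiment
#'
#' Injects MAR missingness into a complete dataset at each level, runs
#' [compare_frameworks()] on the result, and collects the mean metrics,
#' tracing how each framework degrades as missingness grows. One fully
#' observed numeric predictor is held out as the MAR driver (masking
#' probabilities depend on its observed values) and every other non-class
#' attribute is masked at the stated rate; driving the mask from the class
#' label instead would make the missingness pattern itself class-informative
#' and reward imputers for exploiting it.
#'
#' @param complete_ds A complete `sga_dataset` (no masked cells).
#' @param frameworks Framework names.
#' @param levels Missingness levels, see [sweep_levels()].
#' @param drivers MAR driver attribute(s); default: the first numeric
#'   predictor.
#' @param k,seed,ccp_alpha,knn_k,ga Passed to [compare_frameworks()].
#' @return A `sweep_result` data.frame: one row per framework x level with
#'   the four mean metrics.
#' @export
missingness_sweep <- function(complete_ds, frameworks = FRAMEWORKS,
                              levels = sweep_levels(), drivers = NULL,
                              k = 5, seed = 1,
                              ccp_alpha = 0, knn_k = 5, ga = ga_config()) {
  if (n_missing(complete_ds) > 0)
    stop("sweep requires a complete input dataset", call. = FALSE)
  levels <- sweep_levels(levels)
  if (is.null(drivers)) {
    sc <- complete_ds$schema
    num_pred <- sc$name[sc$kind == "numeric" & sc$role == "predictor"]
    drivers <- if (length(num_pred)) num_pred[1]
               else class_attr(complete_ds)
  }
  targets <- setdiff(predictor_attrs(complete_ds), drivers)
  if (!length(targets))
    stop("no non-driver attributes left to mask", call. = FALSE)
  out <- NULL
  for (i in seq_along(levels)) {
    lv <- levels[i]
    masked <- inject_mar(complete_ds,
                         mar_spec(lv, drivers = drivers,
                                  seed = derive_seed(seed, i)),
                         targets = targets)
    cmp <- compare_frameworks(masked, frameworks, k = k,
                              seed = derive_seed(seed, 100 + i),
                              ccp_alpha = ccp_alpha, knn_k = knn_k, ga = ga)
    out <- rbind(out, cbind(level = lv, cmp$summary))
  }
  structure(out, class = c("sweep_result", "data.frame"),
            levels = levels, seed = seed)
}
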