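read_input <- function(input, dialect = "csv", class_attr = NULL) {
  load_table(input, dialect = dialect, class_attr = class_attr)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the imputation pipeline on a file
#'
#' Reads a delimited table, runs the adaptive GA-optimized imputation and
#' writes the completed table (`completed.csv`) plus per-attribute
#' diagnostics (`diagnostics.json`: strategy dispatched, chosen kernel and
#' hyperparameters, iterations, cross-validated MSE) to `out_dir`. A
#' complete input is copied through with a warning.
#'
#' @param input Input file path.
#' @param out_dir Output directory (created if needed).
#' @param dialect `"csv"` or `"keel"`.
#' @param class_attr Class attribute (csv; default last column).
#' @param tau1,tau2 Missingness regime thresholds.
#' @param k KNN neighbours.
#' @param ccp_alpha Pruning penalty (classification commands).
#' @param folds Cross-validation folds (benchmark/sweep commands).
#' @param seed Master seed; all randomness flows from it.
#' @param ga [ga_config()] (its seed is overridden by `seed`).
#' @return Invisibly, the paths written.
#' @export
run_impute <- function(input, out_dir, dialect = "csv", class_attr = NULL,
                       tau1 = 0.10, tau2 = 0.25, k = 5, seed = 1,
                       ga = ga_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_input(input, dialect, class_attr)
  if (n_missing(ds) == 0) warning("nothing to impute: input is complete")
  if (!is.null(ga)) ga$seed <- seed
  res <- impute_dataset(ds, ga = ga, tau1 = tau1, tau2 = tau2, k = k)
  out_csv <- file.path(out_dir, "completed.csv")
  out_json <- file.path(out_dir, "diagnostics.json")
  write_table(res$dataset, out_csv)
  write_json_file(list(seed = seed, tau1 = tau1, tau2 = tau2, k = k,
                       attributes = res$diagnostics), out_json)
  message(sprintf("imputed %d attribute(s) -> %s", nrow(res$diagnostics),
                  out_csv))
  invisible(c(completed = out_csv, diagnostics = out_json))
}

#' @rdname run_impute
#' @export
run_classify <- function(input, out_dir, dialect = "csv", class_attr = NULL,
                         ccp_alpha = 0, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_input(input, dialect, class_attr)
  if (n_missing(ds) > 0)
    stop("input contains missing cells; run the impute command first",
         call. = FALSE)
  tree <- induce_tree(ds)
  if (ccp_alpha > 0) tree <- ccp_prune(tree, ccp_alpha)
  tree_path <- file.path(out_dir, "tree.json")
  rules_path <- file.path(out_dir, "rules.txt")
  pred_path <- file.path(out_dir, "predictions.csv")
  tree_to_json(tree, tree_path)
  writeLines(export_rules(tree), rules_path)
  pred <- predict(tree, ds$values[, predictor_attrs(ds), drop = FALSE])
  write.csv(data.frame(row = seq_along(pred), predicted = pred,
                       actual = ds$values[[class_attr(ds)]]),
            pred_path, row.names = FALSE)
  message(sprintf("tree with %d leaves (ccp_alpha = %g) -> %s",
                  tree$n_leaves, ccp_alpha, tree_path))
  invisible(c(tree = tree_path, rules = rules_path,
              predictions = pred_path))
}

#' @rdname run_impute
#' @param frameworks Frameworks to compare.
#' @export
run_benchmark <- function(input, out_dir, dialect = "csv",
                          class_attr = NULL, frameworks = FRAMEWORKS,
                          folds = 5, ccp_alpha = 0, k = 5, seed = 1,
                          ga = ga_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_input(input, dialect, class_attr)
  cmp <- compare_frameworks(ds, frameworks, k = folds, seed = seed,
                            ccp_alpha = ccp_alpha, knn_k = k, ga = ga)
  per_fold <- do.call(rbind, lapply(cmp$reports, function(r)
    cbind(framework = r$framework, r$per_fold)))
  csv_path <- file.path(out_dir, "benchmark.csv")
  json_path <- file.path(out_dir, "benchmark.json")
  write.csv(per_fold, csv_path, row.names = FALSE)
  write_json_file(list(seed = seed, folds = folds, summary = cmp$summary),
                  json_path)
  message(sprintf("benchmarked %d framework(s) -> %s", length(cmp$reports),
                  csv_path))
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname run_impute
#' @param levels Missingness levels for the sweep.
#' @export
run_sweep <- function(input, out_dir, dialect = "csv", class_attr = NULL,
                      frameworks = FRAMEWORKS, levels = sweep_levels(),
                      folds = 5, ccp_alpha = 0, k = 5, seed = 1,
                      ga = ga_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_input(input, dialect, class_attr)
  sw <- missingness_sweep(ds, frameworks, levels = levels, k = folds,
                          seed = seed, ccp_alpha = ccp_alpha, knn_k = k,
                          ga = ga)
  # long format: framework, level, metric, value
  long <- do.call(rbind, lapply(c("accuracy", "precision", "recall",
                                  "f_measure"), function(m)
    data.frame(framework = sw$framework, level = sw$level, metric = m,
               value = sw[[m]])))
  csv_path <- file.path(out_dir, "sweep.csv")
  write.csv(long, csv_path, row.names = FALSE)
  message(sprintf("sweep over %d level(s) -> %s",
                  length(attr(sw, "levels")), csv_path))
  invisible(c(csv = csv_path))
}

#' @rdname run_impute
#' @param which Synthetic preset: `1` (numeric, high missingness) or `2`
#'   (mixed, moderate missingness).
#' @param n Optional row-count override of the preset.
#' @export
run_synth <- function(out_dir, which = 1, n = NULL, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- if (which == 1) spec_synthetic1(seed) else spec_synthetic2(seed)
  if (!is.null(n)) spec$n <- n
  gen <- if (spec$n_categorical > 0) gen_mixed(spec) else gen_numeric(spec)
  paths <- c(complete = file.path(out_dir, "complete.csv"),
             masked = file.path(out_dir, "masked.csv"),
             truth = file.path(out_dir, "truth.csv"),
             spec = file.path(out_dir, "spec.json"))
  write_table(gen$complete, paths["complete"])
  write_table(gen$masked, paths["masked"])
  write.csv(gen$truth, paths["truth"], row.names = FALSE)
  write_json_file(unclass(spec), paths["spec"])
  message(sprintf("synthetic dataset %d (n = %d) -> %s", which, spec$n,
                  out_dir))
  invisible(paths)
}
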