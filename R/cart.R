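#' Gini impurity of a node
#'
#' `1 - sum((count_i / total)^2)` over the class counts: 0 for a pure node,
#' at most `1 - 1/k` for `k` classes.
#'
#' @param counts Non-negative class counts with positive total.
#' @return The Gini index.
#' @examples
#' gini_index(c(16, 2))  # 0.198 to 3 decimals
#' gini_index(c(93, 1))  # 0.021 to 3 decimals
#' @export
gini_index <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("undefined node: total count is zero", call. = FALSE)
  1 - sum((counts / total)^2)
}

#' Weighted Gini impurity of a binary split
#'
#' Size-weighted average of the child impurities,
#' `sum(|D_i|/|D| * GI(D_i))` over the two partitions.
#'
#' @param left,right Class-count vectors of the two children (both
#'   non-empty).
#' @return The weighted child impurity; the impurity reduction of the split
#'   is the parent Gini minus this value.
#' @export
gini_split <- function(left, right) {
  nl <- sum(left); nr <- sum(right)
  if (nl == 0 || nr == 0) stop("invalid split: empty side", call. = FALSE)
  (nl * gini_index(left) + nr * gini_index(right)) / (nl + nr)
}

# All binary subset partitions {S, complement} of `cats` (one side listed);
# beyond 10 categories only one-vs-rest splits are enumerated to bound the
# 2^(c-1) blow-up.
category_subsets <- function(cats) {
  c <- length(cats)
  if (c <= 1) return(list())
  if (c > 10) return(lapply(cats, function(v) v))
  out <- list()
  for (m in 1:(2^(c - 1) - 1))
    out[[m]] <- cats[as.logical(bitwAnd(m, 2^(seq_len(c) - 1)))]
  out
}

#' Exhaustive best-split search at a node
#'
#' For numeric attributes every midpoint between adjacent distinct sorted
#' values is evaluated; for nominal attributes every binary partition of the
#' observed categories (one-vs-rest beyond 10 categories). Returns the split
#' maximizing the impurity reduction `GI(D) - GI_t(D)`; ties are broken by
#' lower attribute index, then lower threshold / earlier subset.
#'
#' @param x data.frame of predictor columns (complete).
#' @param y Class label vector.
#' @param kinds Character vector (`"numeric"`/`"categorical"`) per column of
#'   `x`; defaults to numeric for numeric columns.
#' @return List with `attribute`, `kind`, `threshold` (numeric splits) or
#'   `subset` (nominal splits; left branch takes membership), and
#'   `reduction`; or `NULL` when no valid split exists.
#' @export
best_split <- function(x, y, kinds = NULL) {
  if (is.null(kinds))
    kinds <- ifelse(vapply(x, is.numeric, logical(1)), "numeric",
                    "categorical")
  classes <- sort(unique(y))
  if (nrow(x) < 2 || length(classes) < 2) return(NULL)
  parent <- gini_index(tabulate(match(y, classes), length(classes)))
  yi <- match(y, classes)
  best <- NULL
  consider <- function(attr_j, kind, thr, subset, red) {
    if (is.null(best) || red > best$reduction + 1e-12) {
      best <<- list(attribute = names(x)[attr_j], kind = kind,
                    threshold = thr, subset = subset, reduction = red)
    }
  }
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (kinds[j] == "numeric") {
      o <- order(v)
      vs <- v[o]; ys <- yi[o]
      distinct <- which(diff(vs) > 0)
      if (!length(distinct)) next
      # cumulative class counts over the sorted rows
      cum <- apply(sapply(seq_along(classes), function(k) ys == k), 2, cumsum)
      cum <- matrix(cum, ncol = length(classes))
      totals <- cum[length(ys), ]
      for (i in distinct) {
        thr <- (vs[i] + vs[i + 1]) / 2
        red <- parent - gini_split(cum[i, ], totals - cum[i, ])
        consider(j, "numeric", thr, NULL, red)
      }
    } else {
      cats <- sort(unique(v))
      for (sub in category_subsets(cats)) {
        inL <- v %in% sub
        if (!any(inL) || all(inL)) next
        lc <- tabulate(yi[inL], length(classes))
        rc <- tabulate(yi[!inL], length(classes))
        red <- parent - gini_split(lc, rc)
        consider(j, "categorical", NULL, sub, red)
      }
    }
  }
  best
}

new_leaf <- function(counts, classes) {
  list(kind = "leaf", counts = counts,
       gini = gini_index(counts),
       label = classes[which.max(counts)])  # ties: lowest class index
}

grow_node <- function(x, y, classes, kinds, min_split, min_leaf, max_depth,
                      depth) {
  counts <- tabulate(match(y, classes), length(classes))
  if (length(unique(y)) == 1 || nrow(x) < min_split || depth >= max_depth)
    return(new_leaf(counts, classes))
  sp <- best_split(x, y, kinds)
  if (is.null(sp) || sp$reduction <= 0) return(new_leaf(counts, classes))
  inL <- if (sp$kind == "numeric") x[[sp$attribute]] <= sp$threshold
         else x[[sp$attribute]] %in% sp$subset
  if (sum(inL) < min_leaf || sum(!inL) < min_leaf)
    return(new_leaf(counts, classes))
  list(kind = "internal", counts = counts, gini = gini_index(counts),
       label = classes[which.max(counts)],
       split = sp[c("attribute", "kind", "threshold", "subset", "reduction")],
       left = grow_node(x[inL, , drop = FALSE], y[inL], classes, kinds,
                        min_split, min_leaf, max_depth, depth + 1),
       right = grow_node(x[!inL, , drop = FALSE], y[!inL], classes, kinds,
                         min_split, min_leaf, max_depth, depth + 1))
}

tree_stats <- function(node) {
  if (node$kind == "leaf") return(c(leaves = 1, depth = 0))
  l <- tree_stats(node$left); r <- tree_stats(node$right)
  c(leaves = unname(l["leaves"] + r["leaves"]),
    depth = unname(1 + max(l["depth"], r["depth"])))
}

#' Induce a binary CART classification tree
#'
#' Recursive partitioning with Gini-index splitting: a pure node becomes a
#' leaf with that class; a node with no valid split (or one hitting the
#' stopping parameters) becomes a majority-class leaf (ties broken by lowest
#' class index); otherwise the node splits by [best_split()] and both
#' children are grown recursively. Numeric conditions route `value <=
#' threshold` to the left child. Complexity is controlled afterwards by
#' [ccp_prune()], not by the growth-stage stopping parameters.
#'
#' @param ds A complete `sga_dataset`, or a data.frame whose last column (or
#'   `class_attr`) is the class.
#' @param class_attr Class attribute when `ds` is a data.frame.
#' @param min_split Minimum rows needed to attempt a split (default 2).
#' @param min_leaf Minimum rows per child (default 1).
#' @param max_depth Depth cap (default unlimited).
#' @return An `sga_tree` with `root`, `classes`, `n_leaves`, `depth` and
#'   `ccp_alpha` (0 for an unpruned tree).
#' @examples
#' ds <- gen_tiny_fixture(1)
#' tr <- induce_tree(baseline_impute(ds, "mean"))
#' export_rules(tr)
#' @export
induce_tree <- function(ds, class_attr = NULL, min_split = 2, min_leaf = 1,
                        max_depth = Inf) {
  if (inherits(ds, "sga_dataset")) {
    if (n_missing(ds) > 0)
      stop("training data contain missing cells; impute first", call. = FALSE)
    cls <- sgadt::class_attr(ds)
    x <- ds$values[, predictor_attrs(ds), drop = FALSE]
    y <- ds$values[[cls]]
    kinds <- attr_kind(ds)[predictor_attrs(ds)]
  } else {
    df <- as.data.frame(ds)
    cls <- if (is.null(class_attr)) names(df)[ncol(df)] else class_attr
    y <- df[[cls]]
    x <- df[, setdiff(names(df), cls), drop = FALSE]
    kinds <- ifelse(vapply(x, is.numeric, logical(1)), "numeric",
                    "categorical")
  }
  if (length(y) == 0) stop("empty training set", call. = FALSE)
  classes <- sort(unique(y))
  root <- grow_node(x, y, classes, kinds, min_split, min_leaf, max_depth, 0)
  st <- tree_stats(root)
  structure(list(root = root, classes = classes,
                 n_leaves = unname(st["leaves"]), depth = unname(st["depth"]),
                 ccp_alpha = 0), class = "sga_tree")
}

# Per-node resubstitution misclassification cost R(t) = errors(t) / n_root,
# subtree cost R(T_t) and leaf count, used for weakest-link pruning.
node_risk <- function(node, n_root) {
  (sum(node$counts) - max(node$counts)) / n_root
}

subtree_risk <- function(node, n_root) {
  if (node$kind == "leaf")
    return(c(risk = node_risk(node, n_root), leaves = 1))
  l <- subtree_risk(node$left, n_root); r <- subtree_risk(node$right, n_root)
  c(risk = unname(l["risk"] + r["risk"]),
    leaves = unname(l["leaves"] + r["leaves"]))
}

# smallest effective alpha g(t) over internal nodes, with its node path
weakest_link <- function(node, n_root, path = character(0)) {
  if (node$kind == "leaf") return(NULL)
  st <- subtree_risk(node, n_root)
  g <- (node_risk(node, n_root) - st["risk"]) / (st["leaves"] - 1)
  here <- list(g = unname(g), path = path)
  for (side in c("left", "right")) {
    cand <- weakest_link(node[[side]], n_root, c(path, side))
    if (!is.null(cand) && cand$g < here$g - 1e-12) here <- cand
  }
  here
}

collapse_at <- function(node, path, classes) {
  if (!length(path)) return(new_leaf(node$counts, classes))
  node[[path[1]]] <- collapse_at(node[[path[1]]], path[-1], classes)
  node
}

#' Minimal cost-complexity (weakest-link) pruning
#'
#' Iteratively collapses the internal node with the smallest effective alpha
#' `g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)` — where `R` is the
#' training misclassification cost — while `g(t) <= alpha`. `alpha = 0`
#' removes only zero-gain subtrees; `alpha = Inf` collapses the tree to the
#' single majority-class leaf. Larger alpha trades accuracy for simplicity:
#' the leaf count is non-increasing in alpha.
#'
#' @param tree An `sga_tree`.
#' @param alpha Non-negative complexity penalty.
#' @return The pruned `sga_tree` with `ccp_alpha` recorded.
#' @export
ccp_prune <- function(tree, alpha) {
  stopifnot(alpha >= 0)
  root <- tree$root
  n_root <- sum(root$counts)
  repeat {
    if (root$kind == "leaf") break
    wl <- weakest_link(root, n_root)
    if (is.null(wl) || wl$g > alpha) break
    root <- collapse_at(root, wl$path, tree$classes)
  }
  st <- tree_stats(root)
  structure(list(root = root, classes = tree$classes,
                 n_leaves = unname(st["leaves"]), depth = unname(st["depth"]),
                 ccp_alpha = alpha), class = "sga_tree")
}

route_row <- function(node, row) {
  while (node$kind == "internal") {
    sp <- node$split
    v <- row[[sp$attribute]]
    if (is.null(v) || (length(v) == 1 && is.na(v)))
      stop("missing value for split attribute '", sp$attribute,
           "'; prediction requires completed data", call. = FALSE)
    goL <- if (sp$kind == "numeric") v <= sp$threshold else v %in% sp$subset
    node <- if (goL) node$left else node$right
  }
  node
}

#' @rdname induce_tree
#' @param object An `sga_tree`.
#' @param newdata data.frame (or `sga_dataset`) providing every attribute the
#'   tree splits on, with no missing values at those attributes.
#' @param ... Unused.
#' @return `predict` returns the vector of predicted class labels.
#' @export
predict.sga_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "sga_dataset")) newdata <- newdata$values
  if (!nrow(newdata)) return(object$classes[0])
  out <- vapply(seq_len(nrow(newdata)), function(i)
    as.character(route_row(object$root, newdata[i, , drop = FALSE])$label),
    character(1))
  if (is.numeric(object$classes)) as.numeric(out) else out
}

condition_text <- function(sp, side) {
  if (sp$kind == "numeric") {
    sprintf("%s %s %.6g", sp$attribute, if (side == "left") "<=" else ">",
            sp$threshold)
  } else {
    vals <- paste(sp$subset, collapse = ",")
    sprintf("%s %s {%s}", sp$attribute,
            if (side == "left") "in" else "not in", vals)
  }
}

collect_rules <- function(node, conds) {
  if (node$kind == "leaf") {
    lhs <- if (length(conds)) paste(conds, collapse = " AND ") else "TRUE"
    return(sprintf("IF %s THEN class = %s  [counts = %s, gini = %.3f]",
                   lhs, node$label, paste(node$counts, collapse = "/"),
                   node$gini))
  }
  c(collect_rules(node$left, c(conds, condition_text(node$split, "left"))),
    collect_rules(node$right, c(conds, condition_text(node$split, "right"))))
}

#' Export a tree as textual decision rules
#'
#' One rule per leaf: the conjunction of root-to-leaf conditions, the
#' predicted class, the leaf class counts and its Gini impurity (3 decimal
#' places). Every row of the training data satisfies exactly one rule.
#'
#' @param tree An `sga_tree`.
#' @return Character vector of rules (length = leaf count).
#' @export
export_rules <- function(tree) {
  collect_rules(tree$root, character(0))
}

node_to_list <- function(node) {
  base <- list(kind = node$kind, counts = node$counts, gini = node$gini,
               label = node$label)
  if (node$kind == "leaf") return(base)
  base$split <- node$split[!vapply(node$split, is.null, logical(1))]
  base$left <- node_to_list(node$left)
  base$right <- node_to_list(node$right)
  base
}

#' Serialize a tree to JSON
#'
#' @param tree An `sga_tree`.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string (invisibly when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(ccp_alpha = tree$ccp_alpha, classes = tree$classes,
              n_leaves = tree$n_leaves, depth = tree$depth,
              root = node_to_list(tree$root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.sga_tree <- function(x, ...) {
  cat(sprintf("<sga_tree> %d leaves, depth %d, ccp_alpha = %g\n",
              x$n_leaves, x$depth, x$ccp_alpha))
  cat(paste0("  ", export_rules(x), collapse = "\n"), "\n")
  invisible(x)
}
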