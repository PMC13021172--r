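#' @importFrom stats complete.cases cor lm median plogis predict quantile rbinom
#'   rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head
NULL

# Default tokens treated as missing when reading delimited text.
MISSING_TOKENS <- c("?", "", "NA", "NaN")

#' Construct a tabular dataset with an explicit missingness mask
#'
#' The central container of the package: an `n x p` table of cell values, a
#' boolean mask marking missing cells (`TRUE` = missing), and an attribute
#' schema designating exactly one class attribute. Missingness is confined to
#' non-class (predictor) attributes; the class column must be fully observed.
#'
#' @param values A data.frame. Numeric columns are treated as numeric
#'   attributes, everything else as categorical. Missing cells are `NA`.
#' @param class_attr Name of the class attribute. Defaults to the last column.
#' @param schema Optional schema data.frame with columns `name`, `kind`
#'   (`"numeric"`/`"categorical"`) and `role` (`"predictor"`/`"class"`). If
#'   omitted it is derived from `values` and `class_attr`.
#' @param mask Optional logical matrix of the same shape as `values`; defaults
#'   to `is.na(values)`.
#' @return An object of class `sga_dataset` with elements `values`, `mask`,
#'   `schema`.
#' @examples
#' df <- data.frame(a = c(1, NA, 3), b = c(2, 4, 6), y = c("p", "q", "p"))
#' ds <- dataset(df, class_attr = "y")
#' n_missing(ds)
#' @export
dataset <- function(values, class_attr = NULL, schema = NULL, mask = NULL) {
  if (!is.data.frame(values)) values <- as.data.frame(values)
  if (nrow(values) == 0L) stop("dataset has zero data rows", call. = FALSE)
  nm <- names(values)
  if (anyDuplicated(nm)) stop("duplicate column names: ",
                              paste(nm[duplicated(nm)], collapse = ", "),
                              call. = FALSE)
  if (is.null(schema)) {
    if (is.null(class_attr)) class_attr <- nm[length(nm)]
    if (!class_attr %in% nm) stop("class attribute '", class_attr,
                                  "' not found", call. = FALSE)
    kind <- vapply(values, function(col) if (is.numeric(col)) "numeric"
                   else "categorical", character(1))
    schema <- data.frame(
      name = nm, kind = unname(kind),
      role = ifelse(nm == class_attr, "class", "predictor"),
      stringsAsFactors = FALSE)
  }
  # factors are stored as character so codes stay under our control
  for (j in seq_along(values))
    if (is.factor(values[[j]])) values[[j]] <- as.character(values[[j]])
  if (is.null(mask)) {
    mask <- is.na(as.matrix(values))
  } else {
    mask <- as.matrix(mask)
  }
  dimnames(mask) <- list(NULL, nm)
  ds <- structure(list(values = values, mask = mask, schema = schema),
                  class = "sga_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  stopifnot(is.data.frame(ds$values), is.matrix(ds$mask))
  if (!all(dim(ds$mask) == dim(ds$values)))
    stop("mask and values have different shapes", call. = FALSE)
  sc <- ds$schema
  if (sum(sc$role == "class") != 1L)
    stop("schema must designate exactly one class attribute", call. = FALSE)
  if (anyDuplicated(sc$name))
    stop("schema names are not unique", call. = FALSE)
  if (!identical(sc$name, names(ds$values)))
    stop("schema names do not match value columns", call. = FALSE)
  cls <- class_attr(ds)
  if (any(ds$mask[, cls]))
    stop("class attribute '", cls, "' contains missing cells", call. = FALSE)
  if (any(is.na(ds$values[[cls]])))
    stop("class attribute '", cls, "' contains NA values", call. = FALSE)
  invisible(ds)
}

#' @rdname dataset
#' @param ds,x An `sga_dataset`.
#' @export
class_attr <- function(ds) ds$schema$name[ds$schema$role == "class"]

#' @rdname dataset
#' @export
predictor_attrs <- function(ds) ds$schema$name[ds$schema$role == "predictor"]

#' @rdname dataset
#' @export
attr_kind <- function(ds) setNames(ds$schema$kind, ds$schema$name)

#' @rdname dataset
#' @export
n_missing <- function(ds) sum(ds$mask)

#' @rdname dataset
#' @param ... Unused.
#' @export
print.sga_dataset <- function(x, ...) {
  cat(sprintf("<sga_dataset> %d rows x %d attributes (%d predictors + class '%s')\n",
              nrow(x$values), ncol(x$values),
              length(predictor_attrs(x)), class_attr(x)))
  cat(sprintf("  missing cells: %d (%.1f%% of predictor cells)\n", n_missing(x),
              100 * n_missing(x) /
                max(1, nrow(x$values) * length(predictor_attrs(x)))))
  invisible(x)
}

#' Read a delimited table into a dataset
#'
#' Supports plain CSV (header row required; class attribute defaults to the
#' last column) and KEEL-style annotated data files (`@attribute`
#' declarations, an `@data` block, and `?` as the missing token; the class
#' attribute is the declared `@output`).
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"keel"`.
#' @param class_attr Class attribute name (csv only; default: last column).
#' @param missing_tokens Strings treated as missing cells.
#' @return An [dataset()] object.
#' @export
load_table <- function(path, dialect = c("csv", "keel"), class_attr = NULL,
                       missing_tokens = MISSING_TOKENS) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") load_csv(path, class_attr, missing_tokens)
  else load_keel(path, missing_tokens)
}

parse_numeric_column <- function(col, declared = FALSE, name = "") {
  obs <- !is.na(col)
  suppressWarnings(num <- as.numeric(col))
  bad <- obs & is.na(num)
  if (any(bad)) {
    if (declared)
      stop("unparseable numeric cell in numeric-declared column '", name,
           "': '", col[which(bad)[1]], "'", call. = FALSE)
    return(NULL) # not numeric after all
  }
  num
}

load_csv <- function(path, class_attr, missing_tokens) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL)
  if (nrow(raw) == 0L) stop("zero data rows in ", path, call. = FALSE)
  if (anyDuplicated(names(raw)))
    stop("duplicate column names in ", path, call. = FALSE)
  for (j in seq_along(raw)) {
    col <- trimws(raw[[j]])
    col[col %in% missing_tokens] <- NA_character_
    num <- parse_numeric_column(col)
    raw[[j]] <- if (is.null(num)) col else num
  }
  dataset(raw, class_attr = class_attr)
}

load_keel <- function(path, missing_tokens) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  decl <- grep("^@attribute", lines, ignore.case = TRUE, value = TRUE)
  if (length(decl) == 0L) stop("no @attribute declarations in ", path,
                               call. = FALSE)
  att_name <- character(0); att_kind <- character(0)
  for (d in decl) {
    body <- trimws(sub("^@attribute\\s+", "", d, ignore.case = TRUE))
    nm <- sub("^([^\\s{\\[]+).*$", "\\1", body, perl = TRUE)
    rest <- trimws(substring(body, nchar(nm) + 1L))
    kind <- if (grepl("^\\{", rest)) "categorical"
            else if (grepl("^(real|integer|numeric)", rest,
                           ignore.case = TRUE)) "numeric"
            else "categorical"
    att_name <- c(att_name, nm); att_kind <- c(att_kind, kind)
  }
  if (anyDuplicated(att_name))
    stop("duplicate attribute names in ", path, call. = FALSE)
  out_line <- grep("^@output", lines, ignore.case = TRUE, value = TRUE)
  cls <- if (length(out_line)) {
    trimws(sub("^@outputs?\\s+", "", out_line[1], ignore.case = TRUE))
  } else att_name[length(att_name)]
  data_at <- grep("^@data", lines, ignore.case = TRUE)
  if (length(data_at) == 0L) stop("no @data block in ", path, call. = FALSE)
  body <- lines[(data_at[1] + 1L):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("zero data rows in ", path, call. = FALSE)
  cells <- strsplit(body, ",")
  if (any(lengths(cells) != length(att_name)))
    stop("row with wrong field count in ", path, call. = FALSE)
  tab <- as.data.frame(do.call(rbind, lapply(cells, trimws)),
                       stringsAsFactors = FALSE)
  names(tab) <- att_name
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    col[col %in% missing_tokens] <- NA_character_
    if (att_kind[j] == "numeric") {
      tab[[j]] <- parse_numeric_column(col, declared = TRUE,
                                       name = att_name[j])
    } else tab[[j]] <- col
  }
  dataset(tab, class_attr = cls)
}

#' Write a dataset back to CSV
#'
#' Masked cells are written as the `na` token (default `"NA"`).
#'
#' @param ds An `sga_dataset`.
#' @param path Output path.
#' @param na Token written for missing cells.
#' @export
write_table <- function(ds, path, na = "NA") {
  write.csv(ds$values, path, row.names = FALSE, na = na)
  invisible(path)
}

#' Label-encode categorical attributes
#'
#' Replaces every categorical column by non-negative integer codes assigned in
#' first-appearance order (a deterministic, seed-independent rule), leaving
#' masked cells masked and numeric columns untouched. The returned codebook
#' permits exact inversion via [decode_categoricals()]. Codes are nominal:
#' their ordering carries no meaning.
#'
#' @param ds An `sga_dataset`.
#' @return A list with elements `dataset` (all-numeric values) and `codebook`
#'   (named list mapping each categorical attribute to its category vector,
#'   position `i` holding the category encoded as `i - 1`).
#' @export
encode_categoricals <- function(ds) {
  codebook <- list()
  vals <- ds$values
  cat_cols <- ds$schema$name[ds$schema$kind == "categorical"]
  for (nm in cat_cols) {
    col <- vals[[nm]]
    cats <- unique(col[!is.na(col)])
    codebook[[nm]] <- cats
    vals[[nm]] <- as.numeric(match(col, cats) - 1L)
  }
  out <- structure(list(values = vals, mask = ds$mask, schema = ds$schema),
                   class = "sga_dataset")
  validate_dataset(out)
  list(dataset = out, codebook = codebook)
}

#' @rdname encode_categoricals
#' @param codebook A codebook produced by [encode_categoricals()].
#' @export
decode_categoricals <- function(ds, codebook) {
  vals <- ds$values
  for (nm in names(codebook)) {
    code <- vals[[nm]]
    vals[[nm]] <- codebook[[nm]][as.integer(round(code)) + 1L]
  }
  out <- structure(list(values = vals, mask = ds$mask, schema = ds$schema),
                   class = "sga_dataset")
  validate_dataset(out)
  out
}

#' Partition a dataset by completeness of one target attribute
#'
#' Rows where `target` is observed form the training part; rows where it is
#' masked form the test part. Row order within each part is preserved, and the
#' two parts partition the input exactly.
#'
#' @param ds An `sga_dataset`.
#' @param target A non-class attribute name.
#' @return List with `train`, `test` (`sga_dataset`s; `test` may have zero
#'   rows) and the original row indices `train_rows`, `test_rows`.
#' @export
split_by_completeness <- function(ds, target) {
  if (!target %in% predictor_attrs(ds))
    stop("'", target, "' is not a non-class attribute", call. = FALSE)
  miss <- ds$mask[, target]
  if (all(miss)) stop("no training data: '", target,
                      "' is fully missing", call. = FALSE)
  subset_rows <- function(rows) {
    structure(list(values = ds$values[rows, , drop = FALSE],
                   mask = ds$mask[rows, , drop = FALSE],
                   schema = ds$schema), class = "sga_dataset")
  }
  list(train = subset_rows(which(!miss)),
       test = subset_rows(which(miss)),
       train_rows = which(!miss), test_rows = which(miss))
}
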