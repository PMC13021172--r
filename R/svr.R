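# Admissible hyperparameter ranges for the kernel-aware search space.
svr_ranges <- function() {
  list(kernel = c("linear", "rbf", "poly"),
       C = c(0.1, 1000),
       epsilon = c(0.001, 1.0),
       gamma = c(1e-5, 10),
       degree = 2:5)
}

#' An epsilon-SVR configuration
#'
#' Bundles the kernel choice with its hyperparameters. Admissible ranges:
#' `C` in \[0.1, 1000\], `epsilon` in \[0.001, 1\], `gamma` in \[1e-5, 10\],
#' `degree` in \{2, 3, 4, 5\}. `gamma` is used by the rbf and poly kernels
#' only, `degree` by poly only; irrelevant parameters are carried but ignored
#' when fitting. The polynomial kernel constant `coef0` is fixed at 1 to
#' avoid a degenerate homogeneous kernel.
#'
#' @param kernel `"linear"`, `"rbf"` or `"poly"`. Kernels: linear
#'   `K = x'y`; rbf `K = exp(-gamma ||x-y||^2)`; poly
#'   `K = (gamma x'y + 1)^degree`.
#' @param C Regularization strength.
#' @param epsilon Half-width of the insensitive tube.
#' @param gamma Kernel coefficient.
#' @param degree Polynomial degree.
#' @return An `svr_config` list.
#' @examples
#' svr_config("rbf", C = 10, epsilon = 0.1, gamma = 0.5)
#' @export
svr_config <- function(kernel = "rbf", C = 1, epsilon = 0.1, gamma = 0.1,
                       degree = 3) {
  r <- svr_ranges()
  kernel <- match.arg(kernel, r$kernel)
  stopifnot(C >= r$C[1], C <= r$C[2],
            epsilon >= r$epsilon[1], epsilon <= r$epsilon[2],
            gamma >= r$gamma[1], gamma <= r$gamma[2],
            degree %in% r$degree)
  structure(list(kernel = kernel, C = C, epsilon = epsilon, gamma = gamma,
                 degree = as.integer(degree)), class = "svr_config")
}

#' @export
print.svr_config <- function(x, ...) {
  extra <- switch(x$kernel,
    linear = "",
    rbf = sprintf(", gamma=%.4g", x$gamma),
    poly = sprintf(", gamma=%.4g, degree=%d", x$gamma, x$degree))
  cat(sprintf("<svr_config> kernel=%s, C=%.4g, epsilon=%.4g%s\n",
              x$kernel, x$C, x$epsilon, extra))
  invisible(x)
}

# Column-wise standardization stats; zero-variance columns get scale 1 so
# they pass through as constants instead of producing NaN.
scaling_stats <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaling <- function(x, st) {
  scale(x, center = st$center, scale = st$scale)
}

#' Fit an epsilon-insensitive support vector regressor
#'
#' Thin wrapper over the libsvm epsilon-regression solver. Predictors and the
#' response are standardized to zero mean and unit variance on the training
#' rows (so the `gamma` and `epsilon` ranges of [svr_config()] refer to a
#' standardized scale); predictions are transformed back to the original
#' response scale. The fit is deterministic for fixed inputs and config.
#'
#' @param x Numeric matrix or data.frame of predictors, no missing cells.
#' @param y Numeric response vector, no missing values.
#' @param cfg An [svr_config()].
#' @param tolerance Termination tolerance of the solver (libsvm default
#'   0.001; the genetic search ranks candidate configurations with a looser
#'   0.01 for speed, then refits the winner at full tolerance).
#' @return An `svr_model`; use `predict(model, newdata)`.
#' @examples
#' x <- matrix(seq(-1, 1, length.out = 20))
#' m <- fit_svr(x, 2 * x[, 1], svr_config("linear", C = 100, epsilon = 0.01))
#' predict(m, matrix(c(-0.5, 0.5)))
#' @export
fit_svr <- function(x, y, cfg, tolerance = 0.001) {
  stopifnot(inherits(cfg, "svr_config"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("insufficient training data for SVR (need >= 2 rows)",
                        call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("SVR training inputs contain missing cells",
                                 call. = FALSE)
  xs <- scaling_stats(x)
  ysd <- sd(y)
  if (!is.finite(ysd) || ysd == 0) {
    # constant response: the epsilon tube swallows everything and libsvm
    # returns an empty model, so short-circuit to a constant predictor
    return(structure(list(fit = NULL, constant = mean(y), cfg = cfg,
                          predictors = colnames(x)), class = "svr_model"))
  }
  ys <- list(center = mean(y), scale = ysd)
  kern <- switch(cfg$kernel, linear = "linear", rbf = "radial",
                 poly = "polynomial")
  fit <- e1071::svm(apply_scaling(x, xs), (y - ys$center) / ys$scale,
                    type = "eps-regression", kernel = kern,
                    cost = cfg$C, epsilon = cfg$epsilon, gamma = cfg$gamma,
                    degree = cfg$degree, coef0 = 1, scale = FALSE,
                    tolerance = tolerance)
  structure(list(fit = fit, xstats = xs, ystats = ys, cfg = cfg,
                 predictors = colnames(x)), class = "svr_model")
}

#' @rdname fit_svr
#' @param object An `svr_model`.
#' @param newdata Predictor matrix/data.frame with the training columns.
#' @param ... Unused.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$predictors) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$predictors, drop = FALSE]
  if (is.null(object$fit)) return(rep(object$constant, nrow(newdata)))
  z <- predict(object$fit, apply_scaling(newdata, object$xstats))
  as.numeric(z) * object$ystats$scale + object$ystats$center
}
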