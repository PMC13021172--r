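# Run code under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards so package randomness never perturbs user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds derived from one master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629 + 1
}

#' Missingness profile of a dataset
#'
#' Computes, per attribute, the missing-cell fraction `lambda` and the
#' imputation regime it falls in: `low` when `lambda <= tau1`, `medium` when
#' `tau1 < lambda <= tau2`, `high` when `lambda > tau2` (boundaries closed on
#' the low side, so an attribute at exactly `tau1` is low). Also reports the
#' instance-level fraction of rows containing at least one missing cell; this
#' summary does not drive strategy dispatch, which is per-attribute.
#'
#' @param ds An `sga_dataset`.
#' @param tau1,tau2 Regime thresholds, `0 < tau1 < tau2 < 1`. Defaults 0.10
#'   and 0.25.
#' @return A `missingness_profile`: list with `attributes` (data.frame of
#'   `name`, `lambda`, `regime`), `instance_fraction`, `tau1`, `tau2`.
#' @examples
#' ds <- gen_tiny_fixture(1)
#' missingness_profile(ds)
#' @export
missingness_profile <- function(ds, tau1 = 0.10, tau2 = 0.25) {
  stopifnot(tau1 > 0, tau1 < tau2, tau2 < 1)
  n <- nrow(ds$values)
  lambda <- colMeans(ds$mask)
  prof <- data.frame(
    name = colnames(ds$mask),
    lambda = unname(lambda),
    regime = vapply(unname(lambda), regime_of, character(1),
                    tau1 = tau1, tau2 = tau2),
    stringsAsFactors = FALSE)
  structure(list(attributes = prof,
                 instance_fraction = mean(rowSums(ds$mask) > 0),
                 tau1 = tau1, tau2 = tau2),
            class = "missingness_profile")
}

# Eq-style dispatch: closed upper boundaries at tau1 and tau2.
regime_of <- function(lambda, tau1 = 0.10, tau2 = 0.25) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (lambda <= tau1) "low" else if (lambda <= tau2) "medium" else "high"
}

#' @export
print.missingness_profile <- function(x, ...) {
  cat(sprintf("<missingness_profile> tau1=%.2f tau2=%.2f; %.1f%% of rows have >=1 missing cell\n",
              x$tau1, x$tau2, 100 * x$instance_fraction))
  print(x$attributes, row.names = FALSE)
  invisible(x)
}

#' Specify a MAR missingness mechanism
#'
#' The probability that a target cell is masked is a logistic function of
#' standardized, fully observed driver attributes:
#' `p_i = sigma(intercept + sum_j coef_j * z_ij)`. The intercept is calibrated
#' by bisection so the expected missing fraction matches `rate` (tolerance
#' 0.01); drivers are never masked themselves, making the mechanism missing
#' at random.
#'
#' @param rate Target missing fraction, in (0, 1).
#' @param drivers Driver attribute names (fully observed). `NULL` picks a
#'   fully observed numeric non-target predictor, else the class attribute.
#' @param coefficients Logistic dependence coefficients, recycled over
#'   drivers. Default 1. All-zero coefficients reduce the mechanism to MCAR.
#' @param seed Integer seed controlling the Bernoulli draws.
#' @return A `mar_spec` list.
#' @export
mar_spec <- function(rate, drivers = NULL, coefficients = 1, seed = 1) {
  stopifnot(rate > 0, rate < 1)
  structure(list(rate = rate, drivers = drivers,
                 coefficients = coefficients, seed = seed),
            class = "mar_spec")
}

# Bisection on the intercept so that mean(plogis(a + eta)) == rate.
calibrate_intercept <- function(eta, rate, tol = 0.01, max_iter = 100) {
  lo <- -50; hi <- 50
  f <- function(a) mean(plogis(a + eta)) - rate
  if (f(lo) > 0 || f(hi) < 0)
    stop("target rate unreachable given coefficients", call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) <= tol / 4) return(mid)
    if (v < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Inject MAR missingness into complete target columns
#'
#' Each cell of each target attribute is masked independently with a
#' row-specific probability given by the calibrated logistic model of
#' [mar_spec()]. Identical spec and seed reproduce the identical mask. The
#' class attribute and the driver attributes are never masked.
#'
#' @param ds An `sga_dataset` whose `targets` and driver columns are complete.
#' @param spec A [mar_spec()].
#' @param targets Attribute names to mask. Default: all non-class attributes
#'   not used as drivers.
#' @return The dataset with masked cells set to `NA` and the mask updated.
#' @export
inject_mar <- function(ds, spec, targets = NULL) {
  stopifnot(inherits(spec, "mar_spec"))
  cls <- class_attr(ds)
  drivers <- spec$drivers
  if (is.null(targets))
    targets <- setdiff(predictor_attrs(ds), drivers)
  if (cls %in% targets) stop("class attribute cannot be a MAR target",
                             call. = FALSE)
  if (is.null(drivers)) {
    cand <- setdiff(ds$schema$name[ds$schema$kind == "numeric" &
                                     ds$schema$role == "predictor"], targets)
    cand <- cand[colSums(ds$mask[, cand, drop = FALSE]) == 0]
    drivers <- if (length(cand)) cand[1] else cls
  }
  if (any(ds$mask[, c(targets, drivers)]))
    stop("driver or target column contains masked cells", call. = FALSE)
  # standardized driver design (class labels become codes if categorical)
  z <- sapply(drivers, function(d) {
    col <- ds$values[[d]]
    if (!is.numeric(col)) col <- as.numeric(factor(col))
    s <- sd(col); if (!is.finite(s) || s == 0) s <- 1
    (col - mean(col)) / s
  })
  z <- matrix(z, nrow = nrow(ds$values))
  beta <- rep_len(spec$coefficients, length(drivers))
  eta <- as.numeric(z %*% beta)
  a <- calibrate_intercept(eta, spec$rate)
  p <- plogis(a + eta)
  vals <- ds$values; mask <- ds$mask
  with_seed(spec$seed, {
    for (nm in targets) {
      hit <- rbinom(length(p), 1, p) == 1
      mask[hit, nm] <- TRUE
      vals[[nm]][hit] <- NA
    }
  })
  structure(list(values = vals, mask = mask, schema = ds$schema),
            class = "sga_dataset")
}

#' Missingness levels for sweep experiments
#'
#' @param levels Strictly increasing fractions in (0, 1). Default
#'   `c(0.1, 0.2, 0.3, 0.4, 0.5)`.
#' @return The validated level vector.
#' @export
sweep_levels <- function(levels = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  if (length(levels) == 0 || any(levels <= 0) || any(levels >= 1) ||
      is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing fractions in (0,1)",
         call. = FALSE)
  levels
}
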