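# Sparse PLS directions by l1-penalised least squares. Viewing the stage
# cross-covariance Z (q x p) as the response of p coordinate-wise regressions
# on the covariate C = Y't (q x 1), each coordinate of the direction solves
#   minimise 1/2 ||Z_j - C r_j||^2 + lambda |r_j|
# whose closed form is the soft-threshold estimator
#   r_j = soft(C'Z_j, lambda) / C'C.

#' Soft-threshold solution of the penalised direction problem
#'
#' Coordinate-wise minimiser of `1/2 * ||Z_j - C r_j||^2 + lambda * |r_j|`:
#' `r_j = sign(a_j) * max(|a_j| - lambda, 0) / (C'C)` with `a = t(Z) %*% C`.
#' Optionally rescaled to unit Euclidean norm (the constraint the unpenalised
#' directions satisfy), with the sign fixed so the largest-magnitude entry is
#' positive.
#'
#' @param z The q x p cross-covariance matrix of the current stage.
#' @param c_vec The length-q covariate vector `C = t(Y) %*% t_score`; must not
#'   be all zero.
#' @param lambda Non-negative l1 penalty.
#' @param normalize Rescale the nonzero solution to unit norm (default `TRUE`).
#' @return The length-p sparse direction vector, or `NULL` when every
#'   coordinate is thresholded to zero ("empty direction").
#' @examples
#' z <- matrix(rnorm(12), 2, 6)
#' soft_threshold_direction(z, c(1, -1), lambda = 0.5)
#' @export
soft_threshold_direction <- function(z, c_vec, lambda, normalize = TRUE) {
  z <- as.matrix(z)
  c_vec <- as.numeric(c_vec)
  if (length(c_vec) != nrow(z)) stop("length(c_vec) must equal nrow(z)", call. = FALSE)
  cc <- sum(c_vec^2)
  if (cc <= 0) stop("covariate C is all zero (C'C must be positive)", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  a <- as.vector(crossprod(z, c_vec))
  r <- sign(a) * pmax(abs(a) - lambda, 0) / cc
  if (all(r == 0)) return(NULL)
  if (normalize) r <- fix_sign(r / sqrt(sum(r^2)))
  r
}

# One sparse stage direction. The covariate C = Y't is evaluated at the
# unpenalised dominant-singular-vector direction and the closed-form
# soft-threshold estimator applied once (at lambda = 0 this is exactly the
# unpenalised direction, since Z'C is then proportional to Z'Z r0).
# `max_iter` > 1 re-evaluates C at the sparse direction and re-solves, a
# fixed-point refinement that is off by default.
sparse_stage_direction <- function(xk, yk, zk, lambda, z_scale,
                                   max_iter = 1L, tol = 1e-8) {
  r <- dominant_right_sv(zk, scale = z_scale)
  if (is.null(r)) return(NULL)
  for (it in seq_len(max_iter)) {
    tk <- xk %*% r
    cvec <- as.vector(crossprod(yk, tk))
    if (sum(cvec^2) <= 0) return(NULL)
    r_new <- soft_threshold_direction(zk, cvec, lambda, normalize = TRUE)
    if (is.null(r_new)) return(NULL)
    delta <- sqrt(sum((r_new - r)^2))
    r <- r_new
    if (delta < tol) break
  }
  r
}

#' Fit a sparse PLS regression
#'
#' Identical pipeline to [fit_plsr()] — projection deflation, `W = R (G'R)^{-1}`
#' assembly, coefficient matrix `B = W Q_y'` — with the stage direction
#' replaced by the l1 soft-threshold estimator, so most voxel weights in each
#' raw direction are exactly zero. If a later stage thresholds to an empty
#' direction the model is returned with fewer components and a warning; an
#' empty first direction is an error (lambda too large).
#'
#' @inheritParams fit_plsr
#' @param lambda Non-negative l1 penalty shared across components (see
#'   [tune_lambda()]).
#' @return An object of class `c("splsr_model", "plsr_model")`; in addition to
#'   the PLS fields it carries `lambda` and `support` (per-component index
#'   sets of nonzero raw-direction coordinates).
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' fit <- fit_splsr(x, rep(1:2, 10), ncomp = 1, lambda = 0.2)
#' lengths(fit$support)
#' @export
fit_splsr <- function(x, y, ncomp, lambda) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  }
  if (lambda == 0) {
    fit <- fit_pls_impl(x, y, ncomp, lambda = 0)
    fit$lambda <- 0
    fit$support <- lapply(seq_len(fit$ncomp),
                          function(k) which(fit$raw_directions[, k] != 0))
    class(fit) <- c("splsr_model", class(fit))
    return(fit)
  }
  fit_pls_impl(x, y, ncomp, lambda = lambda)
}

#' Largest useful l1 penalty for a dataset
#'
#' The first-stage threshold above which the sparse direction is entirely
#' zero: `max_j |C'Z_j|` evaluated at the unpenalised first-stage direction.
#' Used as the top of the default tuning grid.
#'
#' @inheritParams fit_plsr
#' @return A positive scalar.
#' @export
lambda_max <- function(x, y) {
  x <- as.matrix(x)
  yinfo <- as_indicator(y)
  xc <- center_columns(x)$values
  yc <- center_columns(yinfo$indicator)$values
  z <- crossprod(yc, xc)
  r0 <- dominant_right_sv(z, scale = sqrt(sum(z^2)))
  if (is.null(r0)) stop("Y is numerically orthogonal to X", call. = FALSE)
  t0 <- xc %*% r0
  cvec <- as.vector(crossprod(yc, t0))
  max(abs(as.vector(crossprod(z, cvec))))
}

#' Tune the sparsity penalty by cross-validated MSE
#'
#' Stratified k-fold cross-validation of the indicator-matrix prediction MSE
#' over a penalty grid. Grid points whose first direction thresholds to empty
#' on some fold are dropped; ties are broken toward the larger penalty (the
#' sparser model).
#'
#' @inheritParams fit_splsr
#' @param lambda_grid Candidate penalties; default is 0 plus 20 geometric
#'   points up to [lambda_max()] of the full training data.
#' @param folds Number of stratified folds.
#' @param seed Optional integer seed for the fold assignment.
#' @return A list with `lambda` (chosen penalty) and `cv` (tibble: `lambda`,
#'   `mse`, `n_folds_ok`).
#' @export
tune_lambda <- function(x, y, ncomp, lambda_grid = NULL, folds = 5L, seed = NULL) {
  x <- as.matrix(x)
  yinfo <- as_indicator(y)
  if (is.null(lambda_grid)) {
    lmax <- lambda_max(x, yinfo$indicator)
    lambda_grid <- c(0, exp(seq(log(lmax / 100), log(lmax), length.out = 20L)))
  }
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  if (length(lambda_grid) == 0L) stop("`lambda_grid` is empty", call. = FALSE)
  if (any(lambda_grid < 0)) stop("penalties must be non-negative", call. = FALSE)
  fold_id <- stratified_folds(yinfo$labels, folds, seed)
  n <- nrow(x); q <- ncol(yinfo$indicator)
  sse <- matrix(NA_real_, nrow = length(lambda_grid), ncol = folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    xtr <- x[tr, , drop = FALSE]
    ytr <- yinfo$indicator[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    yte <- yinfo$indicator[!tr, , drop = FALSE]
    for (i in seq_along(lambda_grid)) {
      fit <- tryCatch(
        suppressWarnings(fit_splsr(xtr, ytr, min(ncomp, sum(tr) - 1L),
                                   lambda = lambda_grid[i])),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict(fit, xte)
      sse[i, f] <- sum((pred - yte)^2)
    }
  }
  ok <- rowSums(!is.na(sse))
  usable <- ok == folds
  if (!any(usable)) {
    stop("every penalty in the grid produced an empty first direction on some fold",
         call. = FALSE)
  }
  mse <- rowSums(sse, na.rm = TRUE) / (n * q)
  mse[!usable] <- NA_real_
  finite_mse <- mse[usable]
  best_mse <- min(finite_mse)
  # ties -> larger lambda (prefer the sparser model)
  cand <- which(usable & mse <= best_mse + 1e-12 * max(1, best_mse))
  best <- lambda_grid[max(cand)]
  list(lambda = best,
       cv = tibble::tibble(lambda = lambda_grid, mse = mse, n_folds_ok = ok))
}
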