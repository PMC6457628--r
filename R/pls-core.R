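# Multi-response partial least squares regression (PLSR) fitted by the
# projection-deflation form of NIPALS: at each stage k the direction r_(k) is
# the dominant right singular vector of Z_(k) = Y_(k)' X_(k), where X_(k) and
# Y_(k) are the residuals of X and Y after projecting out the span of the
# accumulated score vectors.

#' Centre the columns of a matrix
#'
#' Subtracts the column means and records them, so they can be re-applied to
#' new data at prediction time. Both the predictor matrix (volumes x voxels)
#' and the dummy-coded label matrix are centred this way before a PLS fit.
#'
#' @param x A numeric matrix with at least one row and column; all entries
#'   must be finite.
#' @return A list with `values` (the centred matrix) and `center` (the vector
#'   of column means that were removed).
#' @examples
#' center_columns(matrix(c(1, 3, 2, 4), 2))
#' @export
center_columns <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0L) stop("cannot centre an empty matrix", call. = FALSE)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (!all(is.finite(x))) {
    stop("`x` contains non-finite entries (NA/NaN/Inf); clean the data first",
         call. = FALSE)
  }
  mu <- colMeans(x)
  list(values = sweep(x, 2L, mu, "-"), center = mu)
}

#' Dummy-code task labels into an indicator matrix
#'
#' Converts length-n integer task labels into the n x q 0/1 indicator matrix
#' used as the multi-response target of the PLS regression: entry (i, j) is 1
#' exactly when volume i belongs to task j.
#'
#' @param labels Integer (or factor) task labels taking values in `1..q`.
#' @param q Number of classes (tasks); must be at least 2 and every class must
#'   appear at least once.
#' @return An n x q 0/1 matrix whose rows each sum to 1.
#' @examples
#' dummy_code(c(1, 2, 1, 3), 3)
#' @export
dummy_code <- function(labels, q = NULL) {
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  if (is.null(q)) q <- max(labels)
  q <- as.integer(q)
  if (q < 2L) stop("at least two classes are required (q >= 2)", call. = FALSE)
  if (any(labels < 1L | labels > q)) {
    stop("labels must lie in 1..", q, call. = FALSE)
  }
  missing <- setdiff(seq_len(q), unique(labels))
  if (length(missing) > 0L) {
    stop("class(es) ", paste(missing, collapse = ", "),
         " have no samples; the regression would be degenerate", call. = FALSE)
  }
  y <- matrix(0, nrow = length(labels), ncol = q)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

# Dominant right singular vector of Z (q x p), via the eigendecomposition of
# the small q x q matrix Z Z'. Returns NULL when Z is numerically zero
# relative to `scale` ("no further component"). Sign fixed so the
# largest-magnitude coordinate is positive.
#' Leading PLS direction for one NIPALS stage
#'
#' Given the current-stage residual matrices, forms the cross-covariance
#' `Z = t(y_resid) %*% x_resid` and returns the unit-norm direction vector
#' maximising `t(r) %*% t(Z) %*% Z %*% r` — the dominant right singular vector
#' of Z. The sign is fixed so the largest-magnitude entry is positive.
#'
#' @param x_resid n x p residual predictor matrix at the current stage.
#' @param y_resid n x q residual response matrix at the current stage.
#' @return A unit-norm numeric vector of length p, or `NULL` when Z is
#'   numerically zero (no further component can be extracted).
#' @export
nipals_direction <- function(x_resid, y_resid) {
  z <- crossprod(as.matrix(y_resid), as.matrix(x_resid))
  dominant_right_sv(z, scale = sqrt(sum(z^2)))
}

dominant_right_sv <- function(z, scale, rel_tol = 1e-10) {
  zn <- sqrt(sum(z^2))
  if (!is.finite(zn) || zn <= rel_tol * max(scale, .Machine$double.xmin)) {
    return(NULL)
  }
  if (nrow(z) == 1L) {
    r <- as.vector(z)
  } else {
    zz <- tcrossprod(z)           # q x q
    eig <- eigen(zz, symmetric = TRUE)
    u <- eig$vectors[, 1L]
    r <- as.vector(crossprod(z, u))
  }
  fix_sign(r / sqrt(sum(r^2)))
}

fix_sign <- function(r) {
  i <- which.max(abs(r))
  if (r[i] < 0) -r else r
}

# Residual of `m` after projecting out the column span of `scores`, using the
# Moore-Penrose pseudoinverse (singular values below 1e-12 * max truncated).
project_out <- function(m, scores) {
  if (is.null(scores) || ncol(scores) == 0L) return(m)
  sv <- svd(scores, nu = ncol(scores), nv = 0L)
  keep <- sv$d > 1e-12 * sv$d[1L]
  u <- sv$u[, keep, drop = FALSE]
  m - u %*% crossprod(u, m)
}

#' Fit a multi-response PLS regression
#'
#' Extracts `ncomp` latent components by the projection-deflation NIPALS
#' scheme: at stage k the direction is the dominant right singular vector of
#' the residual cross-covariance, the score is the residual-X image of that
#' direction, and both X and Y are deflated by projection onto the orthogonal
#' complement of the accumulated scores. The direction matrix is then
#' assembled as `W = R (G' R)^{-1}` with `G = X' T (T' T)^{-1}`, giving
#' coefficients `B = W Q_y'` so that fitted responses are
#' `(X - centre) B + y-centre`.
#'
#' @param x n x p numeric predictor matrix (volumes x voxels).
#' @param y Task labels (integer/factor of length n) or an n x q indicator
#'   matrix as produced by [dummy_code()].
#' @param ncomp Number of latent components K, `1 <= K <= min(n - 1, p)`. If
#'   the cross-covariance is exhausted earlier, the model is returned with
#'   fewer components and a warning.
#' @return An object of class `"plsr_model"`: a list with `directions` (W,
#'   p x K), `scores` (T, n x K), `x_loadings`, `y_loadings`,
#'   `coefficients` (B, p x q), `raw_directions` (the unit-norm stage
#'   directions R), `ncomp`, `x_center`, `y_center` and bookkeeping needed to
#'   truncate the component path.
#' @seealso [predict.plsr_model()], [select_n_components()], [fit_splsr()]
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' fit <- fit_plsr(x, rep(1:2, 5), ncomp = 2)
#' fit$ncomp
#' @export
fit_plsr <- function(x, y, ncomp) {
  fit_pls_impl(x, y, ncomp, lambda = 0)
}

# Shared fitting engine for PLSR and sparse PLSR. `lambda` > 0 switches the
# stage-direction estimator to the soft-threshold fixed point.
fit_pls_impl <- function(x, y, ncomp, lambda = 0,
                         max_iter = 1L, iter_tol = 1e-8) {
  x <- as.matrix(x)
  yinfo <- as_indicator(y)
  yd <- yinfo$indicator
  n <- nrow(x); p <- ncol(x); q <- ncol(yd)
  if (nrow(yd) != n) stop("x and y have different numbers of samples", call. = FALSE)
  if (n < 2L) stop("at least two samples are required", call. = FALSE)
  kmax <- min(n - 1L, p)
  ncomp <- as.integer(ncomp)
  if (length(ncomp) != 1L || is.na(ncomp) || ncomp < 1L || ncomp > kmax) {
    stop("`ncomp` must lie in 1..min(n - 1, p) = 1..", kmax, call. = FALSE)
  }
  cx <- center_columns(x)
  cy <- center_columns(yd)
  xc <- cx$values; yc <- cy$values

  scores <- matrix(0, n, 0L)
  rmat <- matrix(0, p, 0L)
  support <- list()
  z_scale <- NULL
  for (k in seq_len(ncomp)) {
    xk <- project_out(xc, scores)
    yk <- project_out(yc, scores)
    zk <- crossprod(yk, xk)
    if (is.null(z_scale)) z_scale <- sqrt(sum(zk^2))
    if (lambda > 0) {
      r <- sparse_stage_direction(xk, yk, zk, lambda, z_scale,
                                  max_iter = max_iter, tol = iter_tol)
    } else {
      r <- dominant_right_sv(zk, scale = z_scale)
    }
    if (is.null(r)) {
      if (k == 1L) {
        if (lambda > 0) {
          stop("lambda too large: the first direction is entirely thresholded to zero",
               call. = FALSE)
        }
        stop("no PLS component can be extracted: Y is numerically orthogonal to X",
             call. = FALSE)
      }
      warning("component extraction stopped early at ", k - 1L, " of ", ncomp,
              " components (cross-covariance exhausted)", call. = FALSE)
      break
    }
    tk <- xk %*% r
    if (sum(tk^2) <= (1e-12 * max(sum(xc^2), .Machine$double.xmin))^1) {
      if (k == 1L) stop("degenerate first score (X residual annihilates the direction)",
                        call. = FALSE)
      warning("component extraction stopped early at ", k - 1L, " of ", ncomp,
              " components (degenerate score)", call. = FALSE)
      break
    }
    scores <- cbind(scores, tk)
    rmat <- cbind(rmat, r)
    support[[length(support) + 1L]] <- which(r != 0)
  }
  kact <- ncol(scores)
  colnames(scores) <- paste0("comp", seq_len(kact))
  colnames(rmat) <- colnames(scores)

  ttt <- crossprod(scores)                       # T'T (numerically diagonal)
  graw <- crossprod(xc, scores)                  # X'T
  yraw <- crossprod(yc, scores)                  # Y'T
  g <- graw %*% solve(ttt)                       # G = X'T (T'T)^{-1}
  gr <- crossprod(g, rmat)                       # G'R (K x K)
  if (rcond_safe(gr) < 1e-12) {
    stop("G'R is numerically singular; the component path is degenerate",
         call. = FALSE)
  }
  w <- rmat %*% solve(gr)                        # W = R (G'R)^{-1}
  qy <- yraw %*% solve(ttt)                      # Q_y = Y'T (T'T)^{-1}
  b <- w %*% t(qy)
  colnames(b) <- yinfo$levels
  structure(list(
    directions = w,
    scores = scores,
    x_loadings = g,
    y_loadings = qy,
    coefficients = b,
    raw_directions = rmat,
    ncomp = kact,
    x_center = cx$center,
    y_center = cy$center,
    task_levels = yinfo$levels,
    q = q,
    n = n,
    p = p,
    lambda = if (lambda > 0) lambda else NULL,
    support = if (lambda > 0) support else NULL,
    .path = list(graw = graw, yraw = yraw, ttt = ttt)
  ), class = c(if (lambda > 0) "splsr_model", "plsr_model"))
}

rcond_safe <- function(m) {
  tryCatch(rcond(m), error = function(e) 0)
}

# Accept labels or an indicator matrix; return the indicator plus class names.
as_indicator <- function(y) {
  if (is.matrix(y)) {
    if (any(rowSums(y) != 1) || !all(y %in% c(0, 1))) {
      stop("indicator matrix must be 0/1 with unit row sums", call. = FALSE)
    }
    if (ncol(y) < 2L) stop("at least two classes are required", call. = FALSE)
    if (any(colSums(y) == 0)) stop("every class needs at least one sample", call. = FALSE)
    lev <- colnames(y)
    if (is.null(lev)) lev <- paste0("task", seq_len(ncol(y)))
    return(list(indicator = y, levels = lev, labels = max.col(y)))
  }
  lev <- if (is.factor(y)) levels(y) else paste0("task", seq_len(max(as.integer(y))))
  ind <- dummy_code(y, q = length(lev))
  colnames(ind) <- lev
  list(indicator = ind, levels = lev, labels = as.integer(y))
}

# Coefficient matrix for a truncation of the component path to k components.
coef_at_k <- function(object, k) {
  stopifnot(k >= 1L, k <= object$ncomp)
  if (k == object$ncomp) return(object$coefficients)
  idx <- seq_len(k)
  ttt <- object$.path$ttt[idx, idx, drop = FALSE]
  g <- object$.path$graw[, idx, drop = FALSE] %*% solve(ttt)
  rk <- object$raw_directions[, idx, drop = FALSE]
  w <- rk %*% solve(crossprod(g, rk))
  qy <- object$.path$yraw[, idx, drop = FALSE] %*% solve(ttt)
  w %*% t(qy)
}

#' Predict from a fitted PLS regression
#'
#' Applies the stored training-set centring and the coefficient matrix:
#' `(newdata - x_centre) B + y_centre`. With `type = "class"` the continuous
#' task scores are converted to a task index by argmax (ties go to the
#' smallest index).
#'
#' @param object A `"plsr_model"` from [fit_plsr()] or [fit_splsr()].
#' @param newdata An m x p matrix (or length-p vector) with the same voxel
#'   ordering as the training data.
#' @param type `"response"` for the m x q continuous score matrix,
#'   `"class"` for predicted task indices.
#' @param ... Unused.
#' @return An m x q matrix, or an integer vector of task indices.
#' @export
predict.plsr_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("`newdata` has ", ncol(newdata), " voxels; the model was trained on ",
         object$p, call. = FALSE)
  }
  if (!all(is.finite(newdata))) stop("`newdata` contains non-finite values", call. = FALSE)
  yhat <- sweep(newdata, 2L, object$x_center, "-") %*% object$coefficients
  yhat <- sweep(yhat, 2L, object$y_center, "+")
  colnames(yhat) <- object$task_levels
  if (type == "response") return(yhat)
  argmax_rows(yhat)
}

# Row-wise argmax with ties broken toward the smallest index.
argmax_rows <- function(m) {
  apply(m, 1L, function(v) which(v >= max(v) - 0)[1L])
}

#' Fitted values of a PLS regression on its training data
#' @param object A `"plsr_model"`.
#' @param ... Unused.
#' @return The n x q fitted response matrix.
#' @export
fitted.plsr_model <- function(object, ...) {
  sweep(object$scores %*% t(object$y_loadings), 2L, object$y_center, "+")
}

#' @export
print.plsr_model <- function(x, ...) {
  kind <- if (inherits(x, "splsr_model")) "Sparse PLS" else "PLS"
  cat(kind, " regression: ", x$n, " samples x ", x$p, " voxels -> ",
      x$q, " tasks, ", x$ncomp, " component(s)\n", sep = "")
  if (!is.null(x$lambda)) {
    cat("lambda = ", format(x$lambda), ", support sizes: ",
        paste(lengths(x$support), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Choose the number of latent components by cross-validation
#'
#' Stratified k-fold cross-validation over a grid of component counts; the
#' loss is the mean squared error of the predicted indicator matrix. Ties are
#' broken toward the smaller (more parsimonious) count.
#'
#' @inheritParams fit_plsr
#' @param ncomp_grid Candidate component counts; default `1:min(10, n - 1, p)`.
#' @param folds Number of cross-validation folds (stratified by class).
#' @param seed Optional integer seed controlling the fold assignment; the
#'   global RNG state is left untouched.
#' @return A list with `ncomp` (the chosen count) and `cv` (a tibble with one
#'   row per candidate: `ncomp`, `mse`).
#' @export
select_n_components <- function(x, y, ncomp_grid = NULL, folds = 5L, seed = NULL) {
  x <- as.matrix(x)
  yinfo <- as_indicator(y)
  n <- nrow(x)
  kmax <- min(n - 1L, ncol(x))
  if (is.null(ncomp_grid)) ncomp_grid <- seq_len(min(10L, kmax))
  ncomp_grid <- sort(unique(as.integer(ncomp_grid)))
  if (any(ncomp_grid < 1L | ncomp_grid > kmax)) {
    stop("`ncomp_grid` must lie within 1..", kmax, call. = FALSE)
  }
  fold_id <- stratified_folds(yinfo$labels, folds, seed)
  kfit <- max(ncomp_grid)
  sse <- rep(0, length(ncomp_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- suppressWarnings(fit_pls_impl(x[tr, , drop = FALSE],
                                         yinfo$indicator[tr, , drop = FALSE],
                                         min(kfit, sum(tr) - 1L),
                                         lambda = 0))
    xte <- sweep(x[!tr, , drop = FALSE], 2L, fit$x_center, "-")
    yte <- yinfo$indicator[!tr, , drop = FALSE]
    for (i in seq_along(ncomp_grid)) {
      k <- min(ncomp_grid[i], fit$ncomp)
      pred <- sweep(xte %*% coef_at_k(fit, k), 2L, fit$y_center, "+")
      sse[i] <- sse[i] + sum((pred - yte)^2)
    }
  }
  mse <- sse / (n * ncol(yinfo$indicator))
  best <- ncomp_grid[which.min(mse)]   # which.min already prefers smaller K on ties
  list(ncomp = best, cv = tibble::tibble(ncomp = ncomp_grid, mse = mse))
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin across folds. Errors when a class has fewer samples than folds.
stratified_folds <- function(labels, folds, seed = NULL) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("every class needs at least `folds` samples for stratified CV",
         call. = FALSE)
  }
  assign_one <- function() {
    id <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  }
  if (is.null(seed)) assign_one() else withr::with_seed(as.integer(seed), assign_one())
}
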