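# Feature selection (PLSR/SPLSR z-score rule and a GLM t-map baseline) and
# the PLSR argmax classifier with accuracy scoring.

#' Standardise an fMRI run for decoding
#'
#' Two-pass normalisation: first each voxel's time course is standardised to
#' zero mean and unit variance, then each volume (row) is standardised across
#' voxels, in that order. Voxels with zero variance carry no information and
#' are excluded up front with a warning; their indices are recorded so that
#' masks trained on one run stay aligned with another.
#'
#' @param x A time x voxels numeric matrix (one run).
#' @param keep Optional integer vector of voxel columns to retain, e.g. the
#'   non-constant voxels of the training run, so train and test runs share a
#'   common geometry. Default: all non-constant voxels of `x`.
#' @return The normalised matrix (rows: volumes, columns: kept voxels), with
#'   attributes `voxel_index` (original column index of each kept voxel) and
#'   `dropped_voxels` (original indices excluded for zero variance).
#' @export
normalize_run <- function(x, keep = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("run contains non-finite values", call. = FALSE)
  p <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  if (is.null(keep)) {
    keep <- which(sds > 0)
    dropped <- which(sds == 0)
    if (length(dropped) > 0L) {
      warning(length(dropped), " zero-variance voxel(s) excluded before normalisation",
              call. = FALSE)
    }
    if (length(keep) == 0L) stop("all voxels have zero variance", call. = FALSE)
  } else {
    keep <- sort(unique(as.integer(keep)))
    if (any(keep < 1L | keep > p)) stop("`keep` indices out of range", call. = FALSE)
    if (any(sds[keep] == 0)) {
      stop("`keep` includes voxel(s) with zero variance in this run", call. = FALSE)
    }
    dropped <- setdiff(seq_len(p), keep)
  }
  xk <- x[, keep, drop = FALSE]
  xk <- scale(xk)                                    # voxel-wise pass
  rm_ <- rowMeans(xk)
  rs <- apply(xk, 1L, stats::sd)
  if (anyNA(rs) || any(rs == 0)) {
    stop("volume(s) with zero variance after voxel standardisation", call. = FALSE)
  }
  out <- (xk - rm_) / rs                             # volume-wise pass
  attr(out, "voxel_index") <- keep
  attr(out, "dropped_voxels") <- dropped
  out
}

#' Column-wise z scores of a coefficient matrix
#'
#' For each task (column) of the p x q PLS coefficient matrix, converts the
#' voxel weights to z scores: `(b - mean(b)) / sd(b)` with the sample
#' standard deviation (n - 1 denominator).
#'
#' @param b A p x q numeric matrix (voxels x tasks).
#' @return The p x q z-score matrix.
#' @export
zscore_columns <- function(b) {
  b <- as.matrix(b)
  sds <- apply(b, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("column(s) ", paste(which(sds == 0), collapse = ", "),
         " have zero standard deviation; no features are selectable there",
         call. = FALSE)
  }
  sweep(sweep(b, 2L, colMeans(b), "-"), 2L, sds, "/")
}

new_feature_mask <- function(per_task_columns, voxel_index, selector, threshold,
                             task_names = NULL) {
  if (is.null(task_names)) task_names <- paste0("task", seq_along(per_task_columns))
  names(per_task_columns) <- task_names
  columns <- sort(unique(unlist(per_task_columns, use.names = FALSE)))
  structure(list(
    columns = columns,
    voxels = voxel_index[columns],
    per_task = lapply(per_task_columns, function(i) voxel_index[sort(i)]),
    per_task_columns = lapply(per_task_columns, sort),
    selector = selector,
    threshold = threshold
  ), class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat("Feature mask (", x$selector, ", threshold ", format(x$threshold), "): ",
      length(x$voxels), " voxel(s); per task: ",
      paste(lengths(x$per_task), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select voxels whose coefficient z score exceeds a threshold
#'
#' The PLSR/SPLSR selection rule: per task j, voxels whose z score in column j
#' of the coefficient matrix is strictly larger than the threshold (default
#' 3.5) are marked relevant to that task; the final mask is the union across
#' tasks, with per-task provenance retained.
#'
#' @param b A p x q coefficient matrix (e.g. `fit$coefficients`).
#' @param threshold z-score cut-off; strictly-greater comparison.
#' @param voxel_index Original voxel index of each row of `b` (default
#'   `1:p`); taken from a [normalize_run()] attribute when present.
#' @param fallback_top Optional: when no voxel anywhere exceeds the threshold,
#'   fall back to the `fallback_top` largest-z voxels per task instead of
#'   failing. Off (`NULL`) by default.
#' @return A `"feature_mask"`: ordered unique voxel indices plus per-task
#'   provenance, selector name and threshold.
#' @export
select_features_z <- function(b, threshold = 3.5, voxel_index = NULL,
                              fallback_top = NULL) {
  b <- as.matrix(b)
  if (is.null(voxel_index)) voxel_index <- seq_len(nrow(b))
  z <- zscore_columns(b)
  per_task <- lapply(seq_len(ncol(z)), function(j) which(z[, j] > threshold))
  if (all(lengths(per_task) == 0L)) {
    if (!is.null(fallback_top)) {
      per_task <- lapply(seq_len(ncol(z)), function(j)
        order(z[, j], decreasing = TRUE)[seq_len(min(fallback_top, nrow(z)))])
    } else {
      maxz <- apply(z, 2L, max)
      stop("no features selected at z > ", threshold,
           " (per-task max z: ", paste(sprintf("%.2f", maxz), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  selector <- if (!is.null(attr(b, "selector"))) attr(b, "selector") else "plsr_z"
  new_feature_mask(per_task, voxel_index, selector, threshold,
                   task_names = colnames(b))
}

#' Voxel-wise GLM t maps for task regressors
#'
#' Fits, for every voxel, an ordinary least squares model of its time course
#' on the HRF-convolved task regressors plus an intercept, and returns the t
#' statistic of each task coefficient (coefficient divided by its standard
#' error, residual degrees of freedom `n - rank(design)`).
#'
#' @param x A time x voxels matrix (normally a [normalize_run()] output).
#' @param design A time x q matrix of task regressors (see
#'   [build_regressors()]); the intercept is added internally.
#' @return An object of class `"glm_tmap"`: list with `t` (p x q t matrix)
#'   and `df` (residual degrees of freedom).
#' @export
glm_t_maps <- function(x, design) {
  x <- as.matrix(x); design <- as.matrix(design)
  n <- nrow(x)
  if (nrow(design) != n) stop("design and data have different numbers of volumes",
                              call. = FALSE)
  d <- cbind(`(Intercept)` = 1, design)
  qrd <- qr(d)
  if (qrd$rank < ncol(d)) stop("design matrix is rank deficient", call. = FALSE)
  dtd_inv <- chol2inv(qr.R(qrd))
  coefs <- dtd_inv %*% crossprod(d, x)               # (q+1) x p
  resid <- x - d %*% coefs
  df <- n - qrd$rank
  sigma2 <- colSums(resid^2) / df
  task_cols <- seq_len(ncol(design)) + 1L
  tmat <- matrix(NA_real_, nrow = ncol(x), ncol = length(task_cols))
  for (j in seq_along(task_cols)) {
    se <- sqrt(sigma2 * dtd_inv[task_cols[j], task_cols[j]])
    tmat[, j] <- coefs[task_cols[j], ] / se
  }
  colnames(tmat) <- colnames(design)
  if (!is.null(attr(x, "voxel_index"))) {
    attr(tmat, "voxel_index") <- attr(x, "voxel_index")
  }
  structure(list(t = tmat, df = df), class = "glm_tmap")
}

#' Select voxels by uncorrected GLM significance
#'
#' Per task, keeps voxels whose one-sided p value (positive activation,
#' `P(T > t)`) is below `alpha` (default 0.001, uncorrected); the mask is the
#' union across tasks with provenance, mirroring the z-score rule.
#'
#' @param tmap A `"glm_tmap"` from [glm_t_maps()].
#' @param alpha Voxel-level significance threshold.
#' @param voxel_index Original voxel index of each row (defaults to the
#'   `voxel_index` attribute carried through [glm_t_maps()], else `1:p`).
#' @inheritParams select_features_z
#' @return A `"feature_mask"` with selector `"glm_t"`.
#' @export
select_features_glm <- function(tmap, alpha = 0.001, voxel_index = NULL,
                                fallback_top = NULL) {
  stopifnot(inherits(tmap, "glm_tmap"))
  tmat <- tmap$t
  if (is.null(voxel_index)) {
    voxel_index <- attr(tmat, "voxel_index")
    if (is.null(voxel_index)) voxel_index <- seq_len(nrow(tmat))
  }
  pvals <- stats::pt(tmat, df = tmap$df, lower.tail = FALSE)
  per_task <- lapply(seq_len(ncol(tmat)), function(j) which(pvals[, j] < alpha))
  if (all(lengths(per_task) == 0L)) {
    if (!is.null(fallback_top)) {
      per_task <- lapply(seq_len(ncol(tmat)), function(j)
        order(tmat[, j], decreasing = TRUE)[seq_len(min(fallback_top, nrow(tmat)))])
    } else {
      maxt <- apply(tmat, 2L, max)
      stop("no features selected at p < ", alpha,
           " (per-task max t: ", paste(sprintf("%.2f", maxt), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  new_feature_mask(per_task, voxel_index, "glm_t", alpha,
                   task_names = colnames(tmat))
}

#' Train the PLSR argmax classifier on masked features
#'
#' Fits a PLS regression of the dummy-coded labels on the masked training
#' columns only; the mask is stored so that test volumes are reduced to the
#' same features before scoring. The number of latent components is taken
#' from `ncomp` or chosen by stratified cross-validation.
#'
#' @param x Normalised training matrix (volumes x voxels, the geometry the
#'   mask's `columns` refer to).
#' @param labels Task labels (length `nrow(x)`).
#' @param mask A `"feature_mask"`.
#' @param ncomp Number of components; `NULL` (default) selects it with
#'   [select_n_components()].
#' @param ncomp_grid,folds,seed Passed to [select_n_components()] when
#'   `ncomp` is `NULL`.
#' @return An object of class `"plsr_classifier"`: list with `model` (the
#'   fitted `"plsr_model"`), `mask`, `task_levels`, `ncomp` and, when CV was
#'   used, the CV table.
#' @export
train_plsr_classifier <- function(x, labels, mask, ncomp = NULL,
                                  ncomp_grid = NULL, folds = 5L, seed = NULL) {
  stopifnot(inherits(mask, "feature_mask"))
  x <- as.matrix(x)
  if (length(mask$columns) == 0L) stop("feature mask is empty", call. = FALSE)
  if (max(mask$columns) > ncol(x)) stop("mask indexes voxels beyond the data",
                                        call. = FALSE)
  xm <- x[, mask$columns, drop = FALSE]
  cv <- NULL
  if (is.null(ncomp)) {
    if (is.null(ncomp_grid)) {
      ncomp_grid <- seq_len(min(10L, nrow(xm) - 1L, ncol(xm)))
    }
    sel <- select_n_components(xm, labels, ncomp_grid = ncomp_grid,
                               folds = folds, seed = seed)
    ncomp <- sel$ncomp
    cv <- sel$cv
  }
  ncomp <- min(ncomp, nrow(xm) - 1L, ncol(xm))
  model <- suppressWarnings(fit_plsr(xm, labels, ncomp = ncomp))
  structure(list(model = model, mask = mask, task_levels = model$task_levels,
                 ncomp = model$ncomp, cv = cv),
            class = "plsr_classifier")
}

#' @export
print.plsr_classifier <- function(x, ...) {
  cat("PLSR argmax classifier: ", length(x$mask$columns), " feature(s), ",
      x$ncomp, " component(s), ", length(x$task_levels), " tasks\n", sep = "")
  invisible(x)
}

# Row-wise argmax with tie diagnostics: ties go to the smallest task index.
argmax_with_ties <- function(scores) {
  pred <- integer(nrow(scores))
  ties <- 0L
  for (i in seq_len(nrow(scores))) {
    v <- scores[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) ties <- ties + 1L
    pred[i] <- top[1L]
  }
  attr(pred, "n_ties") <- ties
  pred
}

#' Predict task states for new volumes
#'
#' Reduces each volume to the classifier's feature mask, computes the
#' continuous task weights `y = (D - centre) B + y-centre` and assigns the
#' task with the largest weight (ties to the smallest index, counted in the
#' `n_ties` attribute of the class output).
#'
#' @param object A `"plsr_classifier"`.
#' @param newdata m x p matrix in the same (normalised) geometry as the
#'   training data, or a single length-p volume.
#' @param type `"class"` (default) or `"response"` for the raw weights.
#' @param ... Unused.
#' @export
predict.plsr_classifier <- function(object, newdata,
                                    type = c("class", "response"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (!all(is.finite(newdata))) stop("test volumes contain non-finite values",
                                     call. = FALSE)
  if (max(object$mask$columns) > ncol(newdata)) {
    stop("test data has fewer voxels than the classifier's mask expects",
         call. = FALSE)
  }
  dm <- newdata[, object$mask$columns, drop = FALSE]
  scores <- predict(object$model, dm, type = "response")
  if (type == "response") return(scores)
  argmax_with_ties(scores)
}

#' Classify a single volume
#'
#' @param clf A `"plsr_classifier"`.
#' @param volume A length-p numeric vector in the classifier's geometry.
#' @return A list with `task` (the predicted index) and `weights` (the length-q
#'   score vector). A tie is reported via a message and resolved to the
#'   smallest task index.
#' @export
classify_volume <- function(clf, volume) {
  scores <- predict(clf, volume, type = "response")
  pred <- argmax_with_ties(scores)
  if (attr(pred, "n_ties") > 0L) {
    message("argmax tie; resolved to the smallest task index")
  }
  list(task = pred[1L], weights = drop(scores))
}

#' Score predicted against true task states
#'
#' Classification accuracy R = M / N: the number of correctly classified test
#' volumes over the total.
#'
#' @param predicted,truth Equal-length vectors of task indices.
#' @return An object of class `"decoding_result"`: list with `predicted`,
#'   `truth`, `n_correct` (M), `n_total` (N) and `accuracy` (R).
#' @examples
#' score(c(1, 2, 2, 1), c(1, 2, 1, 1))$accuracy
#' @export
score <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` have different lengths", call. = FALSE)
  }
  n <- length(truth)
  if (n < 1L) stop("at least one test volume is required", call. = FALSE)
  m <- sum(predicted == truth)
  structure(list(predicted = predicted, truth = truth,
                 n_correct = m, n_total = n, accuracy = m / n),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Decoding accuracy: ", x$n_correct, "/", x$n_total, " = ",
      sprintf("%.3f", x$accuracy), "\n", sep = "")
  invisible(x)
}
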