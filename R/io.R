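# Import/export: NIfTI volumes, BIDS-style events tables, TSV result tables
# and a JSON container for fitted models and masks.

#' Export a simulated run to NIfTI
#'
#' Writes the run as a 4D NIfTI image (x, y, 1 slice, time), with the TR
#' recorded in the header's time spacing.
#'
#' @param run A `"sim_run"` (or a time x pixels matrix plus `dim`).
#' @param file Output path (`.nii` or `.nii.gz`).
#' @param dim Image dimensions when `run` is a bare matrix.
#' @return The file path, invisibly.
#' @export
write_run_nifti <- function(run, file, dim = NULL) {
  if (inherits(run, "sim_run")) {
    dim <- run$layout$dim
    tr <- attr(run$paradigm, "tr")
    data <- run$data
  } else {
    if (is.null(dim)) stop("`dim` is required for a bare matrix", call. = FALSE)
    tr <- 1
    data <- as.matrix(run)
  }
  arr <- array(t(data), dim = c(dim[1L], dim[2L], 1L, nrow(data)))
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, tr))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a 4D NIfTI file as a time x voxels matrix
#'
#' Flattens the spatial dimensions in column-major order so the result can be
#' fed to [normalize_run()].
#'
#' @param file Path to a NIfTI file.
#' @return A time x voxels matrix with attribute `dim_spatial`.
#' @export
read_run_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  d <- dim(img)
  if (length(d) < 4L) stop("expected a 4D (space x time) NIfTI image", call. = FALSE)
  nt <- d[length(d)]
  out <- t(matrix(as.vector(img), ncol = nt))
  attr(out, "dim_spatial") <- d[-length(d)]
  out
}

#' Write a paradigm as a BIDS-style events table
#'
#' Tab-separated file with `onset`, `duration` and `trial_type` columns.
#'
#' @param paradigm An `"fmri_paradigm"`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_events_tsv <- function(paradigm, file) {
  readr::write_tsv(paradigm[, c("onset", "duration", "trial_type")], file)
  invisible(file)
}

#' Read a BIDS-style events table as a paradigm
#'
#' @param file Path to a TSV with `onset`, `duration`, `trial_type` columns
#'   (`trial_type` values `rest` or `task<j>`).
#' @param tr Repetition time in seconds.
#' @return An `"fmri_paradigm"`.
#' @export
read_events_tsv <- function(file, tr = 2) {
  ev <- readr::read_tsv(file, show_col_types = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev))) {
    stop("events file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ev <- ev[order(ev$onset), ]
  task <- suppressWarnings(as.integer(sub("^task", "", ev$trial_type)))
  task[ev$trial_type == "rest"] <- NA_integer_
  out <- tibble::tibble(onset = ev$onset, duration = ev$duration,
                        trial_type = ev$trial_type, task = task)
  total <- max(out$onset + out$duration)
  attr(out, "tr") <- tr
  attr(out, "n_volumes") <- as.integer(round(total / tr))
  class(out) <- c("fmri_paradigm", class(out))
  out
}

#' Write an experiment's result table to TSV
#'
#' @param experiment A `"decoding_experiment"` (or its results tibble).
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_results_tsv <- function(experiment, file) {
  results <- if (inherits(experiment, "decoding_experiment")) {
    experiment$results
  } else {
    experiment
  }
  readr::write_tsv(results, file)
  invisible(file)
}

#' Serialize a fitted PLS model or classifier to a JSON container
#'
#' A plain-text container holding every numeric array as base64-encoded
#' IEEE-754 doubles (little endian) together with its shape, plus the
#' centring offsets, component count and, for sparse fits, the penalty and
#' support sets. The binary encoding makes the round trip bit-exact, so a
#' restored classifier reproduces predictions identically.
#'
#' @param object A `"plsr_model"`, `"plsr_classifier"` or `"feature_mask"`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_model_json <- function(object, file) {
  payload <- serialize_obj(object)
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(file)
}

# base64-encoded little-endian doubles: bit-exact and text-safe
enc_num <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       b64 = jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                           size = 8L, endian = "little")))
}

dec_num <- function(obj) {
  v <- readBin(jsonlite::base64_dec(obj$b64), what = "double",
               n = prod(unlist(obj$dim)), size = 8L, endian = "little")
  if (length(obj$dim) == 2L) matrix(v, obj$dim[[1L]], obj$dim[[2L]]) else v
}

serialize_obj <- function(object) {
  if (inherits(object, "plsr_classifier")) {
    return(list(kind = "plsr_classifier",
                model = serialize_obj(object$model),
                mask = serialize_obj(object$mask),
                task_levels = object$task_levels,
                ncomp = object$ncomp))
  }
  if (inherits(object, "feature_mask")) {
    return(list(kind = "feature_mask",
                columns = object$columns, voxels = object$voxels,
                per_task = object$per_task,
                per_task_columns = object$per_task_columns,
                selector = object$selector, threshold = object$threshold))
  }
  if (inherits(object, "plsr_model")) {
    return(list(kind = if (inherits(object, "splsr_model")) "splsr_model" else "plsr_model",
                directions = enc_num(object$directions),
                scores = enc_num(object$scores),
                x_loadings = enc_num(object$x_loadings),
                y_loadings = enc_num(object$y_loadings),
                coefficients = enc_num(object$coefficients),
                raw_directions = enc_num(object$raw_directions),
                ncomp = object$ncomp, x_center = enc_num(object$x_center),
                y_center = enc_num(object$y_center),
                task_levels = object$task_levels,
                q = object$q, n = object$n, p = object$p,
                lambda = object$lambda, support = object$support))
  }
  stop("cannot serialize objects of class ", paste(class(object), collapse = "/"),
       call. = FALSE)
}

#' Restore a model, classifier or mask written by [write_model_json()]
#'
#' @param file Path to the JSON container.
#' @return The restored object.
#' @export
read_model_json <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  deserialize_obj(payload)
}

deserialize_obj <- function(payload) {
  unmat <- dec_num
  if (payload$kind == "plsr_classifier") {
    model <- deserialize_obj(payload$model)
    mask <- deserialize_obj(payload$mask)
    return(structure(list(model = model, mask = mask,
                          task_levels = payload$task_levels,
                          ncomp = payload$ncomp, cv = NULL),
                     class = "plsr_classifier"))
  }
  if (payload$kind == "feature_mask") {
    return(structure(list(columns = as.integer(payload$columns),
                          voxels = as.integer(payload$voxels),
                          per_task = lapply(payload$per_task, as.integer),
                          per_task_columns = lapply(payload$per_task_columns, as.integer),
                          selector = payload$selector,
                          threshold = payload$threshold),
                     class = "feature_mask"))
  }
  structure(list(directions = unmat(payload$directions),
                 scores = unmat(payload$scores),
                 x_loadings = unmat(payload$x_loadings),
                 y_loadings = unmat(payload$y_loadings),
                 coefficients = unmat(payload$coefficients),
                 raw_directions = unmat(payload$raw_directions),
                 ncomp = payload$ncomp, x_center = dec_num(payload$x_center),
                 y_center = dec_num(payload$y_center),
                 task_levels = payload$task_levels,
                 q = payload$q, n = payload$n, p = payload$p,
                 lambda = payload$lambda,
                 support = if (is.null(payload$support)) NULL else
                   lapply(payload$support, as.integer),
                 .path = NULL),
            class = c(if (payload$kind == "splsr_model") "splsr_model", "plsr_model"))
}

#' Export a feature mask as a flat index list (TSV)
#'
#' @param mask A `"feature_mask"`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_mask_tsv <- function(mask, file) {
  readr::write_tsv(tidy.feature_mask(mask), file)
  invisible(file)
}

#' Export a feature mask or ROI layout as a binary NIfTI map
#'
#' Writes a 2D image with 1 inside the mask and 0 elsewhere, for inspection
#' in standard viewers.
#'
#' @param mask A `"feature_mask"` (uses its original voxel indices) or an
#'   integer vector of voxel indices.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return The file path, invisibly.
#' @export
write_mask_nifti <- function(mask, dim, file) {
  idx <- if (inherits(mask, "feature_mask")) mask$voxels else as.integer(mask)
  img <- array(0L, dim = c(dim[1L], dim[2L], 1L))
  img[idx] <- 1L
  RNifti::writeNifti(RNifti::asNifti(img), file)
  invisible(file)
}
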