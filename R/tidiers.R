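# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted PLS regression into a long coefficient table
#'
#' @param x A `"plsr_model"`.
#' @param ... Unused.
#' @return A tibble with one row per voxel x task: `voxel`, `task`,
#'   `estimate`, `z` (column-wise z score of the estimate).
#' @export
tidy.plsr_model <- function(x, ...) {
  b <- x$coefficients
  z <- tryCatch(zscore_columns(b), error = function(e) b * NA_real_)
  tibble::tibble(
    voxel = rep(seq_len(nrow(b)), times = ncol(b)),
    task = rep(x$task_levels, each = nrow(b)),
    estimate = as.vector(b),
    z = as.vector(z)
  )
}

#' One-row summary of a fitted PLS regression
#'
#' @param x A `"plsr_model"`.
#' @param ... Unused.
#' @return A tibble: `n`, `p`, `q`, `ncomp`, `lambda`, `n_nonzero` (voxels
#'   with any nonzero raw-direction weight; `p` for the dense fit).
#' @export
glance.plsr_model <- function(x, ...) {
  nz <- if (!is.null(x$support)) {
    length(unique(unlist(x$support)))
  } else {
    x$p
  }
  tibble::tibble(n = x$n, p = x$p, q = x$q, ncomp = x$ncomp,
                 lambda = if (is.null(x$lambda)) NA_real_ else x$lambda,
                 n_nonzero = nz)
}

#' Tidy a feature mask into a per-task provenance table
#'
#' @param x A `"feature_mask"`.
#' @param ... Unused.
#' @return A tibble with `task` and `voxel` (original voxel index); a voxel
#'   selected by several tasks appears once per task.
#' @export
tidy.feature_mask <- function(x, ...) {
  tibble::tibble(
    task = rep(names(x$per_task), lengths(x$per_task)),
    voxel = unlist(x$per_task, use.names = FALSE)
  )
}

#' One-row summary of a decoding result
#'
#' @param x A `"decoding_result"`.
#' @param ... Unused.
#' @return A tibble with `n_correct`, `n_total`, `accuracy`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(n_correct = x$n_correct, n_total = x$n_total,
                 accuracy = x$accuracy)
}

#' Tidy an experiment into its per-cell results
#'
#' @param x A `"decoding_experiment"`.
#' @param ... Unused.
#' @return The results tibble (one row per subject x method cell).
#' @export
tidy.decoding_experiment <- function(x, ...) x$results

#' Method-by-CNR summary of an experiment
#'
#' @param x A `"decoding_experiment"`.
#' @param ... Unused.
#' @export
glance.decoding_experiment <- function(x, ...) summarize_experiment(x)

#' Accuracy-versus-CNR plot of a decoding experiment
#'
#' Mean accuracy (with one-standard-error bars) against the contrast-to-noise
#' ratio, one line per method.
#'
#' @param object A `"decoding_experiment"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_experiment <- function(object, ...) {
  summ <- summarize_experiment(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$cnr, y = .data$mean_accuracy,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_accuracy - .data$se_accuracy,
                                        ymax = .data$mean_accuracy + .data$se_accuracy),
                           width = 0.01) +
    ggplot2::labs(x = "Contrast-to-noise ratio", y = "Mean accuracy",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Raster plot of a group pattern map
#'
#' @param object A `"group_map"`.
#' @param what `"t"` (t values inside the surviving mask) or `"clusters"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_map <- function(object, what = c("t", "clusters"), ...) {
  what <- match.arg(what)
  df <- tibble::tibble(
    row = rep(seq_len(object$dim[1L]), times = object$dim[2L]),
    col = rep(seq_len(object$dim[2L]), each = object$dim[1L]),
    value = if (what == "t") ifelse(object$mask, object$t, NA_real_)
            else ifelse(object$clusters > 0L, object$clusters, NA_integer_)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = if (what == "t") "t" else "cluster") +
    ggplot2::theme_void()
}

#' Plot the ground-truth ROI layout
#'
#' @param object An `"roi_layout"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roi_layout <- function(object, ...) {
  p <- prod(object$dim)
  lab <- rep(NA_character_, p)
  for (j in seq_along(object$task_masks)) {
    lab[object$task_masks[[j]]] <- paste0("task", j)
  }
  lab[object$shared_mask] <- "shared"
  df <- tibble::tibble(
    row = rep(seq_len(object$dim[1L]), times = object$dim[2L]),
    col = rep(seq_len(object$dim[2L]), each = object$dim[1L]),
    roi = lab
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$roi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
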