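# Block-design 2D BOLD simulator: randomized four-task paradigms, canonical
# double-gamma HRF regressors added inside task-specific ROIs (plus one ROI
# shared by all tasks), Rician magnitude noise at a controlled
# contrast-to-noise ratio, and optional rigid in-plane motion.

#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF: a gamma response (delay 6 s, dispersion 1) minus a
#' gamma undershoot (delay 16 s, dispersion 1) scaled by the 6:1
#' response-to-undershoot ratio, sampled from 0 to `duration` seconds at the
#' repetition time and normalised to unit peak.
#'
#' @param tr Repetition time in seconds.
#' @param duration Kernel length in seconds (default 32).
#' @return Numeric vector of kernel samples at `0, tr, 2*tr, ...`.
#' @examples
#' h <- canonical_hrf(2)
#' which.max(h)   # peak at roughly 5-6 s
#' @export
canonical_hrf <- function(tr, duration = 32) {
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build a randomized block-design paradigm
#'
#' Task blocks (default: 16 blocks of 12 s, four per task) in randomized
#' order, alternating with rest blocks (default: 17 blocks of 6 s) so the run
#' starts and ends with rest. The run length must be divisible by the TR.
#'
#' @param n_tasks Number of tasks (default 4).
#' @param blocks_per_task Task blocks per task (default 4).
#' @param task_s,rest_s Block durations in seconds (defaults 12 and 6).
#' @param tr Repetition time in seconds (default 2).
#' @param seed Optional integer seed for the block-order randomization.
#' @return A tibble of class `"fmri_paradigm"` with columns `onset`,
#'   `duration`, `trial_type` (`"rest"` or `"task<j>"`) and `task` (integer
#'   index, `NA` for rest), plus attributes `tr` and `n_volumes`.
#' @export
make_paradigm <- function(n_tasks = 4L, blocks_per_task = 4L, task_s = 12,
                          rest_s = 6, tr = 2, seed = NULL) {
  n_tasks <- as.integer(n_tasks)
  order_tasks <- function() sample(rep(seq_len(n_tasks), each = blocks_per_task))
  task_order <- if (is.null(seed)) order_tasks() else
    withr::with_seed(as.integer(seed), order_tasks())
  n_task_blocks <- length(task_order)
  # rest, task, rest, ..., task, rest
  task <- integer(0); duration <- numeric(0)
  for (b in seq_len(n_task_blocks)) {
    task <- c(task, NA_integer_, task_order[b])
    duration <- c(duration, rest_s, task_s)
  }
  task <- c(task, NA_integer_)
  duration <- c(duration, rest_s)
  onset <- cumsum(c(0, duration[-length(duration)]))
  total <- sum(duration)
  if (abs(total / tr - round(total / tr)) > 1e-9) {
    stop("total run duration (", total, " s) is not divisible by the TR", call. = FALSE)
  }
  out <- tibble::tibble(
    onset = onset,
    duration = duration,
    trial_type = ifelse(is.na(task), "rest", paste0("task", task)),
    task = task
  )
  attr(out, "tr") <- tr
  attr(out, "n_volumes") <- as.integer(round(total / tr))
  class(out) <- c("fmri_paradigm", class(out))
  out
}

#' Per-volume task labels of a paradigm
#'
#' Labels each acquired volume by the block covering its onset time
#' (optionally shifted back by a haemodynamic lag). Rest volumes get `NA` and
#' are excluded from classification samples.
#'
#' @param paradigm An `"fmri_paradigm"`.
#' @param lag Optional label lag in seconds (default 0): volume at time t is
#'   labelled by the block covering `t - lag`.
#' @return Integer vector of length `n_volumes`; task index or `NA` for rest.
#' @export
paradigm_labels <- function(paradigm, lag = 0) {
  tr <- attr(paradigm, "tr")
  nvol <- attr(paradigm, "n_volumes")
  t_acq <- (seq_len(nvol) - 1L) * tr - lag
  block <- findInterval(t_acq, paradigm$onset)
  block[block < 1L] <- 1L
  paradigm$task[block]
}

#' HRF-convolved task regressors
#'
#' One boxcar per task (1 while that task's blocks are on, sampled at volume
#' onsets) convolved with the HRF kernel and truncated to the run length.
#'
#' @param paradigm An `"fmri_paradigm"`.
#' @param hrf HRF kernel sampled at the paradigm's TR; default
#'   [canonical_hrf()].
#' @return A `n_volumes` x `n_tasks` matrix, columns named `task1..taskq`.
#' @export
build_regressors <- function(paradigm, hrf = NULL) {
  tr <- attr(paradigm, "tr")
  nvol <- attr(paradigm, "n_volumes")
  if (is.null(hrf)) hrf <- canonical_hrf(tr)
  on_task <- paradigm_labels(paradigm, lag = 0)
  tasks <- sort(unique(paradigm$task[!is.na(paradigm$task)]))
  reg <- matrix(0, nrow = nvol, ncol = length(tasks))
  if (length(tasks) > 0L) colnames(reg) <- paste0("task", tasks)
  for (j in seq_along(tasks)) {
    box <- as.numeric(!is.na(on_task) & on_task == tasks[j])
    conv <- convolve_open(box, hrf)
    reg[, j] <- conv[seq_len(nvol)]
  }
  reg
}

# Full (open) discrete convolution, exact and deterministic.
convolve_open <- function(x, k) {
  n <- length(x) + length(k) - 1L
  out <- numeric(n)
  for (i in seq_along(k)) {
    idx <- seq_along(x) + i - 1L
    out[idx] <- out[idx] + x * k[i]
  }
  out
}

#' Default region-of-interest layout
#'
#' A parametric layout on a square grid: four disjoint square task ROIs
#' centred in the four quadrants plus one central square ROI shared by all
#' tasks. At the reference 270 x 270 grid the ROI side is 30 pixels (900
#' pixels per ROI); other grid sizes preserve the proportions.
#'
#' @param grid Image side in pixels (default 270).
#' @param baseline Baseline image intensity (default 800).
#' @param roi_frac ROI side as a fraction of the grid side (default 1/9).
#' @return An object of class `"roi_layout"`: list with `dim` (c(grid, grid)),
#'   `baseline`, `task_masks` (list of 4 integer pixel-index vectors into the
#'   column-major flattened image) and `shared_mask`.
#' @export
default_roi_layout <- function(grid = 270L, baseline = 800, roi_frac = 1 / 9) {
  grid <- as.integer(grid)
  side <- max(3L, round(grid * roi_frac))
  centers <- list(c(0.25, 0.25), c(0.75, 0.25), c(0.25, 0.75), c(0.75, 0.75))
  square <- function(cx, cy) {
    r0 <- max(1L, round(cx * grid - side / 2))
    c0 <- max(1L, round(cy * grid - side / 2))
    rows <- r0:min(grid, r0 + side - 1L)
    cols <- c0:min(grid, c0 + side - 1L)
    as.vector(outer(rows, (cols - 1L) * grid, "+"))
  }
  task_masks <- lapply(centers, function(ct) square(ct[1L], ct[2L]))
  shared_mask <- square(0.5, 0.5)
  layout <- structure(list(dim = c(grid, grid), baseline = baseline,
                           task_masks = task_masks, shared_mask = shared_mask),
                      class = "roi_layout")
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  masks <- c(layout$task_masks, list(layout$shared_mask))
  p <- prod(layout$dim)
  for (m in masks) {
    if (length(m) == 0L) stop("empty ROI mask", call. = FALSE)
    if (any(m < 1L | m > p)) stop("ROI mask indexes outside the image grid",
                                  call. = FALSE)
  }
  all_idx <- unlist(masks)
  if (anyDuplicated(all_idx)) stop("ROI masks overlap; they must be pairwise disjoint",
                                   call. = FALSE)
  invisible(layout)
}

#' @export
print.roi_layout <- function(x, ...) {
  cat("ROI layout: ", x$dim[1L], "x", x$dim[2L], " grid, baseline ", x$baseline,
      "; task ROIs of ", paste(lengths(x$task_masks), collapse = "/"),
      " px, shared ROI of ", length(x$shared_mask), " px\n", sep = "")
  invisible(x)
}

# Rigid in-plane translation of a flattened image by (dx, dy) pixels with
# bilinear resampling; out-of-frame samples take the baseline intensity.
translate_image <- function(img_vec, dim, dx, dy, fill) {
  g1 <- dim[1L]; g2 <- dim[2L]
  img <- matrix(img_vec, g1, g2)
  rows <- seq_len(g1) - dx
  cols <- seq_len(g2) - dy
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  pick <- function(ri, ci) {
    ok_r <- ri >= 1L & ri <= g1
    ok_c <- ci >= 1L & ci <= g2
    out <- matrix(fill, g1, g2)
    if (any(ok_r) && any(ok_c)) {
      out[ok_r, ok_c] <- img[ri[ok_r], ci[ok_c], drop = FALSE]
    }
    out
  }
  w <- pick(r0, c0) * outer(1 - fr, 1 - fc) +
    pick(r0 + 1L, c0) * outer(fr, 1 - fc) +
    pick(r0, c0 + 1L) * outer(1 - fr, fc) +
    pick(r0 + 1L, c0 + 1L) * outer(fr, fc)
  as.vector(w)
}

#' Render one simulated run
#'
#' Builds the noiseless signal — baseline everywhere, plus
#' `amplitude * regressor_j` inside task ROI j and `amplitude * sum of all
#' task regressors` inside the shared ROI — then applies optional rigid
#' per-volume motion (random-walk translation, bilinear resampling) and
#' Rician corruption `sqrt((v + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`.
#'
#' @param layout An `"roi_layout"`.
#' @param paradigm An `"fmri_paradigm"` (for regressors and volume labels).
#' @param amplitude Task signal amplitude in image units.
#' @param sigma Rician noise standard deviation; 0 for noiseless data.
#' @param seed Optional integer seed (noise and motion draws).
#' @param motion_sd Per-volume random-walk translation step (pixels) in each
#'   axis; 0 (default) disables motion.
#' @param hrf HRF kernel; default [canonical_hrf()] at the paradigm's TR.
#' @return A list of class `"sim_run"`: `data` (n_volumes x n_pixels matrix),
#'   `labels` (per-volume task index, `NA` for rest), `paradigm`,
#'   `regressors`, `layout`, `amplitude`, `sigma`.
#' @export
render_run <- function(layout, paradigm, amplitude, sigma, seed = NULL,
                       motion_sd = 0, hrf = NULL) {
  validate_layout(layout)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  reg <- build_regressors(paradigm, hrf = hrf)
  nvol <- nrow(reg)
  p <- prod(layout$dim)
  data <- matrix(layout$baseline, nrow = nvol, ncol = p)
  for (j in seq_along(layout$task_masks)) {
    data[, layout$task_masks[[j]]] <- layout$baseline + amplitude * reg[, j]
  }
  data[, layout$shared_mask] <- layout$baseline + amplitude * rowSums(reg)
  render <- function() {
    if (motion_sd > 0) {
      dx <- cumsum(stats::rnorm(nvol, 0, motion_sd))
      dy <- cumsum(stats::rnorm(nvol, 0, motion_sd))
      for (i in seq_len(nvol)) {
        data[i, ] <- translate_image(data[i, ], layout$dim, dx[i], dy[i],
                                     fill = layout$baseline)
      }
    }
    if (sigma > 0) {
      n1 <- matrix(stats::rnorm(length(data), 0, sigma), nrow = nvol)
      n2 <- matrix(stats::rnorm(length(data), 0, sigma), nrow = nvol)
      data <- sqrt((data + n1)^2 + n2^2)
    }
    data
  }
  data <- if (is.null(seed)) render() else withr::with_seed(as.integer(seed), render())
  structure(list(data = data, labels = paradigm_labels(paradigm),
                 paradigm = paradigm, regressors = reg, layout = layout,
                 amplitude = amplitude, sigma = sigma),
            class = "sim_run")
}

# Deterministic per-cell seed derivation, kept below 2^31 - 1. Exact in
# double arithmetic because every intermediate stays below 2^53.
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  for (v in parts) h <- (h * 69069 + v + 1) %% 2147483629
  as.integer(h + 1)
}

#' Generate one simulated subject (two runs)
#'
#' Two runs with independently randomized block orders, at a given
#' contrast-to-noise ratio realised as `amplitude = cnr * sigma`.
#'
#' @param cnr Contrast-to-noise ratio (task amplitude over Rician sigma).
#' @param layout ROI layout; default [default_roi_layout()].
#' @param sigma Rician noise sd in image units (default 30).
#' @param seed Integer seed for this subject; run-level seeds are derived
#'   from it deterministically.
#' @param motion_sd Per-volume motion step in pixels (default 0, off).
#' @param tr Repetition time in seconds.
#' @return A list of class `"sim_subject"` with `runs` (two `"sim_run"`s),
#'   `cnr`, `sigma`, `amplitude`, `seed`.
#' @export
generate_subject <- function(cnr, layout = default_roi_layout(), sigma = 30,
                             seed = 1L, motion_sd = 0, tr = 2) {
  if (cnr < 0) stop("`cnr` must be non-negative", call. = FALSE)
  amplitude <- cnr * sigma
  runs <- lapply(1:2, function(r) {
    par_seed <- derive_seed(seed, 101, r)
    noise_seed <- derive_seed(seed, 202, r)
    paradigm <- make_paradigm(tr = tr, seed = par_seed)
    render_run(layout, paradigm, amplitude = amplitude, sigma = sigma,
               seed = noise_seed, motion_sd = motion_sd)
  })
  structure(list(runs = runs, cnr = cnr, sigma = sigma, amplitude = amplitude,
                 seed = seed),
            class = "sim_subject")
}

#' Generate a multi-subject, multi-CNR simulated study
#'
#' The full study design: `n_subjects` simulated subjects at each
#' contrast-to-noise level, each with two runs of a randomized four-task
#' block design (default: 16 task blocks of 12 s alternating with 17 rest
#' blocks of 6 s, TR 2 s, 147 volumes per run).
#'
#' @param cnr_levels Numeric vector of CNR levels (default
#'   `c(0.05, 0.1, 0.2, 0.4)`).
#' @param n_subjects Subjects per CNR level (default 15).
#' @param seed Master seed; all subject/run/noise seeds derive from it.
#' @inheritParams generate_subject
#' @return A list of class `"simulated_study"`: `subjects` (tibble with
#'   columns `cnr`, `subject`, `data` — list column of `"sim_subject"`s),
#'   `layout`, `sigma`, `seed`.
#' @export
generate_study <- function(cnr_levels = c(0.05, 0.1, 0.2, 0.4),
                           n_subjects = 15L, layout = default_roi_layout(),
                           sigma = 30, seed = 1L, motion_sd = 0, tr = 2) {
  cells <- tidyr::expand_grid(cnr = cnr_levels, subject = seq_len(n_subjects))
  cells$data <- purrr::pmap(cells, function(cnr, subject) {
    generate_subject(cnr, layout = layout, sigma = sigma,
                     seed = derive_seed(seed, which(cnr_levels == cnr), subject),
                     motion_sd = motion_sd, tr = tr)
  })
  structure(list(subjects = cells, layout = layout, sigma = sigma, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated study: ", nrow(x$subjects), " dataset(s) (",
      length(unique(x$subjects$cnr)), " CNR level(s) x ",
      length(unique(x$subjects$subject)), " subject(s)), grid ",
      x$layout$dim[1L], "x", x$layout$dim[2L], ", sigma ", x$sigma, "\n", sep = "")
  invisible(x)
}
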