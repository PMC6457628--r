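# Orchestration of the six-method comparison: {SPLSR, PLSR, GLM} feature
# selection crossed with {PLSR argmax, linear-SVM one-vs-one voting}
# classification, plus group-level pattern maps and paired Wilcoxon
# comparisons of methods.

#' The six selector-by-classifier method combinations
#'
#' @return A tibble with columns `name`, `selector` (`splsr_z`, `plsr_z`,
#'   `glm_t`) and `classifier` (`plsr_argmax`, `svm_vote`).
#' @export
method_specs <- function() {
  tibble::tibble(
    name = c("SP_PLSR", "P_PLSR", "G_PLSR", "SP_SVM", "P_SVM", "G_SVM"),
    selector = rep(c("splsr_z", "plsr_z", "glm_t"), 2L),
    classifier = rep(c("plsr_argmax", "svm_vote"), each = 3L)
  )
}

# Default pipeline configuration; any element can be overridden through the
# `config` argument of run_subject()/run_experiment().
default_config <- function() {
  list(
    z_threshold = 3.5,
    glm_alpha = 0.001,
    ncomp_grid = NULL,      # NULL -> 1:min(10, n - 1, p)
    folds = 5L,
    lambda_grid = NULL,     # NULL -> 0 plus 20 geometric points up to lambda_max
    svm_costs = c(0.1, 1, 10),
    label_lag = 4
  )
}

merge_config <- function(config = list()) {
  utils::modifyList(default_config(), config)
}

#' Fit a feature selector on a training run
#'
#' Dispatches on the selector name: `plsr_z` / `splsr_z` fit a (sparse) PLS
#' regression on the task-labelled volumes and apply the z > 3.5 rule to the
#' coefficient columns; `glm_t` fits voxel-wise OLS of the full run on the
#' HRF-convolved task regressors and applies the one-sided p < 0.001 rule.
#'
#' @param x_norm Normalised training run (volumes x kept voxels, with the
#'   `voxel_index` attribute from [normalize_run()]).
#' @param labels Per-volume task labels (`NA` for rest volumes).
#' @param selector One of `"plsr_z"`, `"splsr_z"`, `"glm_t"`.
#' @param design Time x q regressor matrix (needed for `glm_t`).
#' @param config Configuration overrides, see the package vignette.
#' @param seed Optional integer seed for the internal cross-validations.
#' @return A list: `mask` (`"feature_mask"`), `ncomp`, `lambda` (sparse
#'   selector only).
#' @export
fit_selector <- function(x_norm, labels, selector, design = NULL,
                         config = list(), seed = NULL) {
  cfg <- merge_config(config)
  voxel_index <- attr(x_norm, "voxel_index")
  if (is.null(voxel_index)) voxel_index <- seq_len(ncol(x_norm))
  task_rows <- which(!is.na(labels))
  if (selector == "glm_t") {
    if (is.null(design)) stop("`design` is required for the GLM selector", call. = FALSE)
    tmap <- glm_t_maps(x_norm, design)
    mask <- select_features_glm(tmap, alpha = cfg$glm_alpha,
                                voxel_index = voxel_index)
    return(list(mask = mask, ncomp = NA_integer_, lambda = NA_real_))
  }
  xt <- x_norm[task_rows, , drop = FALSE]
  yt <- as.integer(labels[task_rows])
  sel <- select_n_components(xt, yt, ncomp_grid = cfg$ncomp_grid,
                             folds = cfg$folds, seed = seed)
  if (selector == "plsr_z") {
    fit <- suppressWarnings(fit_plsr(xt, yt, ncomp = sel$ncomp))
    lambda <- NA_real_
  } else if (selector == "splsr_z") {
    tuned <- tune_lambda(xt, yt, ncomp = sel$ncomp,
                         lambda_grid = cfg$lambda_grid, folds = cfg$folds,
                         seed = if (is.null(seed)) NULL else seed + 1L)
    lambda <- tuned$lambda
    fit <- suppressWarnings(fit_splsr(xt, yt, ncomp = sel$ncomp, lambda = lambda))
  } else {
    stop("unknown selector: ", selector, call. = FALSE)
  }
  b <- fit$coefficients
  attr(b, "selector") <- selector
  mask <- select_features_z(b, threshold = cfg$z_threshold,
                            voxel_index = voxel_index)
  list(mask = mask, ncomp = fit$ncomp, lambda = lambda)
}

#' One-vs-one majority vote
#'
#' Combines the `q(q-1)/2` pairwise decisions of binary classifiers into a
#' multiclass prediction: the task with the most pairwise wins. Vote ties go
#' to the smallest task index (counted in the `n_ties` attribute).
#'
#' @param decisions An N x P matrix of winning task indices, one column per
#'   task pair.
#' @param pairs A P x 2 matrix of the task pairs the columns refer to.
#' @param q Number of tasks; all `choose(q, 2)` pairs must be present.
#' @return Integer vector of predicted task indices with attribute `n_ties`.
#' @export
one_vs_one_vote <- function(decisions, pairs, q) {
  decisions <- as.matrix(decisions)
  pairs <- as.matrix(pairs)
  need <- t(utils::combn(q, 2L))
  have <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  if (nrow(have) != nrow(need) || !all(have == need)) {
    stop("all ", nrow(need), " task pairs must be present exactly once", call. = FALSE)
  }
  if (ncol(decisions) != nrow(pairs)) {
    stop("`decisions` must have one column per pair", call. = FALSE)
  }
  votes <- matrix(0L, nrow = nrow(decisions), ncol = q)
  for (j in seq_len(ncol(decisions))) {
    for (k in seq_len(nrow(decisions))) {
      votes[k, decisions[k, j]] <- votes[k, decisions[k, j]] + 1L
    }
  }
  argmax_with_ties(votes)
}

# Linear-SVM one-vs-one classifier: one binary SVM per task pair, cost chosen
# by stratified CV on the pair's training samples, combined by majority vote.
train_svm_ovo <- function(x, labels, mask, costs = c(0.1, 1, 10), folds = 5L,
                          seed = NULL) {
  stopifnot(inherits(mask, "feature_mask"))
  xm <- x[, mask$columns, drop = FALSE]
  labels <- as.integer(labels)
  q <- max(labels)
  pairs <- t(utils::combn(q, 2L))
  fits <- vector("list", nrow(pairs))
  for (pr in seq_len(nrow(pairs))) {
    a <- pairs[pr, 1L]; b <- pairs[pr, 2L]
    idx <- which(labels %in% c(a, b))
    xp <- xm[idx, , drop = FALSE]
    yp <- factor(labels[idx], levels = c(a, b))
    cost <- tune_svm_cost(xp, yp, costs, folds,
                          seed = if (is.null(seed)) NULL else seed + pr)
    fits[[pr]] <- e1071::svm(xp, yp, kernel = "linear", cost = cost,
                             scale = FALSE)
    attr(fits[[pr]], "cost") <- cost
  }
  structure(list(fits = fits, pairs = pairs, mask = mask, q = q),
            class = "svm_ovo_classifier")
}

tune_svm_cost <- function(x, y, costs, folds, seed = NULL) {
  if (length(costs) == 1L) return(costs)
  folds <- min(folds, min(table(y)))
  if (folds < 2L) return(costs[1L])
  fold_id <- stratified_folds(as.integer(y), folds, seed)
  err <- vapply(costs, function(cost) {
    e <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- e1071::svm(x[tr, , drop = FALSE], droplevels(y[tr]),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      e <- e + sum(pred != y[!tr])
    }
    e
  }, numeric(1L))
  costs[which.min(err)]
}

#' @export
predict.svm_ovo_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  xm <- as.matrix(newdata)[, object$mask$columns, drop = FALSE]
  decisions <- matrix(0L, nrow = nrow(xm), ncol = nrow(object$pairs))
  for (pr in seq_len(nrow(object$pairs))) {
    pred <- predict(object$fits[[pr]], xm)
    decisions[, pr] <- as.integer(as.character(pred))
  }
  one_vs_one_vote(decisions, object$pairs, object$q)
}

#' Run one subject through a selector/classifier combination
#'
#' The per-subject decoding protocol: the first run is the training data and
#' the second the testing data. Zero-variance voxels are identified on the
#' training run only and the same kept set is applied to both runs; the
#' selector and the classifier see the training run only, and the test run
#' enters only at prediction time. A `"no features selected"` failure is
#' returned as a row with `NA` accuracy, not an error.
#'
#' @param train_run,test_run `"sim_run"` objects (or lists with `data`,
#'   `labels` and `regressors`/`paradigm` elements).
#' @param method A row of [method_specs()] (or a name from it).
#' @param tasks Task subset to decode (default `1:4`); volumes of other tasks
#'   are dropped and labels are re-indexed to `1..length(tasks)`.
#' @param config Configuration overrides (see [fit_selector()]).
#' @param seed Optional integer seed for the internal cross-validations.
#' @param keep_fit Also return the trained classifier and mask (default
#'   `FALSE`).
#' @return A one-row tibble: `method`, `selector`, `classifier`, `n_features`,
#'   `ncomp`, `lambda`, `n_test`, `n_correct`, `accuracy`, `note`; with
#'   `keep_fit = TRUE`, a list with `row`, `classifier`, `mask`.
#' @export
run_subject <- function(train_run, test_run, method, tasks = NULL,
                        config = list(), seed = NULL, keep_fit = FALSE) {
  if (is.character(method)) {
    specs <- method_specs()
    method <- specs[specs$name == method, ]
    if (nrow(method) != 1L) stop("unknown method name", call. = FALSE)
  }
  cfg <- merge_config(config)
  labels_train <- paradigm_labels(train_run$paradigm, lag = cfg$label_lag)
  labels_test <- paradigm_labels(test_run$paradigm, lag = cfg$label_lag)
  if (is.null(tasks)) tasks <- sort(unique(labels_train[!is.na(labels_train)]))

  keep <- which(apply(train_run$data, 2L, stats::sd) > 0)
  xtr <- suppressWarnings(normalize_run(train_run$data, keep = keep))

  sel <- tryCatch(
    fit_selector(xtr, labels_train, method$selector,
                 design = train_run$regressors, config = cfg, seed = seed),
    error = function(e) e)
  if (inherits(sel, "error")) {
    row <- result_row(method, n_features = 0L, ncomp = NA_integer_,
                      lambda = NA_real_, n_test = NA_integer_,
                      n_correct = NA_integer_, accuracy = NA_real_,
                      note = conditionMessage(sel))
    return(if (keep_fit) list(row = row, classifier = NULL, mask = NULL) else row)
  }

  sub_train <- which(labels_train %in% tasks)
  ytr <- match(labels_train[sub_train], tasks)
  xm_train <- xtr[sub_train, , drop = FALSE]
  clf <- if (method$classifier == "plsr_argmax") {
    train_plsr_classifier(xm_train, ytr, sel$mask, ncomp_grid = cfg$ncomp_grid,
                          folds = cfg$folds,
                          seed = if (is.null(seed)) NULL else seed + 7L)
  } else {
    train_svm_ovo(xm_train, ytr, sel$mask, costs = cfg$svm_costs,
                  folds = cfg$folds,
                  seed = if (is.null(seed)) NULL else seed + 7L)
  }

  xte <- normalize_run(test_run$data, keep = keep)
  sub_test <- which(labels_test %in% tasks)
  yte <- match(labels_test[sub_test], tasks)
  pred <- predict(clf, xte[sub_test, , drop = FALSE])
  res <- score(pred, yte)
  row <- result_row(method, n_features = length(sel$mask$columns),
                    ncomp = sel$ncomp, lambda = sel$lambda,
                    n_test = res$n_total, n_correct = res$n_correct,
                    accuracy = res$accuracy, note = NA_character_)
  if (keep_fit) list(row = row, classifier = clf, mask = sel$mask) else row
}

result_row <- function(spec, n_features, ncomp, lambda, n_test, n_correct,
                       accuracy, note) {
  tibble::tibble(method = spec$name, selector = spec$selector,
                 classifier = spec$classifier,
                 n_features = as.integer(n_features),
                 ncomp = as.integer(ncomp), lambda = as.numeric(lambda),
                 n_test = as.integer(n_test),
                 n_correct = as.integer(n_correct),
                 accuracy = as.numeric(accuracy), note = note)
}

#' Run the full simulated decoding experiment
#'
#' The factorial driver: for every contrast-to-noise level and simulated
#' subject, generates the two-run dataset, fits every requested selector once
#' and evaluates every selector-by-classifier method on the requested task
#' subsets. Subjects are generated one at a time from per-cell seeds derived
#' from the master seed, so results are reproducible and memory stays flat.
#'
#' @param cnr_levels CNR levels (default `c(0.05, 0.1, 0.2, 0.4)`).
#' @param n_subjects Subjects per level (default 15).
#' @param methods Method names from [method_specs()] (default all six).
#' @param tasks Task subset (default all four tasks).
#' @param grid Image side in pixels (default 270; reduce for desk-scale runs).
#' @param sigma Rician noise sd (default 30).
#' @param seed Master seed (default 1).
#' @param config Pipeline configuration overrides.
#' @param motion_sd Per-volume motion step in pixels (default 0).
#' @return An object of class `"decoding_experiment"`: list with `results`
#'   (tibble: subject, cnr, method, selector, classifier, accuracy, ...),
#'   `config` and the call parameters.
#' @export
run_experiment <- function(cnr_levels = c(0.05, 0.1, 0.2, 0.4),
                           n_subjects = 15L,
                           methods = method_specs()$name,
                           tasks = 1:4, grid = 270L, sigma = 30,
                           seed = 1L, config = list(), motion_sd = 0) {
  specs <- method_specs()
  specs <- specs[specs$name %in% methods, ]
  if (nrow(specs) == 0L) stop("no known methods requested", call. = FALSE)
  layout <- default_roi_layout(grid = grid)
  cfg <- merge_config(config)
  rows <- list()
  for (ci in seq_along(cnr_levels)) {
    for (s in seq_len(n_subjects)) {
      subj <- generate_subject(cnr_levels[ci], layout = layout, sigma = sigma,
                               seed = derive_seed(seed, ci, s),
                               motion_sd = motion_sd)
      shared <- subject_method_rows(subj, specs, tasks, cfg,
                                    seed = derive_seed(seed, ci, s, 3))
      shared$cnr <- cnr_levels[ci]
      shared$subject <- s
      rows[[length(rows) + 1L]] <- shared
    }
  }
  results <- dplyr::bind_rows(rows)
  results <- dplyr::relocate(results, "cnr", "subject")
  structure(list(results = results, config = cfg,
                 params = list(cnr_levels = cnr_levels, n_subjects = n_subjects,
                               tasks = tasks, grid = grid, sigma = sigma,
                               seed = seed, motion_sd = motion_sd)),
            class = "decoding_experiment")
}

# All requested methods for one subject, fitting each selector only once.
subject_method_rows <- function(subj, specs, tasks, cfg, seed) {
  train_run <- subj$runs[[1L]]; test_run <- subj$runs[[2L]]
  labels_train <- paradigm_labels(train_run$paradigm, lag = cfg$label_lag)
  labels_test <- paradigm_labels(test_run$paradigm, lag = cfg$label_lag)
  keep <- which(apply(train_run$data, 2L, stats::sd) > 0)
  xtr <- suppressWarnings(normalize_run(train_run$data, keep = keep))
  xte <- normalize_run(test_run$data, keep = keep)
  sub_train <- which(labels_train %in% tasks)
  ytr <- match(labels_train[sub_train], tasks)
  xm_train <- xtr[sub_train, , drop = FALSE]
  sub_test <- which(labels_test %in% tasks)
  yte <- match(labels_test[sub_test], tasks)
  xm_test <- xte[sub_test, , drop = FALSE]

  sel_cache <- list()
  out <- list()
  for (i in seq_len(nrow(specs))) {
    method <- specs[i, ]
    sel <- sel_cache[[method$selector]]
    if (is.null(sel)) {
      sel <- tryCatch(
        fit_selector(xtr, labels_train, method$selector,
                     design = train_run$regressors, config = cfg, seed = seed),
        error = function(e) e)
      sel_cache[[method$selector]] <- sel
    }
    if (inherits(sel, "error")) {
      out[[i]] <- result_row(method, 0L, NA_integer_, NA_real_, NA_integer_,
                             NA_integer_, NA_real_, conditionMessage(sel))
      next
    }
    clf <- if (method$classifier == "plsr_argmax") {
      train_plsr_classifier(xm_train, ytr, sel$mask, ncomp_grid = cfg$ncomp_grid,
                            folds = cfg$folds, seed = seed + 7L)
    } else {
      train_svm_ovo(xm_train, ytr, sel$mask, costs = cfg$svm_costs,
                    folds = cfg$folds, seed = seed + 7L)
    }
    pred <- predict(clf, xm_test)
    res <- score(pred, yte)
    out[[i]] <- result_row(method, length(sel$mask$columns), sel$ncomp,
                           sel$lambda, res$n_total, res$n_correct,
                           res$accuracy, NA_character_)
  }
  dplyr::bind_rows(out)
}

#' @export
print.decoding_experiment <- function(x, ...) {
  cat("Decoding experiment: ", nrow(x$results), " cells (",
      length(x$params$cnr_levels), " CNR level(s) x ", x$params$n_subjects,
      " subject(s) x ", length(unique(x$results$method)), " method(s))\n", sep = "")
  print(summarize_experiment(x))
  invisible(x)
}

#' Mean accuracy per method and CNR level
#'
#' @param experiment A `"decoding_experiment"` (or its results tibble).
#' @return A tibble with `method`, `cnr`, `n`, `mean_accuracy`, `sd_accuracy`,
#'   `se_accuracy`; failed cells (NA accuracy) are dropped with their count in
#'   `n_failed`.
#' @export
summarize_experiment <- function(experiment) {
  results <- if (inherits(experiment, "decoding_experiment")) {
    experiment$results
  } else {
    experiment
  }
  results |>
    dplyr::group_by(.data$method, .data$cnr) |>
    dplyr::summarise(
      n = sum(!is.na(.data$accuracy)),
      n_failed = sum(is.na(.data$accuracy)),
      mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
      sd_accuracy = stats::sd(.data$accuracy, na.rm = TRUE),
      se_accuracy = .data$sd_accuracy / sqrt(pmax(.data$n, 1L)),
      .groups = "drop"
    )
}

#' Group-level pattern map with cluster-size thresholding
#'
#' Per voxel, a one-sample t test across subjects of the per-subject weight
#' maps (one-sided, positive weights); voxels with p below the voxel-level
#' threshold are kept, and surviving connected components whose size is not
#' strictly greater than `min_cluster` are removed (8-neighbour connectivity
#' in 2D by default).
#'
#' @param weight_maps A subjects x voxels matrix of spatially aligned maps.
#' @param dim Image dimensions `c(rows, cols)` of the flattened maps.
#' @param voxel_p Voxel-level p threshold (default 0.001).
#' @param min_cluster Minimum cluster size; components must exceed it
#'   strictly, so the default 25 keeps clusters of 26 voxels or more.
#' @param connectivity 8 (default) or 4 neighbour connectivity.
#' @return An object of class `"group_map"`: list with `t` (voxel t values),
#'   `mask` (logical, surviving voxels), `clusters` (integer labels, 0 =
#'   background), `df`, `dim` and the thresholds.
#' @export
group_pattern_map <- function(weight_maps, dim, voxel_p = 0.001,
                              min_cluster = 25L, connectivity = 8L) {
  weight_maps <- as.matrix(weight_maps)
  n <- nrow(weight_maps)
  if (n < 2L) stop("at least two subjects are required", call. = FALSE)
  if (ncol(weight_maps) != prod(dim)) {
    stop("maps are not aligned with the stated image dimensions", call. = FALSE)
  }
  mu <- colMeans(weight_maps)
  sdv <- apply(weight_maps, 2L, stats::sd)
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
  df <- n - 1L
  pval <- stats::pt(tval, df = df, lower.tail = FALSE)
  supra <- pval < voxel_p
  labels <- label_clusters(matrix(supra, dim[1L], dim[2L]),
                           connectivity = connectivity)
  sizes <- tabulate(labels)
  keep_ids <- which(sizes > min_cluster)
  mask <- labels %in% keep_ids & labels > 0L
  clusters <- ifelse(mask, match(labels, keep_ids), 0L)
  structure(list(t = tval, mask = as.vector(mask),
                 clusters = as.vector(clusters), df = df, dim = dim,
                 voxel_p = voxel_p, min_cluster = min_cluster,
                 connectivity = connectivity),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  k <- max(x$clusters)
  cat("Group pattern map: ", sum(x$mask), " voxel(s) in ", k,
      " cluster(s) surviving p < ", x$voxel_p, " & size > ", x$min_cluster,
      "\n", sep = "")
  invisible(x)
}

# Connected-component labelling of a logical matrix (4- or 8-neighbour),
# iterative flood fill; labels are assigned in column-major scan order.
label_clusters <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  g1 <- nrow(mask); g2 <- ncol(mask)
  offsets <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))[-5L, ]
  }
  labels <- matrix(0L, g1, g2)
  current <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((v - 1L) %% g1) + 1L
      cc <- ((v - 1L) %/% g1) + 1L
      for (o in seq_len(nrow(offsets))) {
        rn <- r + offsets[o, 1L]; cn <- cc + offsets[o, 2L]
        if (rn >= 1L && rn <= g1 && cn >= 1L && cn <= g2) {
          idx <- (cn - 1L) * g1 + rn
          if (mask[idx] && labels[idx] == 0L) {
            labels[idx] <- current
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  labels
}

#' Paired Wilcoxon comparisons between methods
#'
#' Two-sided Wilcoxon signed-rank tests on the paired per-subject accuracies
#' of method pairs, within each CNR level. By default every pair of methods
#' sharing a selector or sharing a classifier is compared. Zero differences
#' are dropped (the classic signed-rank convention); a pair whose differences
#' are all zero is reported with `p_value = NA` and flagged not significant.
#'
#' @param results A `"decoding_experiment"` or its results tibble (columns
#'   `cnr`, `subject`, `method`, `accuracy`).
#' @param pairs Optional 2-column character matrix (or list of length-2
#'   vectors) of method names to compare.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A tibble: `cnr`, `method_a`, `method_b`, `n_pairs`, `statistic`,
#'   `p_value`, `significant`, `better` (the method with the higher mean).
#' @export
compare_methods <- function(results, pairs = NULL, alpha = 0.05) {
  if (inherits(results, "decoding_experiment")) results <- results$results
  if (is.null(pairs)) {
    specs <- method_specs()
    specs <- specs[specs$name %in% unique(results$method), ]
    cand <- t(utils::combn(specs$name, 2L))
    shares <- apply(cand, 1L, function(pr) {
      a <- specs[specs$name == pr[1L], ]; b <- specs[specs$name == pr[2L], ]
      a$selector == b$selector || a$classifier == b$classifier
    })
    pairs <- cand[shares, , drop = FALSE]
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  out <- list()
  for (lev in unique(results$cnr)) {
    sub <- results[results$cnr == lev, ]
    for (i in seq_len(nrow(pairs))) {
      a <- sub[sub$method == pairs[i, 1L], ]
      b <- sub[sub$method == pairs[i, 2L], ]
      a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
      common <- intersect(a$subject[!is.na(a$accuracy)],
                          b$subject[!is.na(b$accuracy)])
      if (length(common) < 2L) {
        stop("paired comparison needs at least two complete subject pairs",
             call. = FALSE)
      }
      xa <- a$accuracy[match(common, a$subject)]
      xb <- b$accuracy[match(common, b$subject)]
      if (all(xa == xb)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          cnr = lev, method_a = pairs[i, 1L], method_b = pairs[i, 2L],
          n_pairs = length(common), statistic = NA_real_, p_value = NA_real_,
          significant = FALSE, better = NA_character_)
        next
      }
      wt <- suppressWarnings(stats::wilcox.test(xa, xb, paired = TRUE,
                                                exact = FALSE, correct = TRUE))
      out[[length(out) + 1L]] <- tibble::tibble(
        cnr = lev, method_a = pairs[i, 1L], method_b = pairs[i, 2L],
        n_pairs = length(common), statistic = unname(wt$statistic),
        p_value = wt$p.value, significant = wt$p.value < alpha,
        better = if (mean(xa) >= mean(xb)) pairs[i, 1L] else pairs[i, 2L])
    }
  }
  dplyr::bind_rows(out)
}

#' Selection-recovery study against simulator ground truth
#'
#' For each simulated subject, fits the requested selectors on the first run
#' and compares the per-task selected voxels with the ground-truth
#' task-specific ROIs: the Jaccard index per task (shared ROI excluded from
#' the truth) and the hit rate inside the shared ROI (fraction of shared-ROI
#' voxels in the selection union). A selector that selects nothing for a
#' subject contributes an empty selection rather than an error.
#'
#' @param cnr Contrast-to-noise ratio of the simulated subjects.
#' @param n_subjects Number of subjects (default 15).
#' @param selectors Selector names (subset of `plsr_z`, `splsr_z`, `glm_t`).
#' @param grid Image side in pixels.
#' @param sigma Rician noise sd.
#' @param seed Master seed.
#' @param config Pipeline configuration overrides.
#' @return A tibble with one row per subject x selector: `subject`,
#'   `selector`, `mean_jaccard` (mean over the four tasks), `n_selected`,
#'   `shared_hits`, `shared_size`.
#' @export
selection_recovery <- function(cnr, n_subjects = 15L,
                               selectors = c("plsr_z", "splsr_z"),
                               grid = 96L, sigma = 30, seed = 1L,
                               config = list()) {
  layout <- default_roi_layout(grid = grid)
  cfg <- merge_config(config)
  truth <- lapply(layout$task_masks, sort)
  shared <- sort(layout$shared_mask)
  jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
  }
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj <- generate_subject(cnr, layout = layout, sigma = sigma,
                             seed = derive_seed(seed, 11, s))
    run <- subj$runs[[1L]]
    labels <- paradigm_labels(run$paradigm, lag = cfg$label_lag)
    xtr <- suppressWarnings(normalize_run(run$data))
    for (sel_name in selectors) {
      sel <- tryCatch(
        fit_selector(xtr, labels, sel_name, design = run$regressors,
                     config = cfg, seed = derive_seed(seed, 13, s)),
        error = function(e) NULL)
      per_task <- if (is.null(sel)) rep(list(integer(0)), 4L) else sel$mask$per_task
      union_sel <- sort(unique(unlist(per_task)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = s, selector = sel_name,
        mean_jaccard = mean(vapply(seq_along(truth), function(j)
          jaccard(per_task[[j]], truth[[j]]), numeric(1))),
        n_selected = length(union_sel),
        shared_hits = length(intersect(union_sel, shared)),
        shared_size = length(shared))
    }
  }
  dplyr::bind_rows(rows)
}
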