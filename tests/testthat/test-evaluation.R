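test_that("the six method names are determined by selector x classifier", {
  specs <- method_specs()
  expect_equal(nrow(specs), 6L)
  expect_equal(anyDuplicated(specs$name), 0L)
  expect_equal(anyDuplicated(specs[, c("selector", "classifier")]), 0L)
  expect_setequal(specs$name,
                  c("SP_PLSR", "P_PLSR", "G_PLSR", "SP_SVM", "P_SVM", "G_SVM"))
})

test_that("one-vs-one voting counts pairwise wins and breaks ties low", {
  pairs3 <- t(combn(3, 2))
  # task 2 wins both of its pairs
  d <- rbind(c(2L, 1L, 2L))
  expect_equal(one_vs_one_vote(d, pairs3, 3)[1], 2L)
  # cyclic q = 4: tasks 1..3 each win two pairs -> smallest leader
  pairs4 <- t(combn(4, 2))
  # pairs: 12 13 14 23 24 34; wins: 1>2, 3>1, 1>4, 2>3, 2>4, 3>4
  d4 <- rbind(c(1L, 3L, 1L, 2L, 2L, 3L))
  v <- one_vs_one_vote(d4, pairs4, 4)
  expect_equal(v[1], 1L)
  expect_equal(attr(v, "n_ties"), 1L)
  expect_error(one_vs_one_vote(d[, 1:2, drop = FALSE], pairs3[1:2, ], 3),
               "pairs must be present")
})

test_that("the delegated linear SVM solves a separable toy exactly", {
  withr::with_seed(211, {
    labels <- rep_len(1:3, 30)[sample(30)]
    x <- matrix(rnorm(30 * 5, sd = 0.1), 30, 5)
  })
  for (j in 1:3) x[labels == j, j] <- x[labels == j, j] + 5
  mask <- plsdecode:::new_feature_mask(list(1L, 2L, 3L), 1:5, "plsr_z", 3.5)
  clf <- plsdecode:::train_svm_ovo(x, labels, mask, costs = 1)
  expect_equal(predict(clf, x), labels, ignore_attr = TRUE)
})

test_that("cluster labelling respects connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE     # touching only diagonally
  lab8 <- plsdecode:::label_clusters(m, connectivity = 8L)
  lab4 <- plsdecode:::label_clusters(m, connectivity = 4L)
  expect_equal(max(lab8), 1L)
  expect_equal(max(lab4), 2L)
  m[4, 4] <- TRUE                       # isolated third voxel
  expect_equal(max(plsdecode:::label_clusters(m, 8L)), 2L)
})

test_that("group maps apply the strict cluster-size rule", {
  dim2 <- c(30L, 30L)
  p <- prod(dim2)
  n_sub <- 15L
  base <- withr::with_seed(221, matrix(rnorm(n_sub * p, sd = 0.1), n_sub, p))
  # a 5x5 block (25 voxels: must be removed) and a 6x6 block (36: kept)
  block <- function(r0, c0, k) as.vector(outer(r0:(r0 + k - 1),
                                               (c0:(c0 + k - 1) - 1) * dim2[1], "+"))
  b25 <- block(2, 2, 5); b36 <- block(15, 15, 6)
  maps <- base
  maps[, c(b25, b36)] <- maps[, c(b25, b36)] + 1
  gm <- group_pattern_map(maps, dim2, voxel_p = 0.001, min_cluster = 25L)
  expect_true(all(gm$mask[b36]))
  expect_false(any(gm$mask[b25]))
  # isolated single-voxel false positives cannot survive
  expect_equal(sort(unique(which(gm$mask))), sort(b36))

  empty <- group_pattern_map(matrix(0, 5, p), dim2)
  expect_equal(sum(empty$mask), 0L)
  expect_error(group_pattern_map(maps, c(10L, 10L)), "aligned")
  expect_error(group_pattern_map(maps[1, , drop = FALSE], dim2), "two subjects")
})

test_that("paired Wilcoxon comparisons flag shifts and not identical vectors", {
  acc <- withr::with_seed(231, runif(15, 0.5, 0.9))
  tbl <- tibble::tibble(
    cnr = 0.1,
    subject = rep(1:15, 2),
    method = rep(c("P_PLSR", "P_SVM"), each = 15),
    accuracy = c(acc, acc - 0.1)
  )
  out <- compare_methods(tbl, pairs = rbind(c("P_PLSR", "P_SVM")))
  expect_true(out$significant)
  expect_equal(out$better, "P_PLSR")
  expect_lt(out$p_value, 0.05)

  tbl$accuracy <- rep(acc, 2)
  same <- compare_methods(tbl, pairs = rbind(c("P_PLSR", "P_SVM")))
  expect_false(same$significant)
  expect_true(is.na(same$p_value))

  one <- tbl[tbl$subject == 1, ]
  expect_error(compare_methods(one, pairs = rbind(c("P_PLSR", "P_SVM"))),
               "at least two")
})

test_that("per-subject decoding is deterministic and leakage-free", {
  subj <- small_subject(0.4, seed = 303)
  a <- run_subject(subj$runs[[1]], subj$runs[[2]], "P_PLSR", seed = 11)
  b <- run_subject(subj$runs[[1]], subj$runs[[2]], "P_PLSR", seed = 11)
  expect_identical(a, b)
  expect_gt(a$accuracy, 0.5)

  # sentinel poisoning: a different test run must leave the trained model
  # byte-identical (selector and classifier never see test data)
  fit1 <- run_subject(subj$runs[[1]], subj$runs[[2]], "P_PLSR", seed = 11,
                      keep_fit = TRUE)
  poisoned <- subj$runs[[2]]
  poisoned$data <- poisoned$data +
    withr::with_seed(99, matrix(rnorm(length(poisoned$data), sd = 50),
                                nrow(poisoned$data)))
  fit2 <- run_subject(subj$runs[[1]], poisoned, "P_PLSR", seed = 11,
                      keep_fit = TRUE)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit1$classifier, f1)
  write_model_json(fit2$classifier, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a failed selection becomes an NA row, not a crash", {
  subj <- small_subject(0.4, seed = 305)
  row <- run_subject(subj$runs[[1]], subj$runs[[2]], "P_PLSR",
                     config = list(z_threshold = Inf), seed = 1)
  expect_true(is.na(row$accuracy))
  expect_match(row$note, "no features")
})

test_that("the factorial driver books one row per cell and reruns identically", {
  ex <- run_experiment(cnr_levels = 0.4, n_subjects = 3,
                       methods = c("P_PLSR", "G_PLSR"), grid = 48L, seed = 21)
  expect_equal(nrow(ex$results), 6L)   # 1 CNR x 3 subjects x 2 methods
  expect_true(all(ex$results$accuracy >= 0 & ex$results$accuracy <= 1,
                  na.rm = TRUE))
  ex2 <- run_experiment(cnr_levels = 0.4, n_subjects = 3,
                        methods = c("P_PLSR", "G_PLSR"), grid = 48L, seed = 21)
  expect_identical(ex$results, ex2$results)
  summ <- summarize_experiment(ex)
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$n + summ$n_failed, rep(3L, 2))
})

test_that("decoders sit at chance when the mask carries no signal", {
  subj <- small_subject(0, seed = 307, grid = 48L)   # CNR 0: pure noise
  keep <- seq_len(48L * 48L)
  xtr <- normalize_run(subj$runs[[1]]$data, keep = keep)
  xte <- normalize_run(subj$runs[[2]]$data, keep = keep)
  lab_tr <- paradigm_labels(subj$runs[[1]]$paradigm, lag = 4)
  lab_te <- paradigm_labels(subj$runs[[2]]$paradigm, lag = 4)
  rows_tr <- which(!is.na(lab_tr)); rows_te <- which(!is.na(lab_te))
  mask <- plsdecode:::new_feature_mask(list(1:10, 11:20, 21:30, 31:40),
                                       keep, "plsr_z", 3.5)
  clf <- train_plsr_classifier(xtr[rows_tr, ], as.integer(lab_tr[rows_tr]),
                               mask, ncomp = 3)
  res <- score(predict(clf, xte[rows_te, ]), as.integer(lab_te[rows_te]))
  tol <- 3 * sqrt(0.25 * 0.75 / res$n_total)
  expect_lt(abs(res$accuracy - 0.25), tol + 0.05)
})

test_that("tidiers and plots expose the fitted objects", {
  prob <- random_problem(20, 6, 2, seed = 401)
  fit <- fit_plsr(prob$x, prob$labels, ncomp = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 6L * 2L)
  expect_equal(matrix(td$estimate, 6, 2), unname(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$ncomp, 2L)
  expect_equal(gl$n_nonzero, 6L)

  sp <- fit_splsr(prob$x, prob$labels, ncomp = 1,
                  lambda = lambda_max(prob$x, prob$labels) / 2)
  expect_lte(glance(sp)$n_nonzero, 6L)

  ex <- structure(list(results = tibble::tibble(
    cnr = rep(c(0.1, 0.4), each = 4), subject = rep(1:2, 4),
    method = rep(c("P_PLSR", "G_SVM"), 4),
    accuracy = runif(8)), config = list()), class = "decoding_experiment")
  expect_s3_class(autoplot(ex), "ggplot")
  gm <- group_pattern_map(matrix(rnorm(5 * 100), 5, 100), c(10L, 10L))
  expect_s3_class(autoplot(gm), "ggplot")
  expect_s3_class(autoplot(default_roi_layout(27L)), "ggplot")
})
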