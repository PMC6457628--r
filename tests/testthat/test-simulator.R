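test_that("the canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(2)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # independent fine-grid evaluation of the closed-form double gamma
  tg <- seq(0, 32, by = 0.01)
  fine <- dgamma(tg, 6, 1) - dgamma(tg, 16, 1) / 6
  peak_t <- tg[which.max(fine)]
  expect_gte(peak_t, 5); expect_lte(peak_t, 6)
  # exactly one sign change: positive lobe then undershoot
  sgn <- sign(h[h != 0])
  expect_equal(sum(diff(sgn) != 0), 1L)
})

test_that("paradigm bookkeeping matches the block design", {
  par <- make_paradigm(seed = 7)
  expect_equal(nrow(par), 33L)                       # 16 task + 17 rest blocks
  expect_equal(sum(par$trial_type == "rest"), 17L)
  expect_equal(unname(table(par$task[!is.na(par$task)])), rep(4L, 4L),
               ignore_attr = TRUE)
  expect_equal(par$duration[is.na(par$task)], rep(6, 17))
  expect_equal(par$duration[!is.na(par$task)], rep(12, 16))
  expect_equal(attr(par, "n_volumes"), 147L)         # (16*12 + 17*6) / 2

  for (lag in c(0, 4)) {
    lab <- paradigm_labels(par, lag = lag)
    expect_length(lab, 147L)
    expect_equal(sum(!is.na(lab)), 96L)              # 16 * 12 / 2 task volumes
    expect_equal(unname(table(lab)), rep(24L, 4L), ignore_attr = TRUE)
  }

  expect_identical(make_paradigm(seed = 7), par)     # deterministic given seed
  expect_false(identical(make_paradigm(seed = 8)$task, par$task))
})

test_that("regressors are causal HRF-convolved boxcars", {
  par <- make_paradigm(seed = 9)
  reg <- build_regressors(par)
  expect_equal(dim(reg), c(147L, 4L))
  expect_true(all(reg >= min(canonical_hrf(2)) * 6))
  # single-block paradigm: rises after onset, peaks after offset, decays
  single <- par[par$onset <= par$onset[which(!is.na(par$task))[1]], ]
  onset_vol <- single$onset[nrow(single)] / 2 + 1
  r1 <- reg[, single$task[nrow(single)]]
  expect_equal(unname(r1[seq_len(onset_vol)]), rep(0, onset_vol))
  # untruncated convolution mass identity
  box <- rep(c(0, 1, 0), c(5, 6, 10))
  h <- canonical_hrf(2)
  full <- plsdecode:::convolve_open(box, h)
  expect_equal(sum(full), sum(box) * sum(h), tolerance = 1e-12)
  # all-rest paradigm has no task regressors
  rest_only <- par[is.na(par$task), ][1, ]
  attr(rest_only, "tr") <- 2; attr(rest_only, "n_volumes") <- 3L
  class(rest_only) <- c("fmri_paradigm", class(rest_only))
  expect_equal(ncol(build_regressors(rest_only)), 0L)
})

test_that("the ROI layout is disjoint, non-empty and proportion-preserving", {
  for (g in c(270L, 96L)) {
    layout <- default_roi_layout(grid = g)
    masks <- c(layout$task_masks, list(layout$shared_mask))
    expect_true(all(lengths(masks) >= 100))
    expect_equal(anyDuplicated(unlist(masks)), 0L)
    expect_true(all(unlist(masks) >= 1 & unlist(masks) <= g * g))
  }
  expect_equal(length(default_roi_layout(270L)$task_masks[[1]]), 900L)
})

test_that("noiseless rendering is exact: baseline outside, signal inside", {
  layout <- default_roi_layout(grid = 48)
  par <- make_paradigm(seed = 5)
  run <- render_run(layout, par, amplitude = 10, sigma = 0)
  expect_equal(dim(run$data), c(147L, 48L * 48L))
  outside <- setdiff(seq_len(48 * 48),
                     unlist(c(layout$task_masks, list(layout$shared_mask))))
  expect_true(all(run$data[, outside] == 800))
  v <- layout$task_masks[[1]][1]
  expect_equal(run$data[, v], 800 + 10 * run$regressors[, 1])
  s <- layout$shared_mask[1]
  expect_equal(run$data[, s], 800 + 10 * rowSums(run$regressors))
})

test_that("Rician corruption matches the analytic first moment", {
  layout <- default_roi_layout(grid = 40)
  par <- make_paradigm(seed = 5)
  run <- render_run(layout, par, amplitude = 0, sigma = 30, seed = 77)
  outside <- setdiff(seq_len(40 * 40),
                     unlist(c(layout$task_masks, list(layout$shared_mask))))
  draws <- run$data[, outside]
  # E[R] for Rice(nu, sigma): sigma sqrt(pi/2) L_{1/2}(-x), x = nu^2 / (2 sigma^2)
  nu <- 800; sigma <- 30
  x <- nu^2 / (2 * sigma^2)
  l_half <- (1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
    x * besselI(x / 2, 1, expon.scaled = TRUE)
  expected <- sigma * sqrt(pi / 2) * l_half
  expect_equal(expected, sqrt(nu^2 + sigma^2), tolerance = 1e-3)  # high-SNR limit
  se <- sd(as.vector(draws)) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 4 * se)
})

test_that("rigid motion resampling leaves a shifted copy inside the frame", {
  img <- matrix(0, 10, 10); img[4, 5] <- 1
  shifted <- matrix(plsdecode:::translate_image(as.vector(img), c(10L, 10L),
                                                dx = 2, dy = -1, fill = 0),
                    10, 10)
  expect_equal(shifted[6, 4], 1)
  expect_equal(sum(shifted), 1)
  # fractional shift spreads mass bilinearly but conserves it away from edges
  frac <- matrix(plsdecode:::translate_image(as.vector(img), c(10L, 10L),
                                             dx = 0.5, dy = 0, fill = 0),
                 10, 10)
  expect_equal(sum(frac), 1, tolerance = 1e-12)
  expect_equal(frac[4, 5], 0.5); expect_equal(frac[5, 5], 0.5)
})

test_that("subject and study generation are deterministic with distinct runs", {
  layout <- default_roi_layout(grid = 32)
  a <- generate_subject(0.2, layout = layout, sigma = 30, seed = 12)
  b <- generate_subject(0.2, layout = layout, sigma = 30, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$runs[[1]]$paradigm$task, a$runs[[2]]$paradigm$task))
  expect_equal(a$amplitude, 0.2 * 30)

  study <- generate_study(n_subjects = 15L, layout = layout, sigma = 0, seed = 4)
  expect_equal(nrow(study$subjects), 60L)   # 15 subjects x 4 CNR levels
  study2 <- generate_study(n_subjects = 15L, layout = layout, sigma = 0, seed = 4)
  expect_identical(study$subjects$data[[7]], study2$subjects$data[[7]])
})

test_that("paradigms and runs round-trip through their text/NIfTI formats", {
  par <- make_paradigm(seed = 31)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(par, f)
  back <- read_events_tsv(f, tr = 2)
  expect_equal(back$onset, par$onset)
  expect_equal(back$task, par$task)
  expect_equal(attr(back, "n_volumes"), 147L)
  expect_equal(paradigm_labels(back), paradigm_labels(par))

  layout <- default_roi_layout(grid = 16)
  run <- render_run(layout, par, amplitude = 5, sigma = 1, seed = 3)
  nf <- withr::local_tempfile(fileext = ".nii.gz")
  write_run_nifti(run, nf)
  mat <- read_run_nifti(nf)
  expect_equal(dim(mat), dim(run$data))
  expect_equal(as.vector(mat), as.vector(run$data), tolerance = 1e-6)
})
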