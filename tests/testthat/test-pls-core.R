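test_that("column centring removes means and stores offsets", {
  out <- center_columns(matrix(c(1, 3, 5, 5), 2))
  expect_equal(out$values[, 1], c(-1, 1))
  expect_equal(out$center, c(2, 5))
  expect_equal(out$values[, 2], c(0, 0))

  m <- withr::with_seed(11, matrix(rnorm(15), 5, 3))
  cc <- center_columns(m)
  expect_lt(max(abs(colMeans(cc$values))), 1e-12)

  expect_error(center_columns(matrix(c(1, NA), 1)), "non-finite")
})

test_that("dummy coding produces the 0/1 indicator with unit row sums", {
  expect_equal(dummy_code(c(1, 2, 1, 3), 3),
               rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)))
  expect_equal(dummy_code(c(2, 1), 2), rbind(c(0, 1), c(1, 0)))
  expect_error(dummy_code(rep(1, 4), 1), "q >= 2")
  expect_error(dummy_code(c(1, 4), 3), "1..3")
  expect_error(dummy_code(c(1, 1, 3), 3), "no samples")
})

test_that("stage direction matches an independent eigendecomposition", {
  # q = 1: closed form, r proportional to the single row of Z
  withr::with_seed(21, {
    xr <- scale(matrix(rnorm(20), 5, 4), scale = FALSE)
    yr <- scale(matrix(rnorm(5), 5, 1), scale = FALSE)
  })
  z <- crossprod(yr, xr)
  r <- nipals_direction(xr, yr)
  expect_equal(abs(r), abs(as.vector(z) / sqrt(sum(z^2))), tolerance = 1e-10)
  expect_gt(r[which.max(abs(r))], 0)

  # q = 2: oracle = dominant eigenvector of Z'Z by dense eigen()
  withr::with_seed(22, {
    xr <- scale(matrix(rnorm(12), 4, 3), scale = FALSE)
    yr <- scale(dummy_code(c(1, 2, 1, 2), 2), scale = FALSE)
  })
  z <- crossprod(yr, xr)
  ev <- eigen(crossprod(z), symmetric = TRUE)$vectors[, 1]
  r <- nipals_direction(xr, yr)
  expect_lt(min(max(abs(r - ev)), max(abs(r + ev))), 1e-10)

  expect_null(nipals_direction(xr, matrix(0, 4, 2)))
})

test_that("stage direction maximises the quadratic form over random unit vectors", {
  for (s in 1:5) {
    prob <- random_problem(5, 4, 2, seed = 300 + s)
    xr <- scale(prob$x, scale = FALSE)
    yr <- scale(prob$indicator, scale = FALSE)
    z <- crossprod(yr, xr)
    r <- nipals_direction(xr, yr)
    obj <- drop(crossprod(z %*% r))
    rand <- withr::with_seed(400 + s, matrix(rnorm(1000 * 4), 1000, 4))
    rand <- rand / sqrt(rowSums(rand^2))
    rand_obj <- rowSums((rand %*% t(z))^2)
    expect_gte(obj, max(rand_obj))
  }
})

test_that("full-rank PLS reproduces the least-squares solution", {
  for (s in 1:5) {
    p <- sample(4:8, 1)
    prob <- random_problem(40, p, 3, seed = 500 + s)
    fit <- fit_plsr(prob$x, prob$labels, ncomp = p)
    xc <- scale(prob$x, scale = FALSE)
    yc <- scale(prob$indicator, scale = FALSE)
    b_ols <- solve(crossprod(xc), crossprod(xc, yc))
    expect_matrix_equal(fit$coefficients, b_ols, tol = 1e-6)
    pred_ols <- sweep(xc %*% b_ols, 2, colMeans(prob$indicator), "+")
    expect_matrix_equal(predict(fit, prob$x), pred_ols, tol = 1e-6)
  }
})

test_that("fitted models satisfy the NIPALS constraints", {
  for (s in 1:5) {
    prob <- random_problem(20, 12, 3, seed = 600 + s)
    fit <- fit_plsr(prob$x, prob$labels, ncomp = 4)
    # unit-norm raw directions
    expect_lt(max(abs(colSums(fit$raw_directions^2) - 1)), 1e-10)
    # scores mutually orthogonal (normalised off-diagonal inner products)
    tt <- crossprod(fit$scores)
    nrm <- sqrt(diag(tt))
    cors <- abs(tt / outer(nrm, nrm))
    diag(cors) <- 0
    expect_lt(max(cors), 1e-8)
    # T = X_centred W
    xc <- scale(prob$x, scale = FALSE)
    expect_matrix_equal(fit$scores, xc %*% fit$directions, tol = 1e-8)
  }
})

test_that("noiseless rank-1 responses are recovered exactly with one component", {
  # rank-1 predictors driving a noiseless response: one latent component is
  # the exact model, so a single-component fit reproduces Y
  withr::with_seed(71, {
    t_lat <- rnorm(30)
    load <- rnorm(6)
    b_true <- matrix(rnorm(12), 6, 2)
  })
  x <- t_lat %*% t(load)
  xc <- scale(x, scale = FALSE)
  y <- xc %*% b_true
  fit <- fit_one_component_pls(x, y)
  expect_matrix_equal(predict(fit, x), y, tol = 1e-8)
})

test_that("training-set reconstruction is exact at full rank", {
  prob <- random_problem(25, 5, 3, seed = 81)
  fit <- fit_plsr(prob$x, prob$labels, ncomp = 5)
  resid <- prob$indicator - fitted(fit)
  expect_matrix_equal(predict(fit, prob$x) + resid, prob$indicator, tol = 1e-8)
})

test_that("prediction applies the stored centring", {
  prob <- random_problem(16, 6, 2, seed = 91)
  fit <- fit_plsr(prob$x, prob$labels, ncomp = 3)
  # a training row predicts its own fitted value
  expect_equal(drop(predict(fit, prob$x[3, ])), fitted(fit)[3, ],
               tolerance = 1e-10)
  # the training mean maps to the response means
  expect_equal(drop(predict(fit, colMeans(prob$x))),
               colMeans(prob$indicator), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(predict(fit, matrix(0, 2, 5)), "voxels")
})

test_that("component-count limits and degenerate inputs are rejected", {
  prob <- random_problem(10, 4, 2, seed = 101)
  expect_error(fit_plsr(prob$x, prob$labels, ncomp = 0), "ncomp")
  expect_error(fit_plsr(prob$x, prob$labels, ncomp = 5), "ncomp")
  expect_error(fit_plsr(prob$x, matrix(0, 10, 2)), "row sums")
})

test_that("cross-validation picks one component for rank-1 signal and is deterministic", {
  withr::with_seed(111, {
    labels <- rep_len(1:2, 24)[sample(24)]
    yd <- dummy_code(labels, 2)
    yc <- scale(yd, scale = FALSE)
    x <- yc %*% matrix(rnorm(2 * 8), 2, 8)   # pure rank-1 class signal
  })
  sel <- select_n_components(x, labels, ncomp_grid = 1:3, seed = 5)
  expect_equal(sel$ncomp, 1L)
  expect_equal(nrow(sel$cv), 3L)

  noise <- random_problem(20, 6, 2, seed = 121)
  a <- select_n_components(noise$x, noise$labels, seed = 9)
  b <- select_n_components(noise$x, noise$labels, seed = 9)
  expect_identical(a, b)
  expect_true(a$ncomp %in% a$cv$ncomp)

  expect_error(select_n_components(noise$x, noise$labels, folds = 12),
               "at least")
})

test_that("cross-validation recovers a planted two-component signal", {
  hits <- 0L
  for (s in 1:50) {
    prob <- planted_component_problem(80, 30, 3, noise_sd = 0.5, seed = 1000 + s)
    sel <- select_n_components(prob$x, prob$labels, ncomp_grid = 1:5,
                               seed = 2000 + s)
    hits <- hits + (sel$ncomp == 2L)
  }
  expect_gte(hits, 45L)   # >= 90% of 50 replicates
})


test_that("predictions agree with an independent PLS2 implementation", {
  # mixOmics fits classical NIPALS PLS2; fitted responses must coincide with
  # the projection-deflation scheme at every component count
  x <- withr::with_seed(91, matrix(rnorm(30 * 12), 30, 12,
                                   dimnames = list(NULL, paste0("v", 1:12))))
  labels <- withr::with_seed(92, rep_len(1:3, 30)[sample(30)])
  yd <- dummy_code(labels, 3)
  fit <- fit_plsr(x, labels, ncomp = 4)
  ref <- suppressMessages(mixOmics::pls(x, yd, ncomp = 4, mode = "regression",
                                        scale = FALSE))
  xc <- scale(x, scale = FALSE)
  for (k in c(1L, 2L, 4L)) {
    ours <- sweep(xc %*% plsdecode:::coef_at_k(fit, k), 2, colMeans(yd), "+")
    theirs <- predict(ref, newdata = x)$predict[, , k]
    expect_lt(max(abs(ours - theirs)), 1e-10)
  }
})
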