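# Small in-code fixtures shared across the test files.

# Random multi-class problem with iid Gaussian predictors.
random_problem <- function(n, p, q, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    labels <- rep_len(seq_len(q), n)[sample(n)]
    list(x = x, labels = labels, indicator = dummy_code(labels, q))
  })
}

# Class-driven low-rank signal: X = Yc M + noise, so the X/Y relation has
# exactly q - 1 informative dimensions.
planted_component_problem <- function(n, p, q, noise_sd, seed) {
  withr::with_seed(seed, {
    labels <- rep_len(seq_len(q), n)[sample(n)]
    yd <- dummy_code(labels, q)
    yc <- scale(yd, scale = FALSE)
    m <- matrix(rnorm(q * p), q, p)
    x <- yc %*% m + matrix(rnorm(n * p, sd = noise_sd), n, p)
    list(x = x, labels = labels)
  })
}

# Two-class data where only the first `k_signal` of p voxels carry signal.
sparse_signal_problem <- function(n, p, k_signal, effect, noise_sd, seed) {
  withr::with_seed(seed, {
    labels <- rep_len(1:2, n)[sample(n)]
    x <- matrix(rnorm(n * p, sd = noise_sd), n, p)
    x[, seq_len(k_signal)] <- x[, seq_len(k_signal)] +
      effect * (labels == 1)
    list(x = x, labels = labels)
  })
}

# Small simulated subject for end-to-end tests (desk-scale grid).
small_subject <- function(cnr, seed, grid = 48L, sigma = 30) {
  generate_subject(cnr, layout = default_roi_layout(grid = grid),
                   sigma = sigma, seed = seed)
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}

# Build a feature mask over the identity voxel geometry.
new_feature_mask_for_test <- function(per_task_columns, p) {
  plsdecode:::new_feature_mask(per_task_columns, seq_len(p), "plsr_z", 3.5)
}

# One-component PLS fit for an arbitrary numeric multi-response Y, assembled
# from the exported building blocks (indicator responses are the package's
# use case; this reaches the engine's algebra directly).
fit_one_component_pls <- function(x, y) {
  cx <- center_columns(x)
  cy <- center_columns(y)
  r <- nipals_direction(cx$values, cy$values)
  tk <- cx$values %*% r
  qy <- crossprod(cy$values, tk) / drop(crossprod(tk))
  g <- crossprod(cx$values, tk) / drop(crossprod(tk))
  w <- r / drop(crossprod(g, r))
  b <- w %*% t(qy)
  structure(list(coefficients = b, x_center = cx$center, y_center = cy$center,
                 task_levels = colnames(y), p = ncol(x), q = ncol(y)),
            class = "plsr_model")
}

# Brute-force 1-D oracle for one coordinate of the penalised direction
# problem: scan the objective 1/2 ||Z_j - C r||^2 + lambda |r| over a grid.
scan_soft_threshold_minimizer <- function(zj, c_vec, lambda,
                                          lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  obj <- 0.5 * (sum(zj^2) - 2 * grid * sum(c_vec * zj) +
                  grid^2 * sum(c_vec^2)) + lambda * abs(grid)
  grid[which.min(obj)]
}

# Max coordinate-wise deviation between the closed-form soft-threshold
# direction and the scan oracle over `n_problems` random problems.
soft_threshold_oracle_deviation <- function(n_problems, seed_base) {
  worst <- 0
  for (s in seq_len(n_problems)) {
    withr::with_seed(seed_base + s, {
      z <- matrix(rnorm(3 * 6, sd = 0.8), 3, 6)
      c_vec <- rnorm(3)
      c_vec <- c_vec / sqrt(sum(c_vec^2))
      lambda <- runif(1, 0, 1.5)
    })
    r <- soft_threshold_direction(z, c_vec, lambda, normalize = FALSE)
    if (is.null(r)) r <- rep(0, ncol(z))
    oracle <- vapply(seq_len(ncol(z)), function(j)
      scan_soft_threshold_minimizer(z[, j], c_vec, lambda), numeric(1))
    worst <- max(worst, max(abs(r - oracle)))
  }
  worst
}

# Max |B_pls - B_ols| over random full-rank problems (n = 40, p <= 10).
ols_limit_deviation <- function(n_problems, seed_base) {
  worst <- 0
  for (s in seq_len(n_problems)) {
    p <- withr::with_seed(seed_base + s, sample(4:10, 1))
    prob <- random_problem(40, p, 3, seed = seed_base + 100 + s)
    fit <- fit_plsr(prob$x, prob$labels, ncomp = p)
    xc <- scale(prob$x, scale = FALSE)
    yc <- scale(prob$indicator, scale = FALSE)
    b_ols <- solve(crossprod(xc), crossprod(xc, yc))
    worst <- max(worst, max(abs(fit$coefficients - b_ols)))
  }
  worst
}
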