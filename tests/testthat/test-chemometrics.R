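test_that("PCA matches the covariance eigendecomposition up to sign", {
  set.seed(14)
  X <- matrix(rnorm(12 * 7), 12)
  k <- 4
  p <- pca_fit(X, k)
  ev <- eigen(cov(X), symmetric = TRUE)
  for (j in 1:k) {
    v <- ev$vectors[, j]
    expect_lt(min(sum((p$loadings[j, ] - v)^2),
                  sum((p$loadings[j, ] + v)^2)), 1e-16)
  }
  # explained variance ratios from the same eigenvalues
  expect_equal(p$explained_variance_ratio,
               (ev$values / sum(ev$values))[1:k], tolerance = 1e-8)
  # loadings orthonormal, scores covariance diagonal
  G <- p$loadings %*% t(p$loadings)
  expect_equal(G, diag(k), tolerance = 1e-8, ignore_attr = TRUE)
  S <- cov(p$scores)
  expect_lt(max(abs(S - diag(diag(S)))), 1e-8)
  # deterministic sign convention
  for (j in 1:k)
    expect_gt(p$loadings[j, which.max(abs(p$loadings[j, ]))], 0)
  expect_error(pca_fit(X, 12), "exceeds")
})

test_that("PCA handles rank-1 data and row permutation equivariance", {
  v <- rnorm(9)
  X1 <- outer(c(1, 3, -2, 5), v)
  p1 <- pca_fit(X1, 1)
  expect_equal(p1$explained_variance_ratio[1], 1.0, tolerance = 1e-12)
  set.seed(15)
  X <- matrix(rnorm(10 * 6), 10)
  perm <- sample(10)
  pa <- pca_fit(X, 3)
  pb <- pca_fit(X[perm, ], 3)
  expect_equal(pb$loadings, pa$loadings, tolerance = 1e-10)
  expect_equal(pb$scores, pa$scores[perm, ], tolerance = 1e-10)
})

test_that("PLS1 nails a single-direction signal in one factor", {
  set.seed(16)
  # X varies along one direction only; y is proportional to one column
  X <- outer(rnorm(20), rnorm(9))
  y <- 3 * X[, 4]
  m <- pls1(X, y, n_factors = 1)
  expect_lt(max(abs(residuals(m))), 1e-10)
  expect_equal(fitted(m) + residuals(m), y)
})

test_that("full-rank PLS1 equals the least-squares oracle on 8x5 data", {
  for (sd_ in 1:3) {
    set.seed(sd_)
    X <- matrix(rnorm(8 * 5), 8)
    y <- rnorm(8)
    m <- pls1(X, y, n_factors = 5)
    ols <- lm.fit(cbind(1, X), y)
    expect_equal(unname(m$fitted.values), unname(ols$fitted.values),
                 tolerance = 1e-8)
    expect_equal(unname(coef(m)), unname(coef(ols)[-1]), tolerance = 1e-8)
  }
})

test_that("PLS1 guards its preconditions", {
  X <- matrix(rnorm(8 * 5), 8)
  expect_error(pls1(X, rep(1, 8)), "zero variance")
  expect_error(pls1(X, rnorm(8), n_factors = 6), "achievable rank 5")
  expect_error(pls1(X, rnorm(7)), "length")
})

test_that("shuffled responses land in the permutation null", {
  set.seed(17)
  n <- 30
  X <- matrix(rnorm(n * 15), n)
  y <- drop(X %*% rnorm(15))
  null_r2 <- replicate(200, pls1(X, sample(y), n_factors = 1)$r.squared)
  # a shuffled fit is indistinguishable from the null it belongs to
  one_shuffle <- pls1(X, sample(y), n_factors = 1)$r.squared
  expect_gte(one_shuffle, min(null_r2) - 1e-12)
  expect_lte(one_shuffle, max(null_r2) + 1e-12)
  # while the true relation sits far outside it
  expect_gt(pls1(X, y, n_factors = 1)$r.squared,
            quantile(null_r2, 0.99))
  expect_lt(median(null_r2), 0.5)
})

test_that("regression-vector and factor-wise predictions coincide", {
  set.seed(18)
  X <- matrix(rnorm(25 * 30), 25)
  y <- drop(X[, 1:3] %*% c(1, -2, 0.5)) + rnorm(25, 0, 0.1)
  m <- pls1(X, y, n_factors = 4)
  Xnew <- matrix(rnorm(6 * 30), 6)
  expect_equal(predict(m, Xnew),
               predict(m, Xnew, method = "factorwise"), tolerance = 1e-10)
  expect_equal(predict(m, X), fitted(m), tolerance = 1e-10)
  expect_error(predict(m, Xnew[, 1:7]), "model expects")
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(19)
  X <- matrix(rnorm(15 * 8), 15)
  m <- pls1(X, rnorm(15), n_factors = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls1_json(m, path)
  back <- read_pls1_json(path)
  Xnew <- matrix(rnorm(4 * 8), 4)
  expect_equal(predict(back, Xnew), predict(m, Xnew), tolerance = 1e-12)
})

test_that("kernel LOOCV equals refitting the model on every fold", {
  set.seed(20)
  X <- matrix(rnorm(18 * 10), 18)
  y <- drop(X %*% rnorm(10)) + rnorm(18, 0, 0.4)
  cv <- loocv(X, y, max_factors = 4)
  naive <- matrix(NA_real_, 18, 4)
  for (i in 1:18)
    for (a in 1:4)
      naive[i, a] <- predict(pls1(X[-i, ], y[-i], a), X[i, , drop = FALSE])
  expect_equal(cv$loo_predictions, naive, tolerance = 1e-10)
  expect_equal(cv$press_by_factor, colSums((naive - y)^2),
               tolerance = 1e-10)
  expect_equal(cv$rmsecv, sqrt(cv$press_by_factor / 18))
})

test_that("three-point LOOCV matches hand arithmetic", {
  # single predictor: a 1-factor PLS1 on two points is the line through them
  x <- c(1, 2, 4)
  y <- c(1, 3, 2)
  cv <- loocv(matrix(x), y, max_factors = 1)
  hand <- numeric(3)
  for (i in 1:3) {
    xt <- x[-i]; yt <- y[-i]
    slope <- diff(yt) / diff(xt)
    hand[i] <- yt[1] + slope * (x[i] - xt[1])
  }
  expect_equal(drop(cv$loo_predictions), hand, tolerance = 1e-10)
  expect_equal(cv$press_by_factor[[1]], sum((hand - y)^2),
               tolerance = 1e-10)
})

test_that("PRESS picks the planted dimension on noiseless rank-2 data", {
  for (sd_ in 1:5) {
    prob <- rank2_problem(sd_)
    cv <- loocv(prob$X, prob$y, max_factors = 6)
    expect_identical(cv$chosen_factors, 2L)
    expect_lt(cv$press_by_factor[2], cv$press_by_factor[1])  # strict
  }
})

test_that("pure-noise responses do not reward extra factors", {
  deltas <- vapply(1:20, function(sd_) {
    set.seed(100 + sd_)
    X <- matrix(rnorm(15 * 20), 15)
    y <- rnorm(15)
    cv <- loocv(X, y, max_factors = 5)
    cv$rmsecv[5] - cv$rmsecv[1]
  }, numeric(1))
  expect_gte(median(deltas), 0)
})

test_that("the stratified split honours the 75/25 design", {
  st <- simulate_study(sim_config(seed = 42))
  sp <- split_train_validation(st$sers, seed = 7)
  expect_equal(nrow(sp$train$X), 135L)
  expect_equal(nrow(sp$validation$X), 45L)
  expect_true(all(table(sp$train$labels) == 15L))
  # partition property
  expect_setequal(c(sp$train_idx, sp$validation_idx), 1:180)
  expect_length(intersect(sp$train_idx, sp$validation_idx), 0)
  # determinism
  sp2 <- split_train_validation(st$sers, seed = 7)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_train_validation(st$sers, fraction = 1.2), "\\(0, 1\\)")
  lso <- split_train_validation(st$sers, mode = "leave_sample_out",
                                seed = 7)
  expect_length(intersect(unique(lso$train$labels),
                          unique(lso$validation$labels)), 0)
})

test_that("held-out metrics behave as defined", {
  set.seed(23)
  X <- matrix(rnorm(10 * 4), 10)
  y <- drop(X %*% c(1, 2, 0, -1))
  m <- pls1(X, y, n_factors = 4)
  perfect <- evaluate(m, X, y)
  expect_equal(perfect$rmsep, 0, tolerance = 1e-8)
  expect_equal(perfect$r2, 1, tolerance = 1e-8)
  # constant offset: RMSEP = |c| but correlation R2 stays 1
  off <- evaluate(m, X, y - 3)
  expect_equal(off$rmsep, 3, tolerance = 1e-8)
  expect_equal(off$r2, 1, tolerance = 1e-8)
  expect_lt(off$r2_determination, 1)
  # hand-computed 4-point toy set
  pred <- c(1, 2, 3, 4); act <- c(1.5, 1.5, 3.5, 3.5)
  toy <- list(p = 1, x_mean = 0, y_mean = 0,
              coefficients = 1, n_factors = 1)
  class(toy) <- "pls1"
  ev <- evaluate(toy, matrix(pred), act)
  expect_equal(ev$rmsep, sqrt(mean((pred - act)^2)))
  expect_equal(ev$r2, cor(pred, act)^2)
  expect_warning(const <- evaluate(m, X, rep(2, 10)), "constant")
  expect_true(const$constant_actuals)
  expect_true(is.na(const$r2))
  expect_gt(const$rmsep, 0)
})

test_that("replicate-level splits leak class structure; sample-level do not", {
  # moderate noise, so generalization to unseen extracts is genuinely
  # harder than interpolating within extracts; the direction is a median
  # effect, individual splits fluctuate
  diffs <- unlist(lapply(c(7, 42, 77), function(seed) {
    st <- simulate_study(sim_config(seed = seed, noise_sd = 0.1))
    pp <- preprocess_chain(st$sers)
    pp$y <- st$truth$s1[match(pp$labels, st$truth$sample_id)]
    r2_of <- function(mode, ss) {
      sp <- split_train_validation(pp, mode = mode, seed = ss)
      cv <- loocv(sp$train, max_factors = 6)
      m <- pls1(sp$train, n_factors = cv$chosen_factors)
      evaluate(m, sp$validation)$r2
    }
    vapply(1:3, function(ss)
      r2_of("leave_sample_out", ss) - r2_of("replicate_random", ss),
      numeric(1))
  }))
  expect_lte(median(diffs), 0)
})

test_that("loading diagnostics recover a planted driving band", {
  grid <- seq(1200, 1450, 1)
  set.seed(25)
  n <- 24
  amp <- runif(n, 0.5, 2)
  X <- t(vapply(amp, function(a)
    lorentz_trace(grid, c(1330, 1400), c(a, 1), c(10, 10)) +
      rnorm(length(grid), 0, 0.002), numeric(length(grid))))
  mat <- spectral_matrix(grid, X, kind = "raman")
  mat$y <- amp
  m <- pls1(mat, n_factors = 2)
  diag <- loading_diagnostics(m, tolerance = 15)
  top <- diag[diag$factor == "0 (regression vector)" & diag$rank == 1, ]
  expect_lte(abs(top$position - 1330), 15)
  expect_equal(top$assignment,
               "inter-ring stretching (B ring, C-H bending)")
  # empty table: everything unassigned
  empty <- band_assignments()[0, ]
  d2 <- loading_diagnostics(m, table = empty)
  expect_true(all(d2$assignment == "unassigned"))
  # tolerance semantics: a band 6 cm^-1 away misses a 0.5 cm^-1 window
  d3 <- loading_diagnostics(m, table = data.frame(
    center = top$position + 6, assignment = "x"), tolerance = 0.5)
  expect_equal(d3$assignment[d3$rank == 1][1], "unassigned")
})
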