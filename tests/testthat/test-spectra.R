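test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(1:3, 1:2, "raman"), "lengths differ")
  expect_error(spectrum(5, 1, "raman"), "at least 2")
  expect_error(spectrum(c(500, 400, 450), 1:3, "uvvis"),
               "strictly increasing")
  s <- spectrum(1:5, rnorm(5), "raman")
  expect_s3_class(s, "spectrum")
})

test_that("wide-CSV round trip preserves axis, intensities and metadata", {
  set.seed(42)
  grid <- seq(300, 2000, 7)
  X <- matrix(rexp(4 * length(grid)), 4)
  meta <- data.frame(sample_id = c("a", "a", "b", "b"),
                     pH = c(3, 6, 3, NA),
                     iron_treated = c(TRUE, FALSE, TRUE, FALSE),
                     replicate_id = c("1", "1", "2", "2"),
                     stringsAsFactors = FALSE)
  mat <- spectral_matrix(grid, X, labels = meta$sample_id, kind = "raman",
                         meta = meta)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(mat, path)
  back <- read_spectra_csv(path, kind = "raman")
  expect_equal(back$axis, mat$axis, tolerance = 1e-12)
  expect_equal(back$X, mat$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$meta$sample_id, meta$sample_id)
  expect_identical(back$meta$pH, meta$pH)
  expect_identical(back$meta$iron_treated, meta$iron_treated)
  expect_identical(back$meta$replicate_id, meta$replicate_id)
})

test_that("CSV reader validates content and shape", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("axis,s1|3|0|1,s2|3|1|1", "400,0.1,0.2", "405,oops,0.3",
               "410,0.2,0.4"), path)
  expect_error(read_spectra_csv(path), "row 2.*s1\\|3\\|0\\|1.*oops")
  writeLines(c("axis,s1|3|0|1", "500,1", "400,2", "450,3"), path)
  expect_error(read_spectra_csv(path), "not strictly increasing")
  writeLines(c("axis,s1|3|0|1,s2|6|1|2", "400,0.1,0.2", "410,0.2,0.4"),
             path)
  mat <- read_spectra_csv(path)
  expect_equal(nrow(mat$X), 2L)
  expect_equal(mat$meta$pH, c(3, 6))
  writeLines(c("axis,badheader", "400,1", "410,2"), path)
  expect_error(read_spectra_csv(path), "malformed")
})

test_that("crop uses closed-interval semantics and nests idempotently", {
  s <- spectrum(1:5, c(5, 1, 4, 2, 3), "raman")
  expect_equal(crop(s, 2, 4)$axis, c(2, 3, 4))
  expect_equal(crop(s, 1, 5)$intensity, s$intensity)
  expect_error(crop(s, 10, 20), "empty")
  expect_error(crop(s, 4, 2), "lo < hi")
  # nesting: crop then wider crop == first crop
  set.seed(1)
  for (rep in 1:5) {
    grid <- sort(runif(40, 0, 100))
    m <- spectral_matrix(grid, matrix(rnorm(3 * 40), 3), kind = "raman")
    a <- crop(m, 20, 60)
    b <- crop(crop(m, 20, 60), 10, 90)
    expect_equal(a$axis, b$axis)
    expect_equal(a$X, b$X)
  }
})

test_that("linear resampling is exact for linear traces and round-trips", {
  grid <- seq(0, 10, 0.5)
  s <- spectrum(grid, 3 * grid - 2, "raman")
  same <- resample_linear(s, grid)
  expect_equal(same$intensity, s$intensity)
  new_axis <- seq(0.25, 9.75, 0.25)
  r <- resample_linear(s, new_axis)
  expect_equal(r$intensity, 3 * new_axis - 2)
  expect_error(resample_linear(s, seq(-1, 5, 1)), "extrapolate")
  # random spectrum: densify then read back the original knots
  set.seed(7)
  s2 <- spectrum(grid, rnorm(length(grid)), "raman")
  dense <- resample_linear(s2, seq(0, 10, 0.25))
  back <- resample_linear(dense, grid)
  expect_equal(back$intensity, s2$intensity, tolerance = 1e-9)
})

test_that("lambda_max reports the on-grid argmax with low-axis tie-break", {
  s <- gauss_spectrum(center = 520)
  lm1 <- lambda_max(s)
  expect_equal(lm1$position, 520)
  expect_equal(lm1$height, max(s$intensity))
  # two equal maxima: lowest axis value wins
  y <- rep(0, 10); y[c(3, 8)] <- 1
  tie <- spectrum(seq(500, 545, 5), y, "uvvis")
  expect_equal(lambda_max(tie)$position, 510)
  # off-grid band center against a brute-force argmax oracle
  s2 <- gauss_spectrum(center = 522.5)
  oracle_idx <- which.max(s2$intensity)
  expect_equal(lambda_max(s2)$position, s2$axis[oracle_idx])
  expect_true(lambda_max(s2)$position %in% c(520, 525))
  expect_error(lambda_max(s, 520, 521), "at least 3")
  expect_warning(out <- lambda_max(spectrum(1:5, rep(2, 5), "uvvis")),
                 "degenerate")
  expect_true(out$degenerate)
  expect_equal(out$position, 1)
})

test_that("lambda_max is invariant to positive affine intensity scaling", {
  set.seed(11)
  for (rep in 1:10) {
    s <- gauss_spectrum(center = runif(1, 420, 650), sigma = runif(1, 15, 60))
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    s2 <- spectrum(s$axis, a * s$intensity + b, s$kind)
    expect_equal(lambda_max(s2)$position, lambda_max(s)$position)
  }
})

test_that("sub-grid refinement recovers an off-grid band center", {
  s <- gauss_spectrum(center = 522.5, sigma = 30)
  expect_equal(lambda_max(s, refine = TRUE)$position, 522.5,
               tolerance = 0.05)
})

test_that("pick_peaks matches an exhaustive prominence definition", {
  grid <- seq(300, 2000, 1)
  s <- spectrum(grid, lorentz_trace(grid, 1330, 1, 10), "raman")
  pk <- pick_peaks(s, 0.5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$position, 1330)

  two <- spectrum(grid, lorentz_trace(grid, c(1330, 1600), c(1, 1),
                                      c(10, 10)), "raman")
  pk2 <- pick_peaks(two, 0.5)
  expect_equal(pk2$position, c(1330, 1600))
  # independent prominence oracle: walk out from each peak to the next
  # higher point, base = higher of the two interval minima
  oracle_prom <- function(y, p) {
    n <- length(y)
    left <- if (any(y[1:(p - 1)] > y[p])) {
      j <- max(which(y[1:(p - 1)] > y[p])); min(y[j:(p - 1)])
    } else min(y[1:p])
    right <- if (any(y[(p + 1):n] > y[p])) {
      j <- p + min(which(y[(p + 1):n] > y[p])); min(y[(p + 1):j])
    } else min(y[p:n])
    y[p] - max(left, right)
  }
  for (k in seq_len(nrow(pk2))) {
    p_idx <- which(two$axis == pk2$position[k])
    expect_equal(pk2$prominence[k], oracle_prom(two$intensity, p_idx),
                 tolerance = 1e-12)
  }
  # at full prominence only the global maximum can qualify
  set.seed(5)
  noise <- spectrum(1:200, runif(200), "raman")
  expect_lte(nrow(pick_peaks(noise, 1.0)), 1L)
  expect_error(pick_peaks(s, 0), "min_prominence")
})
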