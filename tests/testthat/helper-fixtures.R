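# Shared fixtures: all synthetic, built in code at test time.

# study conditions with every stochastic term switched off
noiseless_config <- function(...) {
  sim_config(noise_sd = 0, uvvis_noise_sd = 0, scatter_sd = 0,
             baseline_amplitude = 0, ...)
}

gauss_spectrum <- function(center = 520, height = 1, sigma = 30,
                           grid = seq(380, 700, 5), kind = "uvvis",
                           meta = list()) {
  spectrum(grid, height * exp(-(grid - center)^2 / (2 * sigma^2)),
           kind = kind, meta = meta)
}

lorentz_trace <- function(grid, centers, amps, widths) {
  y <- rep(0, length(grid))
  for (i in seq_along(centers))
    y <- y + amps[i] * widths[i]^2 / ((grid - centers[i])^2 + widths[i]^2)
  y
}

# exact rank-2 regression problem: X = T P', y = T q
rank2_problem <- function(seed, n = 24, p = 40) {
  set.seed(seed)
  Tm <- matrix(rnorm(n * 2), n)
  P <- matrix(rnorm(2 * p), 2)
  list(X = Tm %*% P, y = drop(Tm %*% c(2, -1)))
}

# reduced-size study for properties that loop over many seeds
small_study <- function(seed, ...) {
  simulate_study(sim_config(n_samples = 6, replicates_per_sample = 5,
                            seed = seed, ...))
}

cv_r2_bathochromic <- function(study, max_factors = 5) {
  pp <- preprocess_chain(study$sers)
  y <- study$truth$s1[match(pp$labels, study$truth$sample_id)]
  loocv(pp$X, y, max_factors = max_factors)$r2_cv
}
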