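#' Configuration of the synthetic co-pigmentation study
#'
#' Defaults mirror the study design the package targets: 9 anthocyanin
#' extracts, 20 SERS replicates per extract (180 spectra), duplicate UV-vis
#' measurements, a 380-700 nm absorbance grid at 5 nm steps, and a
#' 300-2000 cm^-1 Raman grid at 1 cm^-1 steps.
#'
#' @param n_samples number of extracts (classes).
#' @param replicates_per_sample SERS replicates per extract (>= 2).
#' @param uvvis_replicates UV-vis replicates per extract (duplicates).
#' @param uvvis_grid wavelength grid, nm.
#' @param raman_grid Raman shift grid, cm^-1.
#' @param noise_sd additive Raman noise SD, in units of the strongest band
#'   (height 1).
#' @param uvvis_noise_sd additive absorbance noise SD, AU.
#' @param baseline_order polynomial order of the fluorescence baseline.
#' @param baseline_amplitude baseline scale relative to the strongest band.
#' @param scatter_sd SD of the log-normal multiplicative scatter factor.
#' @param batho_range range (nm) the latent bathochromic shifts are drawn
#'   from.
#' @param hyper3_range,hyper6_range ranges (AU) for the latent hyperchromic
#'   shifts at pH 3 and pH 6.
#' @param shift_coupling cm^-1 of inter-ring band shift per nm of
#'   bathochromic shift (band center = 1340 - shift_coupling * s1).
#' @param acyl_decay nm scale of the exponential decay of the ~1300 cm^-1
#'   acyl-marker band amplitude with s1.
#' @param seed integer RNG seed for the whole study.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 9,
                       replicates_per_sample = 20,
                       uvvis_replicates = 2,
                       uvvis_grid = seq(380, 700, by = 5),
                       raman_grid = seq(300, 2000, by = 1),
                       noise_sd = 0.01,
                       uvvis_noise_sd = 0.002,
                       baseline_order = 3,
                       baseline_amplitude = 0.3,
                       scatter_sd = 0.15,
                       batho_range = c(-5, 55),
                       hyper3_range = c(-0.25, 0.10),
                       hyper6_range = c(0.10, 0.56),
                       shift_coupling = 0.25,
                       acyl_decay = 10,
                       seed = 1L) {
  stopifnot(n_samples >= 1, replicates_per_sample >= 2,
            uvvis_replicates >= 1,
            length(uvvis_grid) >= 3, all(diff(uvvis_grid) > 0),
            length(raman_grid) >= 3, all(diff(raman_grid) > 0),
            noise_sd >= 0, uvvis_noise_sd >= 0, scatter_sd >= 0,
            baseline_order >= 0, batho_range[1] < batho_range[2])
  structure(as.list(environment()), class = "sim_config")
}

#' Latent truth for one synthetic extract
#'
#' Holds the true stability values the spectra encode: `s1`/`s2` are the
#' bathochromic shifts (nm) at pH 3/6, `s3`/`s4` the hyperchromic shifts
#' (AU), and `band_table` the Lorentzian band parameters of the extract's
#' SERS signature. Kept alongside generated spectra so downstream recovery
#' can be tested against ground truth.
#'
#' @param sample_id label.
#' @param s1,s2 true bathochromic shifts (nm) at pH 3 and pH 6.
#' @param s3,s4 true hyperchromic shifts (AU) at pH 3 and pH 6.
#' @param config a [sim_config()] (supplies the stability-to-band coupling).
#' @param band_table optional data.frame (`center`, `amplitude`, `width`)
#'   overriding the default anthocyanin band signature.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(sample_id, s1, s2, s3, s4,
                            config = sim_config(), band_table = NULL) {
  if (is.null(band_table))
    band_table <- default_sers_bands(s1, config)
  stopifnot(all(band_table$width > 0), all(band_table$amplitude >= 0))
  structure(list(sample_id = sample_id, s1 = s1, s2 = s2, s3 = s3, s4 = s4,
                 band_table = band_table),
            class = "synthetic_truth")
}

#' Default SERS band signature as a function of stability
#'
#' Lorentzian band set modelled on the anthocyanin SERS fingerprint:
#' skeleton bending bands near 548/637/715/730 cm^-1, C-O and O-H bands
#' near 1080/1190/1240 cm^-1, and ring-stretching bands at 1330-1630 cm^-1.
#' Two bands carry the stability information as recoverable ground truth:
#' the inter-ring stretching band sits at `1340 - shift_coupling * s1`
#' (stable extracts at higher wavenumber) and the ~1300 cm^-1
#' glycosyl/acyl marker has amplitude `0.5 * exp(-s1 / acyl_decay)`
#' (prominent only in stable, acylated extracts). A weak linear amplitude
#' trend on the 1605 cm^-1 flavylium band keeps part of the encoding linear.
#'
#' @param s1 true bathochromic shift at pH 3, nm.
#' @param config a [sim_config()].
#' @return data.frame with columns `center` (cm^-1), `amplitude`
#'   (relative), `width` (Lorentzian HWHM, cm^-1).
#' @export
default_sers_bands <- function(s1, config = sim_config()) {
  data.frame(
    center = c(548, 637, 715, 730, 1080, 1190, 1240,
               1300, 1340 - config$shift_coupling * s1,
               1370, 1460, 1520, 1570, 1605, 1630),
    amplitude = c(0.35, 0.40, 0.30, 0.32, 0.25, 0.20, 0.45,
                  0.50 * exp(-s1 / config$acyl_decay), 1.00,
                  0.35, 0.55, 0.40, 0.35,
                  0.85 + 0.004 * s1, 0.30),
    width = c(8, 8, 7, 7, 8, 8, 9, 9, 10, 9, 10, 10, 10, 10, 9)
  )
}

# Lorentzian with peak height `a` and half-width-at-half-maximum `g`
.lorentz <- function(x, c0, a, g) a * g^2 / ((x - c0)^2 + g^2)

.uvvis_band <- function(pH) {
  # flavylium band: strong ~520 nm at pH 3; weaker, red-shifted quinoidal
  # envelope at pH 6
  if (pH == 3) list(center = 520, height = 0.90, sigma = 35)
  else list(center = 545, height = 0.55, sigma = 38)
}

#' Simulate a control / iron-treated UV-vis pair
#'
#' The control arm is a Gaussian absorption band (center and height set by
#' the pH arm) over a mild linear baseline; the treated arm shifts the band
#' center by the latent bathochromic shift and its height by the latent
#' hyperchromic shift. Both arms share the noise model (additive Gaussian,
#' `uvvis_noise_sd`). Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param truth a [synthetic_truth()].
#' @param pH 3 or 6.
#' @param config a [sim_config()].
#' @return list with `control` and `treated` [spectrum()] objects.
#' @export
simulate_uvvis_pair <- function(truth, pH, config = sim_config()) {
  stopifnot(pH %in% c(3, 6))
  band <- .uvvis_band(pH)
  s_batho <- if (pH == 3) truth$s1 else truth$s2
  s_hyper <- if (pH == 3) truth$s3 else truth$s4
  grid <- config$uvvis_grid
  center_t <- band$center + s_batho
  if (center_t < min(grid) || center_t > max(grid))
    stop(sprintf("treated band center %g nm falls outside the %g-%g nm grid",
                 center_t, min(grid), max(grid)))
  baseline <- 0.01 + 1e-5 * (grid - min(grid))
  shape <- function(center, height)
    height * exp(-(grid - center)^2 / (2 * band$sigma^2)) + baseline
  mk <- function(center, height, iron) {
    y <- shape(center, height) +
      stats::rnorm(length(grid), 0, config$uvvis_noise_sd)
    spectrum(grid, y, kind = "uvvis",
             meta = list(sample_id = truth$sample_id, pH = pH,
                         iron_treated = iron))
  }
  list(control = mk(band$center, band$height, FALSE),
       treated = mk(center_t, band$height + s_hyper, TRUE))
}

#' Simulate replicate SERS spectra for one extract
#'
#' Each replicate is the sum of the extract's Lorentzian bands plus a
#' random polynomial fluorescence baseline, the whole trace multiplied by a
#' log-normal scatter factor `exp(N(0, scatter_sd))`, plus additive
#' Gaussian noise. The log-normal scatter makes per-spectrum normalization
#' (SNV) the correct correction by construction. Uses the current RNG
#' state.
#'
#' @param truth a [synthetic_truth()].
#' @param config a [sim_config()].
#' @param n_replicates number of spectra (default
#'   `config$replicates_per_sample`).
#' @return a [spectral_matrix()] of Raman kind, labelled by sample id.
#' @export
simulate_sers <- function(truth, config = sim_config(),
                          n_replicates = config$replicates_per_sample) {
  grid <- config$raman_grid
  bands <- truth$band_table
  if (!nrow(bands)) stop("band table is empty")
  signal <- rep(0, length(grid))
  for (b in seq_len(nrow(bands)))
    signal <- signal + .lorentz(grid, bands$center[b], bands$amplitude[b],
                                bands$width[b])
  u <- (grid - min(grid)) / diff(range(grid))
  X <- matrix(0, n_replicates, length(grid))
  for (r in seq_len(n_replicates)) {
    coefs <- stats::runif(config$baseline_order + 1, 0, 1)
    baseline <- config$baseline_amplitude *
      drop(outer(u, 0:config$baseline_order, "^") %*% coefs)
    scatter <- exp(stats::rnorm(1, 0, config$scatter_sd))
    X[r, ] <- scatter * (signal + baseline) +
      stats::rnorm(length(grid), 0, config$noise_sd)
  }
  meta <- data.frame(sample_id = truth$sample_id, pH = NA_real_,
                     iron_treated = FALSE,
                     replicate_id = as.character(seq_len(n_replicates)),
                     stringsAsFactors = FALSE)
  spectral_matrix(grid, X, labels = rep(truth$sample_id, n_replicates),
                  kind = "raman", meta = meta)
}

#' Simulate a full co-pigmentation study
#'
#' Draws latent stability values for `n_samples` extracts (bathochromic
#' shifts uniform in `batho_range` with the pH 6 shift biased above the
#' pH 3 one, hyperchromic shifts uniform in their ranges), then generates
#' the paired UV-vis quadruples (pH 3/6 x control/iron, replicated) and the
#' replicate SERS matrix for every extract. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{sers}{[spectral_matrix()] of all SERS replicates, labelled by
#'       sample.}
#'     \item{uvvis}{per-sample list of replicate quadruples
#'       (`ph3_control`, `ph3_iron`, `ph6_control`, `ph6_iron`), the format
#'       [compute_indexes()] consumes.}
#'     \item{truth}{data.frame of the latent `s1..s4` per sample plus the
#'       seed.}
#'     \item{truth_objects}{the `synthetic_truth` objects (band tables).}
#'   }
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  ids <- sprintf("sample%02d", seq_len(config$n_samples))
  truths <- lapply(ids, function(id) {
    s1 <- stats::runif(1, config$batho_range[1], config$batho_range[2])
    s2 <- min(config$batho_range[2],
              max(config$batho_range[1], s1 + stats::runif(1, 2, 25)))
    s3 <- stats::runif(1, config$hyper3_range[1], config$hyper3_range[2])
    s4 <- stats::runif(1, config$hyper6_range[1], config$hyper6_range[2])
    synthetic_truth(id, s1, s2, s3, s4, config)
  })
  uvvis <- lapply(truths, function(tr) {
    lapply(seq_len(config$uvvis_replicates), function(r) {
      p3 <- simulate_uvvis_pair(tr, 3, config)
      p6 <- simulate_uvvis_pair(tr, 6, config)
      list(ph3_control = p3$control, ph3_iron = p3$treated,
           ph6_control = p6$control, ph6_iron = p6$treated)
    })
  })
  names(uvvis) <- ids
  sers_parts <- lapply(truths, simulate_sers, config = config)
  X <- do.call(rbind, lapply(sers_parts, function(m) m$X))
  labels <- unlist(lapply(sers_parts, function(m) m$labels))
  meta <- do.call(rbind, lapply(sers_parts, function(m) m$meta))
  sers <- spectral_matrix(config$raman_grid, X, labels = labels,
                          kind = "raman", meta = meta)
  truth <- data.frame(sample_id = ids,
                      s1 = vapply(truths, `[[`, numeric(1), "s1"),
                      s2 = vapply(truths, `[[`, numeric(1), "s2"),
                      s3 = vapply(truths, `[[`, numeric(1), "s3"),
                      s4 = vapply(truths, `[[`, numeric(1), "s4"),
                      seed = config$seed,
                      stringsAsFactors = FALSE)
  list(sers = sers, uvvis = uvvis, truth = truth, truth_objects = truths)
}
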