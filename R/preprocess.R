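#' Preprocessing configuration for SERS matrices
#'
#' The pretreatment chain applied before PCA/PLS: Savitzky-Golay second
#' derivative, then standard normal variate (SNV) scaling with statistics
#' taken over `snv_range`, then concatenation of the informative spectral
#' regions. The derivative separates overlapping bands and removes slowly
#' varying fluorescence baselines; SNV removes the multiplicative scatter
#' between replicates; the two default regions carry the anthocyanin
#' fingerprint bands.
#'
#' @param sg_window odd Savitzky-Golay window length in points (> polyorder).
#' @param sg_polyorder polynomial order of the local fit (>= 2).
#' @param derivative_order derivative order (0 disables the step; default 2).
#' @param snv_enabled apply SNV (default TRUE).
#' @param snv_range closed interval (cm^-1) over which the SNV mean/SD are
#'   computed (default 400-1800); the correction is applied to the whole
#'   row.
#' @param regions list of closed intervals (cm^-1) kept for modelling,
#'   increasing and non-overlapping; `NULL` disables region selection.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 9, sg_polyorder = 3,
                              derivative_order = 2,
                              snv_enabled = TRUE,
                              snv_range = c(400, 1800),
                              regions = list(c(370, 918), c(1099, 1692))) {
  stopifnot(sg_window %% 2 == 1, sg_window > sg_polyorder,
            sg_polyorder >= 2, derivative_order >= 0)
  if (!is.null(regions)) {
    m <- do.call(rbind, regions)
    if (any(m[, 1] >= m[, 2])) stop("each region needs lo < hi")
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("regions must be increasing and non-overlapping")
  }
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 derivative_order = as.integer(derivative_order),
                 snv_enabled = snv_enabled,
                 snv_range = snv_range,
                 regions = regions),
            class = "preprocess_config")
}

.grid_step <- function(axis) {
  d <- diff(axis)
  if (diff(range(d)) > 1e-8 * mean(d))
    stop("axis is not uniformly spaced; resample before derivative filtering")
  mean(d)
}

#' Savitzky-Golay smoothing derivative of each spectrum
#'
#' Least-squares local polynomial derivative filter applied row-wise; the
#' axis is unchanged. Edge points come from the one-sided polynomial fits
#' on the first/last window (no reflection padding), so results are exactly
#' reproducible and the filter is exact for polynomials up to
#' `sg_polyorder` at every point including the edges. Derivative units are
#' intensity per (axis unit)^order.
#'
#' @param mat a `spectral_matrix` on a uniform axis.
#' @param config a [preprocess_config()].
#' @return a `spectral_matrix` of derivatives.
#' @export
second_derivative <- function(mat, config = preprocess_config()) {
  stopifnot(inherits(mat, "spectral_matrix"))
  if (config$sg_window > ncol(mat$X))
    stop(sprintf("SG window (%d) exceeds the number of points (%d)",
                 config$sg_window, ncol(mat$X)))
  if (config$derivative_order == 0) return(mat)
  ts <- .grid_step(mat$axis)
  D <- t(apply(mat$X, 1, signal::sgolayfilt,
               p = config$sg_polyorder, n = config$sg_window,
               m = config$derivative_order, ts = ts))
  spectral_matrix(mat$axis, D, labels = mat$labels, y = mat$y,
                  kind = mat$kind, meta = mat$meta)
}

#' Standard normal variate scaling
#'
#' Per spectrum: subtract the mean and divide by the sample standard
#' deviation. When `range` is given, the statistics are computed from the
#' points inside that closed axis interval but the correction is applied to
#' the whole row (path-length correction over a reference range). With
#' `range = NULL` every output row has mean 0 and SD 1 exactly.
#'
#' @param mat a `spectral_matrix`.
#' @param range optional closed axis interval for the statistics.
#' @return a `spectral_matrix` of scaled rows.
#' @export
snv <- function(mat, range = NULL) {
  stopifnot(inherits(mat, "spectral_matrix"))
  idx <- if (is.null(range)) seq_along(mat$axis) else
    .crop_idx(mat$axis, range[1], range[2])
  if (length(idx) < 2L) stop("SNV needs >= 2 points in the statistics range")
  mu <- rowMeans(mat$X[, idx, drop = FALSE])
  sdv <- apply(mat$X[, idx, drop = FALSE], 1, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero))
    stop("zero-variance row(s) cannot be SNV-scaled: row ",
         paste(zero, collapse = ", "))
  Xs <- (mat$X - mu) / sdv
  spectral_matrix(mat$axis, Xs, labels = mat$labels, y = mat$y,
                  kind = mat$kind, meta = mat$meta)
}

#' Concatenate selected spectral regions
#'
#' Keeps the points falling in any of the given closed intervals, in axis
#' order; the feature count is the sum of points per region. The default
#' regions (370-918 and 1099-1692 cm^-1) cover the anthocyanin skeleton
#' bending and ring-stretching fingerprints.
#'
#' @param mat a `spectral_matrix`.
#' @param regions list of closed intervals within the axis span.
#' @return a `spectral_matrix` restricted to the selected features.
#' @export
select_regions <- function(mat,
                           regions = list(c(370, 918), c(1099, 1692))) {
  stopifnot(inherits(mat, "spectral_matrix"))
  keep <- integer(0)
  for (rg in regions) {
    idx <- which(mat$axis >= rg[1] & mat$axis <= rg[2])
    if (!length(idx))
      stop(sprintf("region [%g, %g] selects no points; axis spans [%g, %g]",
                   rg[1], rg[2], min(mat$axis), max(mat$axis)))
    keep <- c(keep, idx)
  }
  keep <- sort(unique(keep))
  spectral_matrix(mat$axis[keep], mat$X[, keep, drop = FALSE],
                  labels = mat$labels, y = mat$y, kind = mat$kind,
                  meta = mat$meta)
}

#' Hash a preprocessing (or any) configuration for provenance
#' @param config any serializable R object.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Full pretreatment chain: derivative, SNV, region selection
#'
#' Applies the steps in that fixed order. The SNV statistics are taken over
#' `snv_range` before any features are dropped, so row means over the
#' finally selected features are generally nonzero — the scaling reference
#' is the wide range, not the model regions. A provenance record (config
#' plus its hash) is attached to the result as attributes
#' `preprocess_config` and `provenance_hash`, and downstream models carry
#' the hash so predictions on differently preprocessed spectra can be
#' flagged.
#'
#' @param mat a `spectral_matrix`.
#' @param config a [preprocess_config()].
#' @return the preprocessed `spectral_matrix`.
#' @export
preprocess_chain <- function(mat, config = preprocess_config()) {
  out <- mat
  if (config$derivative_order > 0)
    out <- second_derivative(out, config)
  if (isTRUE(config$snv_enabled))
    out <- snv(out, range = config$snv_range)
  if (!is.null(config$regions))
    out <- select_regions(out, config$regions)
  attr(out, "preprocess_config") <- config
  attr(out, "provenance_hash") <- config_hash(unclass(config))
  out
}
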