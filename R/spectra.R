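#' Single spectrum container
#'
#' A `spectrum` holds one intensity trace on a strictly increasing axis:
#' wavelength in nm for UV-vis absorbance, Raman shift in cm^-1 for SERS.
#' Sample metadata (sample id, pH arm, iron treatment, replicate) travels
#' with the object so downstream stages can pair control/treated arms.
#'
#' @param axis numeric vector, strictly increasing (nm or cm^-1).
#' @param intensity numeric vector, same length as `axis` (AU or counts).
#' @param kind `"uvvis"` or `"raman"`.
#' @param meta named list of metadata; recognised fields are `sample_id`,
#'   `plant_source`, `supplier`, `pH` (3, 6 or `NA`), `iron_treated`
#'   (logical) and `replicate_id`.
#' @return An object of class `spectrum`.
#' @export
#' @examples
#' s <- spectrum(seq(380, 700, 5), dnorm(seq(380, 700, 5), 520, 30), "uvvis")
#' lambda_max(s)
spectrum <- function(axis, intensity, kind = c("uvvis", "raman"),
                     meta = list()) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("axis and intensity lengths differ (", length(axis), " vs ",
         length(intensity), ")")
  if (length(axis) < 2L)
    stop("a spectrum needs at least 2 points")
  if (anyNA(axis) || any(!is.finite(axis)))
    stop("axis contains non-finite values")
  if (any(diff(axis) <= 0))
    stop("axis must be strictly increasing")
  structure(list(axis = axis, intensity = intensity, kind = kind,
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$kind == "uvvis") "nm" else "cm^-1"
  cat(sprintf("<spectrum: %s, %d points, %g-%g %s>\n",
              x$kind, length(x$axis), min(x$axis), max(x$axis), unit))
  if (!is.null(x$meta$sample_id))
    cat("  sample:", x$meta$sample_id,
        if (isTRUE(x$meta$iron_treated)) "(iron-treated)" else "(control)",
        if (!is.null(x$meta$pH)) paste0("pH ", x$meta$pH) else "", "\n")
  invisible(x)
}

#' Aligned set of spectra sharing one axis
#'
#' Row-wise spectral matrix: `X[i, ]` is spectrum `i` on the shared `axis`.
#' `labels` carry the sample class of each row; `y` optionally holds a
#' per-row numeric target (a stability index) for regression.
#'
#' @param axis shared strictly increasing axis.
#' @param X numeric matrix, one spectrum per row, `ncol(X) == length(axis)`.
#' @param labels character/factor vector, one class label per row.
#' @param y optional numeric target per row.
#' @param kind `"uvvis"` or `"raman"`.
#' @param meta optional data.frame of per-row metadata (sample_id, pH,
#'   iron_treated, replicate_id).
#' @return An object of class `spectral_matrix`.
#' @export
spectral_matrix <- function(axis, X, labels = NULL, y = NULL,
                            kind = c("uvvis", "raman"), meta = NULL) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(axis))
    stop("ncol(X) (", ncol(X), ") != length(axis) (", length(axis), ")")
  if (any(diff(axis) <= 0))
    stop("axis must be strictly increasing")
  if (is.null(labels)) labels <- rep(NA_character_, nrow(X))
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("length(labels) != nrow(X)")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  }
  if (!is.null(meta) && nrow(meta) != nrow(X))
    stop("nrow(meta) != nrow(X)")
  structure(list(axis = axis, X = X, labels = labels, y = y,
                 kind = kind, meta = meta),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  unit <- if (x$kind == "uvvis") "nm" else "cm^-1"
  cat(sprintf("<spectral_matrix: %s, %d spectra x %d points, %g-%g %s>\n",
              x$kind, nrow(x$X), ncol(x$X), min(x$axis), max(x$axis), unit))
  tab <- table(x$labels, useNA = "no")
  if (length(tab) && length(tab) <= 12L)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  if (!is.null(x$y)) cat("  targets: numeric y attached\n")
  invisible(x)
}

#' Extract one row of a spectral matrix as a `spectrum`
#' @param mat a `spectral_matrix`.
#' @param i row index.
#' @return a `spectrum`.
#' @export
get_spectrum <- function(mat, i) {
  stopifnot(inherits(mat, "spectral_matrix"), i >= 1, i <= nrow(mat$X))
  meta <- if (!is.null(mat$meta)) as.list(mat$meta[i, , drop = FALSE]) else
    list(sample_id = mat$labels[i])
  spectrum(mat$axis, mat$X[i, ], kind = mat$kind, meta = meta)
}

# header encoding "sample_id|pH|iron|replicate"; pH "none" and iron 0/1
.encode_colname <- function(sample_id, pH, iron, replicate) {
  paste(sample_id,
        ifelse(is.na(pH), "none", pH),
        as.integer(iron),
        replicate, sep = "|")
}

.decode_colnames <- function(nms) {
  parts <- strsplit(nms, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed spectrum header(s): ",
         paste(nms[bad], collapse = ", "),
         " (expected 'sample_id|pH|iron|replicate')")
  m <- do.call(rbind, parts)
  data.frame(sample_id = m[, 1],
             pH = suppressWarnings(as.numeric(ifelse(m[, 2] == "none",
                                                     NA, m[, 2]))),
             iron_treated = m[, 3] == "1",
             replicate_id = m[, 4],
             stringsAsFactors = FALSE)
}

#' Read a wide spectra CSV
#'
#' Expected layout: first column the axis (nm or cm^-1), each remaining
#' column one spectrum, its header encoding the metadata as
#' `"sample_id|pH|iron|replicate"` (pH `3`, `6` or `none`; iron `0`/`1`).
#'
#' @param path CSV file path (UTF-8, "." decimal separator).
#' @param kind `"uvvis"` or `"raman"`.
#' @return A [spectral_matrix()] whose `labels` are the sample ids.
#' @export
read_spectra_csv <- function(path, kind = c("uvvis", "raman")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("spectra file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("spectra CSV needs an axis column plus >= 1 spectrum")
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {
        i <- which(is.na(num))[1]
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     i, names(df)[j], v[i]))
      }
      df[[j]] <- num
    }
  }
  axis <- df[[1]]
  if (any(diff(axis) <= 0))
    stop("axis column is not strictly increasing")
  meta <- .decode_colnames(names(df)[-1])
  X <- t(as.matrix(df[, -1, drop = FALSE]))
  rownames(X) <- NULL
  spectral_matrix(axis, X, labels = meta$sample_id, kind = kind, meta = meta)
}

#' Write a spectral matrix to the wide CSV layout
#'
#' Inverse of [read_spectra_csv()]; numeric values are written with 17
#' significant digits so a read/write round trip is lossless to well below
#' 1e-12.
#'
#' @param mat a `spectral_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(mat, path) {
  stopifnot(inherits(mat, "spectral_matrix"))
  meta <- mat$meta
  if (is.null(meta))
    meta <- data.frame(sample_id = mat$labels,
                       pH = NA_real_,
                       iron_treated = FALSE,
                       replicate_id = as.character(seq_len(nrow(mat$X))))
  nms <- .encode_colname(meta$sample_id, meta$pH, meta$iron_treated,
                         meta$replicate_id)
  out <- cbind(axis = mat$axis, t(mat$X))
  colnames(out) <- c("axis", nms)
  fmt <- apply(out, 2, function(col) formatC(col, digits = 17, format = "g"))
  utils::write.table(fmt, path, sep = ",", quote = TRUE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Crop to an axis window
#'
#' Retains the points with `lo <= axis <= hi` (closed interval), preserving
#' row order. Used both for UV-vis analysis windows and for picking the
#' informative Raman regions.
#'
#' @param x a `spectrum` or `spectral_matrix`.
#' @param lo,hi window bounds in axis units, `lo < hi`.
#' @return Object of the same class restricted to the window.
#' @export
crop <- function(x, lo, hi) UseMethod("crop")

.crop_idx <- function(axis, lo, hi) {
  if (!(lo < hi)) stop("crop window needs lo < hi")
  keep <- which(axis >= lo & axis <= hi)
  if (!length(keep))
    stop(sprintf("crop window [%g, %g] is empty; axis spans [%g, %g]",
                 lo, hi, min(axis), max(axis)))
  keep
}

#' @export
crop.spectrum <- function(x, lo, hi) {
  keep <- .crop_idx(x$axis, lo, hi)
  spectrum(x$axis[keep], x$intensity[keep], kind = x$kind, meta = x$meta)
}

#' @export
crop.spectral_matrix <- function(x, lo, hi) {
  keep <- .crop_idx(x$axis, lo, hi)
  spectral_matrix(x$axis[keep], x$X[, keep, drop = FALSE],
                  labels = x$labels, y = x$y, kind = x$kind, meta = x$meta)
}

#' Resample a spectrum onto a new axis by linear interpolation
#'
#' Piecewise-linear interpolation; no extrapolation policy is offered, a
#' `new_axis` outside the spectrum's span is an error.
#'
#' @param spec a `spectrum`.
#' @param new_axis strictly increasing numeric vector within
#'   `[min(axis), max(axis)]`.
#' @return A `spectrum` on `new_axis`.
#' @export
resample_linear <- function(spec, new_axis) {
  stopifnot(inherits(spec, "spectrum"))
  new_axis <- as.numeric(new_axis)
  if (min(new_axis) < min(spec$axis) || max(new_axis) > max(spec$axis))
    stop(sprintf(
      "resampling would extrapolate: requested [%g, %g], available [%g, %g]",
      min(new_axis), max(new_axis), min(spec$axis), max(spec$axis)))
  out <- stats::approx(spec$axis, spec$intensity, xout = new_axis,
                       method = "linear", ties = "ordered")
  spectrum(out$x, out$y, kind = spec$kind, meta = spec$meta)
}

#' Locate the absorption maximum in a window
#'
#' Returns the on-grid argmax of intensity within `[lo, hi]`; ties are broken
#' toward the smallest axis value. The position is reported on the sampled
#' grid by default, matching an acquisition step of 5 nm; `refine = TRUE`
#' adds a three-point parabolic sub-grid refinement for interior maxima.
#'
#' @param spec a `spectrum`.
#' @param lo,hi window bounds (defaults: whole axis). The window must contain
#'   at least 3 grid points.
#' @param refine logical; parabolic sub-grid refinement (off by default).
#' @return List with `position` (axis units), `height` (intensity), and
#'   `degenerate` (TRUE when all intensities in the window are equal, in
#'   which case `position == lo`-side edge and a warning is raised).
#' @export
lambda_max <- function(spec, lo = min(spec$axis), hi = max(spec$axis),
                       refine = FALSE) {
  stopifnot(inherits(spec, "spectrum"))
  keep <- .crop_idx(spec$axis, lo, hi)
  if (length(keep) < 3L)
    stop("lambda_max window must contain at least 3 grid points")
  ax <- spec$axis[keep]
  iy <- spec$intensity[keep]
  if (all(iy == iy[1])) {
    warning("degenerate spectrum: all intensities equal in window")
    return(list(position = ax[1], height = iy[1], degenerate = TRUE))
  }
  i <- which.max(iy)  # which.max takes the first maximum: lowest axis value
  pos <- ax[i]
  ht <- iy[i]
  if (refine && i > 1L && i < length(ax)) {
    # parabola through the three points around the grid maximum
    d1 <- (iy[i + 1] - iy[i - 1]) / 2
    d2 <- iy[i + 1] - 2 * iy[i] + iy[i - 1]
    if (d2 < 0) {
      step <- (ax[i + 1] - ax[i - 1]) / 2
      pos <- ax[i] - d1 / d2 * step
      ht <- iy[i] - d1^2 / (4 * d2)
    }
  }
  list(position = pos, height = ht, degenerate = FALSE)
}

#' Peak picking by topographic prominence
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence * max(intensity)`. The prominence of a peak is its height
#' minus the higher of the two saddle minima separating it from higher
#' terrain (or from the trace edge when no higher peak exists on that side).
#'
#' @param spec a `spectrum`.
#' @param min_prominence fraction of the global intensity maximum in (0, 1].
#' @return data.frame with columns `position`, `height`, `prominence`,
#'   sorted by position; zero rows when nothing qualifies.
#' @export
pick_peaks <- function(spec, min_prominence = 0.05) {
  stopifnot(inherits(spec, "spectrum"))
  if (!(min_prominence > 0 && min_prominence <= 1))
    stop("min_prominence must be in (0, 1]")
  y <- spec$intensity
  n <- length(y)
  # strict local maxima (plateau peaks take their first point)
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1]) {
      j <- i
      while (j < n && y[j + 1] == y[j]) j <- j + 1L
      if (j < n && y[j + 1] < y[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand))
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(cand, function(p) {
    h <- y[p]
    left_min <- right_min <- NA_real_
    # walk left until higher terrain (or edge), tracking the lowest saddle
    lo <- h
    for (k in seq(p - 1L, 1L)) {
      if (y[k] > h) break
      lo <- min(lo, y[k])
    }
    left_min <- lo
    lo <- h
    if (p < n) for (k in seq(p + 1L, n)) {
      if (y[k] > h) break
      lo <- min(lo, y[k])
    }
    right_min <- lo
    h - max(left_min, right_min)
  }, numeric(1))
  thr <- min_prominence * max(y)
  keep <- prom >= thr
  out <- data.frame(position = spec$axis[cand][keep],
                    height = y[cand][keep],
                    prominence = prom[keep])
  out[order(out$position), , drop = FALSE]
}
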