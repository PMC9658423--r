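#' Constants for pH-differential anthocyanin quantitation
#'
#' Defaults are the cyanidin-3-glucoside (C3G) values: molecular weight
#' 449.2 g/mol, molar extinction coefficient 26,900 L mol^-1 cm^-1, 1 cm
#' cuvette path length, and the 1000 mg/g unit conversion. Override only
#' when expressing results in another pigment equivalent.
#'
#' @param mw molecular weight, g/mol.
#' @param epsilon molar extinction coefficient, L mol^-1 cm^-1.
#' @param pathlength cuvette path, cm.
#' @param conversion g-to-mg factor.
#' @return named list of constants.
#' @export
c3g_constants <- function(mw = 449.2, epsilon = 26900, pathlength = 1,
                          conversion = 1000) {
  stopifnot(mw > 0, epsilon > 0, pathlength > 0, conversion > 0)
  list(mw = mw, epsilon = epsilon, pathlength = pathlength,
       conversion = conversion)
}

#' Monomeric anthocyanin concentration by the pH-differential method
#'
#' C (mg/L) = A * MW * DF * 1000 / (epsilon * pathlength), with
#' A = (A520 - A700) at pH 1.0 minus (A520 - A700) at pH 4.5. A negative A
#' (treated arm more absorbing at pH 4.5) is returned as a negative
#' concentration with a warning, since it signals an assay problem rather
#' than a computable pigment content.
#'
#' @param A520_pH1,A700_pH1 absorbances of the pH 1.0 dilution (AU).
#' @param A520_pH45,A700_pH45 absorbances of the pH 4.5 dilution (AU).
#' @param DF total dilution factor, >= 1.
#' @param constants see [c3g_constants()].
#' @return concentration in mg/L C3G equivalents.
#' @export
#' @examples
#' ph_differential_concentration(0.269, 0, 0, 0)  # 4.492 mg/L
ph_differential_concentration <- function(A520_pH1, A700_pH1,
                                          A520_pH45, A700_pH45,
                                          DF = 1,
                                          constants = c3g_constants()) {
  vals <- c(A520_pH1, A700_pH1, A520_pH45, A700_pH45, DF)
  if (any(!is.finite(vals))) stop("absorbances and DF must be finite")
  if (any(DF < 1)) stop("dilution factor must be >= 1")
  A <- (A520_pH1 - A700_pH1) - (A520_pH45 - A700_pH45)
  C <- A * constants$mw * DF * constants$conversion /
    (constants$epsilon * constants$pathlength)
  if (any(A < 0))
    warning("negative differential absorbance: check the assay")
  C
}

.check_shared_axis <- function(control, treated) {
  stopifnot(inherits(control, "spectrum"), inherits(treated, "spectrum"))
  if (length(control$axis) != length(treated$axis) ||
      any(control$axis != treated$axis))
    stop("control and treated spectra do not share an axis")
}

#' Bathochromic shift between a control and an iron-treated spectrum
#'
#' Signed displacement of the absorption maximum,
#' lambda_max(treated) - lambda_max(control), in nm. Positive values are
#' bathochromic (red) shifts; negative values hypsochromic.
#'
#' @param control,treated `spectrum` objects on the same axis.
#' @param window nm interval searched for the maxima (default 380-700).
#' @return shift in nm.
#' @export
bathochromic_shift <- function(control, treated, window = c(380, 700)) {
  .check_shared_axis(control, treated)
  lc <- lambda_max(control, window[1], window[2])
  lt <- lambda_max(treated, window[1], window[2])
  lt$position - lc$position
}

#' Hyperchromic shift between a control and an iron-treated spectrum
#'
#' Signed intensity change on iron addition, in AU. The default `"max"` mode
#' compares the window maxima of the two spectra; `"at_control_peak"`
#' instead evaluates the treated spectrum at the control's peak wavelength.
#' Both are plausible readings of a peak-intensity difference; the maxima
#' difference is the default.
#'
#' @inheritParams bathochromic_shift
#' @param mode `"max"` (default) or `"at_control_peak"`.
#' @return shift in AU (positive = hyperchromic, negative = hypochromic).
#' @export
hyperchromic_shift <- function(control, treated, window = c(380, 700),
                               mode = c("max", "at_control_peak")) {
  mode <- match.arg(mode)
  .check_shared_axis(control, treated)
  lc <- lambda_max(control, window[1], window[2])
  if (mode == "max") {
    lt <- lambda_max(treated, window[1], window[2])
    lt$height - lc$height
  } else {
    i <- which(treated$axis == lc$position)
    treated$intensity[i] - lc$height
  }
}

#' Root-mean-square combination of two shift indexes
#'
#' `sqrt((a^2 + b^2) / 2)`: the overall stability score pooling the pH 3 and
#' pH 6 shifts. Symmetric and sign-insensitive; vectorized.
#'
#' @param a,b numeric shift values (nm or AU).
#' @return nonnegative RMS value.
#' @export
#' @examples
#' rms_index(22.57, 44.72)  # 35.42
rms_index <- function(a, b) {
  sqrt((a^2 + b^2) / 2)
}

.quad_arms <- c("ph3_control", "ph3_iron", "ph6_control", "ph6_iron")

#' Six stabilization indexes from replicate UV-vis quadruples
#'
#' Each replicate contributes four spectra: control and iron-treated at pH 3
#' and pH 6. Per replicate, index 1 and 2 are the bathochromic shifts at
#' pH 3 and pH 6 (nm), index 3 and 4 the hyperchromic shifts (AU), and
#' index 5 = rms(index1, index2), index 6 = rms(index3, index4). The
#' replicate-level indexes are then aggregated as mean and sample standard
#' deviation (n - 1). Computing the RMS per replicate before averaging is
#' deliberate: it is the only order consistent with reporting an SD for the
#' RMS indexes, and it differs (slightly) from the RMS of the mean shifts
#' whenever replicates disagree.
#'
#' @param quads list of replicates; each replicate is a named list with
#'   spectra `ph3_control`, `ph3_iron`, `ph6_control`, `ph6_iron`.
#' @param window nm window for peak search (default 380-700, widen to
#'   `c(380, 750)` where acquisition covered it).
#' @param hyper_mode passed to [hyperchromic_shift()].
#' @param sample_id optional label carried into the result.
#' @return An object of class `stability_indexes`: list with
#'   `per_replicate` (data.frame, one row per replicate, columns
#'   index1..index6), `mean`, `sd` (named numeric of length 6) and
#'   `sample_id`.
#' @export
compute_indexes <- function(quads, window = c(380, 700),
                            hyper_mode = "max", sample_id = NA_character_) {
  if (!length(quads)) stop("need at least one replicate quadruple")
  per <- lapply(seq_along(quads), function(r) {
    q <- quads[[r]]
    missing <- setdiff(.quad_arms, names(q))
    missing <- c(missing,
                 names(q)[vapply(q, is.null, logical(1))])
    if (length(missing))
      stop(sprintf("sample '%s', replicate %d: missing spectra [%s]",
                   sample_id, r, paste(unique(missing), collapse = ", ")))
    i1 <- bathochromic_shift(q$ph3_control, q$ph3_iron, window)
    i2 <- bathochromic_shift(q$ph6_control, q$ph6_iron, window)
    i3 <- hyperchromic_shift(q$ph3_control, q$ph3_iron, window, hyper_mode)
    i4 <- hyperchromic_shift(q$ph6_control, q$ph6_iron, window, hyper_mode)
    c(index1 = i1, index2 = i2, index3 = i3, index4 = i4,
      index5 = rms_index(i1, i2), index6 = rms_index(i3, i4))
  })
  per <- as.data.frame(do.call(rbind, per))
  structure(list(per_replicate = per,
                 mean = colMeans(per),
                 sd = apply(per, 2, stats::sd),
                 n_replicates = nrow(per),
                 sample_id = sample_id),
            class = "stability_indexes")
}

#' @export
print.stability_indexes <- function(x, ...) {
  cat(sprintf("<stability_indexes: %s, %d replicate(s)>\n",
              x$sample_id, x$n_replicates))
  m <- x$mean; s <- x$sd
  for (k in 1:6) {
    unit <- if (k %in% c(1, 2, 5)) "nm" else "AU"
    cat(sprintf("  index%d: %8.3f +/- %.3f %s\n", k, m[k],
                if (is.na(s[k])) 0 else s[k], unit))
  }
  invisible(x)
}

#' Tabulate stability indexes for many samples
#'
#' @param index_list list of `stability_indexes` objects.
#' @return data.frame, one row per sample, with `indexK_mean` / `indexK_sd`
#'   columns, ready for CSV export.
#' @export
indexes_table <- function(index_list) {
  rows <- lapply(index_list, function(si) {
    out <- c(as.list(si$mean), as.list(si$sd))
    names(out) <- c(paste0("index", 1:6, "_mean"),
                    paste0("index", 1:6, "_sd"))
    data.frame(sample_id = si$sample_id, out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
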