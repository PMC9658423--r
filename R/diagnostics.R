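#' Reference band assignments for anthocyanin SERS spectra
#'
#' The tentative vibrational assignments of the recurring anthocyanin SERS
#' bands: A/B-ring stretching modes between ~1520 and ~1630 cm^-1 (the
#' ~1600 cm^-1 band being characteristic of the flavylium cation), the
#' inter-ring stretching band near 1330 cm^-1 whose wavenumber tracks
#' pi-electron delocalization, the glycosyl/acyl-associated band near
#' 1300 cm^-1, C-O stretching near 1080 and 1240 cm^-1, hydroxyl bending
#' near 1190 cm^-1, and skeleton in-plane/out-of-plane bending modes below
#' 750 cm^-1.
#'
#' @return data.frame with columns `center` (cm^-1, increasing) and
#'   `assignment`.
#' @export
band_assignments <- function() {
  data.frame(
    center = c(420, 480, 548, 637, 715, 730, 1080, 1190, 1240,
               1300, 1330, 1370, 1460, 1520, 1570, 1605, 1630),
    assignment = c(
      "skeleton out-of-plane bending",
      "skeleton out-of-plane bending",
      "C-C in-plane bending",
      "skeleton bending",
      "aromatic system",
      "aromatic system",
      "C-O stretching",
      "O-H bending",
      "C-O stretching",
      "glycosyl / acyl group modes",
      "inter-ring stretching (B ring, C-H bending)",
      "C-C stretching",
      "ring stretching",
      "ring A + B stretching",
      "ring B stretching",
      "ring A + B stretching (flavylium)",
      "ring A + B stretching"),
    stringsAsFactors = FALSE)
}

#' Rank the spectral bands driving a PLS model
#'
#' For each latent factor, ranks axis positions by the magnitude of the
#' X-loading, keeps local extrema of the loading spectrum (so one band is
#' not reported many times from adjacent grid points), annotates the sign —
#' on second-derivative preprocessed spectra a negative loading excursion
#' marks a band whose original intensity pushes the prediction up — and
#' matches each top band to the nearest reference assignment within
#' `tolerance`, else marks it `"unassigned"`. The collapsed regression
#' vector is ranked the same way under factor label 0.
#'
#' @param model a `pls1` fitted on spectra with a known axis.
#' @param table reference assignments, see [band_assignments()]; may have
#'   zero rows.
#' @param tolerance matching half-width in cm^-1 (> 0).
#' @param n_top bands reported per factor.
#' @param pca optional `spectra_pca` whose components are ranked the same
#'   way and appended with factor labels "PC1", "PC2", ...
#' @return data.frame with columns `factor`, `rank`, `position`, `loading`,
#'   `sign`, `matched_center`, `assignment`.
#' @export
loading_diagnostics <- function(model, table = band_assignments(),
                                tolerance = 15, n_top = 6, pca = NULL) {
  stopifnot(inherits(model, "pls1"), tolerance > 0)
  axis <- model$axis
  if (is.null(axis)) axis <- seq_len(model$p)
  rank_vec <- function(v, label) {
    # local extrema of |v|: points not dominated by an immediate neighbour
    n <- length(v)
    a <- abs(v)
    is_ext <- a >= c(-Inf, a[-n]) & a >= c(a[-1], -Inf)
    cand <- which(is_ext)
    cand <- cand[order(a[cand], decreasing = TRUE)]
    cand <- utils::head(cand, n_top)
    if (!length(cand)) return(NULL)
    matched <- vapply(axis[cand], function(pos) {
      if (!nrow(table)) return(NA_real_)
      d <- abs(table$center - pos)
      if (min(d) <= tolerance) table$center[which.min(d)] else NA_real_
    }, numeric(1))
    assign <- ifelse(is.na(matched), "unassigned",
                     table$assignment[match(matched, table$center)])
    data.frame(factor = label, rank = seq_along(cand),
               position = axis[cand], loading = v[cand],
               sign = ifelse(v[cand] < 0, "negative (positive influence)",
                             "positive (negative influence)"),
               matched_center = matched, assignment = assign,
               stringsAsFactors = FALSE)
  }
  out <- rank_vec(model$coefficients, "0 (regression vector)")
  for (a in seq_len(model$n_factors))
    out <- rbind(out, rank_vec(model$P[, a], as.character(a)))
  if (!is.null(pca))
    for (j in seq_len(pca$k))
      out <- rbind(out, rank_vec(pca$loadings[j, ], paste0("PC", j)))
  rownames(out) <- NULL
  out
}
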