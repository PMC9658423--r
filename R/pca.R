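#' Principal component analysis of a spectral matrix
#'
#' Mean-centered PCA by singular value decomposition. Loadings are returned
#' as unit-norm rows (k x p) with a deterministic sign convention — each
#' component's largest-magnitude loading element is positive — so score and
#' loading plots reproduce bit-for-bit across runs.
#'
#' @param x a `spectral_matrix` or plain numeric matrix (rows = spectra).
#' @param k number of components, `k <= min(n - 1, p)`.
#' @return object of class `spectra_pca`: list with `scores` (n x k),
#'   `loadings` (k x p, orthonormal rows), `explained_variance_ratio`
#'   (fractions of total variance, non-increasing), `mean_spectrum`,
#'   `axis` (when available) and `labels`.
#' @export
pca_fit <- function(x, k = 3) {
  X <- if (inherits(x, "spectral_matrix")) x$X else as.matrix(x)
  axis <- if (inherits(x, "spectral_matrix")) x$axis else NULL
  labels <- if (inherits(x, "spectral_matrix")) x$labels else NULL
  n <- nrow(X); p <- ncol(X)
  if (k > min(n - 1, p))
    stop(sprintf("k = %d exceeds min(n - 1, p) = %d", k, min(n - 1, p)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = k, nv = k)
  V <- sv$v                       # p x k
  # sign convention: largest |loading| element positive, per component
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  evr <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores,
                 loadings = t(V),
                 explained_variance_ratio = evr[seq_len(k)],
                 mean_spectrum = mu,
                 axis = axis,
                 labels = labels,
                 k = k),
            class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf("<spectra_pca: %d components over %d spectra x %d features>\n",
              x$k, nrow(x$scores), ncol(x$loadings)))
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(x$k),
                    100 * x$explained_variance_ratio), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project new spectra onto fitted principal components
#' @param object a `spectra_pca`.
#' @param newdata matrix or `spectral_matrix` with matching feature count.
#' @param ... unused.
#' @return score matrix (n_new x k).
#' @export
predict.spectra_pca <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectral_matrix")) newdata$X else
    as.matrix(newdata)
  if (ncol(X) != length(object$mean_spectrum))
    stop("feature count mismatch with the fitted PCA")
  sweep(X, 2, object$mean_spectrum) %*% t(object$loadings)
}
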