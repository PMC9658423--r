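#' Leave-one-out cross-validation with PRESS factor selection
#'
#' For every candidate factor count `f` up to `max_factors`, refits the
#' PLS1 model on each leave-one-out fold and accumulates
#' `PRESS(f) = sum_i (y_i - yhat_{-i}(f))^2`; `RMSECV(f) = sqrt(PRESS(f)/n)`.
#' The chosen factor count is the smallest `f` attaining the minimum PRESS
#' (parsimony tie-break), with a numerical guard: any `f` whose PRESS is
#' within `1e-10 * sum((y - mean(y))^2)` of the minimum counts as attaining
#' it, so machine-precision noise between exactly-fitting factor counts
#' cannot inflate the chosen dimension.
#'
#' @param x predictor matrix or `spectral_matrix`.
#' @param y response (taken from `x$y` when omitted).
#' @param max_factors largest factor count screened (capped at the rank
#'   achievable on the folds).
#' @details Folds are fitted in the kernel (Gram-matrix) form of PLS1:
#'   with `K = X X'` computed once, every leave-one-out NIPALS sequence —
#'   scores, deflation and the held-out prediction — is carried out on the
#'   (n-1) x (n-1) centered kernel, which yields predictions identical to
#'   refitting [pls1()] on each fold (they agree to machine precision;
#'   the equivalence is part of the test suite) at a fraction of the cost
#'   when spectra have many more features than rows. When the response is
#'   fully deflated before `max_factors` is reached (noise-free low-rank
#'   data), the remaining factor counts inherit the prediction of the last
#'   achievable factor.
#' @return object of class `pls_validation`: `press_by_factor`, `rmsecv`,
#'   `chosen_factors`, `rmsecv_at_chosen`, `r2_cv` (squared Pearson
#'   correlation of LOO predictions at the chosen count vs observed),
#'   `loo_predictions` (n x max_factors), `n`.
#' @export
loocv <- function(x, y = NULL, max_factors = 10) {
  if (inherits(x, "spectral_matrix")) {
    if (is.null(y)) y <- x$y
    x <- x$X
  }
  X <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs at least 3 observations")
  if (max_factors < 1) stop("max_factors must be >= 1")
  # rank on a fold is at most min(n - 2, p); cap the screen there
  max_factors <- min(max_factors, min(n - 2, ncol(X)))
  pred <- .loo_predictions_kernel(X, y, max_factors)
  press <- colSums((pred - y)^2)
  rmsecv <- sqrt(press / n)
  guard <- 1e-10 * sum((y - mean(y))^2)
  chosen <- which(press <= min(press) + guard)[1]
  r2_cv <- stats::cor(pred[, chosen], y)^2
  structure(list(press_by_factor = press,
                 rmsecv = rmsecv,
                 chosen_factors = chosen,
                 rmsecv_at_chosen = rmsecv[chosen],
                 r2_cv = r2_cv,
                 loo_predictions = pred,
                 n = n),
            class = "pls_validation")
}

# Leave-one-out PLS1 predictions for factor counts 1..A via the kernel
# algorithm: every quantity NIPALS needs (scores t = Xc w, y-loadings,
# deflation, and the held-out score t* = x*c' w) is expressible through
# K = X X', so each fold runs on the (n-1)x(n-1) centered kernel.
.loo_predictions_kernel <- function(X, y, A) {
  n <- nrow(X)
  K <- tcrossprod(X)
  pred <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    idx <- seq_len(n)[-i]
    Ki <- K[idx, idx]
    rm_ <- rowMeans(Ki)
    gm <- mean(Ki)
    Kc <- Ki - outer(rm_, rep(1, n - 1L)) -
      outer(rep(1, n - 1L), rm_) + gm          # centered train kernel
    kc <- K[i, idx] - mean(K[i, idx]) - rm_ + gm  # centered test row
    yd <- y[idx] - mean(y[idx])
    yhat <- mean(y[idx])
    tyn1 <- NA_real_
    for (a in seq_len(A)) {
      v0 <- drop(Kc %*% yd)
      tyn <- sum(yd * v0)                      # = ||Xc' yd||^2
      if (a == 1L) tyn1 <- tyn
      if (!(tyn > 1e-12 * max(tyn1, .Machine$double.xmin))) {
        pred[i, a:A] <- yhat                   # response fully deflated
        break
      }
      t_ <- v0 / sqrt(tyn)
      tt <- sum(t_^2)
      q <- sum(yd * t_) / tt
      tstar <- sum(kc * yd) / sqrt(tyn)
      yhat <- yhat + q * tstar
      pred[i, a] <- yhat
      v <- drop(Kc %*% t_)                     # = Xc (Xc' t)
      s <- sum(t_ * v)
      z <- kc - (tstar / tt) * v
      kc <- z - t_ * (sum(z * t_) / tt)
      Kc <- Kc - (outer(t_, v) + outer(v, t_)) / tt +
        (s / tt^2) * outer(t_, t_)
      yd <- yd - q * t_
    }
  }
  pred
}

#' @export
print.pls_validation <- function(x, ...) {
  cat(sprintf("<pls_validation: LOOCV over %d spectra, %d candidate factor(s)>\n",
              x$n, length(x$press_by_factor)))
  cat(sprintf("  chosen factors: %d (RMSECV %.4g, cross-validated R2 %.4f)\n",
              x$chosen_factors, x$rmsecv_at_chosen, x$r2_cv))
  invisible(x)
}

#' Stratified train/validation split of a spectral matrix
#'
#' `replicate_random` draws the training fraction independently within each
#' class (15 of 20 replicates per extract at the default 0.75), matching a
#' replicate-level internal validation. Because replicates of one extract
#' land on both sides, this split shares class structure between train and
#' validation; `leave_sample_out` instead holds out entire extracts, the
#' stricter generalization test. Deterministic given `seed`.
#'
#' @param mat a `spectral_matrix` with class labels.
#' @param fraction training fraction in (0, 1), default 0.75.
#' @param mode `"replicate_random"` or `"leave_sample_out"`.
#' @param seed integer seed.
#' @return list with `train` and `validation` spectral matrices and the
#'   row indices `train_idx` / `validation_idx`.
#' @export
split_train_validation <- function(mat, fraction = 0.75,
                                   mode = c("replicate_random",
                                            "leave_sample_out"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "spectral_matrix"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be inside (0, 1)")
  labels <- mat$labels
  set.seed(seed)
  if (mode == "replicate_random") {
    counts <- table(labels)
    if (any(counts < 4))
      stop("replicate_random needs >= 4 rows per class")
    train_idx <- unlist(lapply(unique(labels), function(cl) {
      rows <- which(labels == cl)
      sample(rows, size = round(fraction * length(rows)))
    }), use.names = FALSE)
  } else {
    classes <- unique(labels)
    n_train <- max(1, round(fraction * length(classes)))
    train_classes <- sample(classes, n_train)
    train_idx <- which(labels %in% train_classes)
  }
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_along(labels), train_idx)
  take <- function(idx)
    spectral_matrix(mat$axis, mat$X[idx, , drop = FALSE],
                    labels = labels[idx],
                    y = if (!is.null(mat$y)) mat$y[idx],
                    kind = mat$kind,
                    meta = if (!is.null(mat$meta))
                      mat$meta[idx, , drop = FALSE])
  out <- list(train = take(train_idx), validation = take(val_idx),
              train_idx = train_idx, validation_idx = val_idx,
              mode = mode, seed = seed)
  attr(out$train, "provenance_hash") <- attr(mat, "provenance_hash")
  attr(out$validation, "provenance_hash") <- attr(mat, "provenance_hash")
  out
}

#' Held-out prediction metrics
#'
#' RMSEP is the root mean squared prediction error on the validation set.
#' `r2` is the squared Pearson correlation of predicted versus actual (the
#' convention of chemometrics packages reporting "correlation R^2");
#' `r2_determination` is the coefficient of determination
#' `1 - SS_res / SS_tot`, reported side by side since the two differ when
#' predictions are biased.
#'
#' @param model a `pls1`.
#' @param x validation predictors (matrix or `spectral_matrix`).
#' @param y validation responses (taken from `x$y` when omitted).
#' @return list with `rmsep`, `r2`, `r2_determination`, `n`, and
#'   `constant_actuals` flag (when TRUE the correlation R^2 is undefined
#'   and returned as NA; RMSEP is still valid).
#' @export
evaluate <- function(model, x, y = NULL) {
  if (inherits(x, "spectral_matrix")) {
    if (is.null(y)) y <- x$y
  }
  if (is.null(y) || !length(y)) stop("validation set is empty")
  pred <- predict(model, x)
  y <- as.numeric(y)
  rmsep <- sqrt(mean((pred - y)^2))
  constant <- stats::sd(y) == 0
  if (constant) {
    warning("constant actual values: correlation R2 undefined")
    r2 <- NA_real_; r2d <- NA_real_
  } else {
    r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, y)^2
    r2d <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  list(rmsep = rmsep, r2 = r2, r2_determination = r2d,
       n = length(y), constant_actuals = constant)
}
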