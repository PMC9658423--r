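#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares with a single response, the latent-variable model
#' linking preprocessed SERS matrices to a stability index. Fitting is the
#' NIPALS sequence on mean-centered data: for each factor, weight
#' `w = X'y / ||X'y||`, score `t = X w`, X-loading `p = X't / t't`,
#' Y-loading `q = y't / t't`, then deflation `X <- X - t p'`,
#' `y <- y - q t`. The factors collapse into a single regression vector
#' `b = W (P'W)^-1 q`, so prediction is `y_mean + (x - x_mean)'b`; the
#' factor-wise recursion is retained (see [predict.pls1()]) as an internal
#' consistency check. With `n_factors` equal to the rank of the centered X,
#' PLS1 reproduces the ordinary least-squares solution.
#'
#' @param x predictor matrix (n x p) or a `spectral_matrix` (whose `y` is
#'   used when `y` is missing; its axis and provenance hash are carried
#'   into the model for loading diagnostics and prediction checks).
#' @param y numeric response of length n (a stability index per spectrum).
#' @param n_factors number of latent variables (>= 1, at most the rank of
#'   the centered predictor matrix).
#' @return object of class `pls1`: weights `W` (p x A), loadings `P`
#'   (p x A), y-loadings `q` (A), scores `T` (n x A), regression vector
#'   `coefficients`, centers `x_mean`/`y_mean`, `fitted.values`,
#'   `residuals`, training `r.squared`, `axis`, `provenance_hash`.
#' @seealso [loocv()] for factor selection, [evaluate()] for held-out
#'   metrics.
#' @export
pls1 <- function(x, y = NULL, n_factors = 2) {
  axis <- NULL; hash <- NULL
  if (inherits(x, "spectral_matrix")) {
    if (is.null(y)) y <- x$y
    axis <- x$axis
    hash <- attr(x, "provenance_hash")
    x <- x$X
  }
  X <- as.matrix(x)
  if (is.null(y)) stop("no response y supplied")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(x)")
  if (stats::sd(y) == 0) stop("response has zero variance")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  rank_x <- qr(Xc)$rank
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (n_factors > rank_x)
    stop(sprintf("n_factors = %d exceeds the achievable rank %d",
                 n_factors, rank_x))
  yc <- y - y_mean
  A <- n_factors
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xd <- Xc; yd <- yc
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * p)
      stop(sprintf("deflated covariance vanished at factor %d", a))
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  fitted <- y_mean + drop(Xc %*% b)
  res <- y - fitted
  ss_tot <- sum(yc^2)
  structure(list(n_factors = A,
                 W = W, P = P, q = q, T = Tm,
                 coefficients = b,
                 x_mean = x_mean, y_mean = y_mean,
                 fitted.values = fitted,
                 residuals = res,
                 r.squared = 1 - sum(res^2) / ss_tot,
                 axis = axis,
                 provenance_hash = hash,
                 n = n, p = p, rank = rank_x),
            class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1: %d factor(s), %d spectra x %d features, training R2 = %.4f>\n",
              x$n_factors, x$n, x$p, x$r.squared))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  # variance of y explained cumulatively per factor
  tt <- colSums(object$T^2)
  yvar <- object$q^2 * tt
  ss_tot <- sum((object$fitted.values + object$residuals -
                   object$y_mean)^2)
  out <- list(model = object,
              y_variance_by_factor = cumsum(yvar) / ss_tot)
  class(out) <- "summary.pls1"
  out
}

#' @export
print.summary.pls1 <- function(x, ...) {
  print(x$model)
  cat("  cumulative fraction of response variance by factor:\n")
  cat("   ", paste(sprintf("F%d %.4f", seq_along(x$y_variance_by_factor),
                           x$y_variance_by_factor), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pls1 <- function(object, ...) object$coefficients

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' Predict stability indexes from new spectra
#'
#' Default path: `y_mean + (x - x_mean)' b` with the collapsed regression
#' vector. `method = "factorwise"` reproduces the prediction through the
#' factor recursion (project, deflate, accumulate `q_a t_a`); the two paths
#' agree to machine precision and the second exists as a structural
#' self-check. When the new spectra carry a preprocessing provenance hash
#' that differs from the model's, a warning is raised.
#'
#' @param object a `pls1` model.
#' @param newdata matrix or `spectral_matrix` with `p` columns.
#' @param method `"regression"` (default) or `"factorwise"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata,
                         method = c("regression", "factorwise"), ...) {
  method <- match.arg(method)
  hash <- NULL
  if (inherits(newdata, "spectral_matrix")) {
    hash <- attr(newdata, "provenance_hash")
    newdata <- newdata$X
  }
  X <- as.matrix(newdata)
  if (ncol(X) != object$p)
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(X), object$p))
  if (!is.null(hash) && !is.null(object$provenance_hash) &&
      !identical(hash, object$provenance_hash))
    warning("preprocessing provenance differs from the model's")
  Xc <- sweep(X, 2, object$x_mean)
  if (method == "regression")
    return(object$y_mean + drop(Xc %*% object$coefficients))
  yhat <- rep(object$y_mean, nrow(X))
  Xd <- Xc
  for (a in seq_len(object$n_factors)) {
    t_a <- drop(Xd %*% object$W[, a])
    yhat <- yhat + object$q[a] * t_a
    Xd <- Xd - tcrossprod(t_a, object$P[, a])
  }
  yhat
}

#' Plot the regression vector or loading spectra of a PLS1 model
#'
#' On second-derivative preprocessed spectra, negative excursions of a
#' loading indicate bands whose (original) intensity contributes
#' positively to the predicted index.
#'
#' @param x a `pls1` model fitted on a `spectral_matrix` (axis known).
#' @param what `"coefficients"` or `"loadings"`.
#' @param factors which factors to draw when `what = "loadings"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pls1 <- function(x, what = c("coefficients", "loadings"),
                      factors = seq_len(x$n_factors), ...) {
  what <- match.arg(what)
  ax <- if (!is.null(x$axis)) x$axis else seq_len(x$p)
  if (what == "coefficients") {
    graphics::plot(ax, x$coefficients, type = "l",
                   xlab = "axis", ylab = "regression coefficient", ...)
  } else {
    graphics::matplot(ax, x$P[, factors, drop = FALSE], type = "l",
                      xlab = "axis", ylab = "X loading", ...)
    graphics::legend("topright", legend = paste0("factor ", factors),
                     col = seq_along(factors), lty = seq_along(factors),
                     bty = "n")
  }
  invisible(x)
}

#' Serialize a fitted PLS1 model to JSON
#' @param model a `pls1`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pls1_json <- function(model, path) {
  stopifnot(inherits(model, "pls1"))
  obj <- unclass(model)
  obj$T <- NULL  # training scores are re-derivable and bulky
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialized PLS1 model
#' @param path JSON file written by [write_pls1_json()].
#' @return a `pls1` model (without training scores).
#' @export
read_pls1_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W <- as.matrix(obj$W); obj$P <- as.matrix(obj$P)
  structure(obj, class = "pls1")
}
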