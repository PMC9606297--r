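# Iteratively reweighted least squares M-estimation used by the
# dose-response outlier screen. Two stages: a monotone Huber pass (safe to
# start from ordinary least squares) followed by a redescending Tukey
# bisquare pass started from the Huber weights. The residual scale is the
# (zero-centred) MAD, floored at `scale_floor` so that plates with
# negligible dispersion - or smooth lack-of-fit of the working polynomial -
# cannot drive the scale towards zero and flag clean wells.

bisquare_weights <- function(u, cc = 4.685) {
  w <- (1 - (u / cc)^2)^2
  w[abs(u) >= cc] <- 0
  w
}

huber_weights <- function(u, k = 1.345) {
  pmin(1, k / pmax(abs(u), .Machine$double.eps))
}

irls_fit <- function(X, y, wfun, w0, scale_floor, maxit = 100L, tol = 1e-8) {
  w <- w0
  cf <- NULL
  for (it in seq_len(maxit)) {
    sw <- sqrt(w)
    cf <- tryCatch(qr.solve(sw * X, sw * y), error = function(e) NULL)
    if (is.null(cf)) return(NULL)
    r <- as.vector(y - X %*% cf)
    s <- max(stats::mad(r, center = 0), scale_floor)
    wn <- wfun(r / s)
    conv <- max(abs(wn - w)) < tol
    w <- wn
    if (conv) break
  }
  list(coefficients = cf, weights = w, residuals = as.vector(y - X %*% cf),
       scale = max(stats::mad(as.vector(y - X %*% cf), center = 0), scale_floor))
}

#' Robust polynomial regression weights
#'
#' Fits `y ~ poly(x, degree)` by two-stage IRLS M-estimation (Huber then
#' Tukey bisquare, tuning constant `cc = 4.685` for 95\% Gaussian efficiency)
#' and returns the final bisquare weights in `[0, 1]`. The robust residual
#' scale is floored at `scale_floor` to keep near-noiseless data from being
#' flagged.
#'
#' @param x,y numeric vectors of equal length.
#' @param degree polynomial degree of the working model (default 4).
#' @param cc bisquare tuning constant.
#' @param scale_floor minimum residual scale, on the response scale.
#' @return list with `weights`, `fitted`, `residuals`, `scale`, `converged`.
#' @export
robust_poly_weights <- function(x, y, degree = 4L, cc = 4.685,
                                scale_floor = 0.05) {
  n <- length(y)
  stopifnot(length(x) == n, n > degree + 1L)
  if (length(unique(x)) <= degree)
    stop("need more than `degree` distinct x values for the polynomial fit")
  X <- cbind(1, stats::poly(x, degree))
  f1 <- irls_fit(X, y, huber_weights, rep(1, n), scale_floor)
  f2 <- if (!is.null(f1))
    irls_fit(X, y, function(u) bisquare_weights(u, cc), f1$weights, scale_floor)
  if (is.null(f2)) {
    warning("robust polynomial fit did not converge; no wells downweighted")
    return(list(weights = rep(1, n), fitted = y, residuals = rep(0, n),
                scale = scale_floor, converged = FALSE))
  }
  list(weights = f2$weights, fitted = as.vector(X %*% f2$coefficients),
       residuals = f2$residuals, scale = f2$scale, converged = TRUE)
}
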