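#' Construct a dose plate
#'
#' Bundles the wells of one sample x drug combination. Control wells are
#' marked by `is_control` (their `dose` is ignored and conventionally 0).
#'
#' @param wells data.frame with columns `dose` (molar), `replicate`,
#'   `signal` (raw viability readout, >= 0) and logical `is_control`.
#' @param sample_id,drug_id identifiers.
#' @return object of class `dose_plate`.
#' @export
dose_plate <- function(wells, sample_id = "sample", drug_id = "drug") {
  stopifnot(is.data.frame(wells),
            all(c("dose", "replicate", "signal", "is_control") %in% names(wells)))
  if (!any(wells$is_control)) stop("plate has no control wells")
  if (any(wells$signal < 0)) stop("raw signals must be nonnegative")
  pos <- wells$dose[!wells$is_control]
  if (length(unique(pos)) < 4L)
    stop("plate needs >= 4 distinct positive doses")
  if (any(pos <= 0)) stop("non-control wells must have positive doses")
  structure(list(wells = wells, sample_id = sample_id, drug_id = drug_id),
            class = "dose_plate")
}

#' @export
print.dose_plate <- function(x, ...) {
  cat(sprintf("<dose_plate> %s x %s: %d wells (%d control), %d doses\n",
              x$sample_id, x$drug_id, nrow(x$wells), sum(x$wells$is_control),
              length(unique(x$wells$dose[!x$wells$is_control]))))
  invisible(x)
}

#' Standardize a plate against its control wells
#'
#' Divides every raw signal by the median signal of the control wells of the
#' same plate, so that a fully viable well reads 1. This is the only
#' normalization applied before curve fitting.
#'
#' @param plate a [dose_plate()].
#' @return the plate with a `response` column added to `$wells`.
#' @export
standardize_plate <- function(plate) {
  stopifnot(inherits(plate, "dose_plate"))
  ctrl <- plate$wells$signal[plate$wells$is_control]
  m <- stats::median(ctrl)
  if (!is.finite(m) || m <= 0)
    stop("control median is not positive; plate rejected")
  plate$wells$response <- plate$wells$signal / m
  plate$control_median <- m
  plate
}

#' Flag outlier wells by robust polynomial regression
#'
#' Fits the standardized responses as a degree-4 polynomial in log dose by
#' robust M-estimation and flags wells whose final robust weight falls below
#' `weight_cut` (default 0.4; weights range from 0 for gross outliers to 1
#' for clean wells).
#'
#' @param log_doses,responses numeric vectors over non-control wells.
#' @param weight_cut weight threshold below which a well is an outlier.
#' @param degree working polynomial degree.
#' @param scale_floor see [robust_poly_weights()].
#' @return list with `weights` and logical `outlier`.
#' @export
flag_outliers <- function(log_doses, responses, weight_cut = 0.4,
                          degree = 4L, scale_floor = 0.05) {
  n <- length(responses)
  stopifnot(length(log_doses) == n)
  if (n < 6L) stop("need >= 6 non-control wells for the outlier screen")
  if (length(unique(log_doses)) <= degree) {
    warning("too few distinct doses for the degree-", degree,
            " screen; no wells flagged")
    return(list(weights = rep(1, n), outlier = rep(FALSE, n)))
  }
  rf <- robust_poly_weights(log_doses, responses, degree = degree,
                            scale_floor = scale_floor)
  list(weights = rf$weights, outlier = rf$weights < weight_cut)
}

#' Least-squares M-spline fit of a dose-response curve
#'
#' Fits standardized responses as a linear combination of cubic M-splines of
#' log dose over `[min(log_doses), max(log_doses)]`, with interior knots at
#' quantiles of the distinct observed log doses
#' (`max(1, n_distinct - 4)` knots). Because M-splines span the same space
#' as the clamped B-spline basis, constants and straight lines are
#' represented exactly. Optionally the fit is constrained to be monotone
#' non-increasing (intercept plus nonpositively weighted I-splines).
#'
#' @param log_doses,responses numeric vectors (outliers already removed).
#' @param degree spline degree, default cubic.
#' @param n_interior number of interior knots; default
#'   `max(1, n_distinct_doses - 4)`.
#' @param monotone if `TRUE`, fit a monotone non-increasing curve.
#' @return object of class `mspline_fit` with `predict` support.
#' @export
fit_monotone_spline <- function(log_doses, responses, degree = 3L,
                                n_interior = NULL, monotone = FALSE) {
  stopifnot(length(log_doses) == length(responses))
  ux <- sort(unique(log_doses))
  if (length(ux) < 4L)
    stop("fewer than 4 distinct doses remain; result censored")
  boundary <- range(ux)
  if (is.null(n_interior)) n_interior <- max(1L, length(ux) - 4L)
  interior <- if (n_interior > 0L)
    stats::quantile(ux, probs = seq_len(n_interior) / (n_interior + 1L),
                    names = FALSE, type = 7)
  else numeric(0)
  interior <- interior[interior > boundary[1] & interior < boundary[2]]
  if (!monotone) {
    M <- mspline_basis(log_doses, interior, boundary, degree)
    cf <- stats::lm.fit(M, responses)$coefficients
    cf[is.na(cf)] <- 0
    obj <- list(type = "mspline", coefficients = cf)
  } else {
    I <- ispline_basis(log_doses, interior, boundary, degree)
    nb <- ncol(I)
    # least squares with b_i <= 0 (non-increasing) via box-constrained BFGS
    fn <- function(par) {
      mu <- par[1] + I %*% pmin(par[-1], 0)
      sum((responses - mu)^2)
    }
    st <- c(max(responses), rep(-1e-3, nb))
    op <- stats::optim(st, fn, method = "L-BFGS-B",
                       lower = c(-Inf, rep(-Inf, nb)),
                       upper = c(Inf, rep(0, nb)),
                       control = list(maxit = 500L))
    obj <- list(type = "ispline_monotone",
                coefficients = c(intercept = op$par[1], pmin(op$par[-1], 0)))
  }
  obj$interior <- interior
  obj$boundary <- boundary
  obj$degree <- degree
  obj$residual_sd <- stats::sd(responses - predict_mspline(obj, log_doses))
  class(obj) <- "mspline_fit"
  obj
}

predict_mspline <- function(object, newx) {
  if (object$type == "mspline") {
    M <- mspline_basis(newx, object$interior, object$boundary, object$degree)
    as.vector(M %*% object$coefficients)
  } else {
    I <- ispline_basis(newx, object$interior, object$boundary, object$degree)
    object$coefficients[1] + as.vector(I %*% object$coefficients[-1])
  }
}

#' @export
predict.mspline_fit <- function(object, newdata, ...) {
  predict_mspline(object, newdata)
}

#' Normalized area under a fitted dose-response curve
#'
#' Integrates the fitted curve over the full log-dose range using the exact
#' I-spline antiderivative of the M-spline basis, then divides by the range,
#' so a curve constant at 1 has AUC exactly 1.
#'
#' @param fit an `mspline_fit`.
#' @return scalar AUC.
#' @export
auc_mspline <- function(fit) {
  stopifnot(inherits(fit, "mspline_fit"))
  a <- fit$boundary[1]; b <- fit$boundary[2]
  if (fit$type == "mspline") {
    Iab <- ispline_basis(c(a, b), fit$interior, fit$boundary, fit$degree)
    as.vector((Iab[2, ] - Iab[1, ]) %*% fit$coefficients) / (b - a)
  } else {
    # intercept integrates linearly; I-splines integrate to order-(k+1)
    # I-splines, evaluated by fine-grained exact quadrature on the basis
    xs <- gauss_legendre_nodes(a, b, fit$interior, fit$degree + 1L)
    mean_curve <- sum(xs$w * predict_mspline(fit, xs$x)) / (b - a)
    mean_curve
  }
}

# Gauss-Legendre nodes per knot interval, exact for piecewise polynomials of
# degree <= 2*npts - 1 on each interval.
gauss_legendre_nodes <- function(a, b, interior, degree) {
  brk <- unique(sort(c(a, interior, b)))
  npts <- ceiling((degree + 1) / 2) + 1L
  gl <- switch(as.character(npts),
    "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
               w = c(5 / 9, 8 / 9, 5 / 9)),
    {
      x <- c(-0.8611363115940526, -0.3399810435848563,
             0.3399810435848563, 0.8611363115940526)
      w <- c(0.3478548451374538, 0.6521451548625461,
             0.6521451548625461, 0.3478548451374538)
      list(x = x, w = w)
    })
  xs <- ws <- numeric(0)
  for (i in seq_len(length(brk) - 1L)) {
    h <- (brk[i + 1] - brk[i]) / 2
    xs <- c(xs, brk[i] + h * (gl$x + 1))
    ws <- c(ws, gl$w * h)
  }
  list(x = xs, w = ws)
}

#' IC50 of a fitted curve
#'
#' The smallest dose in the fitted range at which the standardized response
#' crosses `level` (default 0.5). If the fitted curve never reaches the
#' level anywhere in the dose range the IC50 is censored (`NA` with
#' `censored = TRUE`), mirroring plates whose viability stays above 50\% at
#' the maximum dose.
#'
#' @param fit an `mspline_fit` (or any object with a numeric `predict`).
#' @param level response level defining the IC50.
#' @return list with `log_ic50` (natural-log dose or `NA`), `ic50` (molar)
#'   and logical `censored`.
#' @export
ic50_mspline <- function(fit, level = 0.5) {
  a <- fit$boundary[1]; b <- fit$boundary[2]
  grid <- seq(a, b, length.out = 513L)
  g <- predict_mspline(fit, grid) - level
  if (all(g > 0) || all(g < 0))
    return(list(log_ic50 = NA_real_, ic50 = NA_real_, censored = TRUE))
  idx <- which(g[-length(g)] * g[-1] <= 0)[1]
  if (g[idx] == 0) {
    root <- grid[idx]
  } else {
    root <- stats::uniroot(function(x) predict_mspline(fit, x) - level,
                           lower = grid[idx], upper = grid[idx + 1],
                           tol = 1e-10)$root
  }
  list(log_ic50 = root, ic50 = exp(root), censored = FALSE)
}

#' Five-parameter log-logistic curve
#'
#' `ll5(x) = c + (d - c) / (1 + exp(b * (x - e)))^f` with `x` the natural-log
#' dose, `c`/`d` the lower/upper asymptotes, `b` the slope, `e` the log
#' inflection dose and `f` the asymmetry.
#'
#' @param x natural-log doses.
#' @param lower,upper,slope,log_inflection,asymmetry curve parameters.
#' @return response values.
#' @export
ll5_curve <- function(x, lower, upper, slope, log_inflection, asymmetry = 1) {
  lower + (upper - lower) / (1 + exp(slope * (x - log_inflection)))^asymmetry
}

#' Five-parameter log-logistic cross-check fit
#'
#' Fits the 5-parameter log-logistic model to (log dose, response) pairs by
#' Levenberg-Marquardt nonlinear least squares and reports AUC (normalized,
#' by adaptive quadrature of the fitted curve) and IC50 on the same
#' conventions as the spline estimator, so the two routes are directly
#' comparable.
#'
#' @param log_doses,responses numeric vectors (>= 5 distinct doses).
#' @param level IC50 response level.
#' @return list with `parameters`, `auc`, `log_ic50`, `ic50`, `censored`,
#'   `converged`.
#' @export
fit_loglogistic5 <- function(log_doses, responses, level = 0.5) {
  stopifnot(length(log_doses) == length(responses))
  if (length(unique(log_doses)) < 5L)
    stop("5PL fit needs >= 5 distinct doses")
  a <- min(log_doses); b <- max(log_doses)
  st <- list(lower = max(min(responses), 0), upper = max(responses),
             slope = 1, e = stats::median(log_doses), f = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ lower + (upper - lower) / (1 + exp(slope * (log_doses - e)))^f,
      start = st,
      lower = c(lower = -0.5, upper = 0, slope = 0.01, e = a - 5, f = 0.05),
      upper = c(lower = 1.5, upper = 3, slope = 25, e = b + 5, f = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(parameters = NULL, auc = NA_real_, log_ic50 = NA_real_,
                ic50 = NA_real_, censored = NA, converged = FALSE))
  p <- as.list(stats::coef(fit))
  curve <- function(x) ll5_curve(x, p$lower, p$upper, p$slope, p$e, p$f)
  auc <- stats::integrate(curve, a, b, rel.tol = 1e-9)$value / (b - a)
  g <- function(x) curve(x) - level
  grid <- seq(a, b, length.out = 257L)
  gv <- g(grid)
  idx <- which(gv[-length(gv)] * gv[-1] <= 0)
  if (!length(idx)) {
    return(list(parameters = p, auc = auc, log_ic50 = NA_real_,
                ic50 = NA_real_, censored = TRUE, converged = TRUE))
  }
  root <- stats::uniroot(g, lower = grid[idx[1]], upper = grid[idx[1] + 1],
                         tol = 1e-10)$root
  list(parameters = p, auc = auc, log_ic50 = root, ic50 = exp(root),
       censored = FALSE, converged = TRUE)
}

#' Full dose-response estimation for one plate
#'
#' Runs the complete per-plate procedure: control standardization, robust
#' degree-4 polynomial outlier flagging (robust weight < `weight_cut`),
#' M-spline fit on the retained wells, AUC by exact I-spline integration
#' normalized by the log-dose range, IC50 with censoring, and an optional
#' five-parameter log-logistic cross-check.
#'
#' @param plate a [dose_plate()].
#' @param weight_cut robust-weight threshold for outliers.
#' @param monotone fit the monotone-constrained spline variant.
#' @param crosscheck also fit the 5PL model and report the discrepancy.
#' @param ic50_level standardized response level defining IC50.
#' @param scale_floor robust scale floor for the outlier screen.
#' @return object of class `dose_response_result`.
#' @export
fit_dose_response <- function(plate, weight_cut = 0.4, monotone = FALSE,
                              crosscheck = FALSE, ic50_level = 0.5,
                              scale_floor = 0.05) {
  plate <- standardize_plate(plate)
  w <- plate$wells
  test <- !w$is_control
  ld <- log(w$dose[test])
  resp <- w$response[test]
  fl <- flag_outliers(ld, resp, weight_cut = weight_cut,
                      scale_floor = scale_floor)
  keep <- !fl$outlier
  censored_fit <- FALSE
  fit <- NULL
  if (length(unique(ld[keep])) >= 4L) {
    fit <- fit_monotone_spline(ld[keep], resp[keep], monotone = monotone)
  } else {
    warning("fewer than 4 distinct doses after outlier removal; ",
            "AUC/IC50 censored")
    censored_fit <- TRUE
  }
  res <- list(
    sample_id = plate$sample_id, drug_id = plate$drug_id,
    responses = w$response, is_control = w$is_control,
    weights = fl$weights, outlier = fl$outlier,
    n_outliers = sum(fl$outlier),
    fit = fit, fit_censored = censored_fit,
    auc = if (!censored_fit) auc_mspline(fit) else NA_real_)
  ic <- if (!censored_fit) ic50_mspline(fit, level = ic50_level)
        else list(log_ic50 = NA_real_, ic50 = NA_real_, censored = NA)
  res$ic50 <- ic$ic50
  res$log_ic50 <- ic$log_ic50
  res$ic50_censored <- ic$censored
  if (crosscheck && !censored_fit) {
    cc <- fit_loglogistic5(ld[keep], resp[keep], level = ic50_level)
    res$ll5 <- cc
    res$auc_discrepancy <- if (cc$converged) abs(res$auc - cc$auc) else NA_real_
  }
  class(res) <- "dose_response_result"
  res
}

#' @export
print.dose_response_result <- function(x, ...) {
  cat(sprintf(
    "<dose_response_result> %s x %s: AUC=%.3f IC50=%s (%d outliers)\n",
    x$sample_id, x$drug_id, x$auc,
    if (isTRUE(x$ic50_censored)) "censored" else format(x$ic50, digits = 3),
    x$n_outliers))
  invisible(x)
}

#' Z-scores and clustering orders for a drug-response heatmap
#'
#' Converts a samples x drugs AUC matrix into per-drug Z-scores (mean 0,
#' sd 1 across samples) and computes 'complete'-linkage dendrogram orders:
#' drugs are clustered on Euclidean distances between rows of the drug-drug
#' Spearman correlation matrix, samples on Euclidean distances between
#' their Z-score profiles.
#'
#' @param auc_matrix numeric matrix, samples in rows, drugs in columns.
#' @return list with `z` (samples x drugs), `drug_hclust`, `sample_hclust`,
#'   `drug_order`, `sample_order`, `dropped_drugs`.
#' @export
drug_response_heatmap_inputs <- function(auc_matrix) {
  stopifnot(is.matrix(auc_matrix))
  if (any(rowSums(!is.na(auc_matrix)) == 0) ||
      any(colSums(!is.na(auc_matrix)) == 0))
    stop("all-missing rows or columns are not allowed")
  sds <- apply(auc_matrix, 2L, stats::sd, na.rm = TRUE)
  drop <- which(!is.finite(sds) | sds == 0)
  if (length(drop)) {
    warning("dropping constant drug column(s): ",
            paste(colnames(auc_matrix)[drop], collapse = ", "))
    auc_matrix <- auc_matrix[, -drop, drop = FALSE]
  }
  z <- scale(auc_matrix)
  rho <- stats::cor(auc_matrix, method = "spearman",
                    use = "pairwise.complete.obs")
  drug_h <- stats::hclust(stats::dist(rho), method = "complete")
  sample_h <- stats::hclust(stats::dist(z), method = "complete")
  list(z = z, drug_hclust = drug_h, sample_hclust = sample_h,
       drug_order = drug_h$order, sample_order = sample_h$order,
       dropped_drugs = names(drop))
}
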