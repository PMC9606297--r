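#' M-spline basis matrix
#'
#' Evaluates the M-spline basis (Ramsay-style nonnegative splines that each
#' integrate to one over their support) at the points `x`. M-splines of order
#' `k` are rescaled B-splines: `M_i(x) = k * B_i(x) / (t_{i+k} - t_i)`.
#'
#' @param x numeric vector of evaluation points, all within `boundary`.
#' @param interior numeric vector of interior knots (may be empty).
#' @param boundary length-2 numeric, the closed interval covered by the basis.
#' @param degree polynomial degree (order = degree + 1); default cubic.
#' @return numeric matrix, `length(x)` rows, one column per basis function,
#'   with the knot vector attached as attributes.
#' @seealso [ispline_basis()] for the integrated (I-spline) basis.
#' @export
mspline_basis <- function(x, interior = numeric(0),
                          boundary = range(x), degree = 3L) {
  stopifnot(length(boundary) == 2L, boundary[1] < boundary[2])
  if (any(x < boundary[1] - 1e-12 | x > boundary[2] + 1e-12))
    stop("evaluation points outside the boundary knots")
  x <- pmin(pmax(x, boundary[1]), boundary[2])
  ord <- degree + 1L
  if (length(interior))
    stopifnot(all(interior > boundary[1]), all(interior < boundary[2]))
  knots <- c(rep(boundary[1], ord), sort(interior), rep(boundary[2], ord))
  nb <- length(knots) - ord
  B <- splines::splineDesign(knots, x, ord = ord, outer.ok = TRUE)
  denom <- knots[seq_len(nb) + ord] - knots[seq_len(nb)]
  M <- sweep(B, 2L, ord / denom, `*`)
  structure(M, knots = knots, order = ord, boundary = boundary,
            interior = sort(interior))
}

#' I-spline basis matrix
#'
#' Evaluates the I-spline basis, the running integrals of the M-splines from
#' the lower boundary knot: `I_i(x) = integral of M_i over [boundary[1], x]`.
#' Each `I_i` increases monotonically from 0 to 1. Computed in closed form via
#' the identity `I_i(x) = sum_{j > i} B_{j, k+1}(x)` on the once-augmented
#' knot sequence, so integration of an M-spline fit is exact.
#'
#' @inheritParams mspline_basis
#' @return numeric matrix matching the column layout of [mspline_basis()].
#' @export
ispline_basis <- function(x, interior = numeric(0),
                          boundary = range(x), degree = 3L) {
  stopifnot(length(boundary) == 2L, boundary[1] < boundary[2])
  x <- pmin(pmax(x, boundary[1]), boundary[2])
  ord <- degree + 1L
  knots <- c(rep(boundary[1], ord), sort(interior), rep(boundary[2], ord))
  nb <- length(knots) - ord
  kn1 <- c(rep(boundary[1], ord + 1L), sort(interior), rep(boundary[2], ord + 1L))
  nb1 <- length(kn1) - (ord + 1L)
  B1 <- splines::splineDesign(kn1, x, ord = ord + 1L, outer.ok = TRUE)
  # at the right boundary the last order-(k+1) B-spline evaluates to 0 by the
  # half-open convention of splineDesign; every I_i must reach 1 there
  at_end <- x >= boundary[2] - 1e-12
  I <- vapply(seq_len(nb), function(i) {
    v <- rowSums(B1[, (i + 1L):nb1, drop = FALSE])
    v[at_end] <- 1
    v
  }, numeric(length(x)))
  if (is.null(dim(I))) I <- matrix(I, nrow = length(x))
  structure(I, knots = knots, order = ord, boundary = boundary,
            interior = sort(interior))
}
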