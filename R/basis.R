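#' B-spline basis sets over time and delay
#'
#' Quadratic (order-two) B-spline bases parameterize every kernel in the
#' encoding model: the stimulus kernels as tensor products of a delay basis
#' and a time basis, the post-spike kernel over delay, and the offset kernel
#' over time.  Knots are simple (non-clamped), so a knot vector of length
#' `n` with polynomial degree 2 carries `n - 3` basis functions.
#'
#' @param knots strictly increasing numeric vector of knot positions (ms).
#' @param degree polynomial degree of the B-splines; the default 2
#'   (quadratic) is the convention used throughout the package.
#' @param at integer-ms lattice on which the basis is pre-evaluated.
#'   Defaults to every integer ms in the interior knot span, where the
#'   basis forms a partition of unity.
#' @return An object of class `bspline_basis`: a list with the knots,
#'   degree, number of basis functions `n_basis`, interior `support`
#'   (ms), the evaluation lattice `at`, and the pre-evaluated basis matrix
#'   `X` (`length(at)` rows by `n_basis` columns).
#' @examples
#' b <- bspline_basis(delay_knots())
#' b$n_basis # 23
#' @export
bspline_basis <- function(knots, degree = 2, at = NULL) {
  knots <- as.numeric(knots)
  if (anyNA(knots) || is.unsorted(knots, strictly = TRUE)) {
    stop("`knots` must be strictly increasing with no missing values",
         call. = FALSE)
  }
  if (length(knots) < degree + 2) {
    stop("need at least degree + 2 knots", call. = FALSE)
  }
  n_basis <- as.integer(length(knots) - degree - 1L)
  support <- c(knots[degree + 1L], knots[length(knots) - degree])
  if (is.null(at)) {
    at <- seq(ceiling(support[1]), floor(support[2]))
  }
  at <- as.numeric(at)
  out <- structure(
    list(knots = knots, degree = degree, n_basis = n_basis,
         support = support, at = at, X = NULL),
    class = "bspline_basis")
  out$X <- eval_basis(out, at)
  out
}

#' Evaluate a B-spline basis at arbitrary points
#'
#' Points outside the knot span evaluate to zero in every basis function
#' (kernel values outside the supported span are defined as 0).
#'
#' @param basis a [bspline_basis()] object.
#' @param x numeric vector of evaluation points (ms).
#' @return numeric matrix, `length(x)` by `basis$n_basis`.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "bspline_basis"))
  knots <- basis$knots
  ord <- basis$degree + 1L
  X <- matrix(0, nrow = length(x), ncol = basis$n_basis)
  inside <- x >= knots[1] & x <= knots[length(knots)]
  if (any(inside)) {
    X[inside, ] <- splines::splineDesign(knots, x[inside], ord = ord,
                                         outer.ok = TRUE)
  }
  dimnames(X) <- NULL
  X
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat(sprintf(
    "<bspline_basis> degree %d, %d knots [%g, %g], %d basis functions\n",
    x$degree, length(x$knots), min(x$knots), max(x$knots), x$n_basis))
  invisible(x)
}

#' Default knot grids
#'
#' The four knot grids used by the default model configuration: a delay
#' grid for the stimulus kernels (26 uniform knots, 7 ms apart, spanning
#' -13 to 162 ms; 23 basis functions over a 150 ms delay support), a time
#' grid for the stimulus kernels (159 uniform knots, -554 to 552 ms; 156
#' basis functions over a 1081 ms span centered on saccade onset), a
#' non-uniform post-spike grid whose knots are dense near the spike time
#' and its refractory period (23 knots; 20 basis functions), and an offset
#' grid (77 uniform knots, -570 to 570 ms; 74 basis functions).
#'
#' @return numeric vector of knot positions in ms.
#' @name knot-grids
NULL

#' @rdname knot-grids
#' @export
delay_knots <- function() seq(-13, 162, by = 7)

#' @rdname knot-grids
#' @export
time_knots <- function() seq(-554, 552, by = 7)

#' @rdname knot-grids
#' @export
postspike_knots <- function() {
  c(1, 2, 3, 4, 6, 8, 15, 22, 29, 36, 43, 50, 57, 64, 71, 78, 92, 106,
    120, 134, 148, 162, 176)
}

#' @rdname knot-grids
#' @export
offset_knots <- function() seq(-570, 570, by = 15)

#' Tensor-product basis over (time, delay)
#'
#' Couples a delay basis `U` and a time basis `V` into the separable
#' two-dimensional basis `B[i,j](t, tau) = U[i](tau) * V[j](t)` used by
#' the stimulus kernels.
#'
#' @param delay_basis,time_basis [bspline_basis()] objects over delay and
#'   time respectively.
#' @return An object of class `basis2d`.
#' @export
basis2d <- function(delay_basis, time_basis) {
  stopifnot(inherits(delay_basis, "bspline_basis"),
            inherits(time_basis, "bspline_basis"))
  structure(list(delay = delay_basis, time = time_basis), class = "basis2d")
}

#' @export
print.basis2d <- function(x, ...) {
  cat(sprintf("<basis2d> %d delay x %d time basis functions\n",
              x$delay$n_basis, x$time$n_basis))
  invisible(x)
}
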