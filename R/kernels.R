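#' Kernel field on the (probe, time, delay) lattice
#'
#' A realized stimulus-kernel field `k[p, t, tau]`: the value with which a
#' stimulus at probe `p`, presented `tau` ms before time `t` (saccade
#' onset at t = 0), drives the generator signal.
#'
#' @param values numeric array `[n_probes, n_t, n_tau]`.
#' @param t_axis integer time lattice (ms from saccade onset).
#' @param tau_axis integer delay lattice (ms from stimulus onset).
#' @param grid optional [probe_grid()] the probe dimension refers to.
#' @return object of class `kernel_field`.
#' @export
kernel_field <- function(values, t_axis, tau_axis, grid = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (dim(values)[2] != length(t_axis) || dim(values)[3] != length(tau_axis)) {
    stop("kernel dimensions do not match the time/delay axes", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("kernel field contains non-finite values", call. = FALSE)
  }
  structure(list(values = values, t_axis = as.integer(t_axis),
                 tau_axis = as.integer(tau_axis), grid = grid),
            class = "kernel_field")
}

#' @export
print.kernel_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<kernel_field> %d probes, t in [%d, %d] ms, delay in [%d, %d] ms\n",
              d[1], min(x$t_axis), max(x$t_axis),
              min(x$tau_axis), max(x$tau_axis)))
  invisible(x)
}

#' @export
as_tibble.kernel_field <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    probe = rep(seq_len(d[1]), times = d[2] * d[3]),
    t = rep(rep(x$t_axis, each = d[1]), times = d[3]),
    tau = rep(x$tau_axis, each = d[1] * d[2]),
    value = as.vector(x$values))
}

#' Realize the stimulus-kernel field from basis coefficients
#'
#' The kernel at probe `p` is the double sum over basis indices of
#' `kappa[p, i, j] * U[i](tau) * V[j](t)`.
#'
#' @param kappa numeric array `[n_probes, n_i, n_j]` of stimulus-kernel
#'   coefficients (`n_i` delay, `n_j` time basis functions).
#' @param basis a [basis2d()] object.
#' @param t_axis,tau_axis lattices on which to realize the field; default
#'   to the bases' pre-evaluation lattices.
#' @param grid optional [probe_grid()].
#' @return a [kernel_field()].
#' @export
realize_stimulus_kernel <- function(kappa, basis, t_axis = NULL,
                                    tau_axis = NULL, grid = NULL) {
  stopifnot(inherits(basis, "basis2d"))
  kappa <- as.array(kappa)
  if (length(dim(kappa)) != 3) stop("`kappa` must be a 3-d array", call. = FALSE)
  if (dim(kappa)[2] != basis$delay$n_basis ||
      dim(kappa)[3] != basis$time$n_basis) {
    stop("coefficient indices exceed the basis dimensions", call. = FALSE)
  }
  if (is.null(tau_axis)) tau_axis <- basis$delay$at
  if (is.null(t_axis)) t_axis <- basis$time$at
  U <- eval_basis(basis$delay, tau_axis)   # n_tau x n_i
  V <- eval_basis(basis$time, t_axis)      # n_t  x n_j
  n_p <- dim(kappa)[1]
  vals <- array(0, dim = c(n_p, length(t_axis), length(tau_axis)))
  for (p in seq_len(n_p)) {
    K <- matrix(kappa[p, , ], nrow = dim(kappa)[2])
    vals[p, , ] <- V %*% t(K) %*% t(U)     # n_t x n_tau
  }
  kernel_field(vals, t_axis, tau_axis, grid)
}

#' Realize the post-spike kernel
#'
#' `h(tau) = -sum_i eta[i]^2 * H[i](tau)`; the squared parameterization
#' guarantees a non-positive kernel so that spike history can only be
#' refractory (suppressive).
#'
#' @param eta numeric coefficient vector, one per post-spike basis function.
#' @param basis [bspline_basis()] over delay.
#' @param tau_axis delay lattice; defaults to the basis lattice.
#' @return numeric vector `h(tau)` on `tau_axis`, with the lattice in
#'   attribute `"tau_axis"`.
#' @export
realize_postspike_kernel <- function(eta, basis, tau_axis = NULL) {
  stopifnot(inherits(basis, "bspline_basis"))
  if (length(eta) != basis$n_basis) {
    stop("`eta` length must equal the number of basis functions", call. = FALSE)
  }
  if (is.null(tau_axis)) tau_axis <- basis$at
  H <- eval_basis(basis, tau_axis)
  h <- as.vector(-(H %*% eta^2))
  attr(h, "tau_axis") <- tau_axis
  h
}

#' Realize the offset kernel
#'
#' `b(t) = sum_j beta[j] * O[j](t)`: the stimulus-independent,
#' saccade-locked modulation of baseline activity.
#'
#' @param beta numeric coefficient vector, one per offset basis function.
#' @param basis [bspline_basis()] over time.
#' @param t_axis time lattice; defaults to the basis lattice.
#' @return numeric vector `b(t)` on `t_axis`, lattice in attribute
#'   `"t_axis"`.
#' @export
realize_offset_kernel <- function(beta, basis, t_axis = NULL) {
  stopifnot(inherits(basis, "bspline_basis"))
  if (length(beta) != basis$n_basis) {
    stop("`beta` length must equal the number of basis functions", call. = FALSE)
  }
  if (is.null(t_axis)) t_axis <- basis$at
  O <- eval_basis(basis, t_axis)
  b <- as.vector(O %*% beta)
  attr(b, "t_axis") <- t_axis
  b
}
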