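#' Skewed bivariate Gaussian source kernel
#'
#' The spatial profile of one modulatory source: an
#' orientation-correlated bivariate Gaussian multiplied by two
#' standard-normal CDF skew factors,
#' `G(x, y) = a * exp(-Q(x, y) / (2 (1 - rho^2))) * Phi(gx (x - mux)) *
#' Phi(gy (y - muy))` with `Q` the correlated quadratic form.
#' Coordinates and spreads are in probe-grid units (`x` along columns,
#' `y` along rows).
#'
#' @param x,y coordinates (vectors of equal length are evaluated
#'   elementwise).
#' @param phi named numeric vector or list with elements `a`, `mux`,
#'   `muy`, `sx`, `sy`, `rho`, `gx`, `gy`.
#' @return numeric vector of kernel values.
#' @export
skew_gaussian <- function(x, y, phi) {
  phi <- as.list(phi)
  sx <- phi$sx; sy <- phi$sy; rho <- phi$rho
  if (sx <= 0 || sy <= 0) stop("spreads must be positive", call. = FALSE)
  if (abs(rho) >= 1) stop("singular covariance: |rho| must be < 1",
                          call. = FALSE)
  dx <- x - phi$mux
  dy <- y - phi$muy
  Q <- dx^2 / sx^2 + dy^2 / sy^2 - 2 * rho * dx * dy / (sx * sy)
  phi$a * exp(-Q / (2 * (1 - rho^2))) *
    stats::pnorm(phi$gx * dx) * stats::pnorm(phi$gy * dy)
}

#' Default delay-bin boundaries for the factorization
#'
#' The 28 boundaries (ms) of the non-overlapping delay bins
#' `[tau_b, tau_{b+1})` over which the skew-Gaussian source parameters
#' are estimated; dense around the short-latency response.
#'
#' @return integer vector of 28 boundaries covering the 150 ms delay
#'   support.
#' @export
delay_bins <- function() {
  c(1, 20, 40, 50, 53, 56, 59, 62, 65, 68, 71, 74, 77, 80, 85, 90, 95,
    100, 105, 110, 115, 120, 125, 130, 135, 140, 145, 151)
}

#' Fixation kernel: time-average of the stimulus kernels
#'
#' Per-probe, per-delay mean of the kernel field over the fixation
#' window `t` in `[t1, t2]`.
#'
#' @param kernels a [kernel_field()].
#' @param t1,t2 window bounds in ms from saccade (defaults -400, -300).
#' @return numeric matrix `[n_probes, n_tau]`, delay lattice in
#'   attribute `"tau_axis"`.
#' @export
fixation_kernel <- function(kernels, t1 = -400, t2 = -300) {
  sel <- kernels$t_axis >= t1 & kernels$t_axis <= t2
  if (!any(sel)) stop("empty fixation window", call. = FALSE)
  out <- apply(kernels$values[, sel, , drop = FALSE], c(1, 3), mean)
  attr(out, "tau_axis") <- kernels$tau_axis
  out
}

phi_names <- c("a", "mux", "muy", "sx", "sy", "rho", "gx", "gy")

factor_bounds <- function(source_locs) {
  lower <- c(); upper <- c()
  for (nm in c("RF", "FF", "ST")) {
    loc <- source_locs[[nm]]
    lower <- c(lower, -Inf, loc[2] - 1, loc[1] - 1, 0.2, 0.2, -0.99, -5, -5)
    upper <- c(upper, Inf, loc[2] + 1, loc[1] + 1, 2, 2, 0.99, 5, 5)
  }
  list(lower = c(lower, -Inf), upper = c(upper, Inf))
}

unpack_phi <- function(par) {
  list(RF = stats::setNames(par[1:8], phi_names),
       FF = stats::setNames(par[9:16], phi_names),
       ST = stats::setNames(par[17:24], phi_names),
       c = par[25])
}

factor_sse <- function(par, xs, ys, target) {
  p <- unpack_phi(par)
  pred <- skew_gaussian(xs, ys, p$RF) + skew_gaussian(xs, ys, p$FF) +
    skew_gaussian(xs, ys, p$ST) + p$c
  sum((pred - target)^2)
}

#' Factorize stimulus kernels into RF/FF/ST sources (F-model)
#'
#' For every time point and delay bin, finds the three skew-Gaussian
#' source parameter sets and the spatially uniform baseline `c` that
#' minimize the sum of squared differences between the reconstruction
#' (fixation kernel + sources + baseline) and the fitted stimulus
#' kernels, subject to bound constraints: each source center within one
#' probe spacing of its nominal probe, spreads at most 2 probe
#' spacings, orientation in (-1, 1), skewness bounded by 5.
#' Reconstructed kernels (see [fmodel_kernels()]) are smoothed along
#' delay with a 10 ms moving average.
#'
#' @param x a fitted [smodel()] or a [kernel_field()].
#' @param source_locs named list `RF`, `FF`, `ST` of 0-based
#'   `(row, col)` source probes (see [estimate_locations()]).
#' @param bins delay-bin boundaries (ms), default [delay_bins()]
#'   restricted to the kernel delay support.
#' @param t_values time points at which to fit; default every point of
#'   the kernel time lattice (subsample for speed; reconstruction
#'   interpolates linearly between fitted points).
#' @param fixation_window `(t1, t2)` for the fixation kernel.
#' @param n_starts number of optimizer starts per (t, bin) cell
#'   (warm start from the previous bin, a nominal start at the source
#'   probes, and seeded perturbations).
#' @param seed seed for the perturbed starts.
#' @param verbose print progress per time point.
#' @return object of class `fmodel` with per-(t, bin) source parameter
#'   array `phi` `[3, n_t, n_bins, 8]`, baseline `c_arr`, the fixation
#'   kernel, achieved `sse` and the fixation-only reference
#'   `sse_fix`, plus the generator components inherited from the parent
#'   S-model when `x` is an [smodel()].
#' @export
fit_factorization <- function(x, source_locs, bins = NULL, t_values = NULL,
                              fixation_window = c(-400, -300),
                              n_starts = 3, seed = 1L, verbose = FALSE) {
  parent <- NULL
  if (inherits(x, "smodel")) {
    parent <- x
    kernels <- smodel_kernels(x)
  } else if (inherits(x, "kernel_field")) {
    kernels <- x
  } else stop("`x` must be an smodel or kernel_field", call. = FALSE)
  tau_axis <- kernels$tau_axis
  if (is.null(bins)) {
    bins <- delay_bins()
    bins <- bins[bins <= max(tau_axis) + 1]
    if (length(bins) < 2) bins <- c(min(tau_axis), max(tau_axis) + 1)
  }
  if (is.unsorted(bins, strictly = TRUE)) {
    stop("bin boundaries must be strictly increasing", call. = FALSE)
  }
  if (is.null(t_values)) t_values <- kernels$t_axis
  t_values <- sort(intersect(t_values, kernels$t_axis))
  grid <- kernels$grid
  if (is.null(grid)) stop("kernel field carries no probe grid", call. = FALSE)
  coords <- probe_coords(grid)
  xs <- coords$col; ys <- coords$row
  fixk <- fixation_kernel(kernels, fixation_window[1], fixation_window[2])
  n_bins <- length(bins) - 1L
  n_tv <- length(t_values)
  phi <- array(NA_real_, dim = c(3, n_tv, n_bins, 8),
               dimnames = list(c("RF", "FF", "ST"), NULL, NULL, phi_names))
  c_arr <- matrix(NA_real_, n_tv, n_bins)
  sse <- matrix(NA_real_, n_tv, n_bins)
  sse_fix <- matrix(NA_real_, n_tv, n_bins)
  bounds <- factor_bounds(source_locs)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  nominal <- function(target) {
    par <- numeric(25)
    for (k in 1:3) {
      loc <- source_locs[[c("RF", "FF", "ST")[k]]]
      pid <- probe_id(grid, loc[1], loc[2])
      par[(k - 1) * 8 + 1:8] <- c(4 * target[pid], loc[2], loc[1],
                                  1, 1, 0, 0, 0)
    }
    par[25] <- stats::median(target)
    par
  }
  clamp <- function(par) pmin(pmax(par, bounds$lower), bounds$upper)
  prev <- NULL
  tidx <- match(t_values, kernels$t_axis)
  for (it in seq_len(n_tv)) {
    if (verbose && it %% 10 == 1) message("factorizing t = ", t_values[it])
    for (b in seq_len(n_bins)) {
      sel <- tau_axis >= bins[b] & tau_axis < bins[b + 1]
      if (!any(sel)) next
      resid <- matrix(kernels$values[, tidx[it], sel], nrow = nrow(fixk)) -
        fixk[, sel, drop = FALSE]
      target <- rowMeans(resid)
      starts <- list(nominal(target))
      if (!is.null(prev)) starts <- c(list(prev), starts)
      while (length(starts) < n_starts) {
        pert <- clamp(starts[[1]] + stats::rnorm(25, 0, 0.2))
        starts <- c(starts, list(pert))
      }
      best <- NULL
      for (s in starts) {
        fitb <- tryCatch(
          stats::optim(clamp(s), factor_sse, xs = xs, ys = ys,
                       target = target, method = "L-BFGS-B",
                       lower = bounds$lower, upper = bounds$upper,
                       control = list(maxit = 120)),
          error = function(e) NULL)
        if (!is.null(fitb) &&
            (is.null(best) || fitb$value < best$value)) best <- fitb
      }
      if (is.null(best)) {
        if (is.null(prev)) next
        best <- list(par = prev, value = factor_sse(prev, xs, ys, target))
        warning(sprintf("optimizer failed at t = %d, bin %d; reusing previous solution",
                        t_values[it], b))
      }
      # the all-zero source solution is always admissible; never do worse
      zero <- nominal(target); zero[c(1, 9, 17, 25)] <- 0
      if (factor_sse(zero, xs, ys, target) < best$value) {
        best <- list(par = zero, value = factor_sse(zero, xs, ys, target))
      }
      up <- unpack_phi(best$par)
      phi[1, it, b, ] <- up$RF
      phi[2, it, b, ] <- up$FF
      phi[3, it, b, ] <- up$ST
      c_arr[it, b] <- up$c
      sse[it, b] <- best$value
      sse_fix[it, b] <- sum(target^2)
      prev <- best$par
    }
  }
  out <- structure(list(
    phi = phi, c_arr = c_arr, fixation = fixk, bins = bins,
    t_values = t_values, source_locs = source_locs, grid = grid,
    tau_axis = tau_axis, sse = sse, sse_fix = sse_fix,
    seed = seed), class = "fmodel")
  if (!is.null(parent)) {
    out$postspike <- smodel_postspike(parent)
    out$offset <- smodel_offset(parent)
    out$offset_t_axis <- parent$config$t_axis
    out$b0 <- parent$b0
    out$r0 <- parent$r0
    out$rmax <- parent$rmax
    out$delta_ms <- parent$delta_ms
  }
  out
}

#' Attach generator components to an F-model
#'
#' An `fmodel` fitted from a bare [kernel_field()] carries no post-spike
#' or offset kernel and cannot predict rates; this attaches the
#' remaining generator components (e.g. a synthetic neuron's ground
#' truth, or another model's fitted components).
#'
#' @param fm an `fmodel`.
#' @param postspike post-spike kernel values at delays 1.. ms.
#' @param offset offset kernel values on `offset_t_axis`.
#' @param offset_t_axis time lattice of `offset` (ms from saccade).
#' @param b0 baseline generator constant.
#' @param r0,rmax rate constants (spk/s).
#' @param delta_ms bin size.
#' @return the `fmodel` with generator components attached.
#' @export
fmodel_generator <- function(fm, postspike, offset, offset_t_axis,
                             b0, r0, rmax, delta_ms = 1) {
  stopifnot(inherits(fm, "fmodel"))
  fm$postspike <- postspike
  fm$offset <- offset
  fm$offset_t_axis <- as.integer(offset_t_axis)
  fm$b0 <- b0
  fm$r0 <- r0
  fm$rmax <- rmax
  fm$delta_ms <- delta_ms
  fm
}

#' @export
print.fmodel <- function(x, ...) {
  cat(sprintf("<fmodel> %d time points x %d delay bins, %d-probe grid\n",
              length(x$t_values), length(x$bins) - 1L, n_probes(x$grid)))
  invisible(x)
}

#' Reconstructed kernels of an F-model
#'
#' Rebuilds `k_hat[p, t, tau] = fixation[p, tau] + sum_sr G_sr(p;
#' phi(t, bin(tau))) + c(t, bin(tau))`, interpolating the source and
#' baseline contribution linearly in `t` between fitted time points,
#' then smooths along the delay dimension with a moving-average filter
#' (default span 10 ms, shrinking at the edges).
#'
#' @param fm an `fmodel`.
#' @param t_axis time lattice for the reconstruction; defaults to the
#'   fitted time points.
#' @param smooth_span_ms delay moving-average span; 0 disables.
#' @return a [kernel_field()].
#' @export
fmodel_kernels <- function(fm, t_axis = NULL, smooth_span_ms = 10) {
  if (is.null(t_axis)) t_axis <- fm$t_values
  coords <- probe_coords(fm$grid)
  xs <- coords$col; ys <- coords$row
  n_p <- length(xs)
  n_tv <- length(fm$t_values)
  n_tau <- length(fm$tau_axis)
  bin_of <- findInterval(fm$tau_axis, fm$bins,
                         rightmost.closed = FALSE, left.open = FALSE)
  bin_of[bin_of < 1 | bin_of > length(fm$bins) - 1] <- NA
  # source + baseline contribution at fitted time points
  contrib <- array(0, dim = c(n_p, n_tv, n_tau))
  for (it in seq_len(n_tv)) {
    for (b in seq_len(length(fm$bins) - 1L)) {
      taus <- which(!is.na(bin_of) & bin_of == b)
      if (length(taus) == 0 || is.na(fm$c_arr[it, b])) next
      val <- fm$c_arr[it, b]
      spat <- rep(val, n_p)
      for (k in 1:3) {
        spat <- spat + skew_gaussian(xs, ys, fm$phi[k, it, b, ])
      }
      contrib[, it, taus] <- spat
    }
  }
  vals <- array(0, dim = c(n_p, length(t_axis), n_tau))
  pos <- findInterval(t_axis, fm$t_values)
  for (i in seq_along(t_axis)) {
    t <- t_axis[i]
    if (pos[i] < 1) {
      slab <- contrib[, 1, ]
    } else if (pos[i] >= n_tv) {
      slab <- contrib[, n_tv, ]
    } else {
      t0 <- fm$t_values[pos[i]]; t1 <- fm$t_values[pos[i] + 1]
      w <- (t - t0) / (t1 - t0)
      slab <- (1 - w) * contrib[, pos[i], ] + w * contrib[, pos[i] + 1, ]
    }
    vals[, i, ] <- matrix(slab, nrow = n_p) + fm$fixation
  }
  if (smooth_span_ms > 0) {
    for (p in seq_len(n_p)) {
      vals[p, , ] <- t(apply(vals[p, , , drop = FALSE][1, , ], 1,
                             moving_average, span = smooth_span_ms))
    }
  }
  kernel_field(vals, t_axis, fm$tau_axis, fm$grid)
}

#' Knock out modulatory sources of an F-model
#'
#' Sources not in `keep` are nulled by replacing, at every (time, bin),
#' their parameter vector with one drawn at random from that source's
#' own fitted parameters during the fixation period (t in -400..-300 ms
#' by default).  `keep = character(0)` yields the no-source model;
#' `keep = "FF"` the +FF variant; `keep = c("RF", "ST")` the -FF
#' variant.
#'
#' @param fm an `fmodel`.
#' @param keep character subset of `c("RF", "FF", "ST")` to preserve.
#' @param fixation_window `(t1, t2)` pool window (ms).
#' @param seed integer seed for the draws.
#' @return an `fmodel` with the substituted sources.
#' @export
knockout <- function(fm, keep = character(0),
                     fixation_window = c(-400, -300), seed = 1L) {
  stopifnot(inherits(fm, "fmodel"))
  if (length(keep) > 0) {
    keep <- unique(match.arg(keep, c("RF", "FF", "ST"), several.ok = TRUE))
  }
  drop <- setdiff(c("RF", "FF", "ST"), keep)
  if (length(drop) == 0) return(fm)
  pool_t <- which(fm$t_values >= fixation_window[1] &
                    fm$t_values <= fixation_window[2])
  if (length(pool_t) == 0) {
    stop("no fitted time points inside the fixation window", call. = FALSE)
  }
  n_bins <- length(fm$bins) - 1L
  pool <- expand.grid(it = pool_t, b = seq_len(n_bins))
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  for (nm in drop) {
    k <- match(nm, c("RF", "FF", "ST"))
    for (it in seq_along(fm$t_values)) {
      for (b in seq_len(n_bins)) {
        d <- pool[sample.int(nrow(pool), 1), ]
        fm$phi[k, it, b, ] <- fm$phi[k, d$it, d$b, ]
      }
    }
  }
  fm
}

#' Aggregate F-models into an A-model
#'
#' Element-wise arithmetic mean of the source parameters, baselines and
#' fixation kernels of an ensemble of F-models fitted to resampled
#' subsets of the data (the inherited generator components are averaged
#' likewise).
#'
#' @param fms list of `fmodel` objects sharing structure.
#' @return an `fmodel` (the A-model).
#' @export
aggregate_fmodels <- function(fms) {
  if (length(fms) == 0) stop("empty model list", call. = FALSE)
  ref <- fms[[1]]
  for (fm in fms[-1]) {
    if (!identical(dim(fm$phi), dim(ref$phi)) ||
        !identical(fm$bins, ref$bins) ||
        !identical(fm$t_values, ref$t_values)) {
      stop("F-models have mismatched structures", call. = FALSE)
    }
  }
  mean_of <- function(field) {
    Reduce(`+`, lapply(fms, `[[`, field)) / length(fms)
  }
  out <- ref
  out$phi <- mean_of("phi")
  dimnames(out$phi) <- dimnames(ref$phi)
  out$c_arr <- mean_of("c_arr")
  out$fixation <- mean_of("fixation")
  attr(out$fixation, "tau_axis") <- attr(ref$fixation, "tau_axis")
  for (f in c("postspike", "offset", "b0", "r0", "rmax")) {
    if (!is.null(ref[[f]])) out[[f]] <- mean_of(f)
  }
  if (!is.null(ref$postspike)) {
    attr(out$postspike, "tau_axis") <- attr(ref$postspike, "tau_axis")
  }
  if (!is.null(ref$offset)) attr(out$offset, "t_axis") <- attr(ref$offset, "t_axis")
  out$sse <- NULL; out$sse_fix <- NULL
  out
}

#' @export
predict.fmodel <- function(object, trials,
                           history = c("true", "none", "simulated"),
                           seed = NULL, ...) {
  if (is.null(object$b0)) {
    stop("this fmodel carries no parent generator components", call. = FALSE)
  }
  kernels <- fmodel_kernels(object, t_axis = object$offset_t_axis)
  cif_core(kernels, object$postspike, object$offset, object$offset_t_axis,
           object$b0, object$rmax, object$delta_ms %||% 1, trials,
           history = match.arg(history), seed = seed)
}

#' @export
tidy.fmodel <- function(x, ...) {
  dn <- dim(x$phi)
  tb <- tidyr::expand_grid(
    source = c("RF", "FF", "ST"),
    t = x$t_values,
    bin = seq_len(dn[3]))
  mats <- purrr::map_dfr(seq_len(nrow(tb)), function(r) {
    k <- match(tb$source[r], c("RF", "FF", "ST"))
    it <- match(tb$t[r], x$t_values)
    v <- x$phi[k, it, tb$bin[r], ]
    tibble::as_tibble(as.list(stats::setNames(v, phi_names)))
  })
  dplyr::bind_cols(tb, mats)
}

#' @export
glance.fmodel <- function(x, ...) {
  tibble::tibble(
    n_time_points = length(x$t_values),
    n_bins = length(x$bins) - 1L,
    total_sse = sum(x$sse, na.rm = TRUE),
    total_sse_fixation_only = sum(x$sse_fix, na.rm = TRUE))
}
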