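#' Model configuration
#'
#' Collects the tunable constants of the encoding model: knot grids,
#' delay support, bin size, likelihood floor, the parameter-selection
#' screen settings and the block-ascent settings.  Defaults are the
#' standard configuration (quadratic B-splines on the four default knot
#' grids, 1 ms bins, 150 ms delay support, 100 screen resamples with a
#' 1.5 sigma retention threshold, 35/30/35 train/validation/test split).
#'
#' @param delay_knots,time_knots,postspike_knots,offset_knots knot grids
#'   (ms) for the four bases.
#' @param tau_max delay support of the stimulus kernels (ms).
#' @param t_axis time lattice of the kernels (ms from saccade onset);
#'   default covers the span of `time_knots`' interior.
#' @param delta_ms bin size in ms.
#' @param eps floor applied to `lambda * delta` inside logarithms.
#' @param screen_resamples,screen_frac,screen_threshold selection-screen
#'   settings: number of resamples, fraction of trials per resample, and
#'   the retention threshold in control-standard-deviation units.
#' @param screen_thin evaluate the screen likelihood on every
#'   `screen_thin`-th bin (1 = all bins; larger values trade screen
#'   precision for speed at desk scale).
#' @param init initialization value for all fitted parameters.
#' @param block_tol within-block stop: relative RMS parameter change.
#' @param outer_tol across-cycle stop: relative RMS change of the full
#'   parameter vector.
#' @param max_cycles,max_block_steps iteration caps: block cycles, and
#'   damped Newton (IRLS) steps within one block.
#' @param step_cap largest per-iteration coefficient change inside a
#'   block; keeps the ascent path gradual so the pooled-likelihood
#'   guard can stop early where held-out support runs out.
#' @param screen_iters Newton iterations per single-coefficient screen
#'   fit.
#' @param r0,rmax optional overrides for the mean and maximum firing
#'   rate (spk/s); estimated from the data when `NULL`.
#' @param rmax_fwhm_ms FWHM of the Gaussian used to smooth spike trains
#'   when estimating `rmax` empirically.
#' @return list of class `smodel_config`.
#' @export
smodel_config <- function(delay_knots = perisacc::delay_knots(),
                          time_knots = perisacc::time_knots(),
                          postspike_knots = perisacc::postspike_knots(),
                          offset_knots = perisacc::offset_knots(),
                          tau_max = 150L,
                          t_axis = NULL,
                          delta_ms = 1,
                          eps = 1e-12,
                          screen_resamples = 100L,
                          screen_frac = 0.65,
                          screen_threshold = 1.5,
                          screen_thin = 1L,
                          init = 1e-6,
                          block_tol = 0.01,
                          outer_tol = 1e-6,
                          max_cycles = 20L,
                          max_block_steps = 20L,
                          step_cap = 0.5,
                          screen_iters = 8L,
                          r0 = NULL, rmax = NULL,
                          rmax_fwhm_ms = 33) {
  if (is.null(t_axis)) {
    d <- 2
    lo <- ceiling(time_knots[d + 1])
    hi <- floor(time_knots[length(time_knots) - d])
    t_axis <- seq(lo, hi)
  }
  structure(list(
    delay_knots = delay_knots, time_knots = time_knots,
    postspike_knots = postspike_knots, offset_knots = offset_knots,
    tau_max = as.integer(tau_max), t_axis = as.integer(t_axis),
    delta_ms = delta_ms, eps = eps,
    screen_resamples = as.integer(screen_resamples),
    screen_frac = screen_frac, screen_threshold = screen_threshold,
    screen_thin = as.integer(screen_thin),
    init = init, block_tol = block_tol, outer_tol = outer_tol,
    max_cycles = as.integer(max_cycles),
    max_block_steps = as.integer(max_block_steps),
    step_cap = step_cap,
    screen_iters = as.integer(screen_iters),
    r0 = r0, rmax = rmax, rmax_fwhm_ms = rmax_fwhm_ms),
    class = "smodel_config")
}

build_bases <- function(config) {
  tau_axis <- seq_len(config$tau_max)
  list(
    stim = basis2d(bspline_basis(config$delay_knots, at = tau_axis),
                   bspline_basis(config$time_knots, at = config$t_axis)),
    postspike = bspline_basis(config$postspike_knots,
                              at = seq_len(ceiling(max(config$postspike_knots)))),
    offset = bspline_basis(config$offset_knots, at = config$t_axis))
}

#' Sparse-variable GLM (S-model) object
#'
#' The conditional-intensity model
#' `lambda(t) = f(sum_{x,y,tau} k[x,y](t,tau) s[x,y](t-tau) +
#' sum_tau h(tau) r(t-tau) + b(t) + b0)` with the sigmoidal nonlinearity
#' `f(u) = rmax / (1 + exp(-u))` and `b0 = f^{-1}(r0)`.  Stimulus
#' kernels live in a tensor-product quadratic B-spline basis; the
#' post-spike kernel is constrained non-positive through a squared
#' parameterization; coefficients outside the selection mask are zero.
#'
#' @param kappa array `[n_probes, n_i, n_j]` of stimulus coefficients.
#' @param eta post-spike coefficients.
#' @param beta offset coefficients.
#' @param r0 mean firing rate (spk/s), `0 < r0 < rmax`.
#' @param rmax maximum firing rate (spk/s).
#' @param config an [smodel_config()].
#' @param grid a [probe_grid()].
#' @param mask logical array like `kappa`: the selection mask.
#' @param meta optional list of fit provenance (seeds, split, history).
#' @return object of class `smodel`.
#' @export
smodel <- function(kappa, eta, beta, r0, rmax, config, grid,
                   mask = NULL, meta = list()) {
  if (rmax <= 0 || r0 <= 0 || r0 >= rmax) {
    stop("need 0 < r0 < rmax", call. = FALSE)
  }
  bases <- build_bases(config)
  kappa <- as.array(kappa)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(kappa))
  if (any(kappa[!mask] != 0)) {
    stop("kappa must be zero outside the selection mask", call. = FALSE)
  }
  m <- structure(list(
    kappa = kappa, eta = as.numeric(eta), beta = as.numeric(beta),
    b0 = stats::qlogis(r0 / rmax), r0 = r0, rmax = rmax,
    delta_ms = config$delta_ms, config = config, bases = bases,
    grid = grid, mask = mask, meta = meta), class = "smodel")
  m
}

#' @export
print.smodel <- function(x, ...) {
  cat(sprintf(
    "<smodel> %d probes, %d x %d stimulus basis (%d selected), r0 = %.2f, rmax = %.1f spk/s\n",
    dim(x$kappa)[1], dim(x$kappa)[2], dim(x$kappa)[3], sum(x$mask),
    x$r0, x$rmax))
  invisible(x)
}

#' Realized kernels of an S-model
#'
#' @param model an [smodel()].
#' @return `smodel_kernels()`: a [kernel_field()];
#'   `smodel_postspike()`/`smodel_offset()`: numeric vectors with their
#'   lattice attributes.
#' @export
smodel_kernels <- function(model) {
  realize_stimulus_kernel(model$kappa, model$bases$stim,
                          t_axis = model$config$t_axis,
                          tau_axis = seq_len(model$config$tau_max),
                          grid = model$grid)
}

#' @rdname smodel_kernels
#' @export
smodel_postspike <- function(model) {
  realize_postspike_kernel(model$eta, model$bases$postspike)
}

#' @rdname smodel_kernels
#' @export
smodel_offset <- function(model, t_axis = NULL) {
  realize_offset_kernel(model$beta, model$bases$offset, t_axis = t_axis)
}

#' Sigmoidal response nonlinearity
#'
#' `f(u) = rmax / (1 + exp(-u))`, mapping the generator signal to a
#' firing rate bounded by `rmax`.
#'
#' @param u generator signal.
#' @param rmax maximum firing rate (spk/s).
#' @export
sigmoid_rate <- function(u, rmax) rmax * stats::plogis(u)

# generator signal without the history term, per trial, on the trial-set
# time axis (kernel and offset values outside their lattices are 0).
# Delay lattice of the kernel field must be 1..n_tau ms.
generator_nohist_core <- function(kernels, offset, offset_t_axis, b0,
                                  trials) {
  stopifnot(inherits(trials, "trial_set"))
  t_axis <- trials$t_axis
  np <- dim(kernels$values)[1]
  ntau <- dim(kernels$values)[3]
  # drive is computed on the trial lattice; kernel values at times
  # outside the kernel lattice are 0
  kvals <- array(0, dim = c(np, length(t_axis), ntau))
  on_k <- match(kernels$t_axis, t_axis)
  ok <- !is.na(on_k)
  kvals[, on_k[ok], ] <- kernels$values[, ok, ]
  b <- numeric(length(t_axis))
  om <- match(offset_t_axis, t_axis)
  bok <- !is.na(om)
  b[om[bok]] <- offset[bok]
  lapply(trials$trials, function(tr) {
    probe <- tr$probe
    probe[is.na(probe)] <- 0L
    drive <- stimulus_drive_cpp(probe, as.numeric(kvals), np,
                                length(t_axis), ntau)
    drive + b + b0
  })
}

# shared CIF engine for realized-kernel models
cif_core <- function(kernels, postspike, offset, offset_t_axis, b0, rmax,
                     delta_ms, trials, history = "true", seed = NULL) {
  gen <- generator_nohist_core(kernels, offset, offset_t_axis, b0, trials)
  n_t <- length(trials$t_axis)
  out <- matrix(0, nrow = length(gen), ncol = n_t)
  if (history == "simulated") {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_along(gen)) {
      rate <- numeric(n_t)
      simulate_spikes_history_cpp(gen[[i]], postspike, rmax,
                                  delta_ms / 1000,
                                  trials$trials[[i]]$valid, rate)
      out[i, ] <- rate
    }
  } else {
    for (i in seq_along(gen)) {
      g <- gen[[i]]
      if (history == "true") {
        g <- g + history_filter_cpp(trials$trials[[i]]$spikes, postspike)
      }
      out[i, ] <- sigmoid_rate(g, rmax)
    }
  }
  out
}

#' Conditional intensity of an S-model on observed trials
#'
#' Computes `lambda(t)` per trial.  The history term uses the supplied
#' spike trains (`history = "true"`), is omitted (`"none"`), or is
#' generated sequentially by the model itself while sampling spikes
#' (`"simulated"`; see [generate_spikes()]).
#'
#' @param model an [smodel()].
#' @param trials a [trial_set()] on the same probe grid.
#' @param history one of `"true"`, `"none"`, `"simulated"`.
#' @param seed seed for `history = "simulated"`.
#' @return numeric matrix `[n_trials, n_bins]` of rates (spk/s) on the
#'   trial-set time axis.
#' @export
cif <- function(model, trials, history = c("true", "none", "simulated"),
                seed = NULL) {
  history <- match.arg(history)
  if (!identical(n_probes(model$grid), n_probes(trials$grid))) {
    stop("model and trials use different probe grids", call. = FALSE)
  }
  cif_core(smodel_kernels(model), smodel_postspike(model),
           smodel_offset(model), model$config$t_axis, model$b0,
           model$rmax, model$delta_ms, trials, history = history,
           seed = seed)
}

#' Point-process log-likelihood
#'
#' `LL = sum_t r(t) log(lambda(t) delta) - lambda(t) delta` in natural
#' log (nats), summed over valid bins.  `lambda * delta` is floored at
#' `eps` inside the logarithm.
#'
#' @param rate numeric vector or matrix of rates (spk/s).
#' @param spikes 0/1 vector or matrix matching `rate`.
#' @param delta_ms bin size (ms).
#' @param valid optional logical mask of bins to include.
#' @param eps floor for `lambda * delta` inside the log.
#' @return scalar log-likelihood in nats.
#' @export
log_likelihood <- function(rate, spikes, delta_ms = 1, valid = NULL,
                           eps = 1e-12) {
  if (any(rate < 0, na.rm = TRUE)) {
    stop("negative rate passed to log_likelihood", call. = FALSE)
  }
  ld <- rate * (delta_ms / 1000)
  term <- spikes * log(pmax(ld, eps)) - ld
  if (!is.null(valid)) term <- term[valid]
  sum(term)
}

#' Empirical rate constants
#'
#' `r0` is the total spike count divided by total valid recording time
#' (the neuron's mean firing rate across the session).  `rmax`, the
#' empirical maximum firing rate, is taken from the stimulus-aligned
#' mean responses: for each probe, the presentation-averaged response
#' trace (0-150 ms after stimulus onset, Gaussian-smoothed at FWHM
#' `fwhm_ms`) is computed across the whole session, and `rmax` is the
#' largest value reached, times a headroom factor (the sigmoid ceiling
#' must exceed every realized rate).  Averaging over presentations
#' keeps the estimate stable where the maximum of single-trial smoothed
#' trains is dominated by smoothing noise at 1 ms resolution.  Falls
#' back to the single-trial smoothed maximum when the trial set carries
#' no stimulus events.  Floored at `2 * r0` so the baseline `b0` stays
#' defined.
#'
#' @param trials a [trial_set()].
#' @param fwhm_ms smoothing FWHM in ms.
#' @param headroom multiplicative margin above the peak mean response.
#' @return list with `r0` and `rmax` in spk/s.
#' @export
empirical_rates <- function(trials, fwhm_ms = 33, headroom = 1.25) {
  total_spk <- sum(vapply(trials$trials,
                          function(tr) sum(tr$spikes[tr$valid]), numeric(1)))
  total_s <- sum(vapply(trials$trials,
                        function(tr) sum(tr$valid), numeric(1))) / 1000
  r0 <- total_spk / total_s
  events <- stimulus_events(trials)
  if (nrow(events) > 0) {
    whole <- c(min(trials$t_axis), max(trials$t_axis) + 1)
    peak <- max(vapply(seq_len(n_probes(trials$grid)), function(p) {
      tr <- response_trace(trials, p, whole, span_ms = 150,
                           fwhm_ms = fwhm_ms)
      if (all(is.na(tr))) 0 else max(tr, na.rm = TRUE)
    }, numeric(1)))
    peak <- peak * headroom
  } else {
    peak <- max(vapply(trials$trials, function(tr) {
      if (!any(tr$valid)) return(0)
      max(gaussian_smooth(tr$spikes * 1000, fwhm_ms))
    }, numeric(1)))
  }
  list(r0 = r0, rmax = max(peak, 2 * r0))
}
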