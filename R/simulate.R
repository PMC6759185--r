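#' Conditional-Poisson spike generation
#'
#' Samples a 0/1 spike train from a conditional intensity at 1 ms
#' resolution by sequential Bernoulli thinning, `p(spike in bin t) =
#' min(lambda(t) * delta, 1)`, so at most one spike falls in each bin.
#' With `history = "none"` the supplied rate is used as-is; with
#' `history = "simulated"` the rate is recomputed bin by bin with the
#' already-generated spikes feeding the post-spike kernel (sequential
#' self-history generation).
#'
#' @param rate rate vector (spk/s) for `history = "none"`.
#' @param generator generator signal without the history term, for
#'   `history = "simulated"`.
#' @param postspike post-spike kernel values at delays 1.. (ms).
#' @param rmax maximum firing rate (spk/s) of the sigmoid.
#' @param history `"none"` or `"simulated"`.
#' @param delta_ms bin size (ms).
#' @param valid logical mask; invalid bins never spike.
#' @param seed optional integer seed.
#' @return integer 0/1 spike train; for `"simulated"` the realized rate
#'   is attached as attribute `"rate"`.
#' @export
generate_spikes <- function(rate = NULL, generator = NULL, postspike = NULL,
                            rmax = NULL, history = c("none", "simulated"),
                            delta_ms = 1, valid = NULL, seed = NULL) {
  history <- match.arg(history)
  if (!is.null(seed)) {
    old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  if (history == "none") {
    if (is.null(rate)) stop("`rate` required for history = \"none\"",
                            call. = FALSE)
    if (any(rate < 0)) stop("negative rate", call. = FALSE)
    n <- length(rate)
    if (is.null(valid)) valid <- rep(TRUE, n)
    p <- pmin(rate * delta_ms / 1000, 1)
    sp <- as.integer(stats::runif(n) < p & valid)
    sp
  } else {
    if (is.null(generator) || is.null(rmax)) {
      stop("`generator` and `rmax` required for history = \"simulated\"",
           call. = FALSE)
    }
    if (is.null(postspike)) postspike <- numeric(0)
    n <- length(generator)
    if (is.null(valid)) valid <- rep(TRUE, n)
    rate_out <- numeric(n)
    sp <- simulate_spikes_history_cpp(generator, postspike, rmax,
                                      delta_ms / 1000, valid, rate_out)
    attr(sp, "rate") <- rate_out
    sp
  }
}

#' Specification of a synthetic ground-truth neuron
#'
#' Defines a neuron whose stimulus kernels are built from skew-Gaussian
#' spatial sources, each with a stimulus-time gain profile (a fixation
#' gain that transitions to a perisaccadic gain inside a saccade-locked
#' modulation window) and a response-latency band.  Defaults emulate the
#' recorded task conditions: a 9 x 9 probe grid with 7 ms flashes,
#' trials 2100-2300 ms long, a 10 dva horizontal saccade, an RF source
#' responding at short latency (50-75 ms) that is suppressed for stimuli
#' presented -30..0 ms before the saccade, and FF and ST sources that
#' respond at long latency (80-150 ms) only for stimuli presented
#' -50..0 ms before the saccade.
#'
#' @param grid a [probe_grid()].
#' @param rf_loc,ff_loc,st_loc 0-based `(row, col)` source probe
#'   locations; `ff_loc` defaults to `rf_loc` shifted by the saccade
#'   vector in probe units, `st_loc` to the probe nearest the saccade
#'   target.
#' @param baseline_rate,rmax baseline and maximum firing rate (spk/s).
#' @param sources named list (`RF`, `FF`, `ST`) of per-source settings:
#'   `amp` (kernel amplitude), `sigma` (spreads, probe units), `rho`,
#'   `gamma` (skewness), `fix_gain`, `peri_gain`, `peri_window` (ms,
#'   stimulus time relative to saccade), `latency` (ms band).  Set `amp
#'   = 0` to remove a source.
#' @param refractory list with `strength` (generator units) and
#'   `tau_ms` (decay) of the ground-truth post-spike kernel.
#' @param probe_duration_ms flash duration.
#' @param trial_length_range,saccade_time_range ms ranges (uniform).
#' @param tau_max delay support (ms).
#' @return list of class `synthetic_neuron_spec`.
#' @export
synthetic_neuron_spec <- function(
    grid = probe_grid(9, 9, origin = c(-21, -9), dx = 3.5, dy = 2.25,
                      fp = c(0, 0), st = c(-10, 0)),
    rf_loc = c(2, 6), ff_loc = NULL, st_loc = NULL,
    baseline_rate = 20, rmax = 120,
    sources = list(
      RF = list(amp = 12, sigma = c(0.8, 0.8), rho = 0, gamma = c(0, 0),
                fix_gain = 1, peri_gain = 0.15, peri_window = c(-30, 0),
                latency = c(50, 75)),
      FF = list(amp = 10, sigma = c(0.8, 0.8), rho = 0, gamma = c(0, 0),
                fix_gain = 0, peri_gain = 1, peri_window = c(-50, 0),
                latency = c(80, 150)),
      ST = list(amp = 8, sigma = c(0.8, 0.8), rho = 0, gamma = c(0, 0),
                fix_gain = 0, peri_gain = 1, peri_window = c(-50, 0),
                latency = c(80, 150))),
    refractory = list(strength = 8, tau_ms = 3),
    probe_duration_ms = 7,
    trial_length_range = c(2100, 2300),
    saccade_time_range = c(800, 1000),
    tau_max = 150L) {
  sv <- saccade_vector_probes(grid)
  if (is.null(ff_loc)) ff_loc <- rf_loc + c(sv["drow"], sv["dcol"])
  if (is.null(st_loc)) st_loc <- nearest_probe(grid, grid$st)
  for (loc in list(rf_loc, ff_loc, st_loc)) {
    if (loc[1] < 0 || loc[1] >= grid$n_rows ||
        loc[2] < 0 || loc[2] >= grid$n_cols) {
      stop("source location off the probe grid", call. = FALSE)
    }
  }
  for (s in sources) {
    if (s$latency[2] > tau_max) {
      stop("latency band beyond the delay support", call. = FALSE)
    }
  }
  if (baseline_rate <= 0 || rmax <= baseline_rate) {
    stop("need 0 < baseline_rate < rmax", call. = FALSE)
  }
  structure(list(grid = grid, rf_loc = rf_loc, ff_loc = ff_loc,
                 st_loc = st_loc, baseline_rate = baseline_rate,
                 rmax = rmax, sources = sources, refractory = refractory,
                 probe_duration_ms = probe_duration_ms,
                 trial_length_range = trial_length_range,
                 saccade_time_range = saccade_time_range,
                 tau_max = as.integer(tau_max)),
            class = "synthetic_neuron_spec")
}

#' Saccade vector in probe-grid units
#'
#' Rounded half-away-from-zero component-wise translation, in grid
#' steps, corresponding to the fixation-point to saccade-target vector.
#'
#' @param grid a [probe_grid()].
#' @return named vector `c(drow, dcol)`.
#' @export
saccade_vector_probes <- function(grid) {
  sv <- grid$st - grid$fp
  c(drow = round_half_away(sv[2] / grid$dy),
    dcol = round_half_away(sv[1] / grid$dx))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Probe nearest to a dva coordinate
#' @param grid a [probe_grid()].
#' @param xy dva coordinates.
#' @return 0-based `c(row, col)`.
#' @export
nearest_probe <- function(grid, xy) {
  col <- min(max(round_half_away((xy[1] - grid$origin[1]) / grid$dx), 0),
             grid$n_cols - 1)
  row <- min(max(round_half_away((xy[2] - grid$origin[2]) / grid$dy), 0),
             grid$n_rows - 1)
  c(row = row, col = col)
}

# ground-truth kernel field of a synthetic neuron:
# k[p, t, tau] = sum_sr G_sr(p) * gain_sr(t - tau) * lat_sr(tau)
truth_kernels <- function(spec, t_axis) {
  grid <- spec$grid
  tau_axis <- seq_len(spec$tau_max)
  coords <- probe_coords(grid)
  locs <- list(RF = spec$rf_loc, FF = spec$ff_loc, ST = spec$st_loc)
  n_p <- n_probes(grid)
  vals <- array(0, dim = c(n_p, length(t_axis), length(tau_axis)))
  u_min <- min(t_axis) - max(tau_axis)
  u_axis <- seq(u_min, max(t_axis))
  for (nm in names(spec$sources)) {
    s <- spec$sources[[nm]]
    if (s$amp == 0) next
    loc <- locs[[nm]]
    spatial <- skew_gaussian(coords$col, coords$row,
                             phi = c(a = s$amp, mux = loc[2], muy = loc[1],
                                     sx = s$sigma[1], sy = s$sigma[2],
                                     rho = s$rho, gx = s$gamma[1],
                                     gy = s$gamma[2]))
    gain <- s$fix_gain + (s$peri_gain - s$fix_gain) *
      gaussian_smooth(as.numeric(u_axis >= s$peri_window[1] &
                                   u_axis < s$peri_window[2]), fwhm_ms = 10)
    mid <- mean(s$latency)
    sdv <- diff(s$latency) / 4
    lat <- exp(-0.5 * ((tau_axis - mid) / sdv)^2)
    gm <- matrix(0, nrow = length(t_axis), ncol = length(tau_axis))
    for (k in seq_along(tau_axis)) {
      gm[, k] <- gain[match(t_axis - tau_axis[k], u_axis)] * lat[k]
    }
    for (p in seq_len(n_p)) {
      vals[p, , ] <- vals[p, , ] + spatial[p] * gm
    }
  }
  kernel_field(vals, t_axis, tau_axis, grid)
}

#' Simulate a synthetic ground-truth neuron
#'
#' Builds the ground-truth kernels from the skew-Gaussian sources,
#' rasterizes pseudorandom balanced probe conditions (cycled to fill
#' each trial), and samples conditional-Poisson spikes with sequential
#' self-history refractory feedback.  The generating parameters are
#' returned alongside the data so recovery can be tested.
#'
#' @param spec a [synthetic_neuron_spec()].
#' @param n_trials number of trials.
#' @param seed integer seed; dataset is bit-reproducible given
#'   `spec` + `seed`.
#' @return list of class `simulated_dataset` with elements `trials` (a
#'   [trial_set()]) and `truth` (kernel field, post-spike kernel, rate
#'   constants, spec, seed).
#' @export
make_synthetic_neuron <- function(spec, n_trials = 300, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_neuron_spec"))
  grid <- spec$grid
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- n_probes(grid)
  lens <- round(stats::runif(n_trials, spec$trial_length_range[1],
                             spec$trial_length_range[2]))
  saccs <- round(stats::runif(n_trials, spec$saccade_time_range[1],
                              spec$saccade_time_range[2]))
  # each trial shows a stream of *distinct* balanced conditions back to
  # back; reusing one short sequence would alias delays beyond the
  # sequence period and make the kernels unidentifiable
  per_trial <- ceiling(max(lens) / (n * spec$probe_duration_ms))
  conds <- generate_conditions(grid, n_conditions = n_trials * per_trial,
                               seed = seed)
  cond_orders <- split(conds$probe, conds$condition)
  t_min <- -max(saccs)
  t_max <- max(lens - saccs) - 1L
  t_axis <- seq(t_min, t_max)
  n_t <- length(t_axis)
  kf <- truth_kernels(spec, t_axis)
  h_tau <- seq_len(50L)
  h <- -spec$refractory$strength *
    exp(-(h_tau - 1) / spec$refractory$tau_ms)
  b0 <- stats::qlogis(spec$baseline_rate / spec$rmax)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    ord <- unlist(cond_orders[(i - 1L) * per_trial + seq_len(per_trial)],
                  use.names = FALSE)
    pseq <- rasterize_condition(ord, lens[i], saccs[i],
                                probe_duration_ms = spec$probe_duration_ms,
                                cycle = TRUE)
    probe <- rep(NA_integer_, n_t)
    pos <- match(attr(pseq, "t_axis"), t_axis)
    probe[pos] <- as.integer(pseq)
    valid <- rep(FALSE, n_t)
    valid[pos] <- TRUE
    gen <- stimulus_drive_cpp(ifelse(is.na(probe), 0L, probe),
                              as.numeric(kf$values), n, n_t,
                              dim(kf$values)[3]) + b0
    rate <- numeric(n_t)
    spikes <- simulate_spikes_history_cpp(gen, h, spec$rmax, 1 / 1000,
                                          valid, rate)
    trials[[i]] <- list(trial_id = i, probe = probe,
                        spikes = as.integer(spikes), valid = valid,
                        saccade_offset = NA_real_)
  }
  structure(list(
    trials = trial_set(grid, trials, t_axis),
    truth = list(kernels = kf, postspike = h, b0 = b0,
                 r0 = spec$baseline_rate, rmax = spec$rmax,
                 spec = spec, seed = as.integer(seed))),
    class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset>\n")
  print(x$trials)
  invisible(x)
}

#' Shuffle the stimulus-to-rate pairing
#'
#' Returns a seeded permutation of `1..n` that is never the identity
#' (for n >= 2), used to break the correspondence between stimulus
#' sequences and rate sequences while leaving the marginal rate
#' distribution untouched.
#'
#' @param n number of sequences (>= 2).
#' @param seed integer seed.
#' @return integer permutation of `1..n`.
#' @export
shuffle_pairing <- function(n, seed = 1L) {
  if (n < 2) stop("need at least two sequences to shuffle", call. = FALSE)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  repeat {
    p <- sample.int(n)
    if (!all(p == seq_len(n))) return(p)
  }
}
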