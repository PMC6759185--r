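# Small reusable fixtures, all generated in code.

# 4 x 3 probe grid used by the scaled synthetic neuron: horizontal
# saccade two probe columns long, receptive field top-right so the
# future field (top-left) and saccade-target probe (two rows below it)
# stay separated.
scaled_grid <- function() {
  probe_grid(4, 3, origin = c(-2, -3), dx = 1, dy = 2,
             fp = c(0, 0), st = c(-2, 0))
}

# scaled synthetic-neuron specification: the study's probe timing and
# windows, on the small grid with a shortened time axis.  Source
# spreads shrink with the grid (0.8 * sqrt(12 / 81) ~ 0.3 probe
# spacings) so each source covers the same *fraction* of the grid as at
# full scale; without that, the stimulus stream drives the neuron into
# saturation and the drive statistics stop resembling the task.
scaled_sources <- function(sigma = 0.3) {
  list(
    RF = list(amp = 12, sigma = c(sigma, sigma), rho = 0, gamma = c(0, 0),
              fix_gain = 1, peri_gain = 0.15, peri_window = c(-30, 0),
              latency = c(50, 75)),
    FF = list(amp = 10, sigma = c(sigma, sigma), rho = 0, gamma = c(0, 0),
              fix_gain = 0, peri_gain = 1, peri_window = c(-50, 0),
              latency = c(80, 150)),
    ST = list(amp = 8, sigma = c(sigma, sigma), rho = 0, gamma = c(0, 0),
              fix_gain = 0, peri_gain = 1, peri_window = c(-50, 0),
              latency = c(80, 150)))
}

scaled_spec <- function(sources = scaled_sources(), ...) {
  synthetic_neuron_spec(
    grid = scaled_grid(), rf_loc = c(0, 2),
    sources = sources,
    trial_length_range = c(800, 840),
    saccade_time_range = c(555, 570), ...)
}

# scaled S-model configuration: coarser knot grids whose span the
# scaled trials fully support (so no basis function is data-starved),
# and a smaller screen
scaled_config <- function(max_cycles = 15, screen_resamples = 20,
                          screen_thin = 1, screen_iters = 6, ...) {
  smodel_config(
    delay_knots = seq(-13, 169, 14),
    time_knots = seq(-560, 280, 42),
    offset_knots = seq(-560, 280, 105),
    postspike_knots = c(1, 2, 3, 4, 6, 8, 15, 29, 57, 106, 176),
    screen_resamples = screen_resamples, screen_thin = screen_thin,
    screen_iters = screen_iters, max_cycles = max_cycles, ...)
}

# a tiny deterministic trial set: hand-placed flashes and spikes
tiny_trials <- function(n_trials = 4, n_t = 200, saccade = 100,
                        grid = probe_grid(2, 2, origin = c(0, 0),
                                          dx = 1, dy = 1)) {
  t_axis <- seq_len(n_t) - 1L - saccade
  trs <- lapply(seq_len(n_trials), function(i) {
    probe <- rep(NA_integer_, n_t)
    o <- 1L
    k <- i
    while (o + 6 <= n_t) {
      probe[o + 0:6] <- ((k - 1L) %% 4L) + 1L
      k <- k + 1L
      o <- o + 7L
    }
    spikes <- integer(n_t)
    spikes[seq(5 + i, n_t, by = 17)] <- 1L
    list(trial_id = i, probe = probe, spikes = spikes,
         valid = rep(TRUE, n_t), saccade_offset = NA_real_)
  })
  trial_set(grid, trs, t_axis)
}

# hand-built fmodel on the scaled grid: constant source parameters at
# every (t, bin), for aggregation / knockout / population tests
minimal_fmodel <- function(a = c(RF = 1, FF = 0.5, ST = 0.25),
                           t_values = seq(-450, 150, 50),
                           bins = c(1, 50, 100, 151),
                           grid = scaled_grid()) {
  locs <- list(RF = c(0, 2), FF = c(0, 0), ST = c(2, 0))
  n_tv <- length(t_values)
  n_b <- length(bins) - 1L
  phi <- array(NA_real_, dim = c(3, n_tv, n_b, 8),
               dimnames = list(c("RF", "FF", "ST"), NULL, NULL,
                               c("a", "mux", "muy", "sx", "sy", "rho",
                                 "gx", "gy")))
  for (k in 1:3) {
    loc <- locs[[k]]
    for (it in seq_len(n_tv)) for (b in seq_len(n_b)) {
      phi[k, it, b, ] <- c(a[k], loc[2], loc[1], 1, 1, 0, 0, 0)
    }
  }
  tau_axis <- 1:150
  fix <- matrix(0, n_probes(grid), length(tau_axis))
  attr(fix, "tau_axis") <- tau_axis
  structure(list(phi = phi, c_arr = matrix(0, n_tv, n_b),
                 fixation = fix, bins = bins, t_values = t_values,
                 source_locs = locs, grid = grid, tau_axis = tau_axis,
                 sse = matrix(0, n_tv, n_b),
                 sse_fix = matrix(0, n_tv, n_b), seed = 1L),
            class = "fmodel")
}
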