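#' Analysis windows for the perisaccadic effects
#'
#' Saccadic suppression is read from the early response window
#' (50-75 ms after stimulus onset) for RF stimuli presented -30..0 ms
#' before the saccade; FF- and ST-remapping from the late response
#' window (80-150 ms) for stimuli presented -50..0 ms before the
#' saccade; the fixation reference takes stimuli presented -500..-100
#' ms before the saccade.  All windows are half-open `[a, b)` ms.
#'
#' @return nested list of windows (ms).
#' @export
effect_windows <- function() {
  list(
    suppression = list(stim = c(-30, 0), resp = c(50, 75)),
    FF = list(stim = c(-50, 0), resp = c(80, 150)),
    ST = list(stim = c(-50, 0), resp = c(80, 150)),
    fixation = c(-500, -100))
}

# spike counts (or mean predicted rates) in a response window following
# each presentation of `probe` whose onset falls in `stim_window`
presentation_samples <- function(trials, probe, stim_window, resp_window,
                                 rates = NULL, events = NULL) {
  if (is.null(events)) events <- stimulus_events(trials)
  ev <- events[events$probe == probe &
                 events$onset >= stim_window[1] &
                 events$onset < stim_window[2], , drop = FALSE]
  t_axis <- trials$t_axis
  n_t <- length(t_axis)
  out <- numeric(nrow(ev))
  keep <- logical(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    i0 <- match(ev$onset[k] + resp_window[1], t_axis)
    i1 <- match(ev$onset[k] + resp_window[2] - 1, t_axis)
    if (is.na(i0) || is.na(i1)) next
    tr <- trials$trials[[ev$trial_id[k]]]
    if (!all(tr$valid[i0:i1])) next
    keep[k] <- TRUE
    out[k] <- if (is.null(rates)) {
      sum(tr$spikes[i0:i1])
    } else {
      mean(rates[ev$trial_id[k], i0:i1])
    }
  }
  tibble::tibble(trial_id = ev$trial_id[keep], onset = ev$onset[keep],
                 value = out[keep])
}

#' Estimate the RF, FF and ST probe locations
#'
#' RF is the probe generating the maximum firing rate in the early
#' response window (50-75 ms after stimulus onset) during the fixation
#' period; FF is the RF probe shifted by the rounded saccade vector in
#' probe units; ST is the probe, out of the 4 x 4 block centered on the
#' saccade target, with the largest perisaccadic-minus-fixation late
#' response, excluding the FF probe and its 8-neighborhood.  Argmax
#' ties break deterministically toward the lowest (row, col).
#'
#' @param trials a [trial_set()].
#' @param windows analysis windows, default [effect_windows()].
#' @return list with 0-based `(row, col)` entries `RF`, `FF`, `ST`.
#' @export
estimate_locations <- function(trials, windows = effect_windows()) {
  grid <- trials$grid
  events <- stimulus_events(trials)
  fixw <- windows$fixation
  early <- windows$suppression$resp
  late <- windows$FF$resp
  periw <- windows$FF$stim
  n_p <- n_probes(grid)
  fix_early <- numeric(n_p)
  for (p in seq_len(n_p)) {
    s <- presentation_samples(trials, p, fixw, early, events = events)
    fix_early[p] <- if (nrow(s)) mean(s$value) else -Inf
  }
  rf_p <- which.max(fix_early)         # row-major order = lowest (row, col)
  rf <- probe_rowcol(grid, rf_p)[1, ]
  sv <- saccade_vector_probes(grid)
  ff <- c(rf[["row"]] + sv[["drow"]], rf[["col"]] + sv[["dcol"]])
  if (ff[1] < 0 || ff[1] >= grid$n_rows || ff[2] < 0 ||
      ff[2] >= grid$n_cols) {
    stop("future field falls off the probe grid; enlarge the grid or ",
         "reposition it to cover the post-saccadic receptive field",
         call. = FALSE)
  }
  st0 <- nearest_probe(grid, grid$st)
  rows <- max(0, st0[["row"]] - 1L):min(grid$n_rows - 1L, st0[["row"]] + 2L)
  cols <- max(0, st0[["col"]] - 1L):min(grid$n_cols - 1L, st0[["col"]] + 2L)
  cand <- expand.grid(row = rows, col = cols)
  near_ff <- abs(cand$row - ff[1]) <= 1 & abs(cand$col - ff[2]) <= 1
  cand <- cand[!near_ff, , drop = FALSE]
  if (nrow(cand) == 0) stop("no ST candidates left after excluding the FF ",
                            "neighborhood", call. = FALSE)
  cand <- cand[order(cand$row, cand$col), , drop = FALSE]
  score <- vapply(seq_len(nrow(cand)), function(k) {
    p <- probe_id(grid, cand$row[k], cand$col[k])
    peri <- presentation_samples(trials, p, periw, late, events = events)
    fix <- presentation_samples(trials, p, fixw, late, events = events)
    if (nrow(peri) == 0 || nrow(fix) == 0) return(-Inf)
    mean(peri$value) - mean(fix$value)
  }, numeric(1))
  st <- c(cand$row[which.max(score)], cand$col[which.max(score)])
  list(RF = unname(c(rf[["row"]], rf[["col"]])), FF = unname(ff),
       ST = unname(st))
}

#' Classify a perisaccadic effect
#'
#' Tests whether the response to stimuli at the given probe differs
#' between the perisaccadic and fixation periods: a significant
#' *decrease* of the early-window response for suppression, a
#' significant *increase* of the late-window response for FF- or
#' ST-remapping, at `alpha = 0.05` with no multiplicity adjustment.
#' With `mode = "counts"` the samples are per-presentation spike
#' counts, compared with a one-sided Wilcoxon signed-rank test when the
#' two arms pair up (equal sizes, matched by presentation order) and
#' with a one-sided rank-sum test otherwise; with `mode = "rates"` the
#' samples are per-presentation mean predicted rates (0-150 ms after
#' stimulus onset averaged over the response window) compared with the
#' one-sided rank-sum test.
#'
#' @param trials a [trial_set()].
#' @param effect one of `"suppression"`, `"FF"`, `"ST"`.
#' @param probe linear probe id of the effect's source location.
#' @param mode `"counts"` (recorded spikes) or `"rates"`
#'   (model-predicted rates, supplied via `rates`).
#' @param rates matrix `[n_trials, n_bins]` of predicted rates when
#'   `mode = "rates"`.
#' @param windows analysis windows, default [effect_windows()].
#' @param alpha significance threshold.
#' @return one-row tibble: effect, probe, sample sizes, peri and
#'   fixation means, test used, p value, significance.
#' @export
classify_effect <- function(trials, effect = c("suppression", "FF", "ST"),
                            probe, mode = c("counts", "rates"),
                            rates = NULL, windows = effect_windows(),
                            alpha = 0.05) {
  effect <- match.arg(effect)
  mode <- match.arg(mode)
  if (mode == "rates" && is.null(rates)) {
    stop("`rates` required for mode = \"rates\"", call. = FALSE)
  }
  w <- windows[[effect]]
  rr <- if (mode == "rates") rates else NULL
  peri <- presentation_samples(trials, probe, w$stim, w$resp, rates = rr)
  fix <- presentation_samples(trials, probe, windows$fixation, w$resp,
                              rates = rr)
  alt <- if (effect == "suppression") "less" else "greater"
  if (nrow(peri) < 2 || nrow(fix) < 2) {
    warning("too few presentations to classify; returning not significant")
    return(tibble::tibble(effect = effect, probe = probe,
                          n_peri = nrow(peri), n_fix = nrow(fix),
                          peri_mean = mean(peri$value),
                          fix_mean = mean(fix$value), test = NA_character_,
                          p_value = NA_real_, significant = FALSE))
  }
  paired <- mode == "counts" && nrow(peri) == nrow(fix)
  test <- if (mode == "counts" && paired) {
    "wilcoxon signed-rank (paired)"
  } else "wilcoxon rank-sum"
  wt <- suppressWarnings(
    stats::wilcox.test(peri$value, fix$value, alternative = alt,
                       paired = paired, exact = FALSE))
  tibble::tibble(effect = effect, probe = probe,
                 n_peri = nrow(peri), n_fix = nrow(fix),
                 peri_mean = mean(peri$value), fix_mean = mean(fix$value),
                 test = test, p_value = wt$p.value,
                 significant = is.finite(wt$p.value) && wt$p.value < alpha)
}

#' Stimulus-aligned response trace
#'
#' Average of the stimulus-aligned spike trains 0..`span_ms` after
#' stimulus onset for presentations of `probe` in `stim_window`,
#' smoothed with a Gaussian (display convention: FWHM 13 ms;
#' instantaneous-rate estimation: FWHM 33 ms).
#'
#' @param trials a [trial_set()].
#' @param probe linear probe id.
#' @param stim_window `(a, b)` ms presentation window.
#' @param span_ms trace length after stimulus onset.
#' @param fwhm_ms smoothing FWHM (ms).
#' @return numeric vector of rates (spk/s) at 0..`span_ms - 1` ms after
#'   stimulus onset.
#' @export
response_trace <- function(trials, probe, stim_window, span_ms = 150,
                           fwhm_ms = 13) {
  events <- stimulus_events(trials)
  ev <- events[events$probe == probe & events$onset >= stim_window[1] &
                 events$onset < stim_window[2], , drop = FALSE]
  t_axis <- trials$t_axis
  acc <- numeric(span_ms)
  n <- 0L
  for (k in seq_len(nrow(ev))) {
    i0 <- match(ev$onset[k], t_axis)
    idx <- i0 + seq_len(span_ms) - 1L
    if (is.na(i0) || max(idx) > length(t_axis)) next
    tr <- trials$trials[[ev$trial_id[k]]]
    if (!all(tr$valid[idx])) next
    acc <- acc + tr$spikes[idx]
    n <- n + 1L
  }
  if (n == 0) return(rep(NA_real_, span_ms))
  gaussian_smooth(acc / n * 1000, fwhm_ms)
}

#' Grand-mean normalization of perisaccadic and fixation responses
#'
#' Divides both responses by the grand mean of the firing rates,
#' defined as the mean of the means of the perisaccadic and fixation
#' responses (0-150 ms after stimulus onset, across both conditions).
#'
#' @param peri,fix numeric response traces (spk/s).
#' @return list with normalized `peri`, `fix`, and the `grand_mean`.
#' @export
normalize_responses <- function(peri, fix) {
  gm <- mean(c(mean(peri, na.rm = TRUE), mean(fix, na.rm = TRUE)))
  if (!is.finite(gm) || gm == 0) {
    stop("grand mean of the responses is zero", call. = FALSE)
  }
  list(peri = peri / gm, fix = fix / gm, grand_mean = gm)
}

#' Smoothed single-trial rate estimates
#'
#' Spike trains converted to instantaneous rates by Gaussian smoothing
#' (FWHM 33 ms by default).
#'
#' @param trials a [trial_set()].
#' @param fwhm_ms smoothing FWHM (ms).
#' @return matrix `[n_trials, n_bins]` in spk/s.
#' @export
smoothed_rates <- function(trials, fwhm_ms = 33) {
  t(vapply(trials$trials,
           function(tr) gaussian_smooth(tr$spikes * 1000, fwhm_ms),
           numeric(length(trials$t_axis))))
}

#' Per-neuron prevalence mask of a perisaccadic effect
#'
#' For each (time-from-saccade `t`, latency `tau`) cell, compares the
#' rates observed at latency `tau` after presentations of the source
#' probe at time `t` against the fixation-period rates at the same
#' latency, with a one-sided rank-sum test: the mask is 1 where the
#' perisaccadic rate is significantly lower (suppression) or higher
#' (FF/ST remapping) than the fixation reference, 0 otherwise.
#'
#' @param rates matrix `[n_trials, n_bins]`: smoothed empirical rates
#'   ([smoothed_rates()]) or model-predicted rates.
#' @param trials the [trial_set()] the rates align with.
#' @param probe source probe id.
#' @param effect `"suppression"`, `"FF"`, or `"ST"`.
#' @param t_values,tau_values cell lattice (ms); onsets are assigned to
#'   the nearest `t_values` cell within half the lattice spacing.
#' @param fixation_window fixation stimulus window (ms).
#' @param alpha significance threshold.
#' @param min_n cells with fewer perisaccadic samples are set to 0 and
#'   flagged uncovered.
#' @return list with binary `mask` `[t, tau]` and logical `coverage`.
#' @export
prevalence_mask <- function(rates, trials, probe,
                            effect = c("suppression", "FF", "ST"),
                            t_values, tau_values,
                            fixation_window = c(-500, -100),
                            alpha = 0.05, min_n = 2L) {
  effect <- match.arg(effect)
  alt <- if (effect == "suppression") "less" else "greater"
  events <- stimulus_events(trials)
  ev <- events[events$probe == probe, , drop = FALSE]
  t_axis <- trials$t_axis
  half <- if (length(t_values) > 1) min(diff(sort(t_values))) / 2 else Inf
  mask <- matrix(0L, length(t_values), length(tau_values),
                 dimnames = list(t_values, tau_values))
  coverage <- matrix(FALSE, length(t_values), length(tau_values))
  rate_at <- function(rows, tau) {
    idx <- match(ev$onset[rows] + tau, t_axis)
    ok <- !is.na(idx)
    rates[cbind(ev$trial_id[rows][ok], idx[ok])]
  }
  rows_fix <- which(ev$onset >= fixation_window[1] &
                      ev$onset < fixation_window[2])
  for (j in seq_along(tau_values)) {
    tau <- tau_values[j]
    r_fix <- rate_at(rows_fix, tau)
    for (i in seq_along(t_values)) {
      r_peri <- rate_at(which(abs(ev$onset - t_values[i]) <= half), tau)
      if (length(r_peri) < min_n || length(r_fix) < min_n) next
      coverage[i, j] <- TRUE
      p <- suppressWarnings(
        stats::wilcox.test(r_peri, r_fix, alternative = alt,
                           exact = FALSE)$p.value)
      if (is.finite(p) && p < alpha) mask[i, j] <- 1L
    }
  }
  list(mask = mask, coverage = coverage)
}

#' Population prevalence map
#'
#' Percentage of neurons whose prevalence mask is 1 at each cell.
#'
#' @param masks list of binary matrices of common shape (one per
#'   neuron, from [prevalence_mask()]).
#' @return numeric matrix in percent (0-100).
#' @export
prevalence_map <- function(masks) {
  if (length(masks) == 0) stop("no masks supplied", call. = FALSE)
  Reduce(`+`, masks) / length(masks) * 100
}

#' Pearson similarity between two prevalence maps
#'
#' @param a,b numeric matrices of common shape.
#' @return Pearson product-moment correlation of the vectorized maps.
#' @export
map_correlation <- function(a, b) {
  stats::cor(as.vector(a), as.vector(b), use = "complete.obs")
}
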