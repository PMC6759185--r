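#' Area under the ROC curve between two rate samples
#'
#' Computed through the rank-sum (Mann-Whitney) identity: the
#' probability that a random draw from `x` exceeds one from `y`, with
#' ties counted half.  Equals pair counting
#' `(concordant + ties / 2) / (n1 * n2)`.
#'
#' @param x,y numeric samples (stimulus-conditioned and reference rate
#'   distributions).
#' @return AUC in `[0, 1]`, `NA` if either sample is empty.
#' @export
roc_auc <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(c(x, y))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Spatiotemporal detectability map from rate and stimulus sequences
#'
#' For each probed cell `(probe, t, tau)`, collects the predicted rates
#' at time `t` of the sequences in which that probe was on at `t - tau`
#' and the rates of the same cell after pairing rates with shuffled
#' stimulus sequences, and reports the ROC area between the two
#' distributions: the detectability of a stimulus at that probe,
#' `tau` ms after it appeared.  Significance of each cell is assessed
#' against `n_null` ROC values between two distinct shuffled
#' distributions: a t comparison of the observed value with the null
#' group (pooled variance from the nulls), at threshold `alpha`.
#'
#' @param rates matrix `[n_sequences, n_bins]` of predicted rates.
#' @param stim integer matrix `[n_sequences, n_bins]` of the probe on
#'   per bin (`NA` = none).
#' @param t_axis time axis of the bins (ms from saccade onset).
#' @param probes linear probe ids to map.
#' @param t_values,tau_values cell lattice (ms).
#' @param n_null number of shuffle-vs-shuffle ROC draws.
#' @param alpha significance threshold (the single-neuron convention is
#'   1e-9; population synthetic neurons use 1e-7).
#' @param min_n cells with fewer stimulus-conditioned samples in either
#'   arm are left undefined (`NA`).
#' @param seed integer seed for the shuffles.
#' @return object of class `detectability_map`: arrays `roc`, `p`,
#'   `significant` indexed `[probe, t, tau]` plus the axes.
#' @export
detectability_map <- function(rates, stim, t_axis, probes, t_values,
                              tau_values, n_null = 100, alpha = 1e-9,
                              min_n = 4L, seed = 1L) {
  stopifnot(identical(dim(rates), dim(stim)))
  n_seq <- nrow(rates)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  perm_obs <- shuffle_pairing(n_seq, seed = seed)
  perms <- lapply(seq_len(2 * n_null), function(k) sample.int(n_seq))
  dims <- c(length(probes), length(t_values), length(tau_values))
  roc <- array(NA_real_, dims,
               dimnames = list(probes, t_values, tau_values))
  pval <- array(NA_real_, dims)
  for (ip in seq_along(probes)) {
    p <- probes[ip]
    for (jt in seq_along(tau_values)) {
      tau <- tau_values[jt]
      for (it in seq_along(t_values)) {
        t <- t_values[it]
        ci <- match(t, t_axis); si <- match(t - tau, t_axis)
        if (is.na(ci) || is.na(si)) next
        on <- !is.na(stim[, si]) & stim[, si] == p
        obs <- rates[on, ci]
        shuf <- rates[on[perm_obs], ci]
        if (length(obs) < min_n || length(shuf) < min_n) next
        r_obs <- roc_auc(obs, shuf)
        if (is.na(r_obs)) next
        nulls <- vapply(seq_len(n_null), function(k) {
          a <- rates[on[perms[[2 * k - 1]]], ci]
          b <- rates[on[perms[[2 * k]]], ci]
          roc_auc(a, b)
        }, numeric(1))
        nulls <- nulls[is.finite(nulls)]
        roc[ip, it, jt] <- r_obs
        if (length(nulls) >= 3 && stats::sd(nulls) > 0) {
          # two-sample t comparison of the single observed value
          # against the null group (pooled variance from the nulls)
          z <- (mean(nulls) - r_obs) /
            (stats::sd(nulls) * sqrt(1 + 1 / length(nulls)))
          pval[ip, it, jt] <- stats::pt(z, df = length(nulls) - 1)
        }
      }
    }
  }
  structure(list(roc = roc, p = pval,
                 significant = !is.na(pval) & pval < alpha,
                 probes = probes, t_values = t_values,
                 tau_values = tau_values, n_sequences = n_seq,
                 n_null = n_null, alpha = alpha),
            class = "detectability_map")
}

#' @export
print.detectability_map <- function(x, ...) {
  cat(sprintf(
    "<detectability_map> %d probes x %d times x %d latencies (n = %d sequences, %d nulls)\n",
    length(x$probes), length(x$t_values), length(x$tau_values),
    x$n_sequences, x$n_null))
  invisible(x)
}

#' @export
as_tibble.detectability_map <- function(x, ...) {
  d <- dim(x$roc)
  tibble::tibble(
    probe = rep(x$probes, times = d[2] * d[3]),
    t = rep(rep(x$t_values, each = d[1]), times = d[3]),
    tau = rep(x$tau_values, each = d[1] * d[2]),
    roc = as.vector(x$roc),
    p = as.vector(x$p),
    significant = as.vector(x$significant))
}

#' ROC detectability map of a fitted model
#'
#' Presents `n_sequences` pseudorandom balanced stimulus sequences
#' (same spatial frequency and timing as the experiment) to the model,
#' generates the predicted rates with simulated spike history, and
#' computes [detectability_map()] over the requested cells.
#'
#' @param model a fitted [smodel()] or `fmodel` with generator
#'   components.
#' @param probes,t_values,tau_values cells to map (defaults: all
#'   probes, the model time lattice, the delay lattice; subsample for
#'   speed).
#' @param n_sequences number of stimulus sequences (standard 1000).
#' @param trial_length_ms,saccade_time_ms,probe_duration_ms sequence
#'   timing.
#' @param history spike-history mode for the predicted rates.
#' @param n_null,alpha,seed see [detectability_map()].
#' @return a `detectability_map`.
#' @export
roc_map <- function(model, probes = NULL, t_values = NULL,
                    tau_values = NULL, n_sequences = 1000,
                    trial_length_ms = 2200, saccade_time_ms = 900,
                    probe_duration_ms = 7,
                    history = c("simulated", "none"),
                    n_null = 100, alpha = 1e-9, seed = 1L) {
  history <- match.arg(history)
  grid <- model$grid
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- n_probes(grid)
  per_trial <- ceiling(trial_length_ms / (n * probe_duration_ms))
  conds <- generate_conditions(grid, n_sequences * per_trial, seed = seed)
  cond_orders <- split(conds$probe, conds$condition)
  t_axis <- seq_len(trial_length_ms) - 1L - as.integer(saccade_time_ms)
  trials <- lapply(seq_len(n_sequences), function(i) {
    ord <- unlist(cond_orders[(i - 1L) * per_trial + seq_len(per_trial)],
                  use.names = FALSE)
    pseq <- rasterize_condition(ord, trial_length_ms, saccade_time_ms,
                                probe_duration_ms, cycle = TRUE)
    list(trial_id = i, probe = as.integer(pseq),
         spikes = integer(trial_length_ms),
         valid = rep(TRUE, trial_length_ms), saccade_offset = NA_real_)
  })
  ts <- trial_set(grid, trials, t_axis)
  rates <- stats::predict(model, ts, history = history,
                          seed = seed + 1L)
  stim <- t(vapply(ts$trials, `[[`, integer(length(t_axis)), "probe"))
  if (is.null(probes)) probes <- seq_len(n)
  if (is.null(t_values)) t_values <- t_axis
  if (is.null(tau_values)) {
    tau_values <- seq_len(dim(smodel_try_kernels(model))[3])
  }
  detectability_map(rates, stim, t_axis, probes, t_values, tau_values,
                    n_null = n_null, alpha = alpha, seed = seed + 2L)
}

smodel_try_kernels <- function(model) {
  if (inherits(model, "smodel")) return(dim(smodel_kernels(model)$values))
  c(NA, NA, length(model$tau_axis))
}

#' Maximum detectability and latency traces
#'
#' Per tracked probe and time point: the maximum detectability over
#' latency, `I = max_tau roc`, and the latency at which it occurs,
#' `T = argmax_tau roc` (ties broken toward the smallest latency).
#' Both traces are smoothed over time with a 7 ms moving average;
#' entries are retained only where the peak cell is significant and
#' the smoothed latency exceeds `latency_floor_ms` (50 ms: the peak
#' must occur at or after the normal response latency).
#'
#' @param map a [detectability_map()].
#' @param probes probes to trace (default all mapped).
#' @param span_ms moving-average span over time.
#' @param latency_floor_ms minimum valid smoothed latency.
#' @return tibble with `probe`, `t`, `I`, `T`, `valid`.
#' @export
max_trace <- function(map, probes = NULL, span_ms = 7,
                      latency_floor_ms = 50) {
  if (is.null(probes)) probes <- map$probes
  purrr::map_dfr(probes, function(p) {
    ip <- match(p, map$probes)
    slab <- map$roc[ip, , , drop = FALSE][1, , , drop = TRUE]
    slab <- matrix(slab, nrow = length(map$t_values))
    I <- apply(slab, 1, function(v) if (all(is.na(v))) NA_real_ else
      max(v, na.rm = TRUE))
    Tl <- vapply(seq_along(I), function(i) {
      if (is.na(I[i])) return(NA_real_)
      map$tau_values[which.max(slab[i, ])]  # first max = smallest tau
    }, numeric(1))
    sig <- vapply(seq_along(I), function(i) {
      if (is.na(I[i])) return(FALSE)
      isTRUE(map$significant[ip, i, which.max(slab[i, ])])
    }, logical(1))
    span_bins <- max(1L, round(span_ms / max(1, min(diff(map$t_values),
                                                    na.rm = TRUE))))
    Is <- moving_average(ifelse(is.na(I), 0, I), span_bins)
    Ts <- moving_average(ifelse(is.na(Tl), 0, Tl), span_bins)
    tibble::tibble(probe = p, t = map$t_values, I = Is, T = Ts,
                   valid = sig & Ts > latency_floor_ms & !is.na(I))
  })
}

#' Synthetic population neuron for one remapping effect
#'
#' Averages, across the qualifying neurons' F-models, the skew-Gaussian
#' parameters of the source corresponding to the chosen effect (the
#' parameters are expressed in probe-spacing units, i.e. normalized by
#' the distance between adjacent probes) and zeroes the other sources'
#' amplitudes, yielding an F-model that represents the subpopulation
#' average of that effect.  Saccadic suppression is excluded by default
#' (too few qualifying neurons under the standard conditions).
#'
#' @param fms list of `fmodel` objects with congruent structure.
#' @param effect `"FF"` or `"ST"` (or `"suppression"` with
#'   `include_suppression = TRUE`, which averages the RF source).
#' @param include_suppression allow the suppression/RF variant.
#' @return an `fmodel`.
#' @export
population_neuron <- function(fms, effect = c("FF", "ST", "suppression"),
                              include_suppression = FALSE) {
  effect <- match.arg(effect)
  if (effect == "suppression" && !include_suppression) {
    stop("suppression is excluded from the population analysis by ",
         "default; set include_suppression = TRUE to override",
         call. = FALSE)
  }
  if (length(fms) == 0) stop("empty model list", call. = FALSE)
  agg <- aggregate_fmodels(fms)
  src <- if (effect == "suppression") "RF" else effect
  for (nm in setdiff(c("RF", "FF", "ST"), src)) {
    k <- match(nm, c("RF", "FF", "ST"))
    agg$phi[k, , , "a"] <- 0
  }
  agg
}
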