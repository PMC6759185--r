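#' Log-likelihood per spike relative to the constant-rate NULL model
#'
#' `(LL(model) - LL(NULL)) / n_spikes`, converted from nats to bits,
#' where the NULL model's instantaneous firing rate is the neuron's
#' average firing rate.  With a window, both likelihoods and the spike
#' count are restricted to bins inside it: the perisaccadic convention
#' is spikes observed 0..150 ms after saccade onset (`c(0, 150)`), the
#' fixation convention spikes -450..0 ms before it (`c(-450, 0)`).
#'
#' @param rate model-predicted rate matrix `[n_trials, n_bins]` (spk/s).
#' @param trials the [trial_set()] the rates align with.
#' @param window optional `(a, b)` ms window, half-open.
#' @param null_rate NULL-model rate (spk/s); defaults to the observed
#'   mean rate over the valid bins of the trial set.
#' @param delta_ms bin size (ms).
#' @param trial_subset optional trial indices to evaluate (e.g. the
#'   test trials of a split).
#' @return scalar bits/spk, or `NA` (with a warning) when the window
#'   holds no spikes.
#' @export
delta_ll_per_spike <- function(rate, trials, window = NULL,
                               null_rate = NULL, delta_ms = 1,
                               trial_subset = NULL) {
  if (is.null(trial_subset)) trial_subset <- seq_len(n_trials(trials))
  t_axis <- trials$t_axis
  in_win <- if (is.null(window)) rep(TRUE, length(t_axis)) else {
    t_axis >= window[1] & t_axis < window[2]
  }
  if (is.null(null_rate)) null_rate <- empirical_rates(trials)$r0
  ll_m <- 0; ll_0 <- 0; n_spk <- 0L
  for (i in trial_subset) {
    tr <- trials$trials[[i]]
    sel <- tr$valid & in_win
    if (!any(sel)) next
    r <- tr$spikes[sel]
    ll_m <- ll_m + log_likelihood(rate[i, sel], r, delta_ms)
    ll_0 <- ll_0 + log_likelihood(rep(null_rate, sum(sel)), r, delta_ms)
    n_spk <- n_spk + sum(r)
  }
  if (n_spk == 0) {
    warning("no spikes in the evaluation window; Delta LL/spk undefined")
    return(NA_real_)
  }
  (ll_m - ll_0) / n_spk / log(2)
}

#' Dichotomous model-vs-data agreement metrics
#'
#' Sensitivity, accuracy, precision, the geometric mean of sensitivity
#' and precision (GSP), and the F-measure with weight `alpha` from a
#' confusion matrix of neurons classified as displaying / not
#' displaying an effect in the data (rows) and in the model prediction
#' (columns).
#'
#' @param tp,fn,fp,tn confusion-matrix counts: effect significant in
#'   both (tp), data only (fn), model only (fp), neither (tn).
#' @param alpha F-measure weight (default 1/2).
#' @return one-row tibble with the five metrics (`NA` where a
#'   denominator is zero).
#' @export
dichotomous_metrics <- function(tp, fn, fp, tn, alpha = 0.5) {
  if (min(tp, fn, fp, tn) < 0) stop("negative counts", call. = FALSE)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  acc <- div(tp + tn, tp + fn + fp + tn)
  prec <- div(tp, tp + fp)
  gsp <- if (is.na(sens) || is.na(prec)) NA_real_ else sqrt(sens * prec)
  fm <- if (is.na(sens) || is.na(prec) ||
            (alpha^2 * prec + sens) == 0) NA_real_ else {
    (1 + alpha^2) * sens * prec / (alpha^2 * prec + sens)
  }
  tibble::tibble(sensitivity = sens, accuracy = acc, precision = prec,
                 gsp = gsp, f_measure = fm)
}

#' One-tailed mid-p McNemar test for paired classifier comparison
#'
#' With `b` neurons classified correctly by the first model but not the
#' second and `c` the reverse, the one-tailed mid-p value is
#' `P(X > b) + 0.5 P(X = b)` for `X ~ Binomial(b + c, 1/2)`; small
#' values indicate the first model is correct more often than chance
#' sharing of the discordant pairs allows.  With no discordant pairs
#' the p-value is 1 by convention.
#'
#' @param correct_a,correct_b logical vectors: per-neuron correctness
#'   of the two models (against the data classification).  May be
#'   omitted when `b` and `c` are given directly.
#' @param b,c discordant-pair counts.
#' @return p-value in `[0, 1]`.
#' @export
mcnemar_mid_p <- function(correct_a = NULL, correct_b = NULL,
                          b = NULL, c = NULL) {
  if (is.null(b) || is.null(c)) {
    if (is.null(correct_a) || is.null(correct_b)) {
      stop("supply either correctness vectors or counts b and c",
           call. = FALSE)
    }
    b <- sum(correct_a & !correct_b)
    c <- sum(!correct_a & correct_b)
  }
  n <- b + c
  if (n == 0) return(1)
  stats::pbinom(b, n, 0.5, lower.tail = FALSE) +
    0.5 * stats::dbinom(b, n, 0.5)
}

#' Robust perisaccadic-to-fixation performance ratio
#'
#' Zero-intercept robust linear regression of perisaccadic on fixation
#' performance across units (or trials), by iteratively reweighted
#' least squares with the "fair" weighting function
#' `w = 1 / (1 + |r| / (tune * s))`, `s` a MAD-based residual scale
#' (tuning constant 1.4).  The slope estimates the perisaccadic to
#' fixation performance ratio; its standard error comes from the final
#' weighted fit.
#'
#' @param fixation,perisaccadic numeric vectors (e.g. Delta LL/spk in
#'   the fixation and perisaccadic windows).
#' @param tune tuning constant of the fair weight.
#' @param max_iter,tol IRLS iteration controls.
#' @return one-row tibble with `slope`, `se`, `n`, `iterations`.
#' @export
peri_fix_ratio <- function(fixation, perisaccadic, tune = 1.4,
                           max_iter = 50, tol = 1e-8) {
  ok <- is.finite(fixation) & is.finite(perisaccadic)
  x <- fixation[ok]; y <- perisaccadic[ok]
  if (length(x) < 1 || all(x == 0)) {
    stop("degenerate fixation performance values", call. = FALSE)
  }
  slope <- sum(x * y) / sum(x^2)
  w <- rep(1, length(x))
  for (it in seq_len(max_iter)) {
    r <- y - slope * x
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s < 1e-12) { w <- rep(1, length(x)); break }
    w <- 1 / (1 + abs(r) / (tune * s))
    new_slope <- sum(w * x * y) / sum(w * x^2)
    if (abs(new_slope - slope) <= tol * max(abs(slope), 1e-12)) {
      slope <- new_slope
      break
    }
    slope <- new_slope
  }
  r <- y - slope * x
  dof <- max(length(x) - 1, 1)
  sigma2 <- sum(w * r^2) / dof
  se <- sqrt(sigma2 / sum(w * x^2))
  tibble::tibble(slope = slope, se = se, n = length(x), iterations = it)
}

#' Source contribution percentages
#'
#' Expresses the perisaccadic-to-fixation ratio of partial models as a
#' percentage of the full-model improvement: the increase percentage of
#' a single-source model `+src` is `100 (r_+src - r_0) / (r_F - r_0)`
#' and the decrease percentage of a knockout `-src` is
#' `100 (r_-src - r_F) / (r_0 - r_F)`, with `r_F` the full model's
#' ratio and `r_0` the no-source model's.
#'
#' @param full,no_source ratios of the full F-model and the no-source
#'   model.
#' @param plus named numeric vector of `+src` ratios.
#' @param minus named numeric vector of `-src` ratios.
#' @return tibble with columns `source`, `variant`, `percent`.
#' @export
contribution_percentages <- function(full, no_source, plus = NULL,
                                     minus = NULL) {
  denom <- full - no_source
  if (denom == 0) stop("full and no-source ratios are equal", call. = FALSE)
  out <- list()
  if (!is.null(plus)) {
    out$plus <- tibble::tibble(source = names(plus), variant = "increase",
                               percent = unname(100 * (plus - no_source) / denom))
  }
  if (!is.null(minus)) {
    out$minus <- tibble::tibble(source = names(minus), variant = "decrease",
                                percent = unname(100 * (minus - full) / -denom))
  }
  dplyr::bind_rows(out)
}
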