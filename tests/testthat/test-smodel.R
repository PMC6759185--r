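# small fully-specified model used across CIF tests
tiny_model <- function(kappa_val = 0, r0 = 10, rmax = 100) {
  cfg <- smodel_config(
    delay_knots = seq(-20, 80, 20), time_knots = seq(-160, 160, 40),
    offset_knots = seq(-160, 160, 80), postspike_knots = c(1, 3, 8, 20, 50),
    tau_max = 60)
  g <- probe_grid(2, 2, origin = c(0, 0), dx = 1, dy = 1)
  n_i <- length(cfg$delay_knots) - 3L
  n_j <- length(cfg$time_knots) - 3L
  kappa <- array(0, dim = c(4, n_i, n_j))
  if (kappa_val != 0) kappa[1, 2, 4] <- kappa_val
  smodel(kappa, rep(0, length(cfg$postspike_knots) - 3L),
         rep(0, length(cfg$offset_knots) - 3L), r0 = r0, rmax = rmax,
         config = cfg, grid = g)
}

empty_trials <- function(n_t = 241, saccade = 120, probes = NULL,
                         spikes = NULL) {
  g <- probe_grid(2, 2, origin = c(0, 0), dx = 1, dy = 1)
  probe <- rep(NA_integer_, n_t)
  if (!is.null(probes)) probe[probes$bins] <- probes$id
  sp <- integer(n_t)
  if (!is.null(spikes)) sp[spikes] <- 1L
  tr <- list(trial_id = 1, probe = probe, spikes = sp,
             valid = rep(TRUE, n_t), saccade_offset = NA_real_)
  trial_set(g, list(tr), seq_len(n_t) - 1L - saccade)
}

test_that("with no stimulus, history or offset the CIF sits at r0", {
  m <- tiny_model()
  ts <- empty_trials()
  rate <- cif(m, ts, history = "none")
  expect_equal(as.vector(rate), rep(10, ncol(rate)), tolerance = 1e-9)
})

test_that("a saturating generator approaches rmax and rates stay in range", {
  m <- tiny_model(kappa_val = 500)
  ts <- empty_trials(probes = list(bins = 90:96, id = 1L))
  rate <- cif(m, ts, history = "none")
  expect_lte(max(rate), 100)
  expect_gte(min(rate), 0)
  expect_gt(max(rate), 99)
})

test_that("CIF matches a hand-computed convolution plus sigmoid", {
  m <- tiny_model(kappa_val = 1.3)
  on_bins <- 90:96
  ts <- empty_trials(probes = list(bins = on_bins, id = 1L))
  rate <- cif(m, ts, history = "none")
  U <- eval_basis(m$bases$stim$delay, seq_len(60))
  V <- eval_basis(m$bases$stim$time, ts$t_axis)
  for (t_idx in sort(sample(97:180, 20))) {
    drive <- 0
    for (tau in 1:60) {
      src <- t_idx - tau
      if (src %in% on_bins) {
        drive <- drive + 1.3 * U[tau, 2] * V[t_idx, 4]
      }
    }
    expect_equal(rate[1, t_idx], 100 * plogis(drive + m$b0),
                 tolerance = 1e-9)
  }
})

test_that("true-history CIF is suppressed after spikes", {
  m <- tiny_model()
  m$eta <- c(3, 0)
  ts <- empty_trials(spikes = c(100, 140))
  r_none <- cif(m, ts, history = "none")
  r_true <- cif(m, ts, history = "true")
  expect_lt(r_true[1, 103], r_none[1, 103])
  expect_equal(r_true[1, 60], r_none[1, 60])
})

test_that("log-likelihood matches direct substitution and is monotone at spikes", {
  # single bin, r = 1, lambda * delta = 0.5
  expect_equal(log_likelihood(rate = 500, spikes = 1, delta_ms = 1),
               log(0.5) - 0.5)
  # identical models tie; raising lambda only at spike bins improves LL
  set.seed(6)
  spikes <- as.integer(runif(500) < 0.05)
  base <- rep(50, 500)
  ll0 <- log_likelihood(base, spikes)
  up <- base
  up[spikes == 1L] <- 80
  expect_gt(log_likelihood(up, spikes), ll0)
  expect_equal(ll0 - ll0, 0)
  expect_error(log_likelihood(c(-5, 2), c(0, 0)), "negative")
})

test_that("the selection screen applies the 1.5-sigma retention rule", {
  # unit-level check of the thresholding arithmetic on synthetic stats
  mu <- c(1.6, 1.4, 0, 2)
  mu_bar <- c(0, 0, 0, 2)
  sig_bar <- c(1, 1, 0, 0)
  keep <- ifelse(sig_bar > 0, abs(mu - mu_bar) >= 1.5 * sig_bar,
                 abs(mu - mu_bar) > 0)
  expect_identical(keep, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("the screen retains a planted strong probe and drops pure noise", {
  spec <- scaled_spec()
  sim <- make_synthetic_neuron(spec, n_trials = 60, seed = 23)
  cfg <- scaled_config(screen_resamples = 6, screen_thin = 6)
  scr <- select_parameters(sim$trials, cfg, seed = 3)
  g <- sim$trials$grid
  rf_p <- probe_id(g, 0, 2)
  dull_p <- probe_id(g, 3, 2)  # far from every source
  expect_gt(sum(scr$mask[rf_p, , ]), 0)
  expect_lt(mean(scr$mask[dull_p, , ]), mean(scr$mask[rf_p, , ]))
  expect_identical(dim(scr$mask), c(12L, 11L, 18L))
  # all-zero spikes: empty mask with a warning
  ts0 <- sim$trials
  ts0$trials <- lapply(ts0$trials, function(tr) {
    tr$spikes[] <- 0L
    tr
  })
  expect_warning(scr0 <- select_parameters(ts0, cfg, seed = 3), "empty")
  expect_false(any(scr0$mask))
})

test_that("splits are disjoint, seeded and sized by the fractions", {
  s <- fit_split(300, seed = 4)
  expect_length(s$train, 105)
  expect_length(s$validation, 90)
  expect_length(s$test, 105)
  expect_length(intersect(s$train, s$validation), 0)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(fit_split(300, seed = 4), fit_split(300, seed = 4))
  expect_error(fit_split(10, fractions = c(0.6, 0.6, 0.2)), "sum")
})

test_that("fitting a stationary stimulus-free neuron returns near-zero kernels", {
  # stationary Poisson spikes with no stimulus dependence: fitted
  # stimulus kernels stay at the noise floor
  g <- probe_grid(2, 2, origin = c(0, 0), dx = 1, dy = 1)
  set.seed(31)
  n_t <- 401
  trs <- lapply(1:60, function(i) {
    probe <- rep(NA_integer_, n_t)
    o <- 1L
    while (o + 6 <= n_t) {
      probe[o + 0:6] <- sample(1:4, 1)
      o <- o + 7L
    }
    list(trial_id = i, probe = probe,
         spikes = as.integer(runif(n_t) < 0.03),
         valid = rep(TRUE, n_t), saccade_offset = NA_real_)
  })
  ts <- trial_set(g, trs, seq_len(n_t) - 201L)
  cfg <- smodel_config(
    delay_knots = seq(-20, 80, 20), time_knots = seq(-220, 220, 55),
    offset_knots = seq(-220, 220, 110), postspike_knots = c(1, 3, 8, 20, 50),
    tau_max = 60, screen_resamples = 5, screen_thin = 3, max_cycles = 4)
  m <- fit_smodel(ts, config = cfg, seed = 9)
  kf <- smodel_kernels(m)
  expect_lt(max(abs(kf$values)), 1.5)
  expect_true(all(is.finite(kf$values)))
  # monotone ascent of the pooled objective
  expect_true(all(diff(m$meta$ll_trace) > -1e-6))
  # baseline-only model when the mask is empty
  m0 <- fit_smodel(ts, config = cfg,
                   mask = array(FALSE, dim = dim(m$mask)), seed = 9)
  expect_true(all(m0$kappa == 0))
  expect_identical(m0$meta$note,
                   "empty selection mask: baseline-only model")
})

test_that("tidy and glance summarize a model", {
  m <- tiny_model(kappa_val = 2)
  td <- tidy(m)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_identical(sum(td$term == "kappa"), sum(m$mask))
  gl <- glance(m)
  expect_identical(gl$n_probes, 4L)
  expect_equal(gl$r0, 10)
})

test_that("model invariants are enforced at construction", {
  cfg <- smodel_config(
    delay_knots = seq(-20, 80, 20), time_knots = seq(-160, 160, 40),
    offset_knots = seq(-160, 160, 80), postspike_knots = c(1, 3, 8, 20, 50),
    tau_max = 60)
  g <- probe_grid(2, 2)
  kap <- array(0, dim = c(4, 3, 6))
  expect_error(smodel(kap, rep(0, 2), rep(0, 6), r0 = 50, rmax = 40,
                      cfg, g), "r0 < rmax")
  mask <- array(FALSE, dim = dim(kap))
  kap2 <- kap
  kap2[1, 1, 1] <- 1
  expect_error(smodel(kap2, rep(0, 2), rep(0, 6), r0 = 10, rmax = 100,
                      cfg, g, mask = mask), "selection mask")
})
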