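test_that("skew Gaussian closed forms hold", {
  phi <- c(a = 2, mux = 1, muy = -1, sx = 1.5, sy = 0.5, rho = 0.3,
           gx = 0, gy = 0)
  # zero skewness: value at center is a * Phi(0)^2 = a / 4
  expect_equal(skew_gaussian(1, -1, phi), 2 / 4)
  # rho = 0 factorizes into x-part times y-part
  phi0 <- phi; phi0["rho"] <- 0; phi0["gx"] <- 1; phi0["gy"] <- -2
  xs <- seq(-2, 3, 0.5)
  for (y in c(-2, 0, 1)) {
    v <- skew_gaussian(xs, rep(y, length(xs)), phi0)
    xpart <- exp(-0.5 * (xs - 1)^2 / 1.5^2) * pnorm(1 * (xs - 1))
    ypart <- exp(-0.5 * (y + 1)^2 / 0.5^2) * pnorm(-2 * (y + 1))
    expect_equal(v, 2 * xpart * ypart, tolerance = 1e-12)
  }
  expect_error(skew_gaussian(0, 0, c(phi[1:5], rho = 1, gx = 0, gy = 0)),
               "singular")
  expect_error(skew_gaussian(0, 0, replace(phi, "sx", -1)), "positive")
})

test_that("skew Gaussian matches an independent scalar evaluator on a grid", {
  set.seed(31)
  oracle <- function(x, y, p) {
    dx <- x - p["mux"]; dy <- y - p["muy"]
    Q <- dx^2 / p["sx"]^2 + dy^2 / p["sy"]^2 -
      2 * p["rho"] * dx * dy / (p["sx"] * p["sy"])
    unname(p["a"] * exp(-Q / (2 * (1 - p["rho"]^2))) *
             pnorm(p["gx"] * dx) * pnorm(p["gy"] * dy))
  }
  for (rep in 1:5) {
    p <- c(a = rnorm(1, 0, 3), mux = runif(1, 0, 8), muy = runif(1, 0, 8),
           sx = runif(1, 0.3, 2), sy = runif(1, 0.3, 2),
           rho = runif(1, -0.9, 0.9), gx = runif(1, -5, 5),
           gy = runif(1, -5, 5))
    for (x in 0:8) for (y in 0:8) {
      expect_equal(skew_gaussian(x, y, p), oracle(x, y, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("fixation kernel is the time average over the fixation window", {
  set.seed(5)
  vals <- array(rnorm(2 * 11 * 4), dim = c(2, 11, 4))
  kf <- kernel_field(vals, t_axis = seq(-500, -400, 10), tau_axis = 1:4)
  fx <- fixation_kernel(kf, -500, -400)
  expect_equal(fx, apply(vals, c(1, 3), mean), ignore_attr = TRUE)
  # time-invariant kernel: fixation kernel equals any slice
  vals2 <- array(rep(vals[, 1, ], times = 11), dim = c(2, 4, 11))
  vals2 <- aperm(vals2, c(1, 3, 2))
  kf2 <- kernel_field(vals2, seq(-500, -400, 10), 1:4)
  expect_equal(fixation_kernel(kf2, -500, -400), vals[, 1, ],
               ignore_attr = TRUE)
  # kernel linear in t: mean equals the midpoint value
  ramp <- array(rep(seq(-500, -400, 10), each = 2), dim = c(2, 11, 1))
  kf3 <- kernel_field(ramp, seq(-500, -400, 10), 1)
  expect_equal(as.numeric(fixation_kernel(kf3, -500, -400)), c(-450, -450))
  expect_error(fixation_kernel(kf, 10, 20), "empty")
})

test_that("factorization recovers a planted in-bounds source almost exactly", {
  # well-determined geometry: 81 probes against 25 parameters per cell
  grid <- probe_grid(9, 9, origin = c(-21, -9), dx = 3.5, dy = 2.25,
                     fp = c(0, 0), st = c(-10, 0))
  co <- probe_coords(grid)
  locs <- list(RF = c(2, 6), FF = c(2, 3), ST = c(4, 3))
  t_axis <- seq(-420, -320, 20)
  tau_axis <- 1:60
  # planted source near the FF probe (col 3, row 2), skewed and tilted,
  # switching on at t >= -340 at late delays over a flat baseline
  phi_true <- c(a = 3, mux = 3.3, muy = 2.4, sx = 1.2, sy = 0.9,
                rho = 0.2, gx = 0, gy = 0)
  spatial <- skew_gaussian(co$col, co$row, phi_true)
  vals <- array(0.25, dim = c(nrow(co), length(t_axis), length(tau_axis)))
  for (it in 5:6) for (k in 31:60) {
    vals[, it, k] <- vals[, it, k] + spatial
  }
  kf <- kernel_field(vals, t_axis, tau_axis, grid)
  fm <- fit_factorization(kf, locs, bins = c(1, 31, 61),
                          t_values = c(-340, -320),
                          fixation_window = c(-420, -380), seed = 2)
  # bin with the source: near-zero residual, center recovered closely
  expect_lt(max(fm$sse[, 2]), 1e-3 * sum(spatial^2))
  amps <- abs(fm$phi[, 1, 2, "a"])
  main <- which.max(amps)
  center <- fm$phi[main, 1, 2, c("mux", "muy")]
  expect_lt(max(abs(center - phi_true[c("mux", "muy")])), 0.25)
  # the delay bin without the source: baseline and sources at zero
  expect_lt(abs(fm$c_arr[1, 1]), 1e-2)
  recon <- fmodel_kernels(fm, smooth_span_ms = 0)
  expect_lt(max(abs(recon$values[, 1, 1:30] - 0.25)), 0.05)
})

test_that("fixation-only kernels factorize to zero sources and baseline", {
  grid <- scaled_grid()
  t_axis <- seq(-420, -380, 20)
  vals <- array(rep(sin(seq_len(40) / 6), each = 12 * 3),
                dim = c(12, 3, 40))
  kf <- kernel_field(vals, t_axis, 1:40, grid)
  fm <- fit_factorization(kf, list(RF = c(0, 2), FF = c(0, 0),
                                   ST = c(2, 0)),
                          bins = c(1, 21, 41), t_values = t_axis,
                          fixation_window = c(-420, -380), seed = 3)
  expect_true(all(fm$sse < 1e-8))
  expect_true(all(abs(fm$c_arr) < 1e-4))
  # constraint satisfaction on every fitted cell
  for (k in 1:3) {
    loc <- fm$source_locs[[c("RF", "FF", "ST")[k]]]
    expect_true(all(abs(fm$phi[k, , , "mux"] - loc[2]) <= 1 + 1e-8))
    expect_true(all(abs(fm$phi[k, , , "muy"] - loc[1]) <= 1 + 1e-8))
    expect_true(all(fm$phi[k, , , "sx"] <= 2 + 1e-8))
    expect_true(all(abs(fm$phi[k, , , "rho"]) <= 0.99 + 1e-8))
    expect_true(all(abs(fm$phi[k, , , "gx"]) <= 5 + 1e-8))
  }
})

test_that("default delay bins are the standard 28 boundaries", {
  b <- delay_bins()
  expect_length(b, 28L)
  expect_identical(b[1:6], c(1, 20, 40, 50, 53, 56))
  expect_identical(b[28], 151)
  expect_true(!is.unsorted(b, strictly = TRUE))
})

test_that("moving-average smoothing preserves constants and attenuates peaks", {
  expect_equal(moving_average(rep(3, 20), 10), rep(3, 20))
  x <- c(rep(0, 10), 5, rep(0, 10))
  sm <- moving_average(x, 10)
  expect_lt(max(sm), max(x))
  expect_equal(sum(sm[6:16] > 0), 10)
  expect_equal(moving_average(x, 1), x)
})

test_that("reconstruction, smoothing and interpolation behave", {
  fm <- minimal_fmodel()
  kf <- fmodel_kernels(fm, smooth_span_ms = 0)
  # value at the RF probe center: fixation 0 + a * Phi(0)^2 + others
  co <- probe_coords(fm$grid)
  rf_p <- probe_id(fm$grid, 0, 2)
  manual <- sum(vapply(1:3, function(k)
    skew_gaussian(co$col[rf_p], co$row[rf_p], fm$phi[k, 1, 1, ]),
    numeric(1)))
  expect_equal(kf$values[rf_p, 1, 1], manual)
  # smoothing attenuates the sharp bin edges
  kfs <- fmodel_kernels(fm, smooth_span_ms = 10)
  expect_lte(max(abs(kfs$values)), max(abs(kf$values)) + 1e-12)
  # interpolation between fitted time points is linear
  kf_mid <- fmodel_kernels(fm, t_axis = c(-450, -425, -400),
                           smooth_span_ms = 0)
  expect_equal(kf_mid$values[, 2, ],
               (kf_mid$values[, 1, ] + kf_mid$values[, 3, ]) / 2)
})

test_that("knockout keeps chosen sources and resamples the rest from fixation", {
  fm <- minimal_fmodel()
  same <- knockout(fm, keep = c("RF", "FF", "ST"))
  expect_identical(same$phi, fm$phi)
  none <- knockout(fm, keep = character(0), seed = 4)
  # constant-parameter model: fixation draws are identical values
  expect_equal(none$phi, fm$phi)
  # with time-varying amplitudes the perisaccadic values are replaced by
  # fixation-period draws
  fmv <- minimal_fmodel()
  peri_idx <- which(fmv$t_values > -100)
  fmv$phi["FF", peri_idx, , "a"] <- 9
  ko <- knockout(fmv, keep = c("RF", "ST"), seed = 5)
  expect_true(all(ko$phi["FF", peri_idx, , "a"] == 0.5)) # fixation value
  expect_identical(ko$phi["RF", , , ], fmv$phi["RF", , , ])
})

test_that("aggregation is the element-wise mean", {
  fms <- list(minimal_fmodel(a = c(RF = 0, FF = 0, ST = 0)),
              minimal_fmodel(a = c(RF = 2, FF = 1, ST = 4)))
  agg <- aggregate_fmodels(fms)
  expect_equal(unique(as.vector(agg$phi["RF", , , "a"])), 1)
  expect_equal(unique(as.vector(agg$phi["FF", , , "a"])), 0.5)
  expect_equal(unique(as.vector(agg$phi["ST", , , "a"])), 2)
  # identical models aggregate to themselves
  agg2 <- aggregate_fmodels(list(minimal_fmodel(), minimal_fmodel()))
  expect_equal(agg2$phi, minimal_fmodel()$phi)
  # random ensemble matches a brute-force per-element mean
  set.seed(8)
  ens <- lapply(1:4, function(i) {
    fm <- minimal_fmodel()
    fm$phi[] <- rnorm(length(fm$phi))
    fm$c_arr[] <- rnorm(length(fm$c_arr))
    fm
  })
  agg3 <- aggregate_fmodels(ens)
  expect_equal(agg3$phi,
               (ens[[1]]$phi + ens[[2]]$phi + ens[[3]]$phi + ens[[4]]$phi) / 4)
  expect_equal(agg3$c_arr,
               Reduce(`+`, lapply(ens, `[[`, "c_arr")) / 4)
  bad <- minimal_fmodel(t_values = seq(-450, 150, 100))
  expect_error(aggregate_fmodels(list(minimal_fmodel(), bad)), "mismatched")
})
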