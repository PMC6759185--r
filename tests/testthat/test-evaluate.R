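test_that("dichotomous metrics match manual arithmetic", {
  m <- dichotomous_metrics(10, 10, 10, 10, alpha = 0.5)
  expect_equal(unlist(m), c(sensitivity = 0.5, accuracy = 0.5,
                            precision = 0.5, gsp = 0.5, f_measure = 0.5))
  perfect <- dichotomous_metrics(5, 0, 0, 7)
  expect_true(all(unlist(perfect) == 1))
  # hand-built asymmetric matrix
  m2 <- dichotomous_metrics(8, 2, 4, 6, alpha = 0.5)
  s <- 8 / 10; p <- 8 / 12
  expect_equal(m2$sensitivity, s)
  expect_equal(m2$accuracy, 14 / 20)
  expect_equal(m2$precision, p)
  expect_equal(m2$gsp, sqrt(s * p))
  expect_equal(m2$f_measure, (1 + 0.25) * s * p / (0.25 * p + s))
  # undefined denominators come back NA
  m3 <- dichotomous_metrics(0, 0, 0, 10)
  expect_true(is.na(m3$sensitivity))
  expect_error(dichotomous_metrics(-1, 0, 0, 0), "negative")
})

test_that("metrics lie in the unit interval for random confusion matrices", {
  set.seed(9)
  for (rep in 1:30) {
    cm <- rpois(4, 6) + 1
    m <- dichotomous_metrics(cm[1], cm[2], cm[3], cm[4])
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  }
})

test_that("mid-p McNemar equals binomial enumeration", {
  expect_equal(mcnemar_mid_p(b = 5, c = 0), 0.5 * 0.5^5)
  expect_equal(mcnemar_mid_p(b = 0, c = 0), 1)
  for (b in 0:10) for (cc in 0:10) {
    if (b + cc == 0 || b + cc > 20) next
    n <- b + cc
    enum <- sum(dbinom(seq_len(n)[seq_len(n) > b], n, 0.5)) +
      0.5 * dbinom(b, n, 0.5)
    expect_equal(mcnemar_mid_p(b = b, c = cc), enum, tolerance = 1e-12)
  }
  # correctness-vector interface
  a <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  bb <- c(FALSE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(mcnemar_mid_p(a, bb), mcnemar_mid_p(b = 2, c = 0))
})

test_that("zero-intercept robust ratio recovers exact and contaminated slopes", {
  x <- seq(0.1, 2, length.out = 40)
  exact <- peri_fix_ratio(x, 2 * x)
  expect_equal(exact$slope, 2, tolerance = 1e-9)
  expect_equal(exact$se, 0, tolerance = 1e-9)
  # one gross outlier among collinear points barely moves the slope
  y <- 2 * x
  y[7] <- 40
  robust <- peri_fix_ratio(x, y)
  expect_lt(abs(robust$slope - 2) / 2, 0.05)
  # reduces to ordinary zero-intercept least squares for small residuals
  set.seed(21)
  yn <- 1.4 * x + rnorm(40, 0, 1e-4)
  ols <- sum(x * yn) / sum(x^2)
  expect_equal(peri_fix_ratio(x, yn)$slope, ols, tolerance = 1e-3)
  expect_error(peri_fix_ratio(rep(0, 5), rnorm(5)), "degenerate")
})

test_that("contribution percentages reproduce the printed ratio arithmetic", {
  # ratios as printed for the population: no-source 0.28, +FF 0.95, full 1.35
  out <- contribution_percentages(full = 1.35, no_source = 0.28,
                                  plus = c(FF = 0.95))
  expect_lt(abs(out$percent - 62.65), 0.7)
  expect_equal(contribution_percentages(1.35, 0.28,
                                        plus = c(A = 1.35))$percent, 100)
  expect_equal(contribution_percentages(1.35, 0.28,
                                        plus = c(A = 0.28))$percent, 0)
  dec <- contribution_percentages(1.35, 0.28, minus = c(FF = 0.72))
  expect_equal(dec$percent, 100 * (0.72 - 1.35) / (0.28 - 1.35))
  expect_error(contribution_percentages(1, 1, plus = c(A = 1)), "equal")
})

test_that("Delta LL per spike is zero for the NULL model and positive for sharper rates", {
  ts <- tiny_trials(n_trials = 6)
  r0 <- empirical_rates(ts)$r0
  null_rates <- matrix(r0, nrow = n_trials(ts), ncol = length(ts$t_axis))
  expect_equal(delta_ll_per_spike(null_rates, ts, null_rate = r0), 0)
  # raising the rate only at spike bins increases the likelihood
  sharper <- null_rates
  for (i in seq_len(n_trials(ts))) {
    sharper[i, ts$trials[[i]]$spikes == 1L] <- r0 * 3
  }
  expect_gt(delta_ll_per_spike(sharper, ts, null_rate = r0), 0)
  # hand-computed 3-bin example, in bits
  g <- probe_grid(1, 1)
  tr <- list(trial_id = 1, probe = rep(NA_integer_, 3),
             spikes = c(0L, 1L, 0L), valid = rep(TRUE, 3),
             saccade_offset = NA_real_)
  ts3 <- trial_set(g, list(tr), 0:2)
  rates <- matrix(c(10, 200, 10), nrow = 1)
  manual <- (log(0.2) - 0.22) - (log(1000 / 3 / 1000) - 3 * (1000 / 3) / 1000)
  got <- delta_ll_per_spike(rates, ts3)
  expect_equal(got, manual / 1 / log(2), tolerance = 1e-10)
})
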