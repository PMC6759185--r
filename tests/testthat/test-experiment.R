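test_that("conditions are complete, balanced permutations", {
  g9 <- probe_grid(9, 9, origin = c(-21, -9), dx = 3.5, dy = 2.25)
  cc <- generate_conditions(g9, 5, seed = 1)
  for (cd in split(cc$probe, cc$condition)) {
    expect_length(cd, 81L)
    expect_length(unique(cd), 81L)
  }
  # Latin-square balance: occupancy exactly 1 per (position, probe)
  g3 <- probe_grid(3, 3)
  cc3 <- generate_conditions(g3, 9, seed = 5)
  occ <- table(cc3$position, cc3$probe)
  expect_true(all(occ == 1L))
  # determinism
  expect_identical(generate_conditions(g3, 4, seed = 7),
                   generate_conditions(g3, 4, seed = 7))
  # 1x1 grid: the single probe every time
  g1 <- probe_grid(1, 1)
  expect_true(all(generate_conditions(g1, 3, seed = 1)$probe == 1L))
})

test_that("rasterization places consecutive non-overlapping flashes", {
  ps <- rasterize_condition(c(3, 1), trial_length_ms = 30,
                            saccade_time_ms = 10, probe_duration_ms = 7)
  expect_identical(ps[1:7], rep(3L, 7))
  expect_identical(ps[8:14], rep(1L, 7))
  expect_true(all(is.na(ps[15:30])))
  expect_identical(attr(ps, "t_axis")[11], 0L)
  # 81 flashes of 7 ms occupy 567 bins
  ord <- sample(81)
  ps81 <- rasterize_condition(ord, 600, 0)
  expect_identical(sum(!is.na(ps81)), 567L)
  # round trip recovers the order
  expect_identical(derasterize_condition(ps81), as.integer(ord))
  # empty condition -> all-empty lattice
  expect_true(all(is.na(rasterize_condition(integer(0), 20, 5))))
  expect_error(rasterize_condition(1:4, trial_length_ms = 20,
                                   saccade_time_ms = 0), "shorter")
})

test_that("rasterized stimuli are one-hot over probes", {
  ps <- rasterize_condition(sample(9), 80, 40, cycle = TRUE)
  m <- as_stimulus_matrix(ps, 9)
  expect_true(all(colSums(m) == 1L))  # cycled: every bin occupied
  ps2 <- rasterize_condition(1:4, 40, 0)
  m2 <- as_stimulus_matrix(ps2, 4)
  expect_true(all(colSums(m2) <= 1L))
  expect_identical(sum(m2), 28L)
})

test_that("window_spikes counts half-open windows and matches a brute-force loop", {
  ts <- tiny_trials()
  tr <- ts$trials[[1]]
  expect_identical(window_spikes(tr, c(-100, 100), ts$t_axis),
                   sum(tr$spikes))
  set.seed(4)
  for (rep in 1:20) {
    w <- sort(sample(seq(-100, 99), 2))
    got <- window_spikes(tr, w, ts$t_axis)
    manual <- 0L
    for (i in seq_along(ts$t_axis)) {
      if (ts$t_axis[i] >= w[1] && ts$t_axis[i] < w[2] && tr$spikes[i] == 1L)
        manual <- manual + 1L
    }
    expect_identical(got, manual)
  }
  spikes <- integer(30)
  spikes[c(11, 21)] <- 1L  # t = 10 and 20 on axis 0..29
  expect_identical(window_spikes(spikes, c(0, 15), t_axis = 0:29), 1L)
  expect_error(window_spikes(tr, c(-500, 0), ts$t_axis), "outside")
})

test_that("trial sets enforce shared axes and binary spikes", {
  g <- probe_grid(2, 2)
  t_axis <- 0:9
  good <- list(trial_id = 1, probe = rep(NA_integer_, 10),
               spikes = integer(10), valid = rep(TRUE, 10),
               saccade_offset = NA_real_)
  expect_s3_class(trial_set(g, list(good), t_axis), "trial_set")
  bad <- good
  bad$spikes[3] <- 2L
  expect_error(trial_set(g, list(bad), t_axis), "binary")
  bad2 <- good
  bad2$probe[1] <- 9L
  expect_error(trial_set(g, list(bad2), t_axis), "probe ids")
  short <- good
  short$spikes <- integer(5)
  expect_error(trial_set(g, list(short), t_axis), "share")
})

test_that("trial sets round-trip through the on-disk format bit-exactly", {
  spec <- scaled_spec()
  sim <- make_synthetic_neuron(spec, n_trials = 6, seed = 3)
  dir <- withr::local_tempdir()
  write_trial_set(sim$trials, dir)
  back <- read_trial_set(dir)
  expect_identical(back$t_axis, sim$trials$t_axis)
  expect_equal(back$grid, sim$trials$grid)
  for (i in seq_along(back$trials)) {
    expect_identical(back$trials[[i]]$probe, sim$trials$trials[[i]]$probe)
    expect_identical(back$trials[[i]]$spikes, sim$trials$trials[[i]]$spikes)
    expect_identical(back$trials[[i]]$valid, sim$trials$trials[[i]]$valid)
  }
})

test_that("probe id and coordinate round trips", {
  g <- probe_grid(4, 3, origin = c(-2, -3), dx = 1, dy = 2)
  co <- probe_coords(g)
  expect_identical(nrow(co), 12L)
  expect_identical(probe_id(g, co$row, co$col), co$probe)
  rc <- probe_rowcol(g, co$probe)
  expect_identical(as.integer(rc[, "row"]), co$row)
  expect_identical(as.integer(rc[, "col"]), co$col)
  expect_true(is.na(probe_id(g, 5, 0)))
  expect_error(probe_grid(0, 3), "at least one")
})
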