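#' Probe grid geometry
#'
#' Describes the rectangular grid of possible probe locations, its
#' position in degrees of visual angle (dva), and the fixation point and
#' saccade target of the task.  Probe indices are 0-based `(row, col)`
#' pairs internally; rows map to the vertical (y) screen axis and columns
#' to the horizontal (x) axis.  The linear probe id used by stimulus
#' lattices is `row * n_cols + col + 1`.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param origin dva coordinates `(x, y)` of probe `(row = 0, col = 0)`.
#' @param dx,dy center-to-center probe spacing in dva (> 0).
#' @param fp fixation-point dva coordinates.
#' @param st saccade-target dva coordinates.
#' @return object of class `probe_grid`.
#' @examples
#' g <- probe_grid(9, 9, origin = c(-14, -9), dx = 3.5, dy = 2.25)
#' n_probes(g)
#' @export
probe_grid <- function(n_rows, n_cols, origin = c(0, 0), dx = 1, dy = 1,
                       fp = c(0, 0), st = c(-10, 0)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  if (dx <= 0 || dy <= 0) stop("probe spacings must be positive", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 origin = as.numeric(origin), dx = dx, dy = dy,
                 fp = as.numeric(fp), st = as.numeric(st)),
            class = "probe_grid")
}

#' @rdname probe_grid
#' @param grid a `probe_grid`.
#' @export
n_probes <- function(grid) grid$n_rows * grid$n_cols

#' @export
print.probe_grid <- function(x, ...) {
  cat(sprintf("<probe_grid> %d x %d probes, spacing (%g, %g) dva\n",
              x$n_rows, x$n_cols, x$dx, x$dy))
  invisible(x)
}

#' Probe coordinates as a tibble
#'
#' @param grid a [probe_grid()].
#' @return tibble with columns `probe` (linear id), `row`, `col`
#'   (0-based) and `x`, `y` (dva).
#' @export
probe_coords <- function(grid) {
  row <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  tibble::tibble(
    probe = row * grid$n_cols + col + 1L,
    row = row, col = col,
    x = grid$origin[1] + col * grid$dx,
    y = grid$origin[2] + row * grid$dy)
}

#' Convert between linear probe ids and (row, col)
#' @param grid a [probe_grid()].
#' @param probe linear probe id(s).
#' @return `probe_rowcol()`: 2-column matrix of 0-based (row, col);
#'   `probe_id()`: linear id(s).
#' @export
probe_rowcol <- function(grid, probe) {
  probe <- as.integer(probe) - 1L
  cbind(row = probe %/% grid$n_cols, col = probe %% grid$n_cols)
}

#' @rdname probe_rowcol
#' @param row,col 0-based probe indices.
#' @export
probe_id <- function(grid, row, col) {
  ok <- row >= 0 & row < grid$n_rows & col >= 0 & col < grid$n_cols
  out <- as.integer(row * grid$n_cols + col + 1L)
  out[!ok] <- NA_integer_
  out
}

#' Generate pseudorandom balanced probe conditions
#'
#' A condition is one ordering in which every probe location is flashed
#' exactly once.  Conditions are built in blocks of `n = n_probes`
#' cyclic shifts, each block derived from a fresh seeded random
#' permutation (a Latin-square construction per block), so that when
#' `n_conditions` is a multiple of the grid size every probe location
#' occurs at every sequence position with exactly equal frequency; for
#' other `n_conditions` the occupancy of any (position, location) cell
#' differs by at most one.  Fresh permutations across blocks keep the
#' relative timing of probe pairs varied across conditions, which is
#' what makes per-probe kernels identifiable.
#'
#' @param grid a [probe_grid()].
#' @param n_conditions number of conditions to generate (>= 1).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return tibble with columns `condition`, `position` (1-based slot in
#'   the sequence), and `probe` (linear probe id).
#' @export
generate_conditions <- function(grid, n_conditions, seed = 1L) {
  stopifnot(inherits(grid, "probe_grid"))
  n <- n_probes(grid)
  if (n < 1) stop("zero-size grid", call. = FALSE)
  n_conditions <- as.integer(n_conditions)
  if (is.na(n_conditions) || n_conditions < 1) {
    stop("`n_conditions` must be at least 1", call. = FALSE)
  }
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n_blocks <- (n_conditions + n - 1L) %/% n
  bases <- lapply(seq_len(n_blocks), function(b) sample.int(n))
  orders <- lapply(seq_len(n_conditions), function(c) {
    base <- bases[[((c - 1L) %/% n) + 1L]]
    shift <- (c - 1L) %% n
    base[((seq_len(n) - 1L + shift) %% n) + 1L]
  })
  tibble::tibble(
    condition = rep(seq_len(n_conditions), each = n),
    position = rep(seq_len(n), times = n_conditions),
    probe = unlist(orders))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Rasterize a probe condition into a 1 ms stimulus sequence
#'
#' Probe `k` (0-based position in the order) occupies the half-open bin
#' range `[k * d, (k + 1) * d)` ms from trial start, `d` the probe
#' duration; flashes are consecutive and non-overlapping so at most one
#' probe is on per bin.  The output is indexed so that t = 0 is the
#' saccade onset.
#'
#' @param order integer vector of linear probe ids (one flash each).
#' @param trial_length_ms total trial length in ms.
#' @param saccade_time_ms saccade onset, ms from trial start.
#' @param probe_duration_ms flash duration (default 7 ms).
#' @param cycle if `TRUE`, the sequence is repeated end-to-end to fill
#'   the whole trial (the continuous-stream presentation used by the
#'   task); if `FALSE` (default) bins after the last flash are empty and
#'   the trial must be at least as long as the sequence.
#' @return integer vector of length `trial_length_ms`: the probe id on in
#'   each 1 ms bin, `NA` when no probe is on.  Attribute `t_axis` holds
#'   the bin times (ms, saccade onset at 0, half-open bins `[t, t + 1)`).
#' @export
rasterize_condition <- function(order, trial_length_ms, saccade_time_ms,
                                probe_duration_ms = 7, cycle = FALSE) {
  order <- as.integer(order)
  d <- as.integer(probe_duration_ms)
  if (d < 1) stop("probe duration must be positive", call. = FALSE)
  L <- as.integer(trial_length_ms)
  span <- length(order) * d
  if (!cycle && length(order) > 0 && L < span) {
    stop("trial shorter than the probe sequence", call. = FALSE)
  }
  seq_bins <- rep(order, each = d)
  if (length(order) == 0) {
    probe_seq <- rep(NA_integer_, L)
  } else if (cycle) {
    probe_seq <- seq_bins[((seq_len(L) - 1L) %% span) + 1L]
  } else {
    probe_seq <- c(seq_bins, rep(NA_integer_, L - span))
  }
  attr(probe_seq, "t_axis") <- seq_len(L) - 1L - as.integer(saccade_time_ms)
  probe_seq
}

#' Recover the flash order from a rasterized sequence
#'
#' @param probe_seq output of [rasterize_condition()].
#' @return integer vector of probe ids in presentation order (one entry
#'   per flash run).
#' @export
derasterize_condition <- function(probe_seq) {
  r <- rle(as.integer(probe_seq))
  r$values[!is.na(r$values)]
}

#' Expand a probe sequence into a binary probes x bins lattice
#'
#' @param probe_seq integer probe-id-per-bin vector.
#' @param n_probes number of probes in the grid.
#' @return binary matrix `[n_probes, n_bins]`.
#' @export
as_stimulus_matrix <- function(probe_seq, n_probes) {
  m <- matrix(0L, nrow = n_probes, ncol = length(probe_seq))
  on <- which(!is.na(probe_seq))
  m[cbind(probe_seq[on], on)] <- 1L
  m
}

#' Trial set: saccade-aligned stimuli and spikes over one probe grid
#'
#' All trials share the probe grid and a common time axis (1 ms bins,
#' t = 0 at saccade onset, half-open `[t, t + 1)` convention).  Trials of
#' unequal recorded length are padded to the common axis with an explicit
#' validity mask; likelihood sums and window counts skip invalid bins.
#'
#' @param grid a [probe_grid()].
#' @param trials list, one element per trial, each a list with integer
#'   vectors `probe` (probe id on per bin, `NA` = none), `spikes`
#'   (0/1), logical `valid`, and scalars `trial_id`, `saccade_offset`.
#' @param t_axis shared integer time axis (ms from saccade onset).
#' @return object of class `trial_set`.
#' @export
trial_set <- function(grid, trials, t_axis) {
  stopifnot(inherits(grid, "probe_grid"))
  t_axis <- as.integer(t_axis)
  n_t <- length(t_axis)
  for (tr in trials) {
    if (length(tr$probe) != n_t || length(tr$spikes) != n_t ||
        length(tr$valid) != n_t) {
      stop("all trials must share the time axis", call. = FALSE)
    }
    if (any(tr$spikes[tr$valid] %% 1 != 0) ||
        any(tr$spikes[tr$valid] < 0 | tr$spikes[tr$valid] > 1)) {
      stop("spike trains must be binary", call. = FALSE)
    }
    pv <- tr$probe[tr$valid]
    if (any(!is.na(pv) & (pv < 1 | pv > n_probes(grid)))) {
      stop("probe ids outside the grid", call. = FALSE)
    }
  }
  structure(list(grid = grid, trials = trials, t_axis = t_axis),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d x %d grid, t in [%d, %d] ms\n",
              length(x$trials), x$grid$n_rows, x$grid$n_cols,
              min(x$t_axis), max(x$t_axis)))
  invisible(x)
}

#' Number of trials in a trial set
#' @param trials a [trial_set()].
#' @export
n_trials <- function(trials) length(trials$trials)

#' Count spikes in a half-open time window
#'
#' @param trial one trial of a [trial_set()] (list with `spikes`,
#'   `valid`) or a plain 0/1 spike vector.
#' @param window numeric `(start, end)` in ms from saccade onset,
#'   half-open `[start, end)`.
#' @param t_axis time axis; taken from the trial set when `trial` comes
#'   with one attached via `attr(trial, "t_axis")`.
#' @return integer spike count over valid bins in the window.
#' @export
window_spikes <- function(trial, window, t_axis = NULL) {
  if (is.list(trial)) {
    spikes <- trial$spikes
    valid <- trial$valid %||% rep(TRUE, length(spikes))
  } else {
    spikes <- trial
    valid <- rep(TRUE, length(spikes))
  }
  if (is.null(t_axis)) t_axis <- attr(trial, "t_axis")
  if (is.null(t_axis)) stop("no time axis supplied", call. = FALSE)
  if (window[1] < t_axis[1] || window[2] > t_axis[length(t_axis)] + 1) {
    stop("window outside the time axis", call. = FALSE)
  }
  sel <- t_axis >= window[1] & t_axis < window[2] & valid
  as.integer(sum(spikes[sel]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stimulus presentation events of a trial set
#'
#' One row per probe flash (onset = first bin of a run of consecutive
#' bins with the same probe on).
#'
#' @param trials a [trial_set()].
#' @return tibble with `trial_id`, `probe`, `onset` (ms from saccade),
#'   `duration` (ms).
#' @export
stimulus_events <- function(trials) {
  t_axis <- trials$t_axis
  purrr::map_dfr(trials$trials, function(tr) {
    r <- rle(ifelse(tr$valid, tr$probe, NA_integer_))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    tibble::tibble(trial_id = tr$trial_id,
                   probe = r$values[keep],
                   onset = t_axis[starts[keep]],
                   duration = r$lengths[keep])
  })
}

#' Spike events of a trial set
#' @param trials a [trial_set()].
#' @return tibble with `trial_id`, `time` (ms from saccade onset).
#' @export
spike_events <- function(trials) {
  t_axis <- trials$t_axis
  purrr::map_dfr(trials$trials, function(tr) {
    tibble::tibble(trial_id = tr$trial_id,
                   time = t_axis[which(tr$spikes == 1L & tr$valid)])
  })
}
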