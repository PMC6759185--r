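#' Read and write trial sets on disk
#'
#' A trial set is stored as three plain-text files under one directory:
#' `header.json` (schema version, grid geometry, time axis, per-trial
#' ids, saccade offsets and validity spans), `stimuli.csv` (one row per
#' probe flash: `trial_id, probe_row, probe_col, onset_ms, duration_ms`)
#' and `spikes.csv` (`trial_id, spike_time_ms`).  The round trip is
#' bit-exact for 1 ms binary data.
#'
#' @param trials a [trial_set()].
#' @param path directory to write into (created if missing).
#' @return `write_trial_set()` returns `path` invisibly;
#'   `read_trial_set()` returns a [trial_set()].
#' @export
write_trial_set <- function(trials, path) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- trials$grid
  valid_spans <- lapply(trials$trials, function(tr) {
    w <- which(tr$valid)
    if (length(w) == 0) c(NA_integer_, NA_integer_)
    else c(trials$t_axis[min(w)], trials$t_axis[max(w)])
  })
  header <- list(
    schema = "perisacc-trialset-1",
    grid = list(n_rows = g$n_rows, n_cols = g$n_cols, origin = g$origin,
                dx = g$dx, dy = g$dy, fp = g$fp, st = g$st),
    t_axis = list(t_min = min(trials$t_axis), t_max = max(trials$t_axis)),
    trials = lapply(seq_along(trials$trials), function(i) {
      tr <- trials$trials[[i]]
      list(trial_id = tr$trial_id,
           saccade_offset = tr$saccade_offset %||% NA,
           valid = valid_spans[[i]])
    }))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  ev <- stimulus_events(trials)
  rc <- probe_rowcol(g, ev$probe)
  readr::write_csv(tibble::tibble(trial_id = ev$trial_id,
                                  probe_row = rc[, "row"],
                                  probe_col = rc[, "col"],
                                  onset_ms = ev$onset,
                                  duration_ms = ev$duration),
                   file.path(path, "stimuli.csv"))
  sp <- spike_events(trials)
  readr::write_csv(tibble::tibble(trial_id = sp$trial_id,
                                  spike_time_ms = sp$time),
                   file.path(path, "spikes.csv"))
  invisible(path)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  if (!identical(header$schema, "perisacc-trialset-1")) {
    stop("unrecognized trial-set schema: ", header$schema, call. = FALSE)
  }
  hg <- header$grid
  grid <- probe_grid(hg$n_rows, hg$n_cols, origin = hg$origin,
                     dx = hg$dx, dy = hg$dy, fp = hg$fp, st = hg$st)
  t_axis <- seq(header$t_axis$t_min, header$t_axis$t_max)
  n_t <- length(t_axis)
  stim <- readr::read_csv(file.path(path, "stimuli.csv"),
                          show_col_types = FALSE)
  spik <- readr::read_csv(file.path(path, "spikes.csv"),
                          show_col_types = FALSE)
  meta <- header$trials
  trs <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$trial_id[i]
    probe <- rep(NA_integer_, n_t)
    se <- stim[stim$trial_id == id, ]
    if (nrow(se) > 0) {
      pid <- probe_id(grid, se$probe_row, se$probe_col)
      for (k in seq_len(nrow(se))) {
        idx <- match(se$onset_ms[k], t_axis) + seq_len(se$duration_ms[k]) - 1L
        bad <- idx < 1 | idx > n_t
        if (any(bad) || any(!is.na(probe[idx]))) {
          stop(sprintf(
            "trial %s: overlapping or out-of-axis stimulus at onset %d",
            id, se$onset_ms[k]), call. = FALSE)
        }
        probe[idx] <- pid[k]
      }
    }
    spikes <- integer(n_t)
    st_times <- spik$spike_time_ms[spik$trial_id == id]
    spikes[match(st_times, t_axis)] <- 1L
    valid <- rep(FALSE, n_t)
    vs <- meta$valid[[i]]
    if (!anyNA(vs)) valid[t_axis >= vs[1] & t_axis <= vs[2]] <- TRUE
    list(trial_id = id, probe = probe, spikes = spikes, valid = valid,
         saccade_offset = meta$saccade_offset[i])
  })
  trial_set(grid, trs, t_axis)
}
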