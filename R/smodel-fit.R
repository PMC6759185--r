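#' Train/validation/test split of trials
#'
#' @param n_trials number of trials to split.
#' @param fractions length-3 fractions for train, validation and test
#'   (default 35/30/35 %).
#' @param seed integer seed.
#' @return list of class `fit_split` with disjoint integer index vectors
#'   `train`, `validation`, `test`.
#' @export
fit_split <- function(n_trials, fractions = c(0.35, 0.30, 0.35), seed = 1L) {
  if (length(fractions) != 3 || any(fractions < 0) || sum(fractions) > 1 + 1e-9) {
    stop("`fractions` must be three non-negative values summing to <= 1",
         call. = FALSE)
  }
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(n_trials)
  n_tr <- round(fractions[1] * n_trials)
  n_va <- round(fractions[2] * n_trials)
  n_te <- min(n_trials - n_tr - n_va, round(fractions[3] * n_trials))
  structure(list(train = sort(idx[seq_len(n_tr)]),
                 validation = sort(idx[n_tr + seq_len(n_va)]),
                 test = sort(idx[n_tr + n_va + seq_len(n_te)]),
                 fractions = fractions, seed = seed),
            class = "fit_split")
}

# Stacked design over the valid bins of all trials:
#  uconv [rows, n_p * n_i]  delay-basis-convolved stimulus indicators
#  V     [rows, n_j]        time basis at the bin time
#  O     [rows, n_j_off]    offset basis
#  Hconv [rows, n_i_h]      post-spike-basis-convolved spike history
#  spikes, trial (index), rows_of_trial
precompute_design <- function(trials, bases, config) {
  t_axis <- trials$t_axis
  n_t <- length(t_axis)
  U <- bases$stim$delay$X            # n_tau x n_i (lattice 1..tau_max)
  tau_axis <- bases$stim$delay$at
  n_i <- ncol(U)
  n_p <- n_probes(trials$grid)
  Vfull <- eval_basis(bases$stim$time, t_axis)
  Ofull <- eval_basis(bases$offset, t_axis)
  Hfull <- bases$postspike
  H <- eval_basis(Hfull, seq_len(ceiling(max(Hfull$knots))))
  n_ih <- ncol(H)

  per_trial <- lapply(seq_along(trials$trials), function(ti) {
    tr <- trials$trials[[ti]]
    uc <- matrix(0, nrow = n_t, ncol = n_p * n_i)
    probe <- tr$probe
    for (k in seq_along(tau_axis)) {
      tau <- tau_axis[k]
      tt <- which(seq_len(n_t) > tau)
      src <- probe[tt - tau]
      on <- !is.na(src)
      if (!any(on)) next
      tt <- tt[on]; src <- src[on]
      for (i in seq_len(n_i)) {
        u <- U[k, i]
        if (u == 0) next
        cols <- (src - 1L) * n_i + i
        idx <- cbind(tt, cols)
        uc[idx] <- uc[idx] + u
      }
    }
    hc <- matrix(0, nrow = n_t, ncol = n_ih)
    sp <- which(tr$spikes == 1L)
    for (s in sp) {
      rng <- (s + 1L):min(n_t, s + nrow(H))
      if (s + 1L > n_t) next
      hc[rng, ] <- hc[rng, ] + H[seq_along(rng), ]
    }
    v <- which(tr$valid)
    list(rows = v, uconv = uc[v, , drop = FALSE],
         hconv = hc[v, , drop = FALSE], spikes = tr$spikes[v],
         tsel = v)
  })
  rows_of_trial <- vector("list", length(per_trial))
  off <- 0L
  for (i in seq_along(per_trial)) {
    n <- length(per_trial[[i]]$rows)
    rows_of_trial[[i]] <- off + seq_len(n)
    off <- off + n
  }
  tsel <- unlist(lapply(per_trial, `[[`, "tsel"))
  list(
    uconv = do.call(rbind, lapply(per_trial, `[[`, "uconv")),
    hconv = do.call(rbind, lapply(per_trial, `[[`, "hconv")),
    V = Vfull[tsel, , drop = FALSE],
    O = Ofull[tsel, , drop = FALSE],
    spikes = unlist(lapply(per_trial, `[[`, "spikes")),
    trial = rep(seq_along(per_trial),
                vapply(rows_of_trial, length, integer(1))),
    rows_of_trial = rows_of_trial,
    n_p = n_p, n_i = n_i, n_j = ncol(Vfull))
}

#' Parameter-selection screen for the stimulus coefficients
#'
#' Each stimulus coefficient is fit alone (single-coefficient model with
#' the baseline `b0`, no history, no offset) by maximum likelihood on
#' many resampled subsets of the trials, once against the recorded spike
#' trains and once against a shuffled-response control in which whole
#' spike trains are permuted across trials.  A coefficient is retained
#' when the mean of its resample distribution differs from the control
#' mean by at least `threshold` control standard deviations; all other
#' coefficients are frozen at zero.
#'
#' @param trials a [trial_set()].
#' @param config an [smodel_config()].
#' @param seed integer seed for resampling and shuffling.
#' @param design optional precomputed design (internal reuse).
#' @return list with `mask` (logical array `[n_probes, n_i, n_j]`) and
#'   `stats` (tibble: probe, i, j, mu, mu_bar, sigma_bar, retained).
#' @export
select_parameters <- function(trials, config = smodel_config(), seed = 1L,
                              design = NULL) {
  bases <- build_bases(config)
  if (is.null(design)) design <- precompute_design(trials, bases, config)
  n_p <- design$n_p; n_i <- design$n_i; n_j <- design$n_j
  n_tr <- n_trials(trials)
  if (sum(design$spikes) == 0) {
    warning("all spike trains are empty; selection mask is empty")
    return(list(mask = array(FALSE, dim = c(n_p, n_i, n_j)),
                stats = tibble::tibble()))
  }
  rates <- list(r0 = config$r0, rmax = config$rmax)
  if (is.null(rates$r0) || is.null(rates$rmax)) {
    emp <- empirical_rates(trials, config$rmax_fwhm_ms)
    rates$r0 <- rates$r0 %||% emp$r0
    rates$rmax <- rates$rmax %||% emp$rmax
  }
  b0 <- stats::qlogis(rates$r0 / rates$rmax)
  delta_s <- config$delta_ms / 1000
  R <- config$screen_resamples
  if (R < 2) stop("need at least 2 screen resamples", call. = FALSE)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n_sub <- max(2L, round(config$screen_frac * n_tr))
  est_real <- array(NA_real_, dim = c(R, n_p, n_i * n_j))
  est_ctrl <- array(NA_real_, dim = c(R, n_p, n_i * n_j))
  spikes_by_trial <- split(design$spikes, design$trial)
  for (k in seq_len(R)) {
    sub <- sort(sample.int(n_tr, n_sub))
    rows <- unlist(design$rows_of_trial[sub])
    perm <- sample.int(n_tr)
    r_real <- design$spikes[rows]
    # shuffled control: spike train of a permuted trial, truncated or
    # padded to this trial's valid span
    r_ctrl <- unlist(lapply(sub, function(tr) {
      src <- spikes_by_trial[[perm[tr]]]
      n <- length(design$rows_of_trial[[tr]])
      if (length(src) >= n) src[seq_len(n)] else c(src, integer(n - length(src)))
    }))
    thin <- max(1L, as.integer(config$screen_thin %||% 1L))
    if (thin > 1L) {
      sub_rows <- seq(1L, length(rows), by = thin)
      rows <- rows[sub_rows]
      r_real <- r_real[sub_rows]
      r_ctrl <- r_ctrl[sub_rows]
    }
    V <- design$V[rows, , drop = FALSE]
    for (p in seq_len(n_p)) {
      Ub <- design$uconv[rows, (p - 1L) * n_i + seq_len(n_i), drop = FALSE]
      it <- as.integer(config$screen_iters %||% 8L)
      est_real[k, p, ] <- newton_screen_cpp(Ub, V, r_real, b0,
                                            rates$rmax, delta_s, it)
      est_ctrl[k, p, ] <- newton_screen_cpp(Ub, V, r_ctrl, b0,
                                            rates$rmax, delta_s, it)
    }
  }
  mu <- apply(est_real, c(2, 3), mean)
  mu_bar <- apply(est_ctrl, c(2, 3), mean)
  sig_bar <- apply(est_ctrl, c(2, 3), stats::sd)
  keep <- ifelse(sig_bar > 0,
                 abs(mu - mu_bar) >= config$screen_threshold * sig_bar,
                 abs(mu - mu_bar) > 0)
  # flat index (i,j) runs delay-fastest: column (j-1)*n_i + i
  mask <- array(FALSE, dim = c(n_p, n_i, n_j))
  stats_tb <- tibble::tibble(
    probe = rep(seq_len(n_p), times = n_i * n_j),
    i = rep(rep(seq_len(n_i), each = n_p), times = n_j),
    j = rep(seq_len(n_j), each = n_p * n_i),
    mu = NA_real_, mu_bar = NA_real_, sigma_bar = NA_real_,
    retained = NA)
  for (j in seq_len(n_j)) for (i in seq_len(n_i)) {
    fc <- (j - 1L) * n_i + i
    mask[, i, j] <- keep[, fc]
    sel <- stats_tb$i == i & stats_tb$j == j
    stats_tb$mu[sel] <- mu[, fc]
    stats_tb$mu_bar[sel] <- mu_bar[, fc]
    stats_tb$sigma_bar[sel] <- sig_bar[, fc]
    stats_tb$retained[sel] <- keep[, fc]
  }
  list(mask = mask, stats = stats_tb, n_resamples = R)
}

# log-likelihood from a generator signal
ll_from_gen <- function(g, r, rmax, delta_s, eps) {
  lam <- rmax * stats::plogis(g)
  ld <- lam * delta_s
  sum(r * log(pmax(ld, eps)) - ld)
}

# dLL/dg
ll_weight <- function(g, r, rmax, delta_s) {
  lam <- rmax * stats::plogis(g)
  (r - lam * delta_s) * (1 - lam / rmax)
}

rel_rms_change <- function(new, old) {
  denom <- sqrt(mean(old^2))
  if (denom < 1e-12) denom <- 1e-12
  sqrt(mean((new - old)^2)) / denom
}

#' Fit the S-model by cross-validated block coordinate ascent
#'
#' Implements the fitting schedule: all parameters initialized to a
#' small non-zero value; the screened stimulus coefficients of each
#' probe location updated in turn as one block, then the post-spike
#' block, then the offset block; within a block, quasi-Newton ascent
#' steps on the training likelihood are accepted while the pooled
#' train-plus-validation likelihood improves and the block stops when
#' the relative RMS change of its parameters falls below 1 %; the block
#' cycle repeats until the full parameter vector stops changing.  Test
#' trials are never touched.
#'
#' @param trials a [trial_set()].
#' @param split a [fit_split()]; defaults to a seeded 35/30/35 split.
#' @param config an [smodel_config()].
#' @param mask optional precomputed selection mask; computed by
#'   [select_parameters()] when `NULL`.
#' @param seed integer seed (split and screen derive from it).
#' @param verbose print per-cycle progress.
#' @return a fitted [smodel()]; `meta` carries the split, seeds, the
#'   pooled-likelihood trace and convergence information.
#' @export
fit_smodel <- function(trials, split = NULL, config = smodel_config(),
                       mask = NULL, seed = 1L, verbose = FALSE) {
  if (is.null(split)) split <- fit_split(n_trials(trials), seed = seed)
  bases <- build_bases(config)
  design <- precompute_design(trials, bases, config)
  rates <- list(r0 = config$r0, rmax = config$rmax)
  if (is.null(rates$r0) || is.null(rates$rmax)) {
    emp <- empirical_rates(trials, config$rmax_fwhm_ms)
    rates$r0 <- rates$r0 %||% emp$r0
    rates$rmax <- rates$rmax %||% emp$rmax
  }
  if (rates$r0 <= 0) stop("cannot fit a model to all-zero spike trains",
                          call. = FALSE)
  screen <- NULL
  if (is.null(mask)) {
    screen <- select_parameters(trials, config, seed = seed + 1L,
                                design = design)
    mask <- screen$mask
  }
  n_p <- design$n_p; n_i <- design$n_i; n_j <- design$n_j
  b0 <- stats::qlogis(rates$r0 / rates$rmax)
  delta_s <- config$delta_ms / 1000
  eps <- config$eps
  rows_tr <- unlist(design$rows_of_trial[split$train])
  rows_va <- unlist(design$rows_of_trial[split$validation])
  rows_po <- c(rows_tr, rows_va)
  r_tr <- design$spikes[rows_tr]
  r_po <- design$spikes[rows_po]
  V_tr <- design$V[rows_tr, , drop = FALSE]
  V_po <- design$V[rows_po, , drop = FALSE]
  O_tr <- design$O[rows_tr, , drop = FALSE]
  O_po <- design$O[rows_po, , drop = FALSE]
  H_tr <- design$hconv[rows_tr, , drop = FALSE]
  H_po <- design$hconv[rows_po, , drop = FALSE]
  n_ih <- ncol(H_tr); n_jo <- ncol(O_tr)

  if (!any(mask)) {
    m <- smodel(array(0, dim = c(n_p, n_i, n_j)), numeric(n_ih),
                numeric(n_jo), rates$r0, rates$rmax, config, trials$grid,
                mask = mask,
                meta = list(split = split, seed = seed, screen = screen,
                            note = "empty selection mask: baseline-only model"))
    return(m)
  }

  kappa <- array(0, dim = c(n_p, n_i, n_j))
  kappa[mask] <- config$init
  eta <- rep(config$init, n_ih)
  beta <- rep(config$init, n_jo)

  Ub_tr <- lapply(seq_len(n_p), function(p)
    design$uconv[rows_tr, (p - 1L) * n_i + seq_len(n_i), drop = FALSE])
  Ub_po <- lapply(seq_len(n_p), function(p)
    design$uconv[rows_po, (p - 1L) * n_i + seq_len(n_i), drop = FALSE])

  stim_part <- function(Ub, V, K) rowSums((Ub %*% K) * V)
  stim_tr <- lapply(seq_len(n_p), function(p)
    stim_part(Ub_tr[[p]], V_tr, matrix(kappa[p, , ], n_i)))
  stim_po <- lapply(seq_len(n_p), function(p)
    stim_part(Ub_po[[p]], V_po, matrix(kappa[p, , ], n_i)))
  hist_tr <- -as.vector(H_tr %*% eta^2)
  hist_po <- -as.vector(H_po %*% eta^2)
  off_shift <- 0
  off_tr <- as.vector(O_tr %*% beta)
  off_po <- as.vector(O_po %*% beta)
  g_tr <- Reduce(`+`, stim_tr) + hist_tr + off_tr + b0
  g_po <- Reduce(`+`, stim_po) + hist_po + off_po + b0

  pooled_ll <- ll_from_gen(g_po, r_po, rates$rmax, delta_s, eps)
  ll_trace <- pooled_ll

  # validation-guarded block update by iteratively reweighted least
  # squares (Fisher scoring through the sigmoid link): damped Newton
  # ascent steps on the training likelihood, with step halving, keeping
  # the iterate with the best pooled train+validation likelihood; a
  # block stops when the training objective stalls or the relative RMS
  # parameter change falls below block_tol.  The generator is linear in
  # the block parameters (X theta + rest); for the post-spike block the
  # linear parameter is zeta = eta^2 >= 0 (projected steps).
  # `intercept = TRUE` augments the block with a free constant column:
  # the stimulus columns and the baseline are strongly coupled (a ridge
  # in the likelihood), and letting each block adjust the constant
  # jointly removes the zigzag of pure coordinate ascent.  The
  # accumulated constant is folded into the offset coefficients at the
  # end (B-splines form a partition of unity on the interior span, so a
  # uniform shift of beta adds exactly that constant to b(t)).
  irls_block <- function(X_tr, X_po, theta, g_rest_tr, g_rest_po,
                         nonneg = FALSE, negate = FALSE,
                         intercept = FALSE) {
    sgn <- if (negate) -1 else 1
    if (intercept) {
      X_tr <- cbind(X_tr, sgn * 1)
      X_po <- cbind(X_po, sgn * 1)
      theta <- c(theta, 0)
    }
    stim <- sgn * as.vector(X_tr %*% theta)
    ll_tr <- ll_from_gen(g_rest_tr + stim, r_tr, rates$rmax, delta_s, eps)
    pooled_of <- function(th) {
      ll_from_gen(g_rest_po + sgn * as.vector(X_po %*% th), r_po,
                  rates$rmax, delta_s, eps)
    }
    best <- theta
    best_po <- pooled_of(theta)
    for (it in seq_len(config$max_block_steps)) {
      g <- g_rest_tr + stim
      lam <- rates$rmax * stats::plogis(g)
      q <- 1 - lam / rates$rmax
      w1 <- (r_tr - lam * delta_s) * q * sgn
      W <- lam * delta_s * q^2
      grad <- as.vector(crossprod(X_tr, w1))
      Hw <- crossprod(X_tr, X_tr * W)
      # proportional ridge pins data-starved directions near zero
      # (near-singular curvature would otherwise launch huge steps along
      # basis functions the stimulus stream barely samples)
      Hw <- Hw + diag(1e-4 * max(diag(Hw), 1e-12), length(theta))
      step <- tryCatch(solve(Hw, grad),
                       error = function(e) grad / pmax(diag(Hw), 1e-12))
      mx <- max(abs(step))
      if (mx > config$step_cap) step <- step * (config$step_cap / mx)
      s <- 1
      repeat {
        cand <- theta + s * step
        if (nonneg) cand <- pmax(cand, 0)
        stim_c <- sgn * as.vector(X_tr %*% cand)
        ll_c <- ll_from_gen(g_rest_tr + stim_c, r_tr, rates$rmax,
                            delta_s, eps)
        if (is.finite(ll_c) && ll_c > ll_tr || s < 1 / 128) break
        s <- s / 2
      }
      if (!is.finite(ll_c)) {
        stop("non-finite likelihood during block ascent", call. = FALSE)
      }
      if (ll_c <= ll_tr + 1e-8) break
      changed <- rel_rms_change(cand, theta)
      theta <- cand
      stim <- stim_c
      ll_tr <- ll_c
      po <- pooled_of(theta)
      if (po > best_po + 1e-9) {
        best <- theta
        best_po <- po
      }
      if (changed < config$block_tol) break
    }
    list(theta = best, ll = best_po)
  }

  probe_blocks <- which(vapply(seq_len(n_p),
                               function(p) any(mask[p, , ]), logical(1)))
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    par_before <- c(kappa[mask], eta, beta, off_shift)
    for (p in probe_blocks) {
      sel <- which(mask[p, , ])
      g_rest_tr <- g_tr - stim_tr[[p]]
      g_rest_po <- g_po - stim_po[[p]]
      # explicit design columns of the selected (i, j) pairs
      ij <- arrayInd(sel, c(n_i, n_j))
      X_tr <- Ub_tr[[p]][, ij[, 1], drop = FALSE] *
        V_tr[, ij[, 2], drop = FALSE]
      X_po <- Ub_po[[p]][, ij[, 1], drop = FALSE] *
        V_po[, ij[, 2], drop = FALSE]
      ll_before <- pooled_ll
      res <- irls_block(X_tr, X_po, kappa[p, , ][sel],
                        g_rest_tr, g_rest_po, intercept = TRUE)
      if (isTRUE(getOption("perisacc.debug"))) {
        message(sprintf("  probe %d: pooled %.2f -> %.2f (gain %.3f)",
                        p, ll_before, res$ll, res$ll - ll_before))
      }
      icpt <- res$theta[length(res$theta)]
      K <- matrix(0, n_i, n_j)
      K[sel] <- res$theta[-length(res$theta)]
      kappa[p, , ] <- K
      off_shift <- off_shift + icpt
      off_tr <- off_tr + icpt
      off_po <- off_po + icpt
      stim_tr[[p]] <- stim_part(Ub_tr[[p]], V_tr, K)
      stim_po[[p]] <- stim_part(Ub_po[[p]], V_po, K)
      g_tr <- g_rest_tr + stim_tr[[p]] + icpt
      g_po <- g_rest_po + stim_po[[p]] + icpt
      pooled_ll <- res$ll
    }
    # post-spike block, in zeta = eta^2 >= 0 (g linear in -zeta)
    g_rest_tr <- g_tr - hist_tr
    g_rest_po <- g_po - hist_po
    res <- irls_block(H_tr, H_po, eta^2, g_rest_tr, g_rest_po,
                      nonneg = TRUE, negate = TRUE)
    eta <- sqrt(res$theta)
    hist_tr <- -as.vector(H_tr %*% eta^2)
    hist_po <- -as.vector(H_po %*% eta^2)
    g_tr <- g_rest_tr + hist_tr
    g_po <- g_rest_po + hist_po
    pooled_ll <- res$ll
    # offset block (the accumulated intercept rides separately in
    # off_shift and stays out of the basis part being refit)
    g_rest_tr <- g_tr - (off_tr - off_shift)
    g_rest_po <- g_po - (off_po - off_shift)
    res <- irls_block(O_tr, O_po, beta, g_rest_tr, g_rest_po)
    beta <- res$theta
    off_tr <- as.vector(O_tr %*% beta) + off_shift
    off_po <- as.vector(O_po %*% beta) + off_shift
    g_tr <- g_rest_tr + (off_tr - off_shift)
    g_po <- g_rest_po + (off_po - off_shift)
    pooled_ll <- res$ll
    ll_trace <- c(ll_trace, pooled_ll)
    par_after <- c(kappa[mask], eta, beta, off_shift)
    delta <- rel_rms_change(par_after, par_before)
    if (verbose) {
      message(sprintf("cycle %d: pooled LL %.2f, rel change %.2e",
                      cycles, pooled_ll, delta))
    }
    if (delta < config$outer_tol || cycles >= config$max_cycles) break
  }

  smodel(kappa, eta, beta + off_shift, rates$r0, rates$rmax, config, trials$grid,
         mask = mask,
         meta = list(split = split, seed = seed, screen = screen,
                     ll_trace = ll_trace, cycles = cycles,
                     converged = cycles < config$max_cycles))
}

#' @export
predict.smodel <- function(object, trials,
                           history = c("true", "none", "simulated"),
                           seed = NULL, ...) {
  cif(object, trials, history = match.arg(history), seed = seed)
}

#' @export
tidy.smodel <- function(x, ...) {
  d <- dim(x$kappa)
  rc <- probe_rowcol(x$grid, seq_len(d[1]))
  kap <- tibble::tibble(
    term = "kappa",
    probe = rep(seq_len(d[1]), times = d[2] * d[3]),
    row = rep(rc[, "row"], times = d[2] * d[3]),
    col = rep(rc[, "col"], times = d[2] * d[3]),
    i = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    j = rep(seq_len(d[3]), each = d[1] * d[2]),
    estimate = as.vector(x$kappa),
    selected = as.vector(x$mask))
  kap <- kap[kap$selected, , drop = FALSE]
  other <- tibble::tibble(
    term = c(rep("eta", length(x$eta)), rep("beta", length(x$beta)), "b0"),
    probe = NA_integer_, row = NA_integer_, col = NA_integer_,
    i = c(seq_along(x$eta), rep(NA_integer_, length(x$beta)), NA_integer_),
    j = c(rep(NA_integer_, length(x$eta)), seq_along(x$beta), NA_integer_),
    estimate = c(x$eta, x$beta, x$b0),
    selected = TRUE)
  dplyr::bind_rows(kap, other)
}

#' @export
glance.smodel <- function(x, ...) {
  tibble::tibble(
    n_probes = dim(x$kappa)[1],
    n_selected = sum(x$mask),
    r0 = x$r0, rmax = x$rmax,
    cycles = x$meta$cycles %||% NA_integer_,
    converged = x$meta$converged %||% NA,
    pooled_ll = if (!is.null(x$meta$ll_trace))
      utils::tail(x$meta$ll_trace, 1) else NA_real_)
}
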