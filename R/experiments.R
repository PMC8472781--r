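#' Classify the attractor a trajectory settled into
#'
#' Operates on the time-averaged counts over a trajectory's tail window
#' (see `tail_frac` in [ssa_simulate()]). With Hi/Lo clamps `n_hi`/`n_lo`
#' and margin \eqn{m}: label `S_Xi` when the mean of X(i) exceeds
#' `n_lo + m (n_hi - n_lo)` while every other X stays below
#' `n_lo + (1-m)(n_hi - n_lo)`; `S_Low` when all X stay below the low
#' threshold; `Undecided` otherwise. The default margin 0.5 makes both
#' thresholds the midpoint of the clamp gap, so the rule is scale-free and
#' symmetric across species.
#'
#' @param tail_means Named vector of time-averaged counts (or a
#'   `crn_trajectory` with a `tail_mean` component).
#' @param spec The network the trajectory was simulated on.
#' @param margin Classification margin in (0, 1], default 0.5.
#' @return One of `"S_Low"`, `"S_X<i>"`, `"Undecided"`.
#' @export
classify_attractor <- function(tail_means, spec, margin = 0.5) {
  if (inherits(tail_means, "crn_trajectory")) {
    # trajectories without an accumulated tail window (zero steps, or
    # absorbed before it opened) are judged by their final state
    tail_means <- if (is.null(tail_means$tail_mean))
      tail_means$final_state$counts else tail_means$tail_mean
  }
  if (!length(tail_means)) stop("empty tail window")
  dc <- driving_clamps(spec)
  xs <- x_species(spec)
  hi_thr <- dc$n_lo + margin * (dc$n_hi - dc$n_lo)
  lo_thr <- dc$n_lo + (1 - margin) * (dc$n_hi - dc$n_lo)
  x <- tail_means[xs]
  if (all(x < lo_thr)) return("S_Low")
  for (i in seq_along(xs)) {
    if (x[[i]] > hi_thr && all(x[-i] < lo_thr)) return(paste0("S_", xs[i]))
  }
  "Undecided"
}

# "near_low" | "near_high:2" | "random" -> list(mode, target, label)
parse_init_mode <- function(mode) {
  parts <- strsplit(mode, ":", fixed = TRUE)[[1]]
  target <- if (length(parts) > 1) as.integer(parts[[2]]) else NULL
  label <- switch(parts[[1]],
                  near_low = "S_Low",
                  near_high = paste0("S_X", target),
                  random = NA_character_,
                  stop("unknown init mode: ", mode))
  list(mode = parts[[1]], target = target, label = label)
}

#' Attractor census from random initial conditions
#'
#' Simulates `n_inits` trajectories from dynamic counts drawn uniformly on
#' `[n_lo, n_hi]`, classifies each tail window and tabulates the labels.
#'
#' @param spec A Hi/Lo-driven network.
#' @param n_inits Number of random initial states.
#' @param n_steps Events per trajectory.
#' @param base_seed Base seed (drives both the initial draws and the SSA
#'   streams).
#' @param tail_frac,margin Passed to the simulation and classifier.
#' @return A `crn_census` list: `labels` (per-trajectory), `histogram`
#'   (table over observed labels, Undecided included), provenance fields.
#' @export
attractor_census <- function(spec, n_inits, n_steps, base_seed,
                             tail_frac = 0.1, margin = 0.5) {
  inits <- initial_states(spec, "random", n_copies = n_inits,
                          seed = trajectory_seed(base_seed, 0))
  labels <- character(n_inits)
  for (i in seq_len(n_inits)) {
    tr <- ssa_simulate(spec, inits[[i]], n_steps,
                       seed = trajectory_seed(base_seed, i),
                       tail_frac = tail_frac)
    labels[i] <- classify_attractor(tr, spec, margin)
  }
  structure(list(labels = labels, histogram = table(labels),
                 n_inits = n_inits, n_steps = n_steps, base_seed = base_seed),
            class = "crn_census")
}

#' @export
print.crn_census <- function(x, ...) {
  cat("<crn_census> ", x$n_inits, " random inits x ", x$n_steps, " events\n",
      sep = "")
  print(x$histogram)
  invisible(x)
}

#' Stability sweep over the driving gradient
#'
#' For each clamp count on the grid and each initialization mode, simulates
#' `n_traj` trajectories initialized near the corresponding steady state and
#' reports the retained fraction: the share of trajectories whose tail window
#' still classifies into the initialized label. The retained fraction is the
#' stability proxy from which the critical driving concentration is read off.
#'
#' @param network_fn Function `n_hi -> crn_network` (e.g.
#'   `function(h) build_wta(wta_params(n_hi = h))`).
#' @param n_hi_grid Ascending grid of Hi clamp counts.
#' @param init_modes Character vector of init modes, e.g.
#'   `c("near_low", "near_high:1")`.
#' @param n_traj Trajectories per grid point and mode.
#' @param n_steps Events per trajectory.
#' @param base_seed Integer base seed; the whole sweep is reproducible from
#'   it.
#' @param tail_frac,margin Classification controls.
#' @return A `crn_stability_curve` data.frame with columns `n_hi`,
#'   `init_mode`, `label`, `retained`, `n_retained`, `n_undecided`, `n_traj`;
#'   provenance in attributes.
#' @export
stability_sweep <- function(network_fn, n_hi_grid, init_modes, n_traj,
                            n_steps, base_seed, tail_frac = 0.1,
                            margin = 0.5) {
  stopifnot(!is.unsorted(n_hi_grid))
  rows <- list()
  run <- 0L
  for (h in n_hi_grid) {
    spec <- network_fn(h)
    for (md in init_modes) {
      pm <- parse_init_mode(md)
      init <- initial_states(spec, pm$mode, target = pm$target)[[1]]
      labs <- character(n_traj)
      for (i in seq_len(n_traj)) {
        run <- run + 1L
        tr <- ssa_simulate(spec, init, n_steps,
                           seed = trajectory_seed(base_seed, run),
                           tail_frac = tail_frac)
        labs[i] <- classify_attractor(tr, spec, margin)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        n_hi = h, init_mode = md, label = pm$label,
        retained = mean(labs == pm$label),
        n_retained = sum(labs == pm$label),
        n_undecided = sum(labs == "Undecided"),
        n_traj = n_traj, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_steps") <- n_steps
  attr(out, "base_seed") <- base_seed
  class(out) <- c("crn_stability_curve", "data.frame")
  out
}

#' Critical driving concentration from a stability curve
#'
#' Linearly interpolates the lowest upward crossing of the retained fraction
#' through `threshold` along the Hi-clamp grid. With `threshold = 0` the
#' convention is the lowest grid point with a positive retained fraction.
#'
#' @param curve A `crn_stability_curve` (or compatible data.frame with
#'   columns `n_hi`, `init_mode`, `retained`).
#' @param init_mode Which initialization mode's curve to use.
#' @param threshold Retained-fraction level defining criticality (default
#'   0.5).
#' @return List with `n_crit` (NA when no crossing), `out_of_range` flag and
#'   the bracketing grid points.
#' @export
critical_concentration <- function(curve, init_mode, threshold = 0.5) {
  d <- curve[curve$init_mode == init_mode, c("n_hi", "retained")]
  if (!nrow(d)) stop("no rows for init mode ", init_mode)
  d <- d[order(d$n_hi), ]
  if (threshold == 0) {
    pos <- which(d$retained > 0)
    if (!length(pos))
      return(list(n_crit = NA_real_, out_of_range = TRUE, bracket = NULL))
    return(list(n_crit = d$n_hi[pos[1]], out_of_range = FALSE,
                bracket = d$n_hi[pos[1]]))
  }
  below <- d$retained < threshold
  above <- d$retained >= threshold
  cross <- which(below[-nrow(d)] & above[-1])
  if (!length(cross))
    return(list(n_crit = NA_real_, out_of_range = TRUE, bracket = NULL))
  i <- cross[1]
  x0 <- d$n_hi[i]; x1 <- d$n_hi[i + 1]
  y0 <- d$retained[i]; y1 <- d$retained[i + 1]
  list(n_crit = x0 + (threshold - y0) / (y1 - y0) * (x1 - x0),
       out_of_range = FALSE, bracket = c(x0, x1))
}

#' Harvest steady-state samples from a stabilized ensemble
#'
#' Runs `n_traj` open-network trajectories from the given initialization,
#' discards the first half of each run as burn-in, keeps only trajectories
#' whose tail window classifies into the target label (the ensemble has
#' converged to the intended state), and collects strided count snapshots
#' from the second half.
#'
#' @param spec Open network.
#' @param init_mode Init mode string, e.g. `"near_high:1"`.
#' @param n_samples Number of steady-state samples wanted.
#' @param n_traj Trajectories to run.
#' @param n_steps Events per trajectory.
#' @param base_seed Integer base seed.
#' @param tail_frac,margin Convergence-check controls.
#' @return List with `states` (list of `crn_state`s, possibly fewer than
#'   `n_samples` if trajectories left the target state) and `n_converged`.
#' @export
harvest_ness_states <- function(spec, init_mode, n_samples, n_traj,
                                n_steps, base_seed, tail_frac = 0.1,
                                margin = 0.5) {
  pm <- parse_init_mode(init_mode)
  init <- initial_states(spec, pm$mode, target = pm$target)[[1]]
  per_traj <- ceiling(n_samples / n_traj)
  # stride so that the second half of the run yields per_traj snapshots
  stride <- max(1L, floor((n_steps / 2) / per_traj))
  states <- list(); n_conv <- 0L
  for (i in seq_len(n_traj)) {
    tr <- ssa_simulate(spec, init, n_steps,
                       seed = trajectory_seed(base_seed, i),
                       record_stride = stride, tail_frac = tail_frac)
    if (classify_attractor(tr, spec, margin) != pm$label) next
    n_conv <- n_conv + 1L
    keep <- which(seq_along(tr$snapshot_times) * stride > n_steps / 2)
    keep <- utils::tail(keep, per_traj)
    for (k in keep)
      states[[length(states) + 1L]] <-
        crn_state(tr$snapshots[k, ], tr$snapshot_times[k])
  }
  if (length(states) > n_samples) states <- states[seq_len(n_samples)]
  list(states = states, n_converged = n_conv, n_traj = n_traj)
}

#' Minimum work-rate along a driving-gradient grid
#'
#' For each Hi clamp count: stabilize an open-network ensemble in the target
#' state, harvest steady-state samples and estimate the minimum work-rate by
#' network closure ([min_workrate()]). Grid points where the target state is
#' not stable enough to harvest from are flagged rather than reported.
#'
#' @inheritParams stability_sweep
#' @param init_mode Target state, e.g. `"near_high:1"`.
#' @param n_samples Steady-state samples per grid point.
#' @param n_events Post-closure events per sample.
#' @param min_converged Minimum fraction of converged trajectories for the
#'   grid point to be reported (default 0.5).
#' @return Data.frame with one row per grid point: `n_hi`, `mean_rate`,
#'   `stderr`, `n_samples`, `n_excluded`, `stable`.
#' @export
workrate_curve <- function(network_fn, n_hi_grid, init_mode, n_samples = 1000,
                           n_traj = 20, n_steps = 50000, n_events = 10,
                           base_seed = 1, tail_frac = 0.1, margin = 0.5,
                           min_converged = 0.5) {
  rows <- lapply(seq_along(n_hi_grid), function(gi) {
    h <- n_hi_grid[gi]
    spec <- network_fn(h)
    hv <- harvest_ness_states(spec, init_mode, n_samples, n_traj, n_steps,
                              base_seed = trajectory_seed(base_seed, gi),
                              tail_frac = tail_frac, margin = margin)
    if (hv$n_converged < ceiling(min_converged * n_traj) ||
        length(hv$states) < n_samples / 2) {
      return(data.frame(n_hi = h, mean_rate = NA_real_, stderr = NA_real_,
                        n_samples = length(hv$states), n_excluded = NA_integer_,
                        stable = FALSE))
    }
    wr <- min_workrate(spec, hv$states, n_events = n_events,
                       base_seed = trajectory_seed(base_seed, 1000L + gi))
    data.frame(n_hi = h, mean_rate = wr$mean_rate, stderr = wr$stderr,
               n_samples = wr$n_trajectories, n_excluded = wr$n_excluded,
               stable = TRUE)
  })
  do.call(rbind, rows)
}

#' Deterministic efficiency of each work-harvesting branch
#'
#' For every Hi clamp on the grid and every branch i of the selection
#' network: solve the deterministic rate equations from the concentration
#' analogue of the near-high(i) initialization, verify a high-X(i) steady
#' state exists there, and compute the transduction efficiency with the
#' direct Hi -> B(i) -> Lo decay pairs as the dissipation channels.
#'
#' @param params A [selection_params()] object (its `n_hi` is overridden by
#'   the grid).
#' @param n_hi_grid Hi clamp counts to evaluate.
#' @param z_eq Equilibrium reference concentration (cancels for these
#'   conserving networks; kept as an explicit knob).
#' @param tol Steady-state residual tolerance.
#' @return Data.frame with columns `n_hi`, `branch`, `eta`, `q_tot`,
#'   `q_diss`, `exists`, `converged`.
#' @export
efficiency_curve <- function(params, n_hi_grid, z_eq = 1, tol = 1e-10) {
  rows <- list()
  for (h in n_hi_grid) {
    p <- params; p$n_hi <- h
    spec <- build_selection(p)
    channels <- c(paste0("synth_B", seq_len(p$n_dynamic)),
                  paste0("bdecay_B", seq_len(p$n_dynamic)))
    dc <- driving_clamps(spec)
    hi_thr <- dc$n_lo + 0.5 * (dc$n_hi - dc$n_lo)
    for (i in seq_len(p$n_dynamic)) {
      init <- initial_states(spec, "near_high", target = i)[[1]]$counts
      ss <- find_steady_state(spec, init, tol = tol)
      conv <- attr(ss, "converged")
      exists <- isTRUE(conv) && ss[[paste0("X", i)]] > hi_thr
      eta <- q_tot <- q_diss <- NA_real_
      if (exists) {
        ef <- efficiency(spec, ss, channels, z_eq = z_eq,
                         ss_tol = max(tol * 100, 1e-8))
        eta <- ef$eta; q_tot <- ef$q_tot; q_diss <- ef$q_diss
      }
      rows[[length(rows) + 1L]] <- data.frame(
        n_hi = h, branch = i, eta = eta, q_tot = q_tot, q_diss = q_diss,
        exists = exists, converged = isTRUE(conv))
    }
  }
  do.call(rbind, rows)
}
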