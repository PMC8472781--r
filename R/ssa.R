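#' Single Gillespie step
#'
#' One iteration of the direct method, in plain R: draws a waiting time from
#' Exponential(a0) where a0 is the total propensity, picks a reaction
#' direction with probability w/a0, and applies the net change (clamped
#' species are re-imposed). Used for contract tests and didactics; long runs
#' go through the compiled core in [ssa_simulate()].
#'
#' @param spec A `crn_network`.
#' @param state A `crn_state` or named count vector.
#' @return A list with `waiting_time`, `pair`, `direction`, `state`
#'   (a `crn_state`), and `absorbed`. When no reaction can fire the state is
#'   absorbing: `waiting_time` is `Inf` and no event is returned.
#' @export
ssa_step <- function(spec, state) {
  comp <- crn_compile(spec)
  counts <- state_counts(spec, state)
  t0 <- if (inherits(state, "crn_state")) state$time else 0
  D <- nrow(comp$nu)
  w <- vapply(seq_len(D), function(d) {
    wd <- comp$kV[d]
    for (i in which(comp$nu[d, ] > 0))
      wd <- wd * falling_factorial(counts[i], comp$nu[d, i])
    wd
  }, numeric(1))
  a0 <- sum(w)
  if (a0 <= 0)
    return(list(waiting_time = Inf, pair = NA_character_,
                direction = NA_character_,
                state = crn_state(counts, t0), absorbed = TRUE))
  dt <- stats::rexp(1, rate = a0)
  d <- sample.int(D, 1, prob = w)
  counts <- counts + comp$dS[d, ]
  list(waiting_time = dt,
       pair = comp$pair_labels[comp$dir_pair[d]],
       direction = if (comp$dir_forward[d]) "forward" else "backward",
       state = crn_state(counts, t0 + dt),
       absorbed = FALSE)
}

#' Derive a per-trajectory seed from a base seed
#'
#' Deterministic SplitMix-style integer mix so ensemble members get
#' independent, reproducible RNG streams. Result is in `[0, 2^31 - 2]`.
#'
#' @param base_seed Integer base seed.
#' @param index Trajectory index (1-based).
#' @export
trajectory_seed <- function(base_seed, index) {
  x <- (as.double(base_seed) * 2654435761 + as.double(index) * 40503) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

#' Simulate a trajectory with the Gillespie direct method
#'
#' Exact stochastic simulation of the network's chemical master equation.
#' Chemostatted species participate in propensities at their clamp counts but
#' are never updated; [close_network()] first if you want them dynamic.
#'
#' @param spec A `crn_network`.
#' @param init Initial `crn_state` or named count vector. Clamped species are
#'   forced to their clamp counts.
#' @param n_steps Maximum number of reaction events.
#' @param seed Integer seed; the run is fully determined by
#'   `(spec, init, seed)`.
#' @param t_max Optional stopping time (default `Inf`); the returned state is
#'   the one occupied at `t_max`.
#' @param record_stride Store a count snapshot every `record_stride` events
#'   (0 = none).
#' @param record_events Store the full event log (times + pair/direction);
#'   intended for short thermodynamic post-processing runs.
#' @param tail_frac Fraction of the final events over which to accumulate the
#'   time-weighted mean counts (0 = off); used by attractor classification.
#' @return A `crn_trajectory` list: `initial_state`, `final_state`,
#'   `n_events`, `absorbed`, `hit_tmax`, `seed`, `tail_mean`, optional
#'   `snapshot_times`/`snapshots`, optional `event_times`/`event_pairs`/
#'   `event_directions`, and the network `fingerprint`.
#' @export
ssa_simulate <- function(spec, init, n_steps, seed, t_max = Inf,
                         record_stride = 0, record_events = FALSE,
                         tail_frac = 0) {
  comp <- crn_compile(spec)
  counts <- state_counts(spec, init)
  t0 <- if (inherits(init, "crn_state")) init$time else 0
  stopifnot(n_steps >= 0, t_max >= t0)
  res <- with_seed(seed, ssa_core(comp$nu, comp$dS, comp$kV, counts, t0,
                                  as.integer(n_steps), t_max,
                                  tail_frac, as.integer(record_stride),
                                  record_events))
  out <- list(
    initial_state = crn_state(counts, t0),
    final_state = crn_state(stats::setNames(res$counts, comp$species), res$time),
    n_events = res$n_events,
    absorbed = res$absorbed,
    hit_tmax = res$hit_tmax,
    seed = seed,
    fingerprint = network_fingerprint(spec))
  if (!is.null(res$tail_mean))
    out$tail_mean <- stats::setNames(res$tail_mean, comp$species)
  if (!is.null(res$snapshots)) {
    colnames(res$snapshots) <- comp$species
    out$snapshot_times <- res$snapshot_times
    out$snapshots <- res$snapshots
  }
  if (record_events) {
    out$event_times <- res$event_times
    out$event_pairs <- comp$pair_labels[comp$dir_pair[res$event_dirs]]
    out$event_directions <- ifelse(comp$dir_forward[res$event_dirs],
                                   "forward", "backward")
  }
  class(out) <- "crn_trajectory"
  out
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat("<crn_trajectory> ", x$n_events, " events, t = ",
      format(x$final_state$time, digits = 6),
      if (x$absorbed) " (absorbed)" else "", "\n", sep = "")
  cat("  final counts:",
      paste(names(x$final_state$counts), x$final_state$counts,
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Replay an event log
#'
#' Applies the logged events to the initial state and returns the sequence of
#' count vectors; used to check that recorded snapshots are consistent with
#' the event log.
#'
#' @param spec A `crn_network`.
#' @param traj A `crn_trajectory` simulated with `record_events = TRUE`.
#' @return Matrix (events + 1) x species of counts, first row the initial state.
#' @export
replay_trajectory <- function(spec, traj) {
  if (is.null(traj$event_pairs)) stop("trajectory has no event log")
  comp <- crn_compile(spec)
  n <- state_counts(spec, traj$initial_state)
  out <- matrix(0, length(traj$event_times) + 1L, length(n),
                dimnames = list(NULL, comp$species))
  out[1L, ] <- n
  for (i in seq_along(traj$event_times)) {
    p <- match(traj$event_pairs[[i]], comp$pair_labels)
    d <- if (traj$event_directions[[i]] == "forward") 2L * p - 1L else 2L * p
    n <- n + comp$dS[d, ]
    out[i + 1L, ] <- n
  }
  out
}

#' Simulate an ensemble of independent trajectories
#'
#' Per-trajectory seeds are derived deterministically from `base_seed` via
#' [trajectory_seed()], so the ensemble is reproducible and members are
#' independent.
#'
#' @param spec A `crn_network`.
#' @param inits List of initial states (recycled if shorter than `n_traj`),
#'   or a single state.
#' @param n_steps Events per trajectory.
#' @param base_seed Integer base seed.
#' @param n_traj Number of trajectories (default `length(inits)`).
#' @param ... Passed to [ssa_simulate()].
#' @return A `crn_ensemble`: list of trajectories plus provenance.
#' @export
ssa_ensemble <- function(spec, inits, n_steps, base_seed,
                         n_traj = NULL, ...) {
  if (inherits(inits, "crn_state") || (is.numeric(inits) && !is.null(names(inits))))
    inits <- list(inits)
  if (is.null(n_traj)) n_traj <- length(inits)
  trajectories <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    init <- inits[[(i - 1L) %% length(inits) + 1L]]
    trajectories[[i]] <- ssa_simulate(spec, init, n_steps,
                                      seed = trajectory_seed(base_seed, i), ...)
  }
  structure(list(trajectories = trajectories,
                 spec_fingerprint = network_fingerprint(spec),
                 base_seed = base_seed),
            class = "crn_ensemble")
}

# evaluate thunk under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# --- chemical master equation oracle -----------------------------------------

#' Enumerate a truncated state space
#'
#' Either a rectangular box `[0, n_max]` per dynamic species (reflecting
#' boundary; transitions leaving the box are dropped) or, for networks whose
#' reaction pairs all conserve total molecule count, the conservative shell of
#' states with a fixed total. Chemostatted species are excluded from the
#' enumeration (they are parameters of the propensities, not state).
#'
#' @param spec A `crn_network`.
#' @param n_max Scalar or per-dynamic-species vector of box caps.
#' @param total If non-`NULL`, enumerate states with this exact total count
#'   instead of the full box.
#' @return Integer matrix, one row per state, columns the dynamic species.
#' @export
enumerate_states <- function(spec, n_max, total = NULL) {
  dyn <- species_names(spec)[!chemostat_mask(spec)]
  m <- length(dyn)
  if (length(n_max) == 1L) n_max <- rep(n_max, m)
  stopifnot(length(n_max) == m)
  if (is.null(total)) {
    if (prod(n_max + 1) > 2e5)
      stop("truncated state space too large (", prod(n_max + 1), " states)")
    g <- do.call(expand.grid, lapply(n_max, function(k) 0:k))
  } else {
    rec <- function(i, left) {
      if (i == m) {
        if (left <= n_max[m]) return(matrix(left, 1, 1)) else return(NULL)
      }
      do.call(rbind, lapply(0:min(left, n_max[i]), function(v) {
        sub <- rec(i + 1L, left - v)
        if (is.null(sub)) return(NULL)
        cbind(v, sub)
      }))
    }
    g <- rec(1L, total)
    if (is.null(g)) stop("no states with the requested total")
  }
  st <- as.matrix(g)
  dimnames(st) <- list(NULL, dyn)
  storage.mode(st) <- "integer"
  st
}

state_keys <- function(states) apply(states, 1L, paste, collapse = ",")

# sparse CME generator on an enumerated space; columns index source states
cme_generator <- function(spec, states) {
  comp <- crn_compile(spec)
  dyn <- colnames(states)
  dyn_idx <- match(dyn, comp$species)
  keys <- state_keys(states)
  lookup <- stats::setNames(seq_along(keys), keys)
  full <- matrix(0, nrow(states), length(comp$species),
                 dimnames = list(NULL, comp$species))
  full[, dyn_idx] <- states
  cm <- comp$chemostatted
  full[, cm] <- matrix(comp$clamps[cm], nrow(states), sum(cm), byrow = TRUE)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  D <- nrow(comp$nu)
  for (d in seq_len(D)) {
    ed <- which(comp$nu[d, ] > 0)
    w <- rep(comp$kV[d], nrow(states))
    for (i in ed) {
      nu_i <- comp$nu[d, i]
      ni <- full[, i]
      f <- rep(1, nrow(states))
      for (r in 0:(nu_i - 1L)) f <- f * pmax(ni - r, 0)
      w <- w * f
    }
    tgt <- states + matrix(comp$dS[d, dyn_idx], nrow(states), length(dyn_idx),
                           byrow = TRUE)
    ok <- w > 0 & apply(tgt >= 0, 1L, all)
    if (!any(ok)) next
    ti <- lookup[state_keys(tgt[ok, , drop = FALSE])]
    inside <- !is.na(ti)
    src <- which(ok)
    # transitions leaving the enumeration are dropped (reflecting boundary)
    ii <- c(ii, ti[inside], src[inside])
    jj <- c(jj, src[inside], src[inside])
    xx <- c(xx, w[ok][inside], -w[ok][inside])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(states), nrow(states)))
}

#' Integrate the chemical master equation on a truncated space
#'
#' Brute-force integration of \eqn{\dot p_n = \sum_\rho [w_{-\rho}(n+S_\rho)
#' p_{n+S_\rho} - w_\rho(n) p_n]} on an enumerated state space. Intended as a
#' small-system oracle for the stochastic simulator, not for production runs.
#'
#' @param spec A `crn_network`.
#' @param init Either a `crn_state`/named count vector (point mass) or a list
#'   `list(states = <matrix>, p = <numeric>)`.
#' @param t_grid Output times (must include the times you want to compare at;
#'   0 is prepended if absent).
#' @param n_max,total Passed to [enumerate_states()] unless `init` supplies
#'   its own enumeration.
#' @return A `crn_cme` list: `states`, `times`, `p` (times x states, each row
#'   renormalized), `mass_error` (max |1 - sum p| before renormalization) and
#'   `boundary_mass` per output time (box mode leak monitor).
#' @export
master_equation_evolve <- function(spec, init, t_grid, n_max = NULL,
                                   total = NULL) {
  if (is.list(init) && !inherits(init, "crn_state") &&
      !is.null(init$states)) {
    states <- init$states
    p0 <- init$p
  } else {
    if (is.null(n_max) && is.null(total))
      stop("supply n_max and/or total to enumerate the state space")
    counts <- state_counts(spec, init)
    dyn <- species_names(spec)[!chemostat_mask(spec)]
    if (is.null(n_max)) n_max <- if (is.null(total)) NULL else total
    states <- enumerate_states(spec, n_max, total = total)
    key <- paste(counts[dyn], collapse = ",")
    i0 <- match(key, state_keys(states))
    if (is.na(i0)) stop("initial state outside the enumerated space")
    p0 <- numeric(nrow(states)); p0[i0] <- 1
  }
  p0 <- p0 / sum(p0)
  Q <- cme_generator(spec, states)
  if (t_grid[1] != 0) t_grid <- c(0, t_grid)
  sol <- deSolve::lsoda(y = p0, times = t_grid,
                        func = function(t, y, parms) list(as.numeric(Q %*% y)),
                        rtol = 1e-10, atol = 1e-12)
  p <- unname(sol[, -1, drop = FALSE])
  mass_error <- max(abs(1 - rowSums(p)))
  if (mass_error > 1e-8)
    warning("probability mass conservation violated: ", mass_error)
  p <- p / rowSums(p)
  caps <- apply(states, 2L, max)
  boundary <- apply(states, 1L, function(s) any(s == caps))
  boundary_mass <- rowSums(p[, boundary, drop = FALSE])
  if (is.null(total) && any(boundary_mass > 1e-6))
    warning("truncation leak: boundary states hold mass ",
            max(boundary_mass))
  structure(list(states = states, times = sol[, 1], p = p,
                 mass_error = mass_error, boundary_mass = boundary_mass),
            class = "crn_cme")
}

#' Export a trajectory to CSV with a JSON sidecar
#'
#' Writes the event log as CSV (columns `time`, `pair`, `direction`, then one
#' column per species with the counts after the event) and, when jsonlite is
#' available, a `<path>.json` sidecar holding the network fingerprint, seed
#' and event count.
#'
#' @param traj A `crn_trajectory` simulated with `record_events = TRUE`.
#' @param spec The network it was simulated on.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, spec, path) {
  states <- replay_trajectory(spec, traj)
  df <- data.frame(time = c(traj$initial_state$time, traj$event_times),
                   pair = c(NA, traj$event_pairs),
                   direction = c(NA, traj$event_directions),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(states))
  utils::write.csv(df, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(fingerprint = traj$fingerprint, seed = traj$seed,
                 n_events = traj$n_events, absorbed = traj$absorbed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
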