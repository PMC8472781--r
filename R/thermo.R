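#' Stochastic Gibbs free energy of a closed-network state
#'
#' With all standard chemical potentials at zero, the free energy of a count
#' vector reduces to the combinatorial term \eqn{g(n) = kT \sum_S \ln n(S)!},
#' evaluated via log-gamma. Every species is included (all are dynamic once
#' the network is closed).
#'
#' @param state A `crn_state` or named (or bare) nonnegative count vector.
#' @return Free energy in kT units (always >= 0).
#' @export
gibbs_free_energy <- function(state) {
  counts <- if (inherits(state, "crn_state")) state$counts else state
  stopifnot(all(counts >= 0))
  sum(lgamma(counts + 1))
}

#' Heat released by a single reaction event
#'
#' For a closed network, the heat delivered to the bath by one event is the
#' free-energy drop \eqn{g(n_{before}) - g(n_{after})}: positive when the
#' event runs downhill, negative for an uphill fluctuation.
#'
#' @param before,after States (or count vectors) differing by one event.
#' @return Heat in kT.
#' @export
event_heat <- function(before, after) {
  gibbs_free_energy(before) - gibbs_free_energy(after)
}

#' Minimum work-rate to maintain a nonequilibrium steady state
#'
#' The least power needed to hold an open network's steady state equals its
#' heat production rate at the instant the driving is switched off. The
#' estimator closes the network (releasing every chemostat, initializing the
#' released species at their clamp counts), runs `n_events` further reaction
#' events from each supplied steady-state sample, and averages the initial
#' relaxation rate \eqn{(g(n(t_0)) - g(n(t_{n})))/(t_{n} - t_0)} over
#' trajectories. Dissipation is reported as positive.
#'
#' @param spec The open `crn_network` whose steady state the samples come
#'   from. Already-closed networks are accepted (useful for equilibrium null
#'   checks).
#' @param ness_states List of `crn_state`s (or count vectors) sampled from
#'   the stabilized open-network ensemble.
#' @param n_events Number of post-closure reaction events (default 10).
#' @param base_seed Integer base seed for the closure trajectories.
#' @return A `crn_workrate` list: `mean_rate`, `stderr`, `n_trajectories`,
#'   `n_events`, `n_excluded` (trajectories absorbing before `n_events`,
#'   excluded from the average), and the per-trajectory `rates`.
#' @export
min_workrate <- function(spec, ness_states, n_events = 10, base_seed = 1) {
  stopifnot(n_events >= 1)
  closed <- if (any(chemostat_mask(spec))) close_network(spec) else spec
  if (inherits(ness_states, "crn_state") ||
      (is.numeric(ness_states) && !is.null(names(ness_states))))
    ness_states <- list(ness_states)
  cl <- clamp_counts(spec)
  rates <- rep(NA_real_, length(ness_states))
  for (i in seq_along(ness_states)) {
    s <- ness_states[[i]]
    counts <- if (inherits(s, "crn_state")) s$counts else s
    # released species start at their clamp counts unless the sample sets them
    init <- state_counts(closed, counts, enforce_clamps = FALSE)
    fill <- setdiff(names(cl)[!is.na(cl)], names(counts))
    init[fill] <- cl[fill]
    tr <- ssa_simulate(closed, crn_state(init, 0), n_steps = n_events,
                       seed = trajectory_seed(base_seed, i))
    if (tr$absorbed || tr$n_events < n_events) next  # excluded, reported below
    dt <- tr$final_state$time
    rates[i] <- (gibbs_free_energy(init) -
                 gibbs_free_energy(tr$final_state)) / dt
  }
  ok <- !is.na(rates)
  if (!any(ok)) stop("all trajectories absorbed before n_events")
  r <- rates[ok]
  structure(list(mean_rate = mean(r),
                 stderr = stats::sd(r) / sqrt(length(r)),
                 n_trajectories = length(r),
                 n_events = n_events,
                 n_excluded = sum(!ok),
                 rates = r),
            class = "crn_workrate")
}

#' @export
print.crn_workrate <- function(x, ...) {
  cat("<crn_workrate> ", format(x$mean_rate, digits = 4), " +/- ",
      format(x$stderr, digits = 3), " kT per unit time (",
      x$n_trajectories, " trajectories, ", x$n_events, " events each",
      if (x$n_excluded > 0) paste0(", ", x$n_excluded, " excluded") else "",
      ")\n", sep = "")
  invisible(x)
}

# deterministic fluxes J+ and J- per pair at a concentration vector
pair_fluxes <- function(spec, conc) {
  conc <- state_counts(spec, conc, enforce_clamps = TRUE)
  P <- length(spec$reactions)
  jf <- numeric(P); jb <- numeric(P)
  for (p in seq_len(P)) {
    r <- spec$reactions[[p]]
    jf[p] <- r$kf * prod(conc[names(r$educts)]^r$educts)
    jb[p] <- r$kb * prod(conc[names(r$products)]^r$products)
  }
  list(jf = jf, jb = jb, conc = conc)
}

#' Deterministic mass-action rate equations
#'
#' Right-hand side of \eqn{\dot c = \sum_\rho S_\rho (J_\rho^+ - J_\rho^-)}
#' with \eqn{J_\rho^\pm = k_{\pm\rho} \prod_i c_i^{\nu_i}}, the large-volume
#' limit of the stochastic kinetics. Rows of chemostatted species are zero
#' (their concentrations are held fixed).
#'
#' @param spec A `crn_network`.
#' @param conc Named nonnegative concentration vector.
#' @return Named vector dc/dt.
#' @export
deterministic_rates <- function(spec, conc) {
  fx <- pair_fluxes(spec, conc)
  comp <- crn_compile(spec)
  J <- fx$jf - fx$jb
  dS <- comp$dS_full[seq(1, nrow(comp$dS_full), by = 2), , drop = FALSE]
  dc <- as.numeric(t(dS) %*% J)
  names(dc) <- comp$species
  dc[comp$chemostatted] <- 0
  dc
}

#' Find a deterministic steady state
#'
#' Integrates the rate equations with a stiff solver over successively longer
#' horizons until the residual drops, then polishes with damped Newton on the
#' dynamic species (numeric Jacobian). Converged means
#' \eqn{\|\dot c\|_\infty <} `tol`.
#'
#' @param spec A `crn_network`.
#' @param init_conc Named initial concentration vector.
#' @param tol Sup-norm residual tolerance (default 1e-10).
#' @param t_horizon Initial integration horizon; doubled until convergence.
#' @param max_doublings Number of horizon doublings before giving up.
#' @return Named concentration vector with attributes `residual` and
#'   `converged`. Non-convergence returns the best iterate with
#'   `converged = FALSE` and a warning.
#' @export
find_steady_state <- function(spec, init_conc, tol = 1e-10,
                              t_horizon = 1e3, max_doublings = 12) {
  conc <- state_counts(spec, init_conc, enforce_clamps = TRUE)
  dyn <- !chemostat_mask(spec)
  rhs <- function(t, y, parms) {
    conc[dyn] <- y
    list(deterministic_rates(spec, conc)[dyn])
  }
  resid <- function(cc) max(abs(deterministic_rates(spec, cc)))
  h <- t_horizon
  for (it in seq_len(max_doublings)) {
    if (resid(conc) < sqrt(tol)) break
    sol <- deSolve::lsoda(y = conc[dyn], times = c(0, h), func = rhs,
                          rtol = 1e-10, atol = 1e-10)
    conc[dyn] <- pmax(sol[nrow(sol), -1], 0)
    h <- h * 2
  }
  # Newton polish on the dynamic subspace
  nd <- sum(dyn)
  for (it in seq_len(50)) {
    f <- deterministic_rates(spec, conc)[dyn]
    if (max(abs(f)) < tol) break
    Jm <- matrix(0, nd, nd)
    eps <- pmax(abs(conc[dyn]), 1) * 1e-7
    for (j in seq_len(nd)) {
      cp <- conc; cm <- conc
      jd <- which(dyn)[j]
      cp[jd] <- cp[jd] + eps[j]; cm[jd] <- max(cm[jd] - eps[j], 0)
      Jm[, j] <- (deterministic_rates(spec, cp)[dyn] -
                  deterministic_rates(spec, cm)[dyn]) / (cp[jd] - cm[jd])
    }
    step <- tryCatch(solve(Jm, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- conc
      cand[dyn] <- conc[dyn] + lambda * step
      if (all(cand[dyn] >= 0) &&
          max(abs(deterministic_rates(spec, cand)[dyn])) < max(abs(f))) {
        conc <- cand
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (lambda < 1e-8) break
  }
  r <- resid(conc)
  if (r >= tol)
    warning("steady-state search did not converge: residual ", r)
  attr(conc, "residual") <- r
  attr(conc, "converged") <- r < tol
  conc
}

#' Per-pair fluxes, forces and heat rates
#'
#' For each reversible pair at a concentration vector: the net flux
#' \eqn{J_\rho = J_\rho^+ - J_\rho^-}, the thermodynamic force
#' \eqn{\Delta G_\rho = \sum_{products}\mu_p - \sum_{educts}\mu_e} with
#' \eqn{\mu_\sigma = \mu^0_\sigma + RT\ln(Z_\sigma/Z^{eq}_\sigma)}, and the
#' heat rate \eqn{\dot Q_\rho = -\Delta G_\rho J_\rho}. For pairs that
#' conserve total molecule count a common equilibrium reference cancels out
#' of the force.
#'
#' @param spec A `crn_network`.
#' @param conc Named concentration vector; must be strictly positive on every
#'   species entering a chemical potential.
#' @param z_eq Equilibrium reference concentration: scalar (common to all
#'   species, default 1) or named per-species vector.
#' @return A `crn_fluxforce` data.frame with one row per pair: `label`,
#'   `j_plus`, `j_minus`, `net_flux`, `force`, `heat_rate`; the concentration
#'   vector and `z_eq` are attached as attributes.
#' @export
flux_force_table <- function(spec, conc, z_eq = 1) {
  fx <- pair_fluxes(spec, conc)
  conc <- fx$conc
  nm <- species_names(spec)
  zeq <- if (length(z_eq) == 1L) stats::setNames(rep(z_eq, length(nm)), nm)
         else z_eq[nm]
  stopifnot(all(zeq > 0))
  mu0 <- mu0_vector(spec)
  rows <- lapply(seq_along(spec$reactions), function(p) {
    r <- spec$reactions[[p]]
    used <- union(names(r$educts), names(r$products))
    if (any(conc[used] <= 0))
      stop("force undefined: zero concentration in a potential term of pair '",
           r$label, "'")
    mu <- mu0[used] + log(conc[used] / zeq[used]) / spec$beta
    s <- full_stoich(spec, r$products)[used] - full_stoich(spec, r$educts)[used]
    force <- sum(mu * s)
    J <- fx$jf[p] - fx$jb[p]
    data.frame(label = r$label, j_plus = fx$jf[p], j_minus = fx$jb[p],
               net_flux = J, force = force, heat_rate = -force * J,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "conc") <- conc
  attr(out, "z_eq") <- zeq
  class(out) <- c("crn_fluxforce", "data.frame")
  out
}

#' Free-energy transduction efficiency at a steady state
#'
#' Splits the total steady-state heat rate \eqn{\dot Q_{tot}} (equal to the
#' chemical work rate injected by the chemostats) into the part
#' \eqn{\dot Q_{diss}} dissipated along designated direct-decay channels and
#' the remainder \eqn{\dot W_{harvest} = \dot Q_{tot} - \dot Q_{diss}}
#' diverted into maintaining the dissipative structure;
#' \eqn{\eta = \dot W_{harvest} / \dot Q_{tot}}.
#'
#' @param spec A `crn_network` whose reaction pairs all conserve total
#'   molecule count (otherwise a per-species `z_eq` must be supplied).
#' @param ness_conc Steady-state concentration vector (checked against
#'   `ss_tol`).
#' @param channels Character vector of pair labels forming the direct
#'   dissipation pathway.
#' @param z_eq Equilibrium reference concentration(s), see
#'   [flux_force_table()].
#' @param ss_tol Maximum allowed steady-state residual (default 1e-8).
#' @return A `crn_efficiency` list: `q_tot`, `q_diss`, `w_harvest`, `eta`,
#'   and the underlying `table`.
#' @export
efficiency <- function(spec, ness_conc, channels, z_eq = 1, ss_tol = 1e-8) {
  v <- validate_crn(spec)
  if (!all(v$pairs$conserves_count) && length(z_eq) == 1L)
    stop("network has non-conserving pairs; supply per-species z_eq values")
  r <- max(abs(deterministic_rates(spec, ness_conc)))
  if (r > ss_tol)
    stop("ness_conc is not a steady state (residual ", format(r), ")")
  tab <- flux_force_table(spec, ness_conc, z_eq = z_eq)
  unknown <- setdiff(channels, tab$label)
  if (length(unknown)) stop("unknown channel labels: ",
                            paste(unknown, collapse = ", "))
  q_tot <- sum(tab$heat_rate)
  q_diss <- sum(tab$heat_rate[tab$label %in% channels])
  if (q_tot <= 0)
    stop("total heat rate is not positive (equilibrium or numerical noise); ",
         "efficiency undefined")
  structure(list(q_tot = q_tot, q_diss = q_diss,
                 w_harvest = q_tot - q_diss, eta = (q_tot - q_diss) / q_tot,
                 table = tab),
            class = "crn_efficiency")
}

#' @export
print.crn_efficiency <- function(x, ...) {
  cat("<crn_efficiency> eta = ", format(x$eta, digits = 4),
      " (q_tot = ", format(x$q_tot, digits = 4),
      ", q_diss = ", format(x$q_diss, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Chemostat work rate at a steady state
#'
#' The chemical work injected per unit time by the chemostats:
#' \eqn{\sum_{\sigma\ chemostatted} \mu_\sigma \cdot (-r_\sigma)} where
#' \eqn{r_\sigma} is the net production rate of the clamped species by the
#' network. At any steady state this equals the total heat rate.
#'
#' @inheritParams flux_force_table
#' @return Scalar work rate in kT per unit time.
#' @export
chemostat_work_rate <- function(spec, conc, z_eq = 1) {
  fx <- pair_fluxes(spec, conc)
  comp <- crn_compile(spec)
  J <- fx$jf - fx$jb
  dS <- comp$dS_full[seq(1, nrow(comp$dS_full), by = 2), , drop = FALSE]
  prod_rate <- as.numeric(t(dS) %*% J)
  names(prod_rate) <- comp$species
  nm <- comp$species
  zeq <- if (length(z_eq) == 1L) stats::setNames(rep(z_eq, length(nm)), nm)
         else z_eq[nm]
  mu <- mu0_vector(spec) + log(fx$conc / zeq) / spec$beta
  cm <- comp$chemostatted
  -sum(mu[cm] * prod_rate[cm])
}
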