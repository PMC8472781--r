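#' Parameters of the winner-take-all network
#'
#' A multi-species generalization of the Schloegl bistable motif: `n_dynamic`
#' species X(i) autocatalyze their own creation from a chemostatted
#' high-concentration species Hi (Hi + 2X(i) <-> 3X(i)) and decay to a
#' chemostatted low-concentration species Lo through a channel jointly
#' catalysed by all competing species (X(i) + X(j) + X(k) <->
#' Lo + X(j) + X(k) for n = 3), which implements the winner-take-all
#' inhibition: whichever species is high suppresses the others' growth and
#' accelerates their decay. All pairs have symmetric rate constants, so local
#' detailed balance holds with zero standard potentials, and every pair
#' conserves total molecule count.
#'
#' @param n_dynamic Number of competing species (default 3).
#' @param k_auto Autocatalysis rate constant (default 1e-6).
#' @param k_decay Catalysed-decay rate constant (default 1e-3).
#' @param n_hi,n_lo Clamp counts of Hi and Lo (defaults 500 and 5).
#' @return A `wta_params` list.
#' @export
wta_params <- function(n_dynamic = 3, k_auto = 1e-6, k_decay = 1e-3,
                       n_hi = 500, n_lo = 5) {
  stopifnot(n_dynamic >= 1, k_auto > 0, k_decay > 0, n_hi > n_lo, n_lo >= 0)
  structure(list(n_dynamic = n_dynamic, k_auto = k_auto, k_decay = k_decay,
                 n_hi = n_hi, n_lo = n_lo), class = "wta_params")
}

#' Build the winner-take-all network
#'
#' @param params A [wta_params()] list (or arguments passed on to it).
#' @param ... Overrides forwarded to [wta_params()] when `params` is missing.
#' @return A validated `crn_network` with species Hi, Lo (chemostatted) and
#'   X1..Xn; pair labels `auto_Xi` and `decay_Xi`.
#' @export
build_wta <- function(params = wta_params(...), ...) {
  p <- params
  xs <- paste0("X", seq_len(p$n_dynamic))
  species <- c(list(crn_species("Hi", chemostat = p$n_hi),
                    crn_species("Lo", chemostat = p$n_lo)),
               lapply(xs, crn_species))
  reactions <- list()
  for (i in seq_len(p$n_dynamic)) {
    e <- stats::setNames(c(1, 2), c("Hi", xs[i]))
    pr <- stats::setNames(3, xs[i])
    reactions <- c(reactions, list(
      crn_reaction(e, pr, kf = p$k_auto, kb = p$k_auto,
                   label = paste0("auto_", xs[i]))))
  }
  for (i in seq_len(p$n_dynamic)) {
    reactions <- c(reactions, list(decay_reaction(xs, i, p$k_decay)))
  }
  crn_network(species, reactions)
}

# competitor-catalysed decay: X(i) + sum_{j != i} X(j) <-> Lo + sum_{j != i} X(j)
decay_reaction <- function(xs, i, k_decay) {
  others <- xs[-i]
  e <- stats::setNames(rep(1, length(xs)), c(xs[i], others))
  pr <- stats::setNames(rep(1, length(xs)), c("Lo", others))
  crn_reaction(e, pr, kf = k_decay, kb = k_decay,
               label = paste0("decay_", xs[i]))
}

#' Parameters of the bifurcation-coupled selection network
#'
#' Extends [wta_params()]: the autocatalysts feed on a dynamic reservoir
#' species Re instead of Hi directly; the Hi -> Lo disequilibrium is
#' dissipated through intermediates B(i) whose synthesis
#' (Hi + 2X(i) <-> B(i) + 2X(i)) is catalysed by two molecules of the
#' corresponding competitor; B(i) either decays directly (B(i) <-> Lo) or is
#' bifurcated into the reservoir (B(i) + 2X(i) <-> Re + 2X(i)) at a
#' branch-specific rate, which sets the branch's work-harvesting efficiency.
#'
#' @inheritParams wta_params
#' @param k_synth Intermediate-synthesis rate constant (default 1e-5).
#' @param k_bdecay Direct intermediate-decay rate constant (default 1.0).
#' @param k_bifurcate Per-branch bifurcation rate constants, length
#'   `n_dynamic` (defaults 1e-6, 3e-7, 1e-7).
#' @export
selection_params <- function(n_dynamic = 3, k_auto = 1e-6, k_decay = 1e-3,
                             n_hi = 1000, n_lo = 5, k_synth = 1e-5,
                             k_bdecay = 1.0,
                             k_bifurcate = c(1e-6, 3e-7, 1e-7)) {
  stopifnot(length(k_bifurcate) == n_dynamic, all(k_bifurcate > 0),
            k_synth > 0, k_bdecay > 0)
  p <- wta_params(n_dynamic, k_auto, k_decay, n_hi, n_lo)
  p$k_synth <- k_synth; p$k_bdecay <- k_bdecay; p$k_bifurcate <- k_bifurcate
  class(p) <- c("selection_params", "wta_params")
  p
}

#' Build the bifurcation-coupled selection network
#'
#' @param params A [selection_params()] list.
#' @param ... Overrides forwarded to [selection_params()] when `params` is
#'   missing.
#' @return A validated `crn_network` with 2 chemostatted species (Hi, Lo) and
#'   dynamic X1..Xn, B1..Bn, Re; 15 reversible pairs for n = 3. Pair labels:
#'   `auto_Xi`, `decay_Xi`, `synth_Bi`, `bdecay_Bi`, `bif_Bi`.
#' @export
build_selection <- function(params = selection_params(...), ...) {
  p <- params
  n <- p$n_dynamic
  xs <- paste0("X", seq_len(n)); bs <- paste0("B", seq_len(n))
  species <- c(list(crn_species("Hi", chemostat = p$n_hi),
                    crn_species("Lo", chemostat = p$n_lo)),
               lapply(c(xs, bs, "Re"), crn_species))
  reactions <- list()
  for (i in seq_len(n)) {
    reactions <- c(reactions, list(
      crn_reaction(stats::setNames(c(1, 2), c("Re", xs[i])),
                   stats::setNames(3, xs[i]),
                   kf = p$k_auto, kb = p$k_auto,
                   label = paste0("auto_", xs[i]))))
  }
  for (i in seq_len(n)) {
    reactions <- c(reactions, list(decay_reaction(xs, i, p$k_decay)))
  }
  for (i in seq_len(n)) {
    reactions <- c(reactions, list(
      crn_reaction(stats::setNames(c(1, 2), c("Hi", xs[i])),
                   stats::setNames(c(1, 2), c(bs[i], xs[i])),
                   kf = p$k_synth, kb = p$k_synth,
                   label = paste0("synth_", bs[i])),
      crn_reaction(stats::setNames(1, bs[i]), stats::setNames(1, "Lo"),
                   kf = p$k_bdecay, kb = p$k_bdecay,
                   label = paste0("bdecay_", bs[i])),
      crn_reaction(stats::setNames(c(1, 2), c(bs[i], xs[i])),
                   stats::setNames(c(1, 2), c("Re", xs[i])),
                   kf = p$k_bifurcate[i], kb = p$k_bifurcate[i],
                   label = paste0("bif_", bs[i]))))
  }
  crn_network(species, reactions)
}

# the X-competitor species of a bundled network (dynamic, name X<i>)
x_species <- function(spec) {
  nm <- species_names(spec)
  sort(nm[grepl("^X[0-9]+$", nm) & !chemostat_mask(spec)])
}

# clamp counts of the driving species
driving_clamps <- function(spec) {
  cl <- clamp_counts(spec)
  if (!all(c("Hi", "Lo") %in% names(cl)) || is.na(cl[["Hi"]]) || is.na(cl[["Lo"]]))
    stop("network does not expose Hi/Lo driving chemostats")
  list(n_hi = cl[["Hi"]], n_lo = cl[["Lo"]])
}

#' Generate initial molecule-count states
#'
#' The three initialization recipes used throughout the experiments:
#' `near_low` sets every dynamic species to the Lo clamp count; `near_high`
#' (with `target = i`) sets X(i) — and, when present, B(i) and Re — to the Hi
#' clamp count and every other dynamic species to the Lo clamp; `random`
#' draws each dynamic count uniformly on `[n_lo, n_hi]`.
#'
#' @param spec A network built by [build_wta()] or [build_selection()] (any
#'   network with Hi/Lo chemostats and X-species works).
#' @param mode `"near_low"`, `"near_high"` or `"random"`.
#' @param target Branch index for `near_high`.
#' @param n_copies Number of states to generate.
#' @param seed Seed for `random` mode (required there); same seed, same
#'   states.
#' @return List of `crn_state`s at time 0.
#' @export
initial_states <- function(spec, mode = c("near_low", "near_high", "random"),
                           target = NULL, n_copies = 1, seed = NULL) {
  mode <- match.arg(mode)
  dc <- driving_clamps(spec)
  nm <- species_names(spec)
  dyn <- nm[!chemostat_mask(spec)]
  base <- stats::setNames(rep(dc$n_lo, length(dyn)), dyn)
  if (mode == "near_low") {
    states <- rep(list(base), n_copies)
  } else if (mode == "near_high") {
    if (is.null(target)) stop("near_high needs a target branch index")
    xi <- paste0("X", target)
    if (!xi %in% dyn) stop("no dynamic species ", xi)
    s <- base
    s[xi] <- dc$n_hi
    bi <- paste0("B", target)
    if (bi %in% dyn) s[bi] <- dc$n_hi
    if ("Re" %in% dyn) s["Re"] <- dc$n_hi
    states <- rep(list(s), n_copies)
  } else {
    if (is.null(seed)) stop("random mode requires a seed")
    states <- with_seed(seed, lapply(seq_len(n_copies), function(i) {
      stats::setNames(sample(dc$n_lo:dc$n_hi, length(dyn), replace = TRUE), dyn)
    }))
  }
  lapply(states, crn_state, time = 0)
}
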