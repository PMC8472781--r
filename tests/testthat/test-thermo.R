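test_that("gibbs free energy is the sum of log-factorials", {
  expect_equal(gibbs_free_energy(c(A = 0, B = 1, C = 1)), 0)
  expect_equal(gibbs_free_energy(c(A = 3, B = 2)), log(6) + log(2))
  # permutation invariance
  expect_equal(gibbs_free_energy(c(A = 17, B = 4, C = 230)),
               gibbs_free_energy(c(A = 230, B = 17, C = 4)))
  # large counts go through log-gamma, no factorial overflow
  expect_true(is.finite(gibbs_free_energy(c(A = 5000))))
})

test_that("event heat is the free-energy drop and is antisymmetric", {
  expect_equal(event_heat(c(A = 2, B = 0), c(A = 1, B = 1)), log(2))
  expect_equal(event_heat(c(A = 1, B = 1), c(A = 2, B = 0)), -log(2))
  # uphill fluctuation from a homogeneous state releases negative heat
  expect_lt(event_heat(c(A = 10, B = 10), c(A = 11, B = 9)), 0)
})

test_that("compiled and plain-R closure estimators agree", {
  # independent route: re-implement the per-trajectory estimator with ssa_step
  toy <- two_state_toy()
  sts <- rep(list(c(A = 20, B = 0)), 400)
  wr <- min_workrate(toy, sts, n_events = 10, base_seed = 77)
  set.seed(1234)
  ref <- replicate(400, {
    st <- crn_state(c(A = 20, B = 0), 0)
    g0 <- gibbs_free_energy(st)
    for (k in 1:10) st <- ssa_step(toy, st)$state
    (g0 - gibbs_free_energy(st)) / st$time
  })
  se <- sqrt(wr$stderr^2 + var(ref) / length(ref))
  expect_lt(abs(wr$mean_rate - mean(ref)), 3 * se)
  expect_gt(wr$mean_rate, 0)
})

test_that("work-rate estimator excludes trajectories that absorb early", {
  # 2 A -> A + B with a single A: absorbing immediately once A is consumed
  spec <- crn_network(list(crn_species("A"), crn_species("B")),
                      list(crn_reaction("2 A", "A + B", kf = 1, kb = 1)))
  expect_error(min_workrate(spec, list(c(A = 1, B = 0)), n_events = 5,
                            base_seed = 1),
               "absorbed")
  mixed <- min_workrate(spec, list(c(A = 1, B = 0), c(A = 30, B = 0)),
                        n_events = 5, base_seed = 1)
  expect_equal(mixed$n_excluded, 1)
  expect_equal(mixed$n_trajectories, 1)
})

test_that("deterministic rates vanish at equilibrium and clamp chemostats", {
  w <- build_wta()
  cw <- close_network(w)
  # closed network, all concentrations equal: every pair is equilibrated
  eq <- stats::setNames(rep(7, 5), c("Hi", "Lo", "X1", "X2", "X3"))
  expect_equal(max(abs(deterministic_rates(cw, eq))), 0)
  # open network: chemostat rows are zero regardless
  dc <- deterministic_rates(w, c(X1 = 300, X2 = 10, X3 = 10))
  expect_equal(unname(dc[c("Hi", "Lo")]), c(0, 0))
  # hand-evaluated unimolecular pair
  toy <- two_state_toy()
  expect_equal(deterministic_rates(toy, c(A = 2, B = 0)),
               c(A = -2, B = 2))
})

test_that("steady-state search returns fixed points of the rate equations", {
  toy <- two_state_toy()
  ss <- find_steady_state(toy, c(A = 2, B = 0))
  expect_equal(unname(ss), c(1, 1), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(attr(ss, "residual"), 1e-10)
  # starting exactly at a fixed point returns it
  ss2 <- find_steady_state(toy, c(A = 1, B = 1))
  expect_equal(unname(ss2), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)
  # WTA high branch: high-X1 fixed point with the others near the Lo clamp
  w <- build_wta()
  init <- initial_states(w, "near_high", target = 1)[[1]]$counts
  ssw <- find_steady_state(w, init)
  expect_true(attr(ssw, "converged"))
  expect_gt(ssw[["X1"]], 400)
  expect_lt(ssw[["X2"]], 10)
  expect_lt(ssw[["X3"]], 10)
})

test_that("flux-force tables obey the defining identities", {
  s <- build_selection()
  conc <- c(X1 = 900, X2 = 6, X3 = 6, B1 = 900, B2 = 5, B3 = 6, Re = 890)
  tab <- flux_force_table(s, conc)
  expect_equal(tab$heat_rate, -tab$force * tab$net_flux)
  expect_equal(tab$net_flux, tab$j_plus - tab$j_minus)
  # force of synth_B1 (Hi + 2X1 <-> B1 + 2X1): ln(Z_B1 / Z_Hi), catalysts and
  # the common equilibrium reference cancel
  i <- which(tab$label == "synth_B1")
  expect_equal(tab$force[i], log(900 / 1000))
  # at the closed-network equilibrium all fluxes and forces vanish
  cw <- close_network(build_wta())
  eq <- stats::setNames(rep(7, 5), c("Hi", "Lo", "X1", "X2", "X3"))
  tec <- flux_force_table(cw, eq)
  expect_equal(max(abs(tec$net_flux)), 0)
  expect_equal(max(abs(tec$force)), 0)
  # zero concentration in a potential term is an error
  expect_error(flux_force_table(s, c(X1 = 0, B1 = 1, Re = 1)), "undefined")
})

test_that("forces follow the concentration ratio for a direct decay pair", {
  s <- build_selection()
  conc <- c(X1 = 1, X2 = 1, X3 = 1, B1 = 500, B2 = 1, B3 = 1, Re = 1)
  tab <- flux_force_table(s, conc)
  # B1 <-> Lo with Z_B1 = 500, Z_Lo = 5: force = ln(5/500)
  i <- which(tab$label == "bdecay_B1")
  expect_equal(tab$force[i], log(5 / 500))
})

test_that("efficiency spans its defining limits and respects z_eq invariance", {
  p <- selection_params(n_hi = 1200)
  s <- build_selection(p)
  init <- initial_states(s, "near_high", target = 1)[[1]]$counts
  ss <- find_steady_state(s, init)
  channels <- c(paste0("synth_B", 1:3), paste0("bdecay_B", 1:3))
  ef <- efficiency(s, ss, channels)
  expect_gt(ef$eta, 0); expect_lt(ef$eta, 1)
  # channel set = all pairs -> eta 0; empty -> eta 1
  all_labels <- vapply(s$reactions, function(r) r$label, character(1))
  expect_equal(efficiency(s, ss, all_labels)$eta, 0)
  expect_equal(efficiency(s, ss, character(0))$eta, 1)
  # equilibrium reference cancels for count-conserving networks
  ef2 <- efficiency(s, ss, channels, z_eq = 137.5)
  expect_equal(ef2$eta, ef$eta, tolerance = 1e-9)
  expect_equal(ef2$q_tot, ef$q_tot, tolerance = 1e-9)
})

test_that("total steady-state heat equals the chemostat work rate", {
  p <- selection_params(n_hi = 1200)
  s <- build_selection(p)
  for (i in 1:2) {
    init <- initial_states(s, "near_high", target = i)[[1]]$counts
    ss <- find_steady_state(s, init)
    tab <- flux_force_table(s, ss)
    q_tot <- sum(tab$heat_rate)
    expect_equal(q_tot, chemostat_work_rate(s, ss), tolerance = 1e-6)
    # each pair dissipates at steady state: flux runs down its force
    expect_true(all(tab$heat_rate >= -1e-9 * q_tot))
  }
})
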