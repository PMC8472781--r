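test_that("attractor classification separates high, low and tied tails", {
  w <- build_wta()  # n_hi 500, n_lo 5: midpoint threshold 252.5
  expect_equal(classify_attractor(c(X1 = 500, X2 = 5, X3 = 5), w), "S_X1")
  expect_equal(classify_attractor(c(X1 = 5, X2 = 480, X3 = 7), w), "S_X2")
  expect_equal(classify_attractor(c(X1 = 5, X2 = 5, X3 = 5), w), "S_Low")
  # two species simultaneously high is never a valid single-winner label
  expect_equal(classify_attractor(c(X1 = 400, X2 = 400, X3 = 5), w), "Undecided")
  # a wider margin opens an indeterminate band between the thresholds
  expect_equal(classify_attractor(c(X1 = 250, X2 = 250, X3 = 5), w,
                                  margin = 0.75), "Undecided")
  expect_equal(classify_attractor(c(X1 = 250, X2 = 250, X3 = 5), w,
                                  margin = 0.9), "Undecided")
  expect_error(classify_attractor(numeric(0), w), "empty")
})

test_that("classification thresholds scale with the clamp gap", {
  w <- build_wta(wta_params(n_hi = 100))
  expect_equal(classify_attractor(c(X1 = 80, X2 = 5, X3 = 5), w), "S_X1")
  expect_equal(classify_attractor(c(X1 = 40, X2 = 5, X3 = 5), w), "S_Low")
})

test_that("zero-step censuses reflect the initial conditions only", {
  w <- build_wta()
  cen <- attractor_census(w, n_inits = 40, n_steps = 0, base_seed = 3)
  expect_length(cen$labels, 40)
  # reclassify the raw initial draws: must match exactly
  inits <- initial_states(w, "random", n_copies = 40,
                          seed = trajectory_seed(3, 0))
  relabel <- vapply(inits, function(s) classify_attractor(s$counts, w),
                    character(1))
  expect_identical(cen$labels, relabel)
})

test_that("critical concentration interpolates the 50% crossing", {
  synth <- data.frame(n_hi = c(300, 320), init_mode = "near_high:1",
                      retained = c(0.1, 0.9))
  cc <- critical_concentration(synth, "near_high:1")
  expect_equal(cc$n_crit, 310)
  expect_false(cc$out_of_range)
  # a curve that never crosses is flagged
  flat <- data.frame(n_hi = c(300, 320), init_mode = "near_high:1",
                     retained = c(1, 1))
  expect_true(critical_concentration(flat, "near_high:1")$out_of_range)
  # threshold 0: lowest grid point with a positive fraction
  lowc <- data.frame(n_hi = c(100, 200, 300), init_mode = "near_low",
                     retained = c(0, 0.2, 1))
  expect_equal(critical_concentration(lowc, "near_low", threshold = 0)$n_crit,
               200)
  # only the lowest upward crossing counts when the curve dips twice
  wig <- data.frame(n_hi = c(100, 200, 300, 400), init_mode = "near_low",
                    retained = c(0, 1, 0, 1))
  expect_equal(critical_concentration(wig, "near_low")$n_crit, 150)
})

test_that("single-trajectory sweeps give retained fractions in {0,1}", {
  curve <- stability_sweep(function(h) build_wta(wta_params(n_hi = h)),
                           c(400, 500), c("near_high:1", "near_low"),
                           n_traj = 1, n_steps = 2000, base_seed = 5)
  expect_true(all(curve$retained %in% c(0, 1)))
  expect_equal(nrow(curve), 4)
  # bit-identical rerun from the same base seed
  curve2 <- stability_sweep(function(h) build_wta(wta_params(n_hi = h)),
                            c(400, 500), c("near_high:1", "near_low"),
                            n_traj = 1, n_steps = 2000, base_seed = 5)
  expect_identical(curve, curve2)
})

test_that("steady-state harvesting only returns converged trajectories", {
  w <- build_wta(wta_params(n_hi = 400))
  hv <- harvest_ness_states(w, "near_high:1", n_samples = 100, n_traj = 5,
                            n_steps = 2e4, base_seed = 9)
  expect_equal(hv$n_converged, 5)
  expect_length(hv$states, 100)
  # every harvested state is committed to the high-X1 basin
  for (s in hv$states[c(1, 50, 100)])
    expect_gt(s$counts[["X1"]], 200)
  # at weak driving the high state cannot be harvested
  w2 <- build_wta(wta_params(n_hi = 150))
  hv2 <- harvest_ness_states(w2, "near_high:1", n_samples = 100, n_traj = 5,
                             n_steps = 2e4, base_seed = 9)
  expect_equal(hv2$n_converged, 0)
  expect_length(hv2$states, 0)
})

test_that("work-rate curves flag unstable grid points instead of reporting", {
  wc <- workrate_curve(function(h) build_wta(wta_params(n_hi = h)),
                       c(150, 400), "near_high:1", n_samples = 60,
                       n_traj = 5, n_steps = 2e4, base_seed = 17)
  expect_false(wc$stable[wc$n_hi == 150])
  expect_true(wc$stable[wc$n_hi == 400])
  expect_true(is.na(wc$mean_rate[wc$n_hi == 150]))
  expect_gt(wc$mean_rate[wc$n_hi == 400], 0)
})

test_that("deterministic efficiencies are branch-ordered like the bifurcation rates", {
  ec <- efficiency_curve(selection_params(), 1600)
  expect_true(all(ec$exists))
  e <- ec$eta[order(ec$branch)]
  expect_gt(e[1], e[2]); expect_gt(e[2], e[3]); expect_gt(e[3], 0)
  # symmetric bifurcation constants restore equal efficiencies
  ecs <- efficiency_curve(selection_params(k_bifurcate = rep(3e-7, 3)), 1600)
  expect_equal(ecs$eta[1], ecs$eta[2], tolerance = 1e-6)
  expect_equal(ecs$eta[2], ecs$eta[3], tolerance = 1e-6)
})
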