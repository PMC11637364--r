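test_that("tuning derivatives implement the plasticity rule", {
  p <- jr_params(); dp <- dfic_params(y0_target = 0.01)
  y <- c(0.02, 1, 2, 0, 0, 0)
  # at the detection target the wFIC drift vanishes
  d <- tuning_rhs(c(y, 0.01, 1.5, 1), 0.1, p, dp)
  expect_equal(d[9], 0)
  # detected activity above target with positive y2d strengthens inhibition
  d2 <- tuning_rhs(c(y, 0.02, 1.5, 1), 0.1, p, dp)
  expect_gt(d2[9], 0)
  d3 <- tuning_rhs(c(y, 0.005, 1.5, 1), 0.1, p, dp)
  expect_lt(d3[9], 0)
  expect_equal(d2[9], dp$eta * 1.5 * (0.02 - 0.01))
  # frozen transient and the tau_d -> Inf limit
  expect_equal(tuning_rhs(c(y, 0.02, 1.5, 1), 0.1, p, dp, frozen = TRUE)[9], 0)
  dpi <- dfic_params(tau_d = 1e15, y0_target = 0.01)
  dinf <- tuning_rhs(c(y, 0.3, 0.7, 1), 0.1, p, dpi)
  expect_equal(dinf[7:8], c(0, 0), tolerance = 1e-12)
  # the first six entries are the plain node derivatives
  expect_equal(d[1:6], jr_node_rhs(y, 0.1, 1, p))
})

test_that("default initial conditions respect the documented bands", {
  lo <- default_initial_conditions(0.01, 8, seed = 2)
  expect_equal(lo$mu, 0.09)
  expect_true(all(lo$y[, 1] >= 0 & lo$y[, 1] < 0.01))
  expect_true(all(lo$y[, 2:6] == 0))
  hi <- default_initial_conditions(0.103, 8, seed = 2)
  expect_equal(hi$mu, 0.14)
  expect_true(all(hi$y[, 1] > 0.103))
  expect_identical(default_initial_conditions(0.01, 8, seed = 2),
                   default_initial_conditions(0.01, 8, seed = 2))
  expect_false(identical(lo$y, default_initial_conditions(0.01, 8, 3)$y))
})

test_that("pFIC extraction averages the tail of the wFIC trajectory", {
  fake <- structure(list(times = seq(0, 10000, by = 10),
                         wfic_traj = matrix(1.7, 1001, 2),
                         dp = dfic_params(L_avg = 3000)),
                    class = "tuning_result")
  expect_equal(extract_pfic(fake), c(1.7, 1.7))
  ramp <- fake
  ramp$wfic_traj <- cbind(seq(0, 1, length.out = 1001),
                          seq(2, 0, length.out = 1001))
  # mean of a linear ramp over the window is its midpoint value
  w <- ramp$times > 10000 - 3000
  expect_equal(extract_pfic(ramp), colMeans(ramp$wfic_traj[w, ]))
  expect_equal(extract_pfic(ramp)[1],
               mean(range(seq(0, 1, length.out = 1001)[w])))
  expect_error(extract_pfic(fake, L_avg = 99999), "window")
})

test_that("single-node tuning reaches feasible targets and flags failure", {
  # target on the low FP branch, approached from a fast-cycle regime
  p <- jr_params(mu = 0.2, G = 0)
  tr <- run_tuning(NULL, p, dfic_params(y0_target = 0.01, T_tune = 150000),
                   ic = list(y = matrix(0, 1, 6), y0d = 0, y2d = 0,
                             mu = 0.2), seed = 1)
  expect_true(tr$converged)
  expect_lt(tr$final_rel_dev, 0.01)
  expect_gt(tr$pfic, 1)   # extra inhibition needed against I = 0.2
  # without control the same setup sits on the fast cycle far above 0.01
  free <- integrate_heun(NULL, NULL, p, T = 15000, dt = 1)
  expect_gt(mean(free$states$y0[free$times > 5000, 1]), 0.05)
  # converged tuning implies a nearly constant late wFIC
  expect_lt(abs(extract_pfic(tr) - tr$wfic_final), 1e-3)

  # a super-bistable target lands on the fast cycle with matching center
  ic2 <- default_initial_conditions(0.103, 1, seed = 5)
  p2 <- jr_params(mu = ic2$mu, G = 0)
  tr2 <- run_tuning(NULL, p2, dfic_params(y0_target = 0.103), ic = ic2)
  expect_true(tr2$converged)
  tail_y0 <- tr2$y0_traj[tr2$times > tr2$dp$T_tune - 5000, 1]
  expect_gt(diff(range(tail_y0)), 0.01)   # oscillating, not a fixed point
  expect_equal(mean(tail_y0), 0.103, tolerance = 0.01)

  # a mid-gap target at mu = 0.09 cannot be realized: flagged, not raised
  ic3 <- list(y = matrix(c(0.04, 0, 0, 0, 0, 0), 1), y0d = 0.04, y2d = 0,
              mu = 0.09)
  tr3 <- run_tuning(NULL, jr_params(mu = 0.09, G = 0),
                    dfic_params(y0_target = 0.05, T_tune = 150000),
                    ic = ic3)
  expect_false(tr3$converged)
})

test_that("tuning is robust over the learning-rate / window grid", {
  # single node, target 0.01: converges for every eta x tau_d combination
  for (eta in c(0.005, 0.01)) for (tau_d in c(10, 100, 550, 1000)) {
    dp <- dfic_params(eta = eta, tau_d = tau_d, y0_target = 0.01,
                      T_tune = 100000)
    ic <- default_initial_conditions(0.01, 1, seed = 7)
    tr <- run_tuning(NULL, jr_params(mu = ic$mu, G = 0), dp, ic = ic)
    expect_true(tr$converged,
                label = sprintf("converged at eta=%g tau_d=%g", eta, tau_d))
  }
})

test_that("equilibria found in the atlas agree with direct tuning", {
  atlas <- slice_atlas()
  watlas <- sweep_attractors(0.2, seq(0.8, 2.4, by = 0.05))
  eq <- dfic_equilibrium_scan(watlas, 0.01)
  expect_gt(nrow(eq), 0)
  expect_true(all(eq$stable))
  expect_true(all(eq$slope < 0))
  # direct tuning at the same input converges to the same wFIC
  p <- jr_params(mu = 0.2, G = 0)
  tr <- run_tuning(NULL, p, dfic_params(y0_target = 0.01, T_tune = 150000),
                   ic = list(y = matrix(0, 1, 6), y0d = 0, y2d = 0,
                             mu = 0.2), seed = 1)
  expect_equal(tr$pfic, eq$wfic_star[1], tolerance = 0.05)
  # a mid-gap target has no equilibrium in the wFIC = 1 slice
  eq_gap <- dfic_equilibrium_scan(atlas, 0.075)
  expect_equal(nrow(eq_gap[abs(eq_gap$wfic_star - 1) < 1e-6, ]), 0)
})

test_that("perturbed wFIC returns to equilibrium only when eta > 0", {
  atlas <- sweep_attractors(0.2, seq(0.8, 2.4, by = 0.05))
  eq <- dfic_equilibrium_scan(atlas, 0.01)
  wstar <- eq$wfic_star[1]
  expect_true(verify_stability(0.2, wstar, 0.01,
                               dp = dfic_params(T_tune = 120000)))
  expect_false(verify_stability(0.2, wstar, 0.01,
                                dp = dfic_params(eta = 0,
                                                 T_tune = 30000)))
})
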