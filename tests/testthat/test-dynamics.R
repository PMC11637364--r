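test_that("sigmoid hits its midpoint, asymptotes and reference values", {
  p <- jr_params()
  expect_equal(jr_sigmoid(6, p), 0.0025)
  expect_equal(jr_sigmoid(1e6, p), 0.005)
  expect_equal(jr_sigmoid(-1e6, p), 0)
  expect_equal(jr_sigmoid(0, p), ref_sigmoid(0), tolerance = 1e-12)
  expect_equal(ref_sigmoid(0), 1.6785e-4, tolerance = 1e-4)
  v <- seq(-20, 40, by = 0.5)
  expect_true(all(diff(jr_sigmoid(v, p)) > 0))   # strictly increasing
  expect_true(all(jr_sigmoid(v, p) > 0 & jr_sigmoid(v, p) < 0.005))
})

test_that("node right-hand side matches a termwise oracle", {
  p <- jr_params()
  expect_equal(jr_node_rhs(rep(0, 6), 0, 1, p),
               ref_rhs(rep(0, 6), 0, 1), tolerance = 1e-14)
  set.seed(42)
  for (k in 1:20) {
    y <- rnorm(6, sd = 5)
    I <- rnorm(1, sd = 0.3)
    w <- runif(1, 0, 3)
    expect_equal(jr_node_rhs(y, I, w, p), ref_rhs(y, I, w),
                 tolerance = 1e-12)
  }
  # dy0 = y3 identically
  y <- rnorm(6)
  expect_identical(jr_node_rhs(y, 0.1, 1, p)[1], y[4])
})

test_that("derivatives vanish at a settled fixed point", {
  p <- jr_params(mu = 0.05, G = 0)
  tr <- integrate_heun(NULL, NULL, p, T = 30000, dt = 0.5)
  expect_lt(max(abs(jr_node_rhs(tr$y_final, 0.05, 1, p))), 1e-8)
})

test_that("coupling input follows the delayed partner state", {
  # two-node chain with a 3-step delay: node 2's input must reflect
  # node 1's effective PSP three steps earlier
  cn <- connectome(matrix(c(0, 0, 1, 0), 2, byrow = TRUE),
                   matrix(c(0, 15, 15, 0), 2))   # 15 mm -> 3 steps at 1 ms
  p <- jr_params(mu = 0.1, G = 0.5)
  ic <- matrix(c(0.01, 0, 1, 0.5, 0, 0, 0.2, -0.1, 0, 0, 0.05, 0), 2)
  tr <- integrate_heun(ic, cn, p, T = 200, dt = 1, record_input = TRUE)
  theta <- compute_delays(cn, 1)$steps[2, 1]
  expect_equal(theta, 3L)
  idx <- seq(theta + 5, length(tr$times) - 1)
  eff1 <- tr$states$y1[, 1] - tr$states$y2[, 1]
  expected <- p$mu + p$G * 1 * jr_sigmoid(eff1[idx - theta], p)
  expect_equal(tr$input[idx, 2], expected, tolerance = 1e-12)
  # the un-coupled node receives exactly mu
  expect_equal(tr$input[, 1], rep(p$mu, nrow(tr$input)))
})

test_that("with G = 0 every node receives mu and evolves independently", {
  p <- jr_params(mu = 0.12, G = 0)
  ic <- matrix(rep(c(0.005, 1, 2, 0, 0, 0), each = 2), 2)
  tr <- integrate_heun(ic, NULL, p, T = 2000, dt = 1, record_input = TRUE)
  expect_true(all(tr$input == p$mu))
  expect_identical(tr$states$y0[, 1], tr$states$y0[, 2])
  expect_identical(tr$psp[, 1], tr$psp[, 2])
})

test_that("stochastic integration with sigma = 0 is bitwise deterministic", {
  p0 <- jr_params(mu = 0.1, G = 0, sigma = 0)
  cn <- generate_small_network(3, seed = 5)
  a <- integrate_heun(NULL, cn, p0, T = 1000, stochastic = TRUE, seed = 3)
  b <- integrate_heun(NULL, cn, p0, T = 1000, stochastic = FALSE)
  expect_identical(a$states, b$states)
  # with sigma > 0, same seed reproduces and different seeds differ
  p1 <- jr_params(mu = 0.1, G = 0, sigma = 1e-3)
  s1 <- integrate_heun(NULL, cn, p1, T = 1000, stochastic = TRUE, seed = 3)
  s2 <- integrate_heun(NULL, cn, p1, T = 1000, stochastic = TRUE, seed = 3)
  s3 <- integrate_heun(NULL, cn, p1, T = 1000, stochastic = TRUE, seed = 4)
  expect_identical(s1$states, s2$states)
  expect_false(identical(s1$states, s3$states))
  expect_false(identical(s1$states, b$states))
})

test_that("Heun integration converges at second order", {
  p <- jr_params(mu = 0.05, G = 0)
  # short horizon keeps the comparison mid-transient, away from the
  # fixed point where both step sizes agree to rounding error
  end_state <- function(dt) {
    integrate_heun(matrix(c(0.01, 2, 3, 0, 0, 0), 1), NULL, p,
                   T = 150, dt = dt)$y_final
  }
  y1 <- end_state(1); y2 <- end_state(0.5); y4 <- end_state(0.25)
  e1 <- sqrt(sum((y1 - y2)^2)); e2 <- sqrt(sum((y2 - y4)^2))
  expect_gt(e1 / e2, 3)   # Richardson ratio ~ 4 for a second-order scheme
  expect_lt(e1 / e2, 5.5)
})

test_that("states stay bounded for strong constant inputs", {
  for (I in c(-1, 1)) {
    tr <- integrate_heun(NULL, NULL, jr_params(mu = I, G = 0),
                         T = 100000, dt = 0.5, record_dt = 50)
    expect_true(all(is.finite(tr$psp)))
    expect_lt(max(abs(tr$psp)), 100)
  }
})

test_that("single-node rhythms fall in the reported frequency bands", {
  p <- jr_params(G = 0)
  fast <- integrate_heun(NULL, NULL, jr_params(mu = 0.2, G = 0),
                         T = 15000, dt = 0.5)
  keep <- fast$times >= 5000
  cl <- classify_attractor(fast$states$y0[keep, 1], fast$psp[keep, 1], 0.5)
  expect_identical(cl$kind, "fast_LC")
  expect_gte(cl$freq, 10); expect_lte(cl$freq, 12)
  slow <- integrate_heun(NULL, NULL, jr_params(mu = 0.12, G = 0),
                         T = 25000, dt = 0.5)
  keep <- slow$times >= 15000
  cl2 <- classify_attractor(slow$states$y0[keep, 1], slow$psp[keep, 1], 0.5)
  expect_identical(cl2$kind, "slow_LC")
  expect_gte(cl2$freq, 1); expect_lte(cl2$freq, 5)
})

test_that("psp modes agree for wfic = 1 and scale y2 otherwise", {
  tr <- list(states = list(y1 = matrix(10, 2, 2), y2 = matrix(4, 2, 2)),
             wfic = c(1, 1))
  expect_equal(compute_psp(tr, mode = "raw"), matrix(6, 2, 2))
  expect_equal(compute_psp(tr, mode = "effective"), matrix(6, 2, 2))
  expect_equal(compute_psp(tr, wfic = c(1.5, 1.5), mode = "effective"),
               matrix(4, 2, 2))
})

test_that("mean-field decomposition reconstructs the input exactly", {
  cn <- generate_whole_brain_like(20, seed = 2)
  p <- jr_params(mu = 0.09, G = 2)
  tr <- integrate_heun(NULL, cn, p, T = 3000, dt = 1, record_input = TRUE)
  dec <- meanfield_decomposition(tr, cn, p)
  recon <- dec$mu + dec$mean_field + dec$residual
  expect_lt(max(abs(recon - tr$input)), 1e-12)
  # identical uncoupled nodes: the residual vanishes
  p0 <- jr_params(mu = 0.1, G = 0)
  tr0 <- integrate_heun(NULL, NULL, p0, T = 500, dt = 1,
                        record_input = TRUE, n_nodes = 3)
  dec0 <- meanfield_decomposition(tr0, connectome(matrix(0, 3, 3)), p0)
  expect_lt(max(abs(dec0$residual)), 1e-12)
  # heavy-tailed coupling: the indegree term dominates the residual
  late <- tr$times > 1000
  expect_gt(var(as.numeric(dec$mean_field[late, ])),
            var(as.numeric(dec$residual[late, ])))
})
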