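#' Population sigmoid
#'
#' The sigmoidal rate function `S(v) = 2 v_max / (1 + exp(r (v0 - v)))`
#' converting an average membrane potential (mV) into an average firing
#' rate (1/ms).  Strictly increasing, bounded by `2 v_max`, and equal to
#' `v_max` at the threshold `v0`.
#'
#' @param v membrane potential, mV (vectorized).
#' @param p a [jr_params()] object.
#' @return Firing rate(s), 1/ms.
#' @export
jr_sigmoid <- function(v, p) {
  2 * p$v_max / (1 + exp(p$r * (p$v0 - v)))
}

#' Right-hand side of a single Jansen-Rit node
#'
#' Time derivatives of the six node states
#' `(y0, y1, y2, y3, y4, y5)`: pyramidal, excitatory and inhibitory PSP
#' blocks and their rates.  The inhibitory input onto pyramidal cells is
#' scaled by `wfic`, the feedback-inhibition control variable.
#'
#' @param y numeric vector of 6 states, ordered `y0..y5`.
#' @param I_ext external input rate received by the node.
#' @param wfic inhibitory scaling (dimensionless, >= 0).
#' @param p a [jr_params()] object.
#' @return Numeric vector of 6 derivatives.
#' @export
jr_node_rhs <- function(y, I_ext, wfic = 1, p = jr_params()) {
  stopifnot(length(y) == 6, is.finite(I_ext), wfic >= 0)
  cpp_node_rhs(as.numeric(y), wfic, I_ext, par_vector(p))
}

#' Delay-coupled network integration (Heun scheme)
#'
#' Integrates a network of Jansen-Rit nodes coupled through a
#' [connectome()] with conduction delays, using the predictor-corrector
#' Heun scheme.  The long-range input to node i is
#' `I_ext_i(t) = mu + G * sum_j C_ij S(y1_j(t - theta_ij) - wFIC_j y2_j(t - theta_ij))`,
#' evaluated once per step from a ring buffer of delayed firing rates.
#' In stochastic mode, additive Gaussian white noise with increment
#' `sigma * sqrt(dt) * xi` enters the `y3` equation only, with the same
#' increment in predictor and corrector stage, so `sigma = 0` reproduces
#' the deterministic trajectory bitwise.
#'
#' @param initial N x 6 matrix of initial states (or a vector of 6 for a
#'   single node); `NULL` means all zeros.
#' @param connectome a [connectome()]; `NULL` simulates `n_nodes`
#'   isolated nodes (no coupling).
#' @param p a [jr_params()]; `p$mu`, `p$G`, `p$sigma` are used.
#' @param wfic inhibitory scaling: scalar or length-N vector.
#' @param T total simulated time, ms.
#' @param dt integration step, ms.
#' @param stochastic logical; if `TRUE`, noise of amplitude `p$sigma` is
#'   applied.
#' @param seed integer seed for the noise stream.
#' @param record_dt recording interval, ms (must be a multiple of `dt`).
#' @param record_input if `TRUE`, the per-node input `I_ext_i(t)` is
#'   recorded alongside the states.
#' @param n_nodes number of nodes when `connectome` is `NULL`.
#' @return An object of class `jr_trajectory`: list with `times` (ms),
#'   `states` (list of T x N matrices `y0..y5`), `psp` (T x N matrix
#'   `y1 - y2`), `wfic`, optional `input`, `y_final`, `dt`, `record_dt`.
#' @export
integrate_heun <- function(initial = NULL, connectome = NULL,
                           p = jr_params(), wfic = 1, T = 1000, dt = 1,
                           stochastic = FALSE, seed = 1, record_dt = dt,
                           record_input = FALSE, n_nodes = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (T < dt) stop("T must be at least dt")
  if (is.null(connectome)) {
    n <- if (!is.null(n_nodes)) n_nodes
         else if (is.matrix(initial)) nrow(initial) else 1L
    weights <- matrix(0, n, n)
    steps <- matrix(0L, n, n)
  } else {
    n <- connectome$n_nodes
    weights <- connectome$weights
    steps <- compute_delays(connectome, dt)$steps
  }
  if (is.null(initial)) initial <- matrix(0, n, 6)
  if (!is.matrix(initial)) initial <- matrix(initial, 1, 6)
  stopifnot(nrow(initial) == n, ncol(initial) == 6)
  wfic <- rep_len(wfic, n)
  rec_every <- record_dt / dt
  if (abs(rec_every - round(rec_every)) > 1e-8)
    stop("record_dt must be a multiple of dt")
  sigma <- if (stochastic) p$sigma else 0
  out <- cpp_network_run(weights, steps, par_vector(p), p$G, p$mu,
                         initial, wfic, T, dt, as.integer(round(rec_every)),
                         sigma, as.integer(seed),
                         FALSE, 0, 1, 0, 0, numeric(n), numeric(n),
                         record_input, 0:5)
  states <- out$states
  names(states) <- paste0("y", 0:5)
  structure(list(times = out$times, states = states,
                 psp = states$y1 - states$y2, wfic = wfic,
                 input = if (record_input) out$input else NULL,
                 y_final = out$y_final, dt = dt, record_dt = record_dt,
                 stochastic = stochastic, seed = seed, p = p),
            class = "jr_trajectory")
}

#' @export
print.jr_trajectory <- function(x, ...) {
  cat(sprintf("Jansen-Rit trajectory: %d nodes, %g ms at dt = %g ms (%s)\n",
              ncol(x$psp), max(x$times), x$dt,
              if (x$stochastic) "stochastic" else "deterministic"))
  invisible(x)
}

#' Pyramidal postsynaptic potential of a trajectory
#'
#' The PSP of the pyramidal population is `y1 - y2` (`mode = "raw"`, the
#' model's output signal).  `mode = "effective"` returns
#' `y1 - wfic * y2`, the argument of the sigmoid in the pyramidal
#' PSP-rate equation, which is the potential actually gating the
#' pyramidal firing under feedback inhibition control.
#'
#' @param traj a `jr_trajectory` (or a list with `states$y1`,
#'   `states$y2`).
#' @param wfic per-node inhibitory scaling used for `"effective"`;
#'   defaults to the trajectory's own.
#' @param mode `"raw"` or `"effective"`.
#' @return T x N matrix of potentials (mV).
#' @export
compute_psp <- function(traj, wfic = NULL, mode = c("raw", "effective")) {
  mode <- match.arg(mode)
  y1 <- traj$states$y1
  y2 <- traj$states$y2
  if (mode == "raw") return(y1 - y2)
  if (is.null(wfic)) wfic <- traj$wfic
  wfic <- rep_len(wfic, ncol(y1))
  y1 - sweep(y2, 2, wfic, `*`)
}

#' Mean-field decomposition of the network input
#'
#' Splits the recorded per-node input into a constant offset, an
#' indegree-weighted mean-field component and a node-specific residual:
#' `I_ext_i(t) = mu + d_i R(t) + xi_i(t)`, where
#' `R(t) = G * mean_j S(y1_j - wFIC_j y2_j)` is the global mean firing
#' rate scaled by the coupling and `d_i` the indegree.  The three
#' components sum to the recorded input exactly (the residual is defined
#' as the remainder).
#'
#' @param traj a `jr_trajectory` recorded with `record_input = TRUE`.
#' @param connectome the [connectome()] used for the simulation.
#' @param p the [jr_params()] used.
#' @return List with `mu`, `R` (vector over time), `mean_field`
#'   (T x N matrix `d_i R(t)`), `residual` (T x N), `input` (T x N).
#' @export
meanfield_decomposition <- function(traj, connectome, p = traj$p) {
  if (is.null(traj$input))
    stop("trajectory was not recorded with record_input = TRUE")
  d <- indegree(connectome)
  eff <- compute_psp(traj, mode = "effective")
  rates <- matrix(jr_sigmoid(as.numeric(eff), p), nrow(eff), ncol(eff))
  R <- p$G * rowMeans(rates)
  mean_field <- outer(R, d)
  residual <- traj$input - p$mu - mean_field
  list(mu = p$mu, R = R, mean_field = mean_field, residual = residual,
       input = traj$input)
}
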