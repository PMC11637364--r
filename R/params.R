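#' Jansen-Rit model parameters
#'
#' Constructs the parameter set of the three-population Jansen-Rit neural
#' mass model together with the network-level constants (constant drive
#' `mu`, global coupling `G`, noise amplitude `sigma`).  Defaults are the
#' standard physiologically motivated values; time is in milliseconds
#' throughout, so the rate constants `a`, `b` and the sigmoid maximum
#' `v_max` are per-ms quantities (the maximum population firing rate is
#' `2 * v_max` = 0.005/ms = 5/s).
#'
#' @param A,B maximum amplitude of the excitatory / inhibitory
#'   postsynaptic potential (mV).
#' @param a,b reciprocal of the excitatory / inhibitory synaptic time
#'   constant (1/ms).
#' @param v0 firing threshold of the sigmoid (mV).
#' @param r steepness of the sigmoid (1/mV).
#' @param J number of synaptic contacts; the local coupling constants
#'   default to `c1 = J`, `c2 = 0.8 J`, `c3 = c4 = 0.25 J`.
#' @param c1,c2,c3,c4 local coupling constants (dimensionless).
#' @param v_max half of the maximum firing rate of a population (1/ms).
#' @param mu constant external drive (same units as the sigmoid output).
#' @param G global coupling scaling all long-range inputs (>= 0).
#' @param sigma additive noise amplitude entering the pyramidal
#'   PSP-rate equation in stochastic integration.
#'
#' @return An object of class `jr_params` (a named list).
#' @examples
#' p <- jr_params()
#' jr_sigmoid(p$v0, p)  # half-maximum rate 0.0025/ms at threshold
#' @export
jr_params <- function(A = 3.25, B = 22, a = 0.1, b = 0.05, v0 = 6,
                      r = 0.56, J = 135, c1 = J, c2 = 0.8 * J,
                      c3 = 0.25 * J, c4 = 0.25 * J, v_max = 0.0025,
                      mu = 0.09, G = 0, sigma = 1e-7) {
  stopifnot(a > 0, b > 0, r > 0, v_max > 0, A > 0, B > 0,
            c1 >= 0, c2 >= 0, c3 >= 0, c4 >= 0, G >= 0, sigma >= 0)
  structure(list(A = A, B = B, a = a, b = b, v0 = v0, r = r,
                 c1 = c1, c2 = c2, c3 = c3, c4 = c4, v_max = v_max,
                 mu = mu, G = G, sigma = sigma),
            class = "jr_params")
}

# compact parameter vector handed to the compiled integrators
par_vector <- function(p) {
  c(p$A, p$B, p$a, p$b, p$v0, p$r, p$c1, p$c2, p$c3, p$c4, p$v_max)
}

#' @export
print.jr_params <- function(x, ...) {
  cat("Jansen-Rit parameters (time in ms):\n")
  cat(sprintf("  A = %g mV, B = %g mV, a = %g/ms, b = %g/ms\n",
              x$A, x$B, x$a, x$b))
  cat(sprintf("  v0 = %g mV, r = %g/mV, v_max = %g/ms\n", x$v0, x$r, x$v_max))
  cat(sprintf("  c1..c4 = %g, %g, %g, %g\n", x$c1, x$c2, x$c3, x$c4))
  cat(sprintf("  mu = %g, G = %g, sigma = %g\n", x$mu, x$G, x$sigma))
  invisible(x)
}

#' Dynamic feedback-inhibition-control (dFIC) tuning parameters
#'
#' Parameters of the homeodynamic plasticity mechanism that drives the
#' per-node inhibitory scaling `wFIC_i` until the slow average of the
#' pyramidal output `y0` reaches `y0_target`.  Two slow activity-detection
#' states (`y0d`, `y2d`, low-pass filters with time constant `tau_d`)
#' feed the gradient-like learning rule
#' `dwFIC/dt = eta * y2d * (y0d - y0_target)`.
#'
#' Two window lengths are exposed because they serve different purposes:
#' `L_avg` (default 3000 ms) is the tail over which converged `wFIC` is
#' averaged into the constant `pFIC`, while `L_conv` (default 5000 ms) is
#' the tail of `y0` used for the 1% convergence verdict.
#'
#' @param eta learning rate, 1/(ms mV^2).
#' @param tau_d detection (low-pass) time constant, ms.
#' @param y0_target desired long-term average of `y0`.
#' @param T_tune total tuning duration, ms.
#' @param transient initial window (ms) during which `wFIC` is frozen at
#'   its initial value while the detection states warm up.
#' @param L_avg tail window (ms) averaged into `pFIC`.
#' @param L_conv tail window (ms) for the convergence check.
#' @param tol_rel relative tolerance of the convergence check.
#'
#' @return An object of class `dfic_params`.
#' @export
dfic_params <- function(eta = 0.005, tau_d = 1000, y0_target = 0.01,
                        T_tune = 250000, transient = 15000,
                        L_avg = 3000, L_conv = 5000, tol_rel = 0.01) {
  stopifnot(eta >= 0, tau_d > 0, T_tune > transient,
            L_avg <= T_tune - transient, L_conv <= T_tune - transient,
            tol_rel > 0)
  structure(list(eta = eta, tau_d = tau_d, y0_target = y0_target,
                 T_tune = T_tune, transient = transient, L_avg = L_avg,
                 L_conv = L_conv, tol_rel = tol_rel),
            class = "dfic_params")
}

#' @export
print.dfic_params <- function(x, ...) {
  cat(sprintf(paste0("dFIC tuning: eta = %g, tau_d = %g ms, target = %g, ",
                     "T_tune = %g ms (transient %g ms)\n"),
              x$eta, x$tau_d, x$y0_target, x$T_tune, x$transient))
  invisible(x)
}

#' Balloon hemodynamic model parameters
#'
#' The standard Balloon-model constants (signal decay `kappa`,
#' flow-dependent elimination `gamma`, hemodynamic transit time `tau`,
#' Grubb exponent `alpha`, resting oxygen extraction `rho`, resting
#' venous volume fraction `V0`) plus the scanner repetition time `TR`
#' at which the simulated BOLD signal is sampled.
#'
#' @param kappa signal decay rate, 1/s.
#' @param gamma flow-dependent elimination rate, 1/s.
#' @param tau hemodynamic transit time, s.
#' @param alpha Grubb vessel stiffness exponent, in (0, 1].
#' @param rho resting oxygen extraction fraction, in (0, 1).
#' @param V0 resting venous blood volume fraction.
#' @param TR repetition (sampling) time, ms.
#' @return An object of class `balloon_params`.
#' @export
balloon_params <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                           alpha = 0.32, rho = 0.34, V0 = 0.02, TR = 720) {
  stopifnot(kappa > 0, gamma > 0, tau > 0, alpha > 0, alpha <= 1,
            rho > 0, rho < 1, V0 > 0, TR > 0)
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 rho = rho, V0 = V0, TR = TR),
            class = "balloon_params")
}
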