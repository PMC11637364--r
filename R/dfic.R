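# Dynamic feedback inhibition control: augmented tuning dynamics,
# convergence detection, pFIC extraction and equilibrium analysis.

#' Right-hand side of the dFIC-augmented node
#'
#' Appends the three tuning derivatives to the six node derivatives:
#' the activity-detection low-pass filters
#' `dy0d/dt = (y0 - y0d)/tau_d`, `dy2d/dt = (y2 - y2d)/tau_d`, and the
#' plasticity rule `dwFIC/dt = eta * y2d * (y0d - y0_target)`.  If the
#' detected slow activity exceeds the target, inhibition strengthens
#' (`wFIC` grows), lowering the activity, and vice versa.  During the
#' transient window the `wFIC` derivative is frozen at 0.
#'
#' @param y_aug vector of 9 states: `y0..y5, y0d, y2d, wfic`.
#' @param I_ext external input to the node.
#' @param p a [jr_params()].
#' @param dp a [dfic_params()].
#' @param frozen logical; if `TRUE` the `wFIC` derivative is 0.
#' @return Numeric vector of 9 derivatives.
#' @export
tuning_rhs <- function(y_aug, I_ext, p = jr_params(), dp = dfic_params(),
                       frozen = FALSE) {
  stopifnot(length(y_aug) == 9)
  y <- y_aug[1:6]
  y0d <- y_aug[7]; y2d <- y_aug[8]; wfic <- y_aug[9]
  dy <- jr_node_rhs(y, I_ext, wfic, p)
  c(dy,
    (y[1] - y0d) / dp$tau_d,
    (y[3] - y2d) / dp$tau_d,
    if (frozen) 0 else dp$eta * y2d * (y0d - dp$y0_target))
}

#' Initial conditions for the tuning run
#'
#' Low ("sub-bistable") targets below the attractor-surface gap are
#' approached from below: per-node `y0` drawn uniform in `[0, target)`
#' with the remaining states at rest, paired with the preset drive
#' `mu = 0.09` near the low fixed-point branch.  High ("super-bistable")
#' targets are approached from above: `y0` uniform in
#' `(target, target + 0.05]` with `y1`, `y2` set consistently on the
#' high branch and the preset `mu = 0.14`.  The split point 0.05 lies
#' inside the attractor gap, where neither preset applies cleanly.
#'
#' @param y0_target the tuning target.
#' @param n_nodes number of nodes.
#' @param seed RNG seed (same seed, same ICs).
#' @param mu optional drive override; default is the preset for the
#'   target class.
#' @param p a [jr_params()] (used for the high-branch consistency).
#' @return List with `y` (N x 6 matrix), `y0d`, `y2d` (vectors, seeded
#'   from the initial state), and `mu`.
#' @export
default_initial_conditions <- function(y0_target, n_nodes = 1, seed = 1,
                                       mu = NULL, p = jr_params()) {
  super <- y0_target >= 0.05
  if (is.null(mu)) mu <- if (super) 0.14 else 0.09
  y <- matrix(0, n_nodes, 6)
  withr_seed(seed, {
    if (super) {
      y0 <- stats::runif(n_nodes, y0_target, y0_target + 0.05)
      y[, 1] <- y0
      y[, 2] <- (p$A / p$a) * (p$c2 * jr_sigmoid(p$c1 * y0, p) + mu)
      y[, 3] <- (p$B / p$b) * p$c4 * jr_sigmoid(p$c3 * y0, p)
    } else {
      y[, 1] <- stats::runif(n_nodes, 0, y0_target)
    }
  })
  list(y = y, y0d = y[, 1], y2d = y[, 3], mu = mu)
}

#' Run the deterministic dFIC tuning process
#'
#' Integrates the augmented network (nodes plus detection states and
#' `wFIC`) with the deterministic Heun scheme for `dp$T_tune` ms.  The
#' tuning itself is always noise-free; `wFIC` starts at 1 (the original
#' model), is frozen during the transient, evolves under the plasticity
#' rule afterwards, and is clipped below at 0.  Convergence is judged
#' per node: the mean of `y0` over the final `L_conv` ms must lie within
#' `tol_rel` (relative) of the target.  The per-node constant `pFIC`
#' is the time average of `wFIC` over the final `L_avg` ms.
#'
#' @param connectome a [connectome()], or `NULL` for isolated nodes.
#' @param p a [jr_params()]; `p$mu` and `p$G` set the drive and
#'   coupling.
#' @param dp a [dfic_params()].
#' @param ic initial conditions as returned by
#'   [default_initial_conditions()]; `NULL` generates them from `seed`
#'   (also adopting the preset `mu` for the target).
#' @param seed seed for the randomized initial conditions.
#' @param record_dt recording interval, ms.
#' @param dt integration step, ms.
#' @param n_nodes node count when `connectome` is `NULL`.
#' @return An object of class `tuning_result`: `times`, `wfic_traj`,
#'   `y0_traj`, `y0d_traj`, `y2d_traj` (T x N), `pfic`, `converged`,
#'   `final_rel_dev`, `wfic_final`, `y_final`, plus the configuration.
#' @export
run_tuning <- function(connectome = NULL, p = jr_params(),
                       dp = dfic_params(), ic = NULL, seed = 1,
                       record_dt = 10, dt = 1, n_nodes = NULL) {
  n <- if (!is.null(connectome)) connectome$n_nodes
       else if (!is.null(n_nodes)) n_nodes
       else if (!is.null(ic)) nrow(ic$y) else 1L
  if (is.null(ic)) {
    ic <- default_initial_conditions(dp$y0_target, n, seed, p = p)
    p$mu <- ic$mu
  }
  if (is.null(connectome)) {
    weights <- matrix(0, n, n)
    steps <- matrix(0L, n, n)
  } else {
    weights <- connectome$weights
    steps <- compute_delays(connectome, dt)$steps
  }
  rec_every <- as.integer(round(record_dt / dt))
  out <- cpp_network_run(weights, steps, par_vector(p), p$G, p$mu,
                         ic$y, rep(1, n), dp$T_tune, dt, rec_every,
                         0, as.integer(seed),
                         TRUE, dp$eta, dp$tau_d, dp$y0_target,
                         dp$transient, ic$y0d, ic$y2d, FALSE, 0L)
  times <- out$times
  y0 <- out$states[[1]]
  conv_win <- times > dp$T_tune - dp$L_conv
  avg_win <- times > dp$T_tune - dp$L_avg
  y0_mean <- colMeans(y0[conv_win, , drop = FALSE])
  final_rel_dev <- abs(y0_mean - dp$y0_target) / abs(dp$y0_target)
  pfic <- colMeans(out$wfic[avg_win, , drop = FALSE])
  structure(list(times = times, wfic_traj = out$wfic, y0_traj = y0,
                 y0d_traj = out$y0d, y2d_traj = out$y2d,
                 pfic = pfic, converged = final_rel_dev <= dp$tol_rel,
                 final_rel_dev = final_rel_dev,
                 wfic_final = out$wfic_final, y_final = out$y_final,
                 y0d_final = out$y0d_final, y2d_final = out$y2d_final,
                 p = p, dp = dp, record_dt = record_dt, dt = dt),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("dFIC tuning to target %g: %d/%d nodes converged (<= %g%%)\n",
              x$dp$y0_target, sum(x$converged), length(x$converged),
              100 * x$dp$tol_rel))
  cat("  pFIC:", paste(sprintf("%.4f", x$pfic), collapse = " "), "\n")
  cat("  final relative deviation (%):",
      paste(sprintf("%.3f", 100 * x$final_rel_dev), collapse = " "), "\n")
  invisible(x)
}

#' Extract the constant pFIC vector from a tuning run
#'
#' The per-node inhibitory constant used in post-FIC simulations is the
#' arithmetic time average of `wFIC_i` over the final `L_avg` ms of the
#' tuning grid.
#'
#' @param tr a `tuning_result`.
#' @param L_avg averaging window, ms; default from the tuning
#'   configuration.
#' @return Numeric vector of length N.
#' @export
extract_pfic <- function(tr, L_avg = tr$dp$L_avg) {
  t_end <- max(tr$times)
  if (L_avg > t_end) stop("averaging window exceeds the trajectory")
  win <- tr$times > t_end - L_avg
  colMeans(tr$wfic_traj[win, , drop = FALSE])
}

#' Scan an attractor atlas for dFIC equilibria
#'
#' A dFIC equilibrium at input `I_ext` is a `wFIC` value at which a
#' stable attractor's cycle-averaged `y0` equals the target.  Along
#' each attractor branch (grouped by kind) at fixed `I_ext`, sign
#' changes of `y0_mean - y0_target` across consecutive scanned `wFIC`
#' values are located and linearly interpolated; the equilibrium is
#' stable when the local slope `d y0_mean / d wFIC` is negative (the
#' plasticity rule's stability condition), which holds by construction
#' for inhibitory control.
#'
#' @param atlas an `attractor_atlas` spanning the `wFIC` region of
#'   interest.
#' @param y0_target the target level.
#' @return Data frame with columns `I_ext`, `wfic_star`,
#'   `attractor_kind`, `slope`, `stable`; zero rows when the target
#'   intersects no attractor (a target inside the coverage gap).
#' @export
dfic_equilibrium_scan <- function(atlas, y0_target) {
  st <- atlas[atlas$kind != "unclassified", ]
  if (nrow(st) == 0) stop("empty atlas")
  # coexisting low and high fixed points are distinct branches
  branch <- ifelse(st$kind == "FP",
                   ifelse(st$y0_mean < 0.05, "FP_low", "FP_high"),
                   st$kind)
  rows <- list()
  for (I in sort(unique(st$I_ext))) {
    for (kd in unique(branch[st$I_ext == I])) {
      br <- st[st$I_ext == I & branch == kd, ]
      br <- br[order(br$wfic), ]
      if (nrow(br) < 2) next
      dval <- br$y0_mean - y0_target
      cross <- which(dval[-1] * dval[-length(dval)] <= 0 &
                       (dval[-1] != 0 | dval[-length(dval)] != 0) &
                       diff(br$wfic) > 0)
      for (k in cross) {
        frac <- dval[k] / (dval[k] - dval[k + 1])
        wstar <- br$wfic[k] + frac * (br$wfic[k + 1] - br$wfic[k])
        slope <- (br$y0_mean[k + 1] - br$y0_mean[k]) /
          (br$wfic[k + 1] - br$wfic[k])
        rows[[length(rows) + 1]] <-
          data.frame(I_ext = I, wfic_star = wstar, attractor_kind = kd,
                     slope = slope, stable = slope < 0,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(I_ext = numeric(0), wfic_star = numeric(0),
                      attractor_kind = character(0), slope = numeric(0),
                      stable = logical(0)))
  do.call(rbind, rows)
}

#' Verify a dFIC equilibrium by perturbation
#'
#' Perturbs `wFIC` by `+/- perturb` (relative) from the equilibrium
#' value, lets the node settle onto the attractor at the perturbed
#' scaling, then runs the tuning dynamics at fixed external input and
#' checks that `wFIC` returns to the equilibrium within `tol`
#' (relative) from both sides.  With `eta = 0` there is no restoring
#' drift and the check fails.
#'
#' @param I_ext constant external input (becomes `mu` at `G = 0`).
#' @param wfic_star equilibrium inhibitory scaling.
#' @param y0_target the target the equilibrium realizes.
#' @param p a [jr_params()].
#' @param dp a [dfic_params()]; its `T_tune` bounds the verification
#'   run.
#' @param perturb relative perturbation, default 0.05.
#' @param tol relative return tolerance, default 0.02.
#' @return `TRUE` if both perturbations return to `wfic_star`;
#'   `FALSE` otherwise (including divergence).
#' @export
verify_stability <- function(I_ext, wfic_star, y0_target,
                             p = jr_params(), dp = dfic_params(),
                             perturb = 0.05, tol = 0.02) {
  p$mu <- I_ext
  p$G <- 0
  dp$y0_target <- y0_target
  ok <- TRUE
  for (sgn in c(-1, 1)) {
    w0 <- wfic_star * (1 + sgn * perturb)
    settled <- tryCatch(
      integrate_heun(NULL, NULL, p, wfic = w0, T = 10000, dt = 1),
      error = function(e) NULL)
    if (is.null(settled)) return(FALSE)
    ic <- list(y = matrix(settled$y_final, 1, 6),
               y0d = settled$y_final[1], y2d = settled$y_final[3],
               mu = I_ext)
    res <- tryCatch({
      n <- 1L
      out <- cpp_network_run(matrix(0, 1, 1), matrix(0L, 1, 1),
                             par_vector(p), 0, p$mu, ic$y, w0,
                             dp$T_tune, 1, 100L, 0, 1L,
                             TRUE, dp$eta, dp$tau_d, y0_target,
                             0, ic$y0d, ic$y2d, FALSE, 0L)
      out$wfic_final
    }, error = function(e) NA_real_)
    if (!is.finite(res) || abs(res - wfic_star) / wfic_star > tol)
      ok <- FALSE
  }
  ok
}
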