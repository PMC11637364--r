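#' Simulate BOLD with the Balloon hemodynamic model
#'
#' Integrates, per node, the four Balloon states (vasodilatory signal,
#' blood inflow, venous volume, deoxyhemoglobin content) driven by a
#' neural activity time series, and reads out the standard nonlinear
#' BOLD percent-signal change, sampled (not averaged) at multiples of
#' the repetition time `TR`.  Zero drive leaves the system at its
#' resting baseline (zero percent change); a constant drive settles to
#' a constant plateau.
#'
#' @param neural T x N matrix (or vector for one node) of nonnegative
#'   neural drive.  The recommended drive is the pyramidal firing rate
#'   `S(PSP)` expressed per second (see [bold_from_psp()]); a raw-PSP
#'   drive is accepted but should be rescaled by the caller.
#' @param dt sampling interval of `neural`, ms.
#' @param bp a [balloon_params()].
#' @param demean subtract each node's mean drive before integrating
#'   (off by default; the Balloon equations expect activity relative
#'   to baseline, and a nonnegative rate drive encodes the baseline in
#'   its mean level).
#' @return An object of class `bold_series`: list with `times` (ms,
#'   exact multiples of `TR`), `signal` (T_bold x N, percent change),
#'   `TR`.
#' @export
balloon_simulate <- function(neural, dt, bp = balloon_params(),
                             demean = FALSE) {
  if (!is.matrix(neural)) neural <- matrix(neural, ncol = 1)
  if (anyNA(neural) || any(!is.finite(neural)))
    stop("non-finite neural drive")
  if (demean) neural <- sweep(neural, 2, colMeans(neural))
  out <- cpp_balloon_run(neural, dt, bp$kappa, bp$gamma, bp$tau,
                         bp$alpha, bp$rho, bp$V0, bp$TR)
  structure(list(times = out$times, signal = out$signal, TR = bp$TR),
            class = "bold_series")
}

#' BOLD from a pyramidal PSP time series
#'
#' Convenience wrapper converting PSPs to the pyramidal firing-rate
#' drive `1000 * S(PSP)` (per second, bounded and nonnegative) before
#' Balloon integration.
#'
#' @param psp T x N matrix of pyramidal PSPs (mV).
#' @param dt sampling interval, ms.
#' @param p a [jr_params()] for the sigmoid.
#' @param bp a [balloon_params()].
#' @param drive `"rate"` (default) or `"psp"` (raw PSP scaled to a
#'   comparable magnitude).
#' @return A `bold_series`.
#' @export
bold_from_psp <- function(psp, dt, p = jr_params(),
                          bp = balloon_params(),
                          drive = c("rate", "psp")) {
  drive <- match.arg(drive)
  x <- if (drive == "rate") 1000 * jr_sigmoid(psp, p) else psp / 10
  if (!is.matrix(x)) x <- matrix(x, nrow = NROW(psp))
  balloon_simulate(x, dt, bp)
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("BOLD series: %d samples x %d nodes, TR = %g ms\n",
              nrow(x$signal), ncol(x$signal), x$TR))
  invisible(x)
}
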