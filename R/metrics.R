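# Analysis statistics: FC, FCD, KS similarity, multimodal fitness,
# Welch spectra, Poincare maps and window resampling.

upper_tri <- function(m) m[upper.tri(m)]

#' Functional connectivity of a BOLD series
#'
#' Pearson correlation matrix across nodes, with `fc_mean` the mean of
#' the strict upper triangle (the global synchronization level).  A
#' zero-variance node yields correlation 0 against every other node and
#' is flagged.
#'
#' @param bold a `bold_series` or a T x N numeric matrix.
#' @return An object of class `fc_matrix`: list with `values` (N x N),
#'   `fc_mean`, `flagged` (indices of zero-variance nodes).
#' @export
functional_connectivity <- function(bold) {
  x <- if (inherits(bold, "bold_series")) bold$signal else as.matrix(bold)
  if (nrow(x) < 3) stop("need at least 3 time points")
  sds <- apply(x, 2, stats::sd)
  flagged <- unname(which(sds == 0))
  values <- suppressWarnings(stats::cor(x))
  values[!is.finite(values)] <- 0
  diag(values) <- 1
  dimnames(values) <- NULL
  structure(list(values = values, fc_mean = mean(upper_tri(values)),
                 flagged = flagged),
            class = "fc_matrix")
}

#' Correlation between two FC matrices
#'
#' Pearson correlation of the strict upper triangles of a simulated and
#' an empirical FC matrix (the static-FC fit score `R_FC`).
#'
#' @param sim,emp `fc_matrix` objects or plain N x N matrices of equal
#'   size.
#' @return Scalar in `[-1, 1]`.
#' @export
fc_fit <- function(sim, emp) {
  ms <- if (inherits(sim, "fc_matrix")) sim$values else as.matrix(sim)
  me <- if (inherits(emp, "fc_matrix")) emp$values else as.matrix(emp)
  if (!all(dim(ms) == dim(me))) stop("FC matrices differ in size")
  stats::cor(upper_tri(ms), upper_tri(me))
}

#' Functional connectivity dynamics (FCD)
#'
#' Sliding-window FC: windows of `window_s` seconds advanced by
#' `step_tr` repetition times; each window's FC upper triangle is
#' vectorized and the FCD matrix collects Pearson correlations between
#' all window pairs.  The value distribution (strict upper triangle of
#' the FCD matrix, overlapping-window pairs included) summarizes how
#' strongly FC patterns recur over time.
#'
#' @param bold a `bold_series` (or T x N matrix plus `TR`).
#' @param window_s window length, seconds (default 60).
#' @param step_tr window increment in TRs (default 1).
#' @param TR repetition time in ms when `bold` is a plain matrix.
#' @return An object of class `fcd_result`: `window_fcs` (W x P),
#'   `fcd_matrix` (W x W), `values`, `window_trs`.
#' @export
fcd <- function(bold, window_s = 60, step_tr = 1, TR = NULL) {
  x <- if (inherits(bold, "bold_series")) bold$signal else as.matrix(bold)
  if (is.null(TR)) TR <- bold$TR
  wlen <- floor(window_s * 1000 / TR)
  n_tr <- nrow(x)
  if (wlen > n_tr) stop("window longer than the series")
  starts <- seq(1, n_tr - wlen + 1, by = step_tr)
  wf <- t(vapply(starts, function(s) {
    v <- suppressWarnings(stats::cor(x[s:(s + wlen - 1), , drop = FALSE]))
    v[!is.finite(v)] <- 0
    upper_tri(v)
  }, numeric(ncol(x) * (ncol(x) - 1) / 2)))
  fm <- suppressWarnings(stats::cor(t(wf)))
  fm[!is.finite(fm)] <- 0
  diag(fm) <- 1
  structure(list(window_fcs = wf, fcd_matrix = fm,
                 values = upper_tri(fm), window_trs = wlen),
            class = "fcd_result")
}

#' Kolmogorov-Smirnov similarity of two value distributions
#'
#' `1 - KSD`, where KSD is the two-sample Kolmogorov-Smirnov statistic;
#' 1 for identical samples, 0 for disjoint supports.
#'
#' @param sim_values,emp_values nonempty numeric samples.
#' @return Scalar in `[0, 1]`.
#' @export
ks_similarity <- function(sim_values, emp_values) {
  if (!length(sim_values) || !length(emp_values)) stop("empty sample")
  1 - unname(suppressWarnings(
    stats::ks.test(sim_values, emp_values)$statistic))
}

#' Multimodal fitness (MMF) of a simulation
#'
#' Combines the static-FC correlation and the FCD similarity as a
#' weighted mean, `MMF = (d1 R_FC + d2 (1 - KSD)) / (d1 + d2)` with
#' default weights `d1 = 1`, `d2 = 0.75` chosen so that both terms
#' contribute comparably given their typical maxima.  Simulations more
#' synchronized than `sync_threshold` (mean FC above 0.25) are
#' rejected as biologically implausible and carry no MMF value.
#'
#' @param r_fc static FC fit.
#' @param one_minus_ksd FCD similarity.
#' @param fc_mean mean upper-triangle FC of the simulation.
#' @param d1,d2 weights.
#' @param sync_threshold rejection threshold on `fc_mean`.
#' @return An object of class `fit_scores`: list with `r_fc`,
#'   `one_minus_ksd`, `fc_mean`, `mmf` (NA when rejected), `rejected`,
#'   `d1`, `d2`, `sync_threshold`.
#' @examples
#' mmf(0.6, 0.8, fc_mean = 0.2)$mmf  # (0.6 + 0.6) / 1.75
#' @export
mmf <- function(r_fc, one_minus_ksd, fc_mean, d1 = 1, d2 = 0.75,
                sync_threshold = 0.25) {
  rejected <- fc_mean > sync_threshold
  structure(list(
    r_fc = r_fc, one_minus_ksd = one_minus_ksd, fc_mean = fc_mean,
    mmf = if (rejected) NA_real_
          else (d1 * r_fc + d2 * one_minus_ksd) / (d1 + d2),
    rejected = rejected, d1 = d1, d2 = d2,
    sync_threshold = sync_threshold), class = "fit_scores")
}

#' @export
print.fit_scores <- function(x, ...) {
  cat(sprintf("fit: R_FC = %.4f, 1-KSD = %.4f, FC_mean = %.4f -> %s\n",
              x$r_fc, x$one_minus_ksd, x$fc_mean,
              if (x$rejected) "rejected (over-synchronized)"
              else sprintf("MMF = %.4f", x$mmf)))
  invisible(x)
}

#' Welch power spectral density
#'
#' Average periodogram over Hann-windowed overlapping segments
#' (defaults: 4 s segments, 50% overlap, giving sub-Hz resolution at
#' the model's delta-to-alpha rhythms).  One-sided density normalized
#' so that the integral over frequency approximates the signal
#' variance.
#'
#' @param x numeric vector or T x N matrix.
#' @param dt sampling interval, ms.
#' @param seg_s segment length, seconds.
#' @param overlap fractional segment overlap.
#' @return List with `freq` (Hz) and `power` (F x N density matrix).
#' @export
welch_psd <- function(x, dt, seg_s = 4, overlap = 0.5) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  fs <- 1000 / dt
  nseg <- min(nrow(x), floor(seg_s * fs))
  step <- max(1, floor(nseg * (1 - overlap)))
  starts <- seq(1, nrow(x) - nseg + 1, by = step)
  if (length(starts) < 2)
    stop("series too short for at least two Welch segments")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(w^2)
  nf <- nseg %/% 2
  power <- matrix(0, nf, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + nseg - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    sp <- Mod(stats::mvfft(seg))^2 / (u * fs)
    power <- power + 2 * sp[2:(nf + 1), , drop = FALSE]
  }
  list(freq = (1:nf) / (nseg / fs), power = power / length(starts))
}

#' Poincare map of a PSP time series
#'
#' Local maxima are points that strictly dominate their neighborhood in
#' a `maxima_window_ms` window (default 100 ms, i.e. +/- 50 ms); the
#' map sends each maximum to the next one, producing the point pairs
#' `(PSP_k, PSP_k+1)` whose location identifies the dynamical regime a
#' node occupies between the two maxima.
#'
#' @param psp_node numeric vector, one node's PSP.
#' @param dt sampling interval, ms.
#' @param maxima_window_ms full width of the dominance window, ms.
#' @return List with `idx`, `times` (ms), `maxima` (mV) and `pairs`
#'   (K-1 x 2 matrix); empty for monotone input.
#' @export
poincare_map <- function(psp_node, dt, maxima_window_ms = 100) {
  half <- max(1L, as.integer(round(maxima_window_ms / 2 / dt)))
  idx <- cpp_window_maxima(as.numeric(psp_node), half)
  vals <- psp_node[idx]
  pairs <- if (length(vals) >= 2)
    cbind(vals[-length(vals)], vals[-1]) else matrix(numeric(0), 0, 2)
  list(idx = idx, times = (idx - 1) * dt, maxima = vals, pairs = pairs)
}

#' Classify regime occupancy from Poincare pairs
#'
#' Quadrant rule with activity threshold `c` (default 6 mV) and upper
#' bound `hi` (18 mV): a pair with both maxima below `c` indicates the
#' low fixed point; both at or above `c`, the fast limit cycle; one on
#' each side, the slow limit cycle (which forms two alternating maxima
#' per period).  Each inter-maxima interval is attributed to its
#' pair's regime (time-weighted occupancy); a node "exhibits" a regime
#' when its occupancy is at least `min_frac` of the simulation time.
#'
#' @param pairs K x 2 matrix from [poincare_map()].
#' @param times_ms times of the maxima, ms.
#' @param total_t_ms total simulation time, ms.
#' @param c regime threshold, mV.
#' @param hi upper bound of the fast-cycle quadrant, mV.
#' @param min_frac minimum occupancy fraction for an exhibited regime.
#' @return List with `occupancy` (named fractions), `exhibited`
#'   (named logicals), `regime_count`.
#' @export
classify_regimes <- function(pairs, times_ms, total_t_ms, c = 6,
                             hi = 18, min_frac = 0.075) {
  occ <- c(low_FP = 0, fast_LC = 0, slow_LC = 0)
  if (nrow(pairs) >= 1 && length(times_ms) != nrow(pairs) + 1)
    stop("times_ms must hold one time per maximum (pairs + 1)")
  if (nrow(pairs) >= 1) {
    gaps <- diff(times_ms)
    lab <- ifelse(pairs[, 1] < c & pairs[, 2] < c, "low_FP",
            ifelse(pairs[, 1] >= c & pairs[, 2] >= c, "fast_LC",
                   "slow_LC"))
    for (rg in names(occ))
      occ[rg] <- sum(gaps[lab == rg]) / total_t_ms
  }
  exhibited <- occ >= min_frac
  list(occupancy = occ, exhibited = exhibited,
       regime_count = sum(exhibited))
}

#' Poincare regime analysis for all nodes of a simulation
#'
#' Applies [poincare_map()] and [classify_regimes()] per node and
#' tabulates how many nodes exhibit one, two or three regimes.
#'
#' @param psp T x N matrix of PSPs.
#' @param dt sampling interval, ms.
#' @inheritParams classify_regimes
#' @param maxima_window_ms dominance window, ms.
#' @return An object of class `poincare_result`: `occupancy` (N x 3),
#'   `exhibited` (N x 3 logical), `regime_count` (N),
#'   `count_histogram` (named counts for 1, 2, 3 regimes), `pairs`
#'   (list per node).
#' @export
poincare_classify <- function(psp, dt, maxima_window_ms = 100, c = 6,
                              hi = 18, min_frac = 0.075) {
  if (!is.matrix(psp)) psp <- matrix(psp, ncol = 1)
  n <- ncol(psp)
  total_t <- (nrow(psp) - 1) * dt
  occ <- matrix(0, n, 3, dimnames = list(NULL, c("low_FP", "fast_LC",
                                                 "slow_LC")))
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    pm <- poincare_map(psp[, i], dt, maxima_window_ms)
    cl <- classify_regimes(pm$pairs, pm$times, total_t, c, hi, min_frac)
    occ[i, ] <- cl$occupancy
    pairs[[i]] <- pm$pairs
  }
  exhibited <- occ >= min_frac
  rc <- rowSums(exhibited)
  structure(list(occupancy = occ, exhibited = exhibited,
                 regime_count = rc,
                 count_histogram = c(`1` = sum(rc == 1),
                                     `2` = sum(rc == 2),
                                     `3` = sum(rc == 3)),
                 pairs = pairs),
            class = "poincare_result")
}

#' Window-resampled MMF statistics
#'
#' Computes MMF scores on overlapping sub-windows of a BOLD run (default
#' 19.2 min) against an empirical target, then either bootstraps the
#' window scores (resampling with replacement, confidence interval for
#' the mean) or, given a second condition, performs a label-permutation
#' test of the mean MMF difference (sampling without replacement,
#' two-sided p-value).
#'
#' @param bold a `bold_series`.
#' @param emp a `surrogate_empirical` (or list with `fc_target`,
#'   `fcd_values`).
#' @param window_min sub-window length, minutes.
#' @param mode `"bootstrap"` or `"permutation"`.
#' @param n_resamples number of resamples.
#' @param seed RNG seed.
#' @param bold2 second condition for the permutation test.
#' @param step_min window step, minutes.
#' @param fcd_window_s FCD window within each sub-window, seconds.
#' @return For bootstrap: list with `window_mmf`, `boot_means`, `ci`
#'   (2.5/97.5%), `mean`.  For permutation: list with `window_mmf`,
#'   `window_mmf2`, `observed_diff`, `p_value`.
#' @export
window_resample_mmf <- function(bold, emp, window_min = 19.2,
                                mode = c("bootstrap", "permutation"),
                                n_resamples = 1000, seed = 1,
                                bold2 = NULL, step_min = 2,
                                fcd_window_s = 60) {
  mode <- match.arg(mode)
  emp_fc <- if (inherits(emp$fc_target, "fc_matrix")) emp$fc_target
            else list(values = emp$fc_target)
  window_scores <- function(b) {
    n_tr <- nrow(b$signal)
    wlen <- floor(window_min * 60000 / b$TR)
    step <- max(1, floor(step_min * 60000 / b$TR))
    if (wlen > n_tr) stop("BOLD series shorter than the resampling window")
    starts <- seq(1, n_tr - wlen + 1, by = step)
    if (length(starts) < 2) stop("need at least two overlapping windows")
    vapply(starts, function(s) {
      sub <- structure(list(signal = b$signal[s:(s + wlen - 1), ,
                                              drop = FALSE], TR = b$TR),
                       class = "bold_series")
      fc <- functional_connectivity(sub)
      fd <- fcd(sub, window_s = fcd_window_s)
      sc <- mmf(fc_fit(fc, emp_fc$values),
                ks_similarity(fd$values, emp$fcd_values), fc$fc_mean)
      if (sc$rejected) NA_real_ else sc$mmf
    }, numeric(1))
  }
  m1 <- window_scores(bold)
  withr_seed(seed, {
    if (mode == "bootstrap") {
      v <- m1[!is.na(m1)]
      boots <- vapply(seq_len(n_resamples), function(i)
        mean(sample(v, length(v), replace = TRUE)), numeric(1))
      out <- list(window_mmf = m1, boot_means = boots,
                  ci = stats::quantile(boots, c(0.025, 0.975)),
                  mean = mean(v))
    } else {
      if (is.null(bold2)) stop("permutation mode needs a second condition")
      m2 <- window_scores(bold2)
      v1 <- m1[!is.na(m1)]; v2 <- m2[!is.na(m2)]
      obs <- mean(v1) - mean(v2)
      pool <- c(v1, v2)
      perm <- vapply(seq_len(n_resamples), function(i) {
        pick <- sample(length(pool), length(v1))
        mean(pool[pick]) - mean(pool[-pick])
      }, numeric(1))
      out <- list(window_mmf = m1, window_mmf2 = m2, observed_diff = obs,
                  p_value = (1 + sum(abs(perm) >= abs(obs))) /
                    (1 + n_resamples))
    }
  })
  out
}
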