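# Brute-force attractor mapping of the isolated Jansen-Rit node over the
# (I_ext, wFIC) plane.  Stable attractors are found by direct integration
# from several initial conditions (cold low/high states plus warm-started
# branch following), classified from the trajectory tail, and
# deduplicated.  Unstable branches are not mapped.

# dominant spectral frequency (Hz) of a demeaned tail sampled at dt (ms)
spectral_peak <- function(x, dt) {
  x <- x - mean(x)
  n <- length(x)
  # decimate to keep the FFT small; the rhythms of interest are < 30 Hz
  dec <- max(1L, floor(n / 8192))
  if (dec > 1) {
    x <- x[seq(1, n, by = dec)]
    dt <- dt * dec
    n <- length(x)
  }
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) / (n * dt / 1000)
  keep <- freqs > 0.2 & freqs <= 0.5 / (dt / 1000)
  if (!any(keep)) return(0)
  freqs[keep][which.max(spec[keep])]
}

#' Classify the attractor of a settled single-node trajectory tail
#'
#' A tail with peak-to-peak `y0` amplitude below `amp_threshold` is a
#' fixed point (FP).  Otherwise the segment is a limit cycle whose
#' frequency is the dominant spectral peak of the PSP; cycles at or
#' below 6 Hz are labelled `slow_LC` (delta/theta band) and faster ones
#' `fast_LC` (alpha band).  The cycle-averaged `y0` ("center" of the
#' attractor) is the time average over an integer number of cycles.
#' A tail whose halves disagree in mean by more than half its amplitude
#' is reported `unclassified` (still in transit between attractors).
#'
#' @param y0_tail,psp_tail state and PSP samples after settling (>= 5 s
#'   recommended).
#' @param dt sampling interval, ms.
#' @param amp_threshold FP/LC peak-to-peak amplitude threshold on `y0`.
#' @return List with `kind` (`"FP"`, `"slow_LC"`, `"fast_LC"`,
#'   `"unclassified"`), `y0_mean`, `freq` (Hz, 0 for FP), `psp_mean`,
#'   `psp_amp`.
#' @export
classify_attractor <- function(y0_tail, psp_tail, dt,
                               amp_threshold = 1e-4) {
  n <- length(y0_tail)
  q <- n %/% 4
  early <- seq_len(q)
  late <- seq(n - q + 1, n)
  amp_early <- diff(range(y0_tail[early]))
  amp_late <- diff(range(y0_tail[late]))
  # A fixed point is recognized either by a flat late tail, or by small
  # ringing that is clearly decaying: the Jansen-Rit high-activity state
  # is a weakly damped focus whose transient oscillations would
  # otherwise masquerade as a limit cycle.  Genuine cycles of this model
  # have y0 amplitude >> 0.02 or a non-decaying envelope.
  if (amp_late < amp_threshold ||
      (amp_late < 0.02 && amp_late < 0.9 * amp_early)) {
    return(list(kind = "FP", y0_mean = mean(y0_tail[late]), freq = 0,
                psp_mean = mean(psp_tail[late]),
                psp_amp = diff(range(psp_tail[late]))))
  }
  amp <- diff(range(y0_tail))
  psp_amp <- diff(range(psp_tail))
  half <- n %/% 2
  drift <- abs(mean(y0_tail[seq_len(half)]) - mean(y0_tail[-seq_len(half)]))
  freq <- spectral_peak(psp_tail, dt)
  # a pure linear drift has half-mean difference amp/2; settled cycles
  # stay well below a quarter of their amplitude
  if (freq == 0 || drift > 0.25 * amp) {
    return(list(kind = "unclassified", y0_mean = mean(y0_tail),
                freq = freq, psp_mean = mean(psp_tail), psp_amp = psp_amp))
  }
  # average over an integer number of cycles (tail-aligned, so any
  # remaining early transient is excluded) to avoid partial-cycle bias
  period_steps <- 1000 / freq / dt
  n_cyc <- floor(n / period_steps)
  use <- seq(n - max(1, round(n_cyc * period_steps)) + 1, n)
  list(kind = if (freq <= 6) "slow_LC" else "fast_LC",
       y0_mean = mean(y0_tail[use]), freq = freq,
       psp_mean = mean(psp_tail[use]), psp_amp = psp_amp)
}

# fixed-point-consistent initial condition on the high-activity branch:
# solves y0 = (A/a) S(y1(y0) - wfic y2(y0)) for the largest root
high_branch_ic <- function(I_ext, wfic, p, lower = 0.03, upper = 0.25) {
  g <- function(y0) {
    y1 <- (p$A / p$a) * (p$c2 * jr_sigmoid(p$c1 * y0, p) + I_ext)
    y2 <- (p$B / p$b) * p$c4 * jr_sigmoid(p$c3 * y0, p)
    (p$A / p$a) * jr_sigmoid(y1 - wfic * y2, p) - y0
  }
  grid <- seq(upper, lower, length.out = 60)
  vals <- vapply(grid, g, numeric(1))
  sgn <- sign(vals)
  cross <- which(sgn[-1] != sgn[-length(sgn)])[1]
  if (is.na(cross)) return(NULL)
  root <- stats::uniroot(g, c(grid[cross + 1], grid[cross]))$root
  y1 <- (p$A / p$a) * (p$c2 * jr_sigmoid(p$c1 * root, p) + I_ext)
  y2 <- (p$B / p$b) * p$c4 * jr_sigmoid(p$c3 * root, p)
  c(root, y1, y2, 0, 0, 0)
}

# integrate one isolated node and classify its settled attractor
node_attractor <- function(I_ext, wfic, ic, p, t_settle = 5000,
                           t_measure = 10000, dt = 0.5,
                           amp_threshold = 1e-4) {
  run <- cpp_node_run(I_ext, wfic, as.numeric(ic), par_vector(p),
                      t_settle + t_measure, t_settle, dt, 1L)
  cl <- classify_attractor(run$y0, run$psp, dt, amp_threshold)
  cl$I_ext <- I_ext
  cl$wfic <- wfic
  cl$y_final <- run$y_final
  cl
}

# add a classified attractor to a per-cell list unless a duplicate
# (same kind, y0_mean within dedup_tol) is already present
add_record <- function(records, cl, dedup_tol) {
  if (cl$kind == "unclassified") return(records)
  for (r in records) {
    if (r$kind == cl$kind && abs(r$y0_mean - cl$y0_mean) < dedup_tol)
      return(records)
  }
  c(records, list(cl))
}

#' Brute-force attractor atlas over (I_ext, wFIC)
#'
#' For every grid cell the isolated node is integrated from up to four
#' initial conditions: a cold low state (all zeros), a cold
#' high-branch state (fixed-point-consistent), and two warm-started
#' branch-following passes (ascending and descending in `I_ext`, each
#' continuing from the final state of the neighbouring cell).  Warm
#' starts track limit-cycle branches beyond the fold points where cold
#' starts fall off, a continuation-lite replacement for numerical
#' bifurcation continuation; only stable attractors are found.
#'
#' @param I_ext_grid monotone increasing grid of external inputs.
#' @param wfic_grid monotone increasing grid of inhibitory scalings.
#' @param p a [jr_params()].
#' @param t_settle,t_measure settling and measuring window per cell, ms.
#' @param dt integration step, ms.
#' @param amp_threshold FP/LC amplitude threshold (see
#'   [classify_attractor()]).
#' @param dedup_tol minimum `y0_mean` separation of distinct coexisting
#'   attractors of the same kind.
#' @return An `attractor_atlas`: a data frame with columns `I_ext`,
#'   `wfic`, `kind`, `y0_mean`, `freq`, `psp_mean`, `psp_amp`.
#' @export
sweep_attractors <- function(I_ext_grid, wfic_grid = 1, p = jr_params(),
                             t_settle = 5000, t_measure = 10000, dt = 0.5,
                             amp_threshold = 1e-4, dedup_tol = 2e-3) {
  stopifnot(!is.unsorted(I_ext_grid), !is.unsorted(wfic_grid))
  rows <- list()
  for (w in wfic_grid) {
    cells <- vector("list", length(I_ext_grid))
    # ascending warm pass + cold low start
    warm <- NULL
    for (k in seq_along(I_ext_grid)) {
      I <- I_ext_grid[k]
      recs <- list()
      cl <- node_attractor(I, w, rep(0, 6), p, t_settle, t_measure, dt,
                           amp_threshold)
      recs <- add_record(recs, cl, dedup_tol)
      if (!is.null(warm)) {
        cl2 <- node_attractor(I, w, warm, p, t_settle, t_measure, dt,
                              amp_threshold)
        recs <- add_record(recs, cl2, dedup_tol)
        warm <- cl2$y_final
      } else {
        warm <- cl$y_final
      }
      cells[[k]] <- recs
    }
    # descending warm pass + cold high start
    warm <- NULL
    for (k in rev(seq_along(I_ext_grid))) {
      I <- I_ext_grid[k]
      hic <- high_branch_ic(I, w, p)
      if (!is.null(hic)) {
        # small kick off the exact root so that an unstable fixed point
        # departs within the settling window instead of lingering
        hic[1] <- hic[1] + 1e-3
        cl <- node_attractor(I, w, hic, p, t_settle, t_measure, dt,
                             amp_threshold)
        cells[[k]] <- add_record(cells[[k]], cl, dedup_tol)
        if (is.null(warm)) warm <- cl$y_final
      }
      if (!is.null(warm)) {
        cl2 <- node_attractor(I, w, warm, p, t_settle, t_measure, dt,
                              amp_threshold)
        cells[[k]] <- add_record(cells[[k]], cl2, dedup_tol)
        warm <- cl2$y_final
      }
    }
    for (k in seq_along(I_ext_grid)) {
      for (r in cells[[k]]) {
        rows[[length(rows) + 1]] <-
          data.frame(I_ext = r$I_ext, wfic = r$wfic, kind = r$kind,
                     y0_mean = r$y0_mean, freq = r$freq,
                     psp_mean = r$psp_mean, psp_amp = r$psp_amp,
                     stringsAsFactors = FALSE)
      }
    }
  }
  atlas <- do.call(rbind, rows)
  class(atlas) <- c("attractor_atlas", "data.frame")
  atlas
}

#' Coexistence (bistability) intervals along I_ext at fixed wFIC
#'
#' Labels each grid point of a single-wFIC atlas slice by the set of
#' coexisting attractor classes (low/high fixed points split at
#' `y0_split`) and extracts the contiguous `I_ext` intervals of each
#' coexistence class, plus the onset of the fast-limit-cycle-only regime
#' and of the oscillation-free high fixed point.
#'
#' @param atlas an `attractor_atlas` (one wFIC value, or pass `wfic` to
#'   select a slice).
#' @param wfic slice to analyse, default 1.
#' @param y0_split `y0_mean` boundary between low and high FPs.
#' @return List with data frame `intervals` (columns `class`, `I_min`,
#'   `I_max`) and scalars `fast_only_onset`, `high_fp_onset` (smallest
#'   `I_ext` above which no limit cycle remains).
#' @export
bistability_intervals <- function(atlas, wfic = 1, y0_split = 0.05) {
  sl <- atlas[abs(atlas$wfic - wfic) < 1e-9, ]
  if (nrow(sl) == 0) stop("atlas has no slice at wfic = ", wfic)
  Is <- sort(unique(sl$I_ext))
  label_of <- function(r) {
    if (r$kind == "FP") {
      if (r$y0_mean < y0_split) "low_FP" else "high_FP"
    } else r$kind
  }
  sets <- lapply(Is, function(I) {
    sub <- sl[sl$I_ext == I, ]
    sort(unique(vapply(seq_len(nrow(sub)),
                       function(i) label_of(sub[i, ]), character(1))))
  })
  has <- function(set, a, b) all(c(a, b) %in% set)
  classes <- list(fp_fp = c("low_FP", "high_FP"),
                  fp_fastlc = c("low_FP", "fast_LC"),
                  fastlc_slowlc = c("fast_LC", "slow_LC"))
  ivs <- lapply(names(classes), function(nm) {
    pair <- classes[[nm]]
    in_class <- vapply(sets, has, logical(1), pair[1], pair[2])
    if (!any(in_class)) return(NULL)
    data.frame(class = nm, I_min = min(Is[in_class]),
               I_max = max(Is[in_class]), stringsAsFactors = FALSE)
  })
  intervals <- do.call(rbind, ivs[!vapply(ivs, is.null, logical(1))])
  only_fast <- vapply(sets, function(s) identical(s, "fast_LC"), logical(1))
  any_lc <- vapply(sets, function(s) any(c("fast_LC", "slow_LC") %in% s),
                   logical(1))
  no_lc_above <- Is[!any_lc & Is > stats::median(Is)]
  list(intervals = intervals,
       fast_only_onset = if (any(only_fast)) min(Is[only_fast]) else NA_real_,
       high_fp_onset = if (length(no_lc_above)) min(no_lc_above) else NA_real_)
}

#' Feasibility of activity targets and the attractor-coverage gap
#'
#' A target level `y0_target` is feasible at a given `I_ext` if some
#' stable attractor with cycle-averaged `y0` within `y0_tol` of the
#' target exists at some scanned `wFIC`.  The function reports, per
#' target, the feasible `I_ext` values, and summarizes the coverage of
#' activity levels by the attractor surface: the uncovered `y0`
#' subintervals (spacings larger than `cover_tol` between consecutive
#' attained `y0_mean` values) and, as `gap`, the single widest such
#' spacing regardless of `cover_tol` — the maximal interval of
#' activity levels attained by no scanned attractor.  On a
#' single-`wFIC` slice the gap separates the top of the
#' low-fixed-point sheet from the bottom of the cycle/high-FP sheet;
#' on wide `wFIC` ranges the narrow delta/theta cycle family erodes it
#' (see the package vignette).  Targets inside uncovered intervals
#' lack a dFIC equilibrium for at least part of the scanned `I_ext`
#' range.
#'
#' @param atlas an `attractor_atlas` covering the region of interest.
#' @param y0_targets target levels to test (default: fine grid over the
#'   attained range).
#' @param y0_tol matching tolerance between target and attractor center.
#' @param cover_tol spacing above which consecutive attained `y0`
#'   values are considered to leave a hole in the surface.
#' @return List with `feasible` (data frame `y0_target`,
#'   `n_feasible_I`, `frac_feasible_I`), `uncovered` (data frame
#'   `lower`, `upper`, one row per hole wider than `cover_tol`), and
#'   `gap = c(lower, upper)`, the widest spacing between attained
#'   levels.
#' @export
target_feasibility <- function(atlas, y0_targets = NULL, y0_tol = 2e-3,
                               cover_tol = 4e-3) {
  st <- atlas[atlas$kind != "unclassified", ]
  ys <- sort(unique(st$y0_mean))
  if (is.null(y0_targets))
    y0_targets <- seq(min(ys), max(ys), by = y0_tol)
  Is <- sort(unique(st$I_ext))
  feas <- vapply(y0_targets, function(tg) {
    ok <- abs(st$y0_mean - tg) <= y0_tol
    length(unique(st$I_ext[ok]))
  }, numeric(1))
  gaps_idx <- which(diff(ys) > cover_tol)
  uncovered <- if (length(gaps_idx)) {
    data.frame(lower = ys[gaps_idx], upper = ys[gaps_idx + 1])
  } else data.frame(lower = numeric(0), upper = numeric(0))
  widest <- which.max(diff(ys))
  gap <- c(ys[widest], ys[widest + 1])
  list(feasible = data.frame(y0_target = y0_targets, n_feasible_I = feas,
                             frac_feasible_I = feas / length(Is)),
       uncovered = uncovered, gap = gap)
}

#' Range of the low-activity fixed-point branch
#'
#' Minimum and maximum of the stable low fixed point's `y0` over a
#' window of external inputs (default `[0, 0.12]`), from a fixed-wFIC
#' atlas slice.  This is the "sub-bistable" activity band available as
#' a low dFIC target.
#'
#' @param atlas an `attractor_atlas`.
#' @param wfic slice, default 1.
#' @param I_range window of `I_ext`.
#' @param y0_split low/high FP boundary.
#' @return Named vector `c(y0_low, y0_high)`.
#' @export
sub_bistable_range <- function(atlas, wfic = 1, I_range = c(0, 0.12),
                               y0_split = 0.05) {
  sl <- atlas[abs(atlas$wfic - wfic) < 1e-9 & atlas$kind == "FP" &
                atlas$y0_mean < y0_split &
                atlas$I_ext >= I_range[1] & atlas$I_ext <= I_range[2], ]
  if (nrow(sl) == 0) stop("no low fixed points in the requested window")
  c(y0_low = min(sl$y0_mean), y0_high = max(sl$y0_mean))
}

#' Write an attractor atlas as tidy CSV
#' @param atlas an `attractor_atlas`.
#' @param path output file.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE)
  invisible(path)
}
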