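#' Structural connectome
#'
#' A connectome couples Jansen-Rit nodes through a nonnegative weight
#' matrix and white-matter tract lengths from which conduction delays are
#' derived.  Weights are treated as directed with `weights[i, j]` the
#' input to node `i` from node `j` (symmetric matrices are a special
#' case); the diagonal must be zero (no self-coupling).
#'
#' @param weights N x N nonnegative matrix of connection weights.
#' @param tract_lengths N x N nonnegative matrix of tract lengths (mm).
#' @param labels optional character vector of region names.
#' @param conduction_speed conduction speed in m/s (numerically equal to
#'   mm/ms); default 5.
#' @return An object of class `jr_connectome` with fields `n_nodes`,
#'   `weights`, `tract_lengths`, `labels`, `conduction_speed`.
#' @export
connectome <- function(weights, tract_lengths = NULL, labels = NULL,
                       conduction_speed = 5) {
  weights <- as.matrix(weights)
  if (is.null(tract_lengths))
    tract_lengths <- matrix(0, nrow(weights), ncol(weights))
  tract_lengths <- as.matrix(tract_lengths)
  if (!is.numeric(weights) || !is.numeric(tract_lengths))
    stop("weights and tract_lengths must be numeric matrices")
  if (nrow(weights) != ncol(weights))
    stop("weights must be square")
  if (!all(dim(weights) == dim(tract_lengths)))
    stop("weights and tract_lengths must have the same shape")
  if (anyNA(weights) || anyNA(tract_lengths) ||
      any(!is.finite(weights)) || any(!is.finite(tract_lengths)))
    stop("connectome matrices must be finite")
  if (any(weights < 0)) stop("negative weights are not allowed")
  if (any(tract_lengths < 0)) stop("negative tract lengths are not allowed")
  if (any(diag(weights) != 0))
    stop("diagonal of weights must be zero (no self-coupling)")
  if (conduction_speed <= 0) stop("conduction_speed must be positive")
  n <- nrow(weights)
  if (is.null(labels)) labels <- sprintf("region_%03d", seq_len(n))
  if (length(labels) != n) stop("labels must have one entry per node")
  dimnames(weights) <- dimnames(tract_lengths) <- NULL
  structure(list(n_nodes = n, weights = weights,
                 tract_lengths = tract_lengths, labels = labels,
                 conduction_speed = conduction_speed),
            class = "jr_connectome")
}

#' @export
print.jr_connectome <- function(x, ...) {
  cat(sprintf("Structural connectome: %d nodes, conduction speed %g m/s\n",
              x$n_nodes, x$conduction_speed))
  cat(sprintf("  weight range [%g, %g], mean indegree %.4g\n",
              min(x$weights), max(x$weights), mean(indegree(x))))
  cat(sprintf("  tract length range [%g, %g] mm\n",
              min(x$tract_lengths), max(x$tract_lengths)))
  invisible(x)
}

read_square_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  # a header row of labels is detected by non-numeric first line
  toks <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(toks)))
  m <- utils::read.table(path, header = has_header, sep = sep,
                         check.names = FALSE)
  labels <- if (has_header) colnames(m) else NULL
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- NULL
  list(matrix = m, labels = labels)
}

#' Load a connectome from weights and tract-length files
#'
#' Reads the plain-text dialect used by whole-brain simulators: two
#' whitespace- or comma-delimited square matrices (`weights.txt`,
#' `tract_lengths.txt`), optionally with a header row of region labels.
#' Tract lengths loaded this way must be symmetric (tolerance 1e-9).
#'
#' @param weights_path path to the weights matrix file.
#' @param lengths_path path to the tract-lengths matrix file (mm).
#' @param conduction_speed conduction speed in m/s, default 5.
#' @return A validated [connectome()].
#' @export
load_connectome <- function(weights_path, lengths_path,
                            conduction_speed = 5) {
  w <- read_square_matrix(weights_path)
  l <- read_square_matrix(lengths_path)
  if (max(abs(l$matrix - t(l$matrix))) > 1e-9)
    stop("tract_lengths matrix is not symmetric")
  connectome(w$matrix, l$matrix, labels = w$labels,
             conduction_speed = conduction_speed)
}

#' Write a connectome to plain-text files
#'
#' @param c a [connectome()].
#' @param weights_path,lengths_path output file paths; `.csv` extensions
#'   produce comma-separated files with a label header, anything else the
#'   whitespace-delimited dialect.
#' @return Invisibly, the two paths.
#' @export
write_connectome <- function(c, weights_path, lengths_path) {
  write_one <- function(m, path) {
    if (grepl("\\.csv$", path)) {
      colnames(m) <- c$labels
      utils::write.table(m, path, sep = ",", row.names = FALSE,
                         col.names = TRUE, quote = FALSE)
    } else {
      utils::write.table(m, path, sep = " ", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    }
  }
  write_one(c$weights, weights_path)
  write_one(c$tract_lengths, lengths_path)
  invisible(c(weights_path, lengths_path))
}

#' Conduction delays in integration steps
#'
#' Converts tract lengths to integer delay steps:
#' `steps = round(length_mm / speed / dt)` with speed in mm/ms (a speed
#' of 5 m/s is 5 mm/ms).  Rounding is round-half-to-even; a zero-delay
#' entry means the coupling uses the current state.
#'
#' @param c a [connectome()].
#' @param dt integration step, ms.
#' @return An object of class `delay_table`: list with integer matrix
#'   `steps`, `dt`, and `max_delay`.
#' @examples
#' cn <- connectome(matrix(c(0, 1, 2, 0), 2), matrix(c(0, 10, 10, 0), 2))
#' compute_delays(cn, dt = 1)$steps  # 10 mm at 5 mm/ms -> 2 steps
#' @export
compute_delays <- function(c, dt) {
  if (dt <= 0) stop("dt must be positive")
  steps_real <- c$tract_lengths / c$conduction_speed / dt
  steps <- matrix(as.integer(round(steps_real)), c$n_nodes, c$n_nodes)
  structure(list(steps = steps, dt = dt, max_delay = max(steps)),
            class = "delay_table")
}

#' Node indegree
#'
#' The indegree `d_i = sum_j C_ij` of each node: the row sum of incoming
#' connection weights.  In heavy-tailed connectomes the indegree spread is
#' the quantity dFIC compensates.
#'
#' @param c a [connectome()].
#' @return Numeric vector of length `n_nodes`.
#' @export
indegree <- function(c) {
  rowSums(c$weights)
}

#' Generate a small random test network
#'
#' A fully connected directed network with off-diagonal weights drawn
#' Uniform(0.5, 1.5) and symmetric tract lengths Uniform(20, 120) mm,
#' reproducible by seed.  Mirrors the 4-node random networks used to
#' explore tuning-parameter robustness.
#'
#' @param n number of nodes (>= 2), default 4.
#' @param seed RNG seed.
#' @param conduction_speed m/s, default 5.
#' @return A [connectome()].
#' @export
generate_small_network <- function(n = 4, seed = 1, conduction_speed = 5) {
  if (n < 2) stop("n must be >= 2")
  withr_seed(seed, {
    w <- matrix(stats::runif(n * n, 0.5, 1.5), n, n)
    diag(w) <- 0
    l <- matrix(0, n, n)
    l[upper.tri(l)] <- stats::runif(n * (n - 1) / 2, 20, 120)
    l <- l + t(l)
  })
  connectome(w, l, conduction_speed = conduction_speed)
}

#' Generate a whole-brain-like synthetic connectome
#'
#' Emulates the statistical pathology of tractography-derived structural
#' connectivity that dFIC is designed to counteract: heavy-tailed
#' (log-normal, mu = 0, sigma = 2.5, spanning roughly four orders of
#' magnitude like tractography weights) off-diagonal weights rescaled so
#' the mean indegree is 1 before global-coupling scaling, and distance-like
#' tract lengths obtained as Euclidean distances between node positions
#' drawn uniformly in a 140 x 170 x 110 mm box (brain-sized bounding
#' volume), so lengths are symmetric and triangle-consistent.
#'
#' @param n number of nodes, default 84.
#' @param seed RNG seed.
#' @param sdlog log-normal shape parameter of the weights.
#' @param conduction_speed m/s, default 5.
#' @return A [connectome()].
#' @export
generate_whole_brain_like <- function(n = 84, seed = 1, sdlog = 2.5,
                                      conduction_speed = 5) {
  if (n < 2) stop("n must be >= 2")
  withr_seed(seed, {
    w <- matrix(stats::rlnorm(n * n, meanlog = 0, sdlog = sdlog), n, n)
    diag(w) <- 0
    w <- w / mean(rowSums(w))
    pos <- cbind(stats::runif(n, 0, 140), stats::runif(n, 0, 170),
                 stats::runif(n, 0, 110))
    l <- as.matrix(stats::dist(pos))
  })
  connectome(w, l, conduction_speed = conduction_speed)
}

#' Normalize connectome weights
#'
#' @param c a [connectome()].
#' @param mode `"none"` (identity), `"max"` (divide by the global
#'   maximum), or `"log"` (elementwise `log1p` then max-normalize).
#' @return A [connectome()] with transformed weights.
#' @export
normalize_weights <- function(c, mode = c("none", "max", "log")) {
  mode <- match.arg(mode)
  w <- c$weights
  if (mode == "none") return(c)
  if (max(w) == 0) stop("cannot max-normalize an all-zero weight matrix")
  w <- if (mode == "max") w / max(w) else {
    lw <- log1p(w)
    lw / max(lw)
  }
  connectome(w, c$tract_lengths, labels = c$labels,
             conduction_speed = c$conduction_speed)
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
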