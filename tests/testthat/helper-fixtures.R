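# shared fixtures, built in code at test time

fixture_connectome_files <- function(w, l, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("connectome")
    dir.create(dir)
  }
  wp <- file.path(dir, "weights.txt")
  lp <- file.path(dir, "tract_lengths.txt")
  write.table(w, wp, row.names = FALSE, col.names = FALSE)
  write.table(l, lp, row.names = FALSE, col.names = FALSE)
  list(weights = wp, lengths = lp)
}

# reference sigmoid written out independently of the package internals
ref_sigmoid <- function(v, v_max = 0.0025, r = 0.56, v0 = 6) {
  2 * v_max / (1 + exp(r * (v0 - v)))
}

# reference six-equation right-hand side, straight from the model
# definition, used as a termwise oracle against the compiled code
ref_rhs <- function(y, I_ext, wfic, A = 3.25, B = 22, a = 0.1, b = 0.05,
                    c1 = 135, c2 = 108, c3 = 33.75, c4 = 33.75) {
  S <- ref_sigmoid
  c(y[4],
    y[5],
    y[6],
    A * a * S(y[2] - wfic * y[3]) - 2 * a * y[4] - a^2 * y[1],
    A * a * (c2 * S(c1 * y[1]) + I_ext) - 2 * a * y[5] - a^2 * y[2],
    B * b * c4 * S(c3 * y[1]) - 2 * b * y[6] - b^2 * y[3])
}

# a cached single-slice atlas at wFIC = 1, shared by several tests
slice_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sweep_attractors(seq(-0.05, 0.35, by = 0.002), 1)
    cache
  }
})
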