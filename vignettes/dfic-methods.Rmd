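---
title: "Controlling Jansen-Rit network activity with dynamic feedback inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling Jansen-Rit network activity with dynamic feedback inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jrfic)
```

## The problem

Whole-brain network models couple one neural mass per region through a
structural connectome. Tractography-derived weight matrices are
heavy-tailed: a few regions receive orders of magnitude more input than
the median region. When such a network is driven hard enough to produce
realistic inter-regional interactions, the high-indegree regions
saturate — the simulation becomes over-excited, over-synchronized and
dynamically poor. Lowering the global coupling `G` to avoid this also
removes the network interactions one wanted in the first place.

`jrfic` addresses this with *dynamic feedback inhibition control*
(dFIC): a slow plasticity-like equation attached to each region that
scales the inhibitory input onto that region's pyramidal population
until its long-term average activity sits at a chosen target level.
After this deterministic tuning phase the converged scalings are frozen
(per-region constants `pFIC_i`) and used in stochastic "post-FIC"
simulations. The net effect is that `G` can be chosen for its effect on
inter-regional correlation structure while excitability is regulated
independently, per region.

## The node model

Each region is a three-population Jansen-Rit neural mass: pyramidal
cells, excitatory and inhibitory interneurons. Six states per node
(`y0, y1, y2` and their derivatives `y3, y4, y5`) describe the three
postsynaptic-potential blocks; potentials are converted to firing rates
by the sigmoid

\[ S(v) = \frac{2 v_{max}}{1 + e^{r (v_0 - v)}} \]

and the pyramidal output signal is the PSP `y1 - y2`. The inhibitory
input to the pyramidal block is scaled by the control variable
`wFIC`, so the pyramidal rate equation reads

\[ \dot y_3 = A a\, S(y_1 - wFIC\, y_2) - 2 a y_3 - a^2 y_0 . \]

Network input enters the excitatory block:
`I_ext_i(t) = mu + G * sum_j C_ij S(y1_j(t - theta_ij) - wFIC_j y2_j(t - theta_ij))`,
with conduction delays `theta_ij` derived from tract lengths at 5 m/s.
All parameters (`jr_params()`) use milliseconds; `v_max = 0.0025/ms`
so the maximum population rate is 5/s. With the default constants the
isolated node produces the classic repertoire: a low-activity fixed
point, a high-activity fixed point, a fast alpha-band (10–12 Hz) limit
cycle and a slow delta/theta (1–5 Hz) limit cycle, with several
bistable input ranges between them.

## The control law

Two leaky averages per node (time constant `tau_d`, default 1000 ms)
track the slow components of `y0` and `y2`; the control variable moves
along the gradient-like rule

\[ \dot{wFIC}_i = \eta\, \overline{y_2}_i \,(\overline{y_0}_i - y_0^{target}), \]

with learning rate `eta` (default 0.005 /(ms·mV²)). When the detected
activity exceeds the target, inhibition strengthens and activity falls,
and vice versa; because average activity decreases monotonically with
`wFIC` along each attractor branch, any equilibrium of this slow flow
is stable. Tuning is always integrated deterministically; `wFIC`
starts at 1 (the uncontrolled model), is frozen for a 15 s transient
while the detectors warm up, and is clipped at 0 from below since
negative inhibition is unphysical.

Convergence is declared per node when the mean of `y0` over the last
`L_conv = 5000` ms lies within 1% of the target; the constant used in
post-FIC runs is the mean of `wFIC` over the last `L_avg = 3000` ms.
The two windows are deliberately distinct parameters because they serve
different purposes (verdict vs. extraction); both are exposed in
`dfic_params()`.

## Which targets are reachable: the attractor atlas

A target is reachable at a given input only if the uncontrolled node
has a stable attractor whose cycle-averaged `y0` equals the target at
some `wFIC`. `sweep_attractors()` maps these attractors by brute
force over an `(I_ext, wFIC)` grid: every cell is integrated from a
cold low state, a cold high-branch state (obtained by solving the
fixed-point equations and nudging `y0` by 1e-3 so unstable roots
depart within the settling window), and two warm passes that carry the
final state of the neighbouring cell up and down the input axis —
a continuation-lite strategy that tracks limit-cycle branches past the
fold points where cold starts fall off. Only stable attractors can be
found this way; unstable branches are out of scope.

Classification of a 10 s tail (after 5 s settling, dt = 0.5 ms) is
deliberately conservative about weakly damped ringing: the
high-activity state is a focus whose transients can oscillate for
seconds. A record is a fixed point if the last-quarter amplitude of
`y0` is below 1e-4, or below 0.02 while clearly decaying (less than
0.9 of the first-quarter amplitude); these constants were calibrated
against measured decay and growth rates around the Hopf points, where
genuine cycles always exceed them. Cycles are labelled slow (≤ 6 Hz)
or fast by the dominant spectral peak of the PSP, and their center is
the time average over an integer number of cycles. Segments that
still drift are reported `unclassified` and excluded from analyses.

At `wFIC = 1` the resulting slice reproduces the known bistability
boundaries of the model to grid resolution (fixed-point coexistence
for inputs in about [-0.012, 0.09], fixed point/fast cycle up to about
0.113, fast/slow cycle coexistence up to about 0.137, oscillation
death near 0.31), as asserted in the test suite.

`target_feasibility()` summarizes the atlas from the control
perspective: which target levels intersect the attractor surface, at
which inputs, and where the surface leaves holes. Low targets (up to
about 0.02) lie on the low fixed-point sheet and high targets (from
about 0.095) on the fast-cycle/high-fixed-point sheet, both over broad
contiguous input ranges. Between them lies the problematic band: much
of it is covered by nothing at all at `wFIC = 1`, and what coverage
exists elsewhere comes from the narrow delta/theta cycle family, whose
averages climb from about 0.034 to 0.095 as it continues to 5–7 Hz at
`wFIC > 1`. The function therefore reports every uncovered
subinterval, plus `gap`, the single widest range of activity levels
attained by no scanned attractor. A noteworthy finding of the
brute-force map is that the in-between band is *less* empty than
continuation of the primary branches suggests: the persistent
intermediate-frequency cycles (verified stable over 100 s) provide
equilibria across much of it, shrinking the widest truly uncovered
range on the full plane to a few thousandths in `y0` just above the
low sheet. The practical reading is "targets between the sheets are
unreliable — feasibility depends delicately on the input", not "no
equilibrium exists anywhere".
Mid-band tuning targets are accordingly flagged by `run_tuning()` as
non-converged when the drive does not happen to intersect that narrow
family.

## From tuning to BOLD and fit scores

Post-FIC simulations replace `wFIC_i(t)` by the constants `pFIC_i`,
add Gaussian white noise (`sigma = 1e-7`, entering the pyramidal rate
equation only, identical increment in both Heun stages so that
`sigma = 0` reproduces the deterministic path bitwise) and record the
PSPs. The matched no-FIC control uses `pFIC_i = 1` with the identical
noise stream and drive, which isolates the effect of the learned
inhibition.

PSPs drive the four-state Balloon model (vasodilatory signal, inflow,
volume, deoxyhemoglobin; standard constants `kappa = 0.65/s`,
`gamma = 0.41/s`, `tau = 0.98 s`, `alpha = 0.32`, `rho = 0.34`,
`V0 = 0.02`, overridable in `balloon_params()`) through the bounded
pyramidal rate `1000 * S(PSP)` per second; the nonlinear percent-change
readout is sampled at `TR = 720` ms. An impulse of drive produces a
response peaking 3–7 s later and halving a small impulse halves the
peak, which the tests assert.

Fit quality against an (empirical or surrogate) target combines the
Pearson correlation of FC upper triangles (`fc_fit()`), the
Kolmogorov-Smirnov similarity of sliding-window FCD value
distributions (60 s windows advanced by one TR), and the mean FC as a
synchronization gate: simulations with mean FC above 0.25 are
rejected outright. The multimodal fitness is the weighted mean
`MMF = (d1 R_FC + d2 (1 - KSD)) / (d1 + d2)` with `d1 = 1`,
`d2 = 0.75`; the weighted-mean form keeps MMF within [-1, 1] and
treats both terms comparably given their different typical maxima.
Welch spectra (4 s Hann segments, 50% overlap — about 0.25 Hz
resolution at the rhythms of interest) and bootstrap/permutation
statistics over 19.2 min sub-windows complete the analysis stack.

Regime occupancy is quantified by a Poincaré map of PSP maxima: a
point is a maximum if it strictly dominates a 100 ms window, and each
pair of consecutive maxima is classified by the 6 mV threshold — both
below: low fixed point; both at or above: fast cycle; one on each
side: slow cycle, which produces two alternating maxima per period.
One textual quadrant in the source material reads `[6, 0] x [0, 6]`
where only `[6, 18] x [0, 6]` is geometrically possible; the latter is
implemented. Occupancy is time-weighted (each inter-maxima interval
is attributed to its pair's regime) rather than pair-counted, so slow
cycles are not under-represented; a node "exhibits" a regime at 7.5%
occupancy.

## Synthetic study conditions

Everything is testable without imaging data:

* `generate_small_network()` — fully connected directed weights
  Uniform(0.5, 1.5), symmetric distances Uniform(20, 120) mm. Used for
  the 4-node tuning-robustness studies.
* `generate_whole_brain_like()` — 84 nodes; log-normal weights
  (`sigma = 2.5`, spanning roughly four orders of magnitude as
  tractography weights do) rescaled to unit mean indegree, and
  distances as Euclidean separations of points in a brain-sized
  140 x 170 x 110 mm box. The shape parameter matters: a milder tail
  (`sigma = 1`) concentrates the indegrees of a dense 84-node network
  so strongly (max/median ≈ 1.4) that the over-excitation pathology
  dFIC exists to counteract never appears.
* `generate_surrogate_empirical()` — a two-factor correlation matrix
  calibrated to mean FC ≈ 0.23 (per-node loadings Uniform(0.28, 0.68)
  on a shared factor, a sign-mixed second factor for block structure)
  and a bimodal FCD value distribution (65% N(0.12, 0.06) bulk, 35%
  N(0.55, 0.12) recurring mode).

What these surrogates do not emulate: spatial embedding of FC,
distance-dependent connection probability, subject-level variability,
and any physiological hemodynamic heterogeneity. Passing tests on
surrogates therefore demonstrates the mechanics and calibration of the
method, not empirical fit quality on real cohorts; real FC/FCD targets
in the same formats can be supplied wherever a surrogate is accepted.

## Numerical choices and problem sizes

Integration is Heun's predictor-corrector scheme; the delayed coupling
term is evaluated once per step from a ring buffer that stores each
node's firing rate, so a delayed read uses the historic `wFIC` value —
at the slow timescale of the control law the difference from using the
instantaneous value is negligible. Step sizes follow the model's
stiffness: 0.5 ms for single-node attractor sweeps, 1 ms for network
tuning and stochastic runs. Delay steps round half to even; zero-delay
entries read the current state. Blow-ups abort with a diagnostic
rather than returning garbage.

The test suite and the acceptance script use deliberately desk-sized
problems chosen to keep every quantity stable at its asserted
tolerance: slice sweeps at input step 0.002 with 5 s settling and 10 s
measurement per cell; the full-plane atlas at 0.002 x 0.02 (script) or
0.004 x 0.05 (tests); 250 s tuning runs for convergence checks; 2–3
minute stochastic runs for the pipeline demonstrations. Convergence
of these sizes was verified by doubling them in development without
material change to the reported quantities.

## Known limitations

* Only stable attractors are mapped; bifurcation types and unstable
  branches require proper continuation software.
* Tuning is deterministic by design; tuning in the presence of noise
  (and the resulting small positive bias of stochastic runs relative
  to the target) is not implemented.
* One `y0_target` applies to all nodes; per-node heterogeneous targets
  are not supported.
* The delta/theta cycle family between the two main sheets makes
  mid-band targets (roughly 0.02–0.095) unreliable rather than
  uniformly infeasible; `run_tuning()` reports per-node convergence
  so such failures are visible, but choosing targets in this band
  remains the user's risk.
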