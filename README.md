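# jrfic

Jansen-Rit brain-network simulation with **dynamic feedback inhibition
control** (dFIC).

Whole-brain models couple one Jansen-Rit neural mass per region through
a structural connectome. Because tractography weight matrices are
heavy-tailed, regions with large indegree saturate as soon as the
global coupling *G* is strong enough to produce realistic
inter-regional interactions: the simulation over-excites and
over-synchronizes. `jrfic` implements a homeodynamic plasticity
mechanism that decouples the two roles of *G*: a slow control equation
per region,

    dwFIC_i/dt = eta * y2d_i * (y0d_i - y0_target),

adjusts the inhibitory scaling `wFIC_i` of the pyramidal population
(with `y0d`, `y2d` leaky averages of the pyramidal and inhibitory PSP
states, time constant `tau_d`) until the long-term average activity of
every region sits at the chosen target `y0_target`. Because average
activity decreases monotonically with inhibition along each attractor
branch, the equilibrium of this slow flow is stable whenever a stable
attractor of the uncontrolled node exists at the target level. After
deterministic tuning, the converged scalings are frozen into per-region
constants `pFIC_i` for stochastic "post-FIC" simulations.

The package contains, in pure R over a small compiled core:

* delay-coupled deterministic/stochastic Heun integration of Jansen-Rit
  networks (`integrate_heun`), with connectome loaders for the
  plain-text weights/tract-lengths dialect and synthetic generators for
  small random and heavy-tailed whole-brain-like networks;
* the dFIC tuning machinery (`run_tuning`, `extract_pfic`,
  `default_initial_conditions`, `verify_stability`);
* brute-force attractor atlases of the isolated node over external
  input and inhibitory scaling (`sweep_attractors`), bistability
  intervals, dFIC equilibrium scans and target-feasibility/gap analysis;
* Balloon-model BOLD synthesis (`balloon_simulate`, `bold_from_psp`);
* the fitting and characterization stack: FC, sliding-window FCD,
  Kolmogorov-Smirnov similarity, the multimodal fitness
  `MMF = (d1*R_FC + d2*(1-KSD)) / (d1+d2)` with a mean-FC
  synchronization gate, Welch spectra, Poincaré-map regime
  classification, and window bootstrap/permutation statistics;
* an end-to-end pipeline (`run_pipeline`) that tunes, simulates
  matched post-FIC and no-FIC conditions on identical noise streams,
  and scores both against empirical or surrogate targets, plus a thin
  command-line front end (`inst/cli/jrfic`).

## Worked example

Tune a 4-node random network to a low activity target, then run a
stochastic post-FIC simulation and characterize it:

```r
library(jrfic)

cn <- generate_small_network(4, seed = 1)
p  <- jr_params(mu = 0.09, G = 1)
dp <- dfic_params(y0_target = 0.01)          # low fixed-point target
ic <- default_initial_conditions(0.01, 4, seed = 1)

tune <- run_tuning(cn, p, dp, ic = ic, seed = 1)
tune
#> dFIC tuning to target 0.01: 4/4 nodes converged (<= 1%)
#>   pFIC: 1.0131 1.0108 1.0157 1.0139
#>   final relative deviation (%): 0.000 0.000 0.000 0.000

post <- integrate_heun(tune$y_final, cn, p, wfic = tune$pfic,
                       T = 150000, dt = 1, stochastic = TRUE,
                       seed = 1, record_dt = 2)
bold <- bold_from_psp(post$psp, dt = 2)
functional_connectivity(bold)$fc_mean
#> [1] 1
poincare_classify(post$psp, dt = 2)$count_histogram
#> 1 2 3
#> 4 0 0
```

Each region needed slightly more inhibition than the original model
(`pFIC` just above 1) to hold its average pyramidal activity within 1%
of the target against the coupling it receives. The per-node `pFIC`
ordering follows the indegree — the most-connected region gets the
strongest inhibition. In this tiny noise-driven network all four
regions stay in a single dynamical regime and the BOLD signals are
essentially perfectly correlated (`FC_mean = 1`): exactly the kind of
over-synchronized result the MMF fitness would reject through its
`FC_mean > 0.25` gate. On 84-node heavy-tailed networks
(`generate_whole_brain_like`), near-critical targets instead produce
regime switching and differentiated FC; see the vignette.

The isolated node's regime structure, which determines which targets
are reachable, is mapped by brute force:

```r
atlas <- sweep_attractors(seq(-0.05, 0.4, by = 0.002), 1)
bistability_intervals(atlas)$intervals
#>           class  I_min I_max
#> 1         fp_fp -0.010 0.090
#> 2     fp_fastlc -0.014 0.112
#> 3 fastlc_slowlc  0.114 0.136
```

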