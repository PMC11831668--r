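# kmcdown

On-the-fly rate-constant downscaling for stiff, well-mixed stochastic
reaction kinetics.

## The problem

Exact event-driven simulation (kinetic Monte Carlo / Gillespie SSA) of a
reaction network executes one reaction per step. In stiff networks a few
fast, reversible, quasi-equilibrated reaction pairs consume essentially all
steps — in the built-in biochemical-oscillator benchmark, four fast
channels account for ~99.7% of ~2×10⁷ events per 500 simulated minutes —
while the slow reactions that drive the interesting dynamics fire rarely.
Because a quasi-equilibrated pair contributes no transient to the slow
dynamics, its rate constants can be divided by a *downscale factor* `df`
with negligible effect on the slow marginal, cutting the cost roughly as
`1/df`. The question is how far one can push `df` before the dynamics
distort, and how to answer that *during* the run with a quantitative error
bar rather than by manual convergence studies.

`kmcdown` provides:

* a **Modified Next Reaction Method** engine (C++ inner loop, ~1.5×10⁷
  events/s) with one serialisable random stream per slow channel and a
  shared stream for the fast channels, plus snapshot/restore — the
  substrate for common-random-number (CRN) replication;
* a **downscaling controller** that periodically snapshots the state,
  simulates a reference window plus `n` CRN replicates at factors
  `df_b^0 … df_b^(n-1)`, measures how cost (relative step count) and error
  (the Euclidean norm of slow-channel interarrival-time differences against
  the reference) scale with `df`, fits `C(df) = c·df^m` and
  `E(df) = p·df^q`, bounds the region where the cost law holds, and picks
  `df_opt = argmin [ α·C(df) + β·E(df) ]`
  subject to quasi-equilibrium, frequency-ordering, time-scale-separation,
  error-saturation and absolute/relative error gates;
* the benchmark **oscillator network** (operator + autocatalytic dimer
  positive feedback, activable-degrader negative feedback, period ≈200 min,
  stiffness dial `zeta`), a YAML network-config reader/writer, spectral and
  probability-mass-function **validation tools**, and programmatic **toy
  fixtures** with analytic references.

## Worked example

Run the benchmark at stiffness `zeta = 100` with the controller on:

```r
library(kmcdown)
net <- build_benchmark_network(zeta = 100)
run <- run_with_downscaling(net, downscale_config(), master_seed = 2, t_end = 11)
print(run)
#> downscale_run: t = 11 min; 1 attempt(s), 1 accepted; cumulative df = 85.96724
#>   attempt 1 (0.5405, 10.54): accepted df_opt = 85.97
```

After 10⁵ steps (0.54 simulated minutes) the controller opened a 10-minute
window, verified the fast pairs were quasi-equilibrated and separated from
the slow channels, and generated nine CRN replicates:

```r
a <- run$attempts[[1]]
#> TSS 3.101 | df_max 125 | cost slope -0.994 | E(df) = 0.003753 * df^0.343
#> df_opt 86.0 with fitted error 0.0173 (baseline 0.0065)
```

Reading: the fast channels fired 10^3.1 times more often than the fastest
slow channel; replicate cost followed the ideal `1/df` law (slope −0.994)
up to `df_max = 125`; the interarrival-time error grew as `df^0.34` from a
CRN baseline of 0.0065 minutes. With cost weight α = 1 and error weight
β = 2 the objective bottomed out at `df ≈ 86`, whose fitted error 0.017 is
below the 0.05 cap and within two orders of magnitude of the baseline — so
the window was regenerated at that factor, χ and φ were reduced 86-fold,
and the run continued ~86× cheaper per fast event.

Characterizing the unscaled benchmark (`zeta = 10`, 500 min, seed 1) with
the analysis tools:

```r
net10 <- build_benchmark_network(zeta = 10)
res <- simulate_chunk(initialize_engine(net10, master_seed = 1), t_f = 500,
                      record_slow_events = FALSE, sample_interval = 0.1)
estimate_period(trajectory_series(res$chunk$samples, "Y"))
#> [1] 202.5
100 * sum(res$chunk$counts[3:6]) / res$chunk$steps
#> [1] 99.73306
```

— a ≈200-minute oscillation with the four fast channels carrying 99.7% of
all 1.58×10⁷ steps.

A command-line front end over the same functions lives in
`inst/cli/kmcdown.R` (`simulate`, `downscale`, `analyze`, `compare`), and
`vignettes/downscaling-methods.Rmd` documents the model, the controller's
gates and every tunable parameter.

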