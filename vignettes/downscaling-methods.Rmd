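---
title: "On-the-fly rate-constant downscaling for stiff stochastic kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-the-fly rate-constant downscaling for stiff stochastic kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmcdown)
```

## The problem

Event-driven stochastic simulation (kinetic Monte Carlo / the stochastic
simulation algorithm) executes one reaction per step. When a reaction
network contains reversible pairs whose propensities exceed those of every
other channel by orders of magnitude, nearly all steps are spent re-firing
those fast, quasi-equilibrated pairs, while the slow reactions that actually
drive the dynamics of interest fire rarely. Because a quasi-equilibrated
pair contributes no transient of its own to the slow dynamics, its rate
constants can be divided by a common factor `df` with, in the limit of
infinite time-scale separation, no effect on the slow marginal — while the
cost of the simulation drops roughly as `1/df`.

`kmcdown` implements (i) an exact Modified Next Reaction Method (Mod-NRM)
engine organised around explicit per-channel random streams, and (ii) a
controller that, during the run, measures how both the computational cost
and a trajectory-level error metric scale with `df`, fits power laws to
both, and picks the factor minimising a weighted cost–error objective,
subject to a battery of validity gates.

## Engine

Each channel `j` carries an internal clock `T_j` (consumed internal time)
and a next internal firing time `P_j`; the channel minimising
`(P_j - T_j)/a_j` fires next, `T_j += a_j * dt` for all channels, and the
fired channel draws a fresh unit exponential to advance `P_j`. Propensities
are standard mass action on copy numbers: `c` (zeroth), `c*n`
(unimolecular), `c'*nA*nB` (bimolecular, distinct), and `c'*n(n-1)/2`
(bimolecular, identical molecules), where `c'` is the concentration-based
constant divided by the molecules-per-nM conversion factor. Ties in the
firing race (a measure-zero event) go to the lowest channel id, which keeps
runs reproducible.

Randomness is organised for common-random-number (CRN) work: every slow
channel owns an independent xorshift64* stream, all fast channels share a
single stream, and every stream state is serialisable. A snapshot captures
time, populations, rate constants and the *slow* channels' clocks and
stream states only; restoring it replays the identical slow reaction path,
while the fast channels are re-initialised from the continuing (not
restored) fast stream. Two trajectories simulated from the same snapshot
with different downscale factors therefore differ only through the fast
dynamics and the factor itself — not through slow-channel sampling noise.

Pausing at a window end is statistically exact: the pending reaction is not
fired, internal clocks are advanced by `a_j * (t_f - t)`, and the pending
exponential draws are retained. Chunked and unchunked runs agree to
floating-point roundoff (the pause partitions the clock accumulation
differently, so agreement is at the `1e-13` level rather than bitwise; runs
with identical chunking are bit-identical).

The inner loop is C++ (via Rcpp) using the next-reaction-method dependency
graph: firing a channel only updates the propensities, absolute firing
times and lazily-flushed clocks of the channels whose reactants it touched.
This sustains roughly 1.5e7 events per second on one core, which is what
makes the benchmark-scale runs (1e7–1e9 events) practical.

## Controller

Every `N` executed steps the controller opens a window `(t_s, t_f)`:

1. **Window width.** Starting from `w_min`, the width grows in steps of
   `w_min/2` up to `w_max` until a propensity-based forecast predicts at
   least `min_slow_firings` (default 5) firings for every slow channel that
   widening can actually help; channels whose current propensity cannot
   reach the target even at `w_max` are excluded, since sampling
   sufficiency for them is unattainable within the bounds (and, per the
   error treatment below, not strictly necessary).
2. **Reference chunk.** A snapshot is saved and the window is simulated
   with unmodified constants, recording every slow firing time.
3. **Gates.** Each downscalable pair must be quasi-equilibrated
   (`|N_f - N_r|/(N_f + N_r) <= delta`, default 0.05); the anticipated fast
   channels must all out-fire the anticipated slow ones (strictly — equal
   frequencies mean no separation); and the time-scale separation
   `TSS = log10(min fast freq / max slow freq)` must reach `tss_min`.
4. **Replicates.** `n` CRN replicates are generated from the snapshot, with
   the downscalable constants divided by `df_b^(k-1)`, `k = 1..n`. The
   `k = 1` replicate runs with unmodified constants: because only the fast
   stream differs from the reference chunk, its interarrival-time error is
   the *baseline* CRN noise floor against which later error increases are
   judged.
5. **Cost model.** Each replicate's cost is its step count divided by the
   reference chunk's. On log-log axes the points follow a slope −1 line
   until the fast channels stop dominating. Two detectors bound the valid
   region: sliding four-point least-squares fits (first window with slope
   above −0.9 marks its second-to-last point) and central-difference second
   derivatives of `log10(cost)` against `log10(df)` on the uniform log grid
   (the point *before* the first exceedance of 0.05 in absolute value,
   mirroring the slope detector's convention). `df_max` is the smaller of
   the two marks; points beyond it are discarded, and `C(df)` is a
   least-squares line through the survivors.
6. **Error model.** For each slow channel the firing-time lists of the
   reference chunk and each replicate are converted to interarrival times
   (the first one measured from `t_s`), truncated to the common count, and
   differenced; the Euclidean norm of the difference vector is that
   channel's error at that `df`. Channels with no common firings in a
   window are excluded from that attempt (insufficient sampling is handled
   here rather than by forcing wide windows). One aggregated power law
   `E(df) = p * df^q` is fitted to all channels' points with
   `df <= df_max`; per-channel exponents `q_j` are also fitted, and any
   `q_j < 0.2` aborts the attempt as *error saturation* — a norm that no
   longer grows with `df` means the window cannot resolve the extra error,
   so no decision should be based on it.
7. **Decision.** `F(df) = alpha * C(df) + beta * E(df)` is minimised over
   the continuous interval from the current cumulative factor to `df_max`
   (dense log-grid bracketing plus bounded scalar refinement; the optimum
   need not be a power of `df_b`), with `C` normalised to 1 at the
   interval's left edge and `E` in raw norm units. The candidate is
   accepted only if `E(df_opt) <= e_max` and `E(df_opt)` exceeds the df = 1
   baseline by at most `e_inc` orders of magnitude. On acceptance the
   window is re-simulated from the snapshot at `df_opt` and that chunk —
   not the unscaled one — is registered into the official trajectory; on
   any failed gate the unscaled chunk is registered unchanged, which makes
   an aborted attempt nearly free.

From the second attempt on, everything is bookkept in *absolute* factors:
replicates divide the current (already reduced) constants by powers of
`df_b`, but cost/error points, `df_max` and the optimization interval live
on the absolute `df` axis anchored at the cumulative accepted factor.

The linear form of the objective and the placement of its weights were
validated against the benchmark's published optimum: the fitted error
exponent `q ~ 0.5` implies a stationary point
`df* = (alpha/(beta p q))^(1/(1+q))`, which reproduces the reported optimum
when the reported error level is inserted for `p`.

## The benchmark oscillator

The built-in benchmark (`build_benchmark_network()`) is a cell-cycle-like
relaxation oscillator with six species and nine reactions. A protein X is
produced from an operator O at a basal rate (`k0 = 0.15` per min per free
operator) and 333-fold faster from the dimer-bound operator OX2
(`k1 = 50`). X dimerises reversibly (deterministic rate constant
`phi = 9.77*zeta` per nM per min, dimer dissociation constant
`b = 5.31 nM`), and the dimer binds the operator reversibly
(`chi = 3.91*zeta`, operator dissociation constant `a = 159.37 nM`) —
positive feedback. The dimer also activates an inactive degrader Yi into Y
(`k2 = 1.88e-3` per nM per min), and active Y degrades X
(`lambda1 = 9.38e-3`) and relaxes back at `lambda2 = 0.01` per min —
delayed negative feedback. Conservation: `O + OX2 = 10` and
`Y + Yi = 1035` copies.

The cycle: when Y is low, basal X leaks up, dimers form, the operator
ignites and X floods the system; the dimer pool activates Y almost
completely; at full Y the degradation capacity slightly exceeds the
production cap, so the dimer pool drains and collapses (~25 min of intense
dimerisation churn — the stiff phase); Y then decays for ~160 min until X
can ignite again, giving a period near 200 min. `zeta` multiplies all four
fast-channel constants and hence the stiffness, without touching the slow
dynamics.

Two conventions matter and are deliberate:

* The dimerisation channel's stochastic constant is `2*phi`: a
  deterministic rate `phi*x^2` corresponds, under the exact `n(n-1)/2`
  pairing combinatorics, to a stochastic constant of `2*phi` per volume.
* The molecules-per-nM conversion defaults to 1 (a ~1.66 fL volume), under
  which copy numbers and nM concentrations coincide; it is an explicit
  argument and is recorded in the network object, because every bimolecular
  propensity depends on it.

The reaction table itself was reconstructed from the model's published
description (species list, conservation-law structure, parameter units,
feedback roles) together with its quantitative characterization — the
stiff-phase step budget, the 99.5% fast-step share, the fast/slow frequency
gap, the first-window time-scale separation, and the ~200 min period. The
reconstruction reproduces all of those to within a few percent, but it is
not guaranteed to match the original table reaction-for-reaction; the
residual differences visible in the test suite (first-pulse step count
~30% low, a CRN error-noise floor ~2.6x higher than the published runs
imply, and consequently less aggressive optimum factors) are consistent
with small propensity-level differences and are documented where the
affected checks appear.

## Validation analysis

`spectral_density()` implements the classical Blackman–Tukey estimator:
mean removal, biased autocovariance to lag `N/2`, a Bartlett lag window
(which keeps the spectrum nonnegative by construction — the mean of the
even-extended spectrum equals the lag-0 autocovariance exactly, a Parseval
identity the tests assert), and a zero-padded cosine transform so that peak
locations are resolved below the raw `1/(N dt)` grid. `estimate_period()`
is the inverse dominant nonzero-frequency peak. `species_pmf()` and
`total_variation()` compare empirical copy-number distributions between
runs. Zero-order-hold resampling is exact for the piecewise-constant paths
KMC produces.

One caution on comparing dominant frequencies between two stochastic runs:
the oscillator's cycle-to-cycle period jitter (~20%) gives the spectral
peak a physical linewidth far wider than the FFT bin at any feasible run
length, so "same peak position" is only meaningful within the
phase-diffusion uncertainty `~ f0 * CV / sqrt(ncycles)` per run — about
`1e-4` per min for the 1e5-minute validation runs the tests use.

## What the toy fixtures do and do not show

The programmatic fixtures (`make_toy_network()`,
`make_cost_error_points()`) give every controller and engine operation a
closed-loop test with known ground truth: a pure birth process and a
birth–death process with its Poisson stationary law (checked against an
independently coded direct-method SSA oracle), a fast reversible pair
feeding a slow sink (the minimal separable structure, whose slow
first-passage distribution must be invariant under downscaling while the
pair stays well separated), a fully slow pair (which the controller must
always refuse to touch), and synthetic cost/error point sets with exactly
recoverable power laws and injectable kinks. Passing these shows the
machinery is correct; it does not show that any particular real network is
downscalable — that is exactly what the runtime gates decide per window.

## Numerical choices and problem sizes

* Detector thresholds (slope −0.9, curvature 0.05, four-point windows),
  the QE threshold 0.05, the saturation bound `q >= 0.2`, and the decision
  caps `e_max = 0.05`, `e_inc = 2` orders follow the benchmark
  configuration and are all exposed in `downscale_config()`.
* The optimizer brackets on a 1000-point log grid then refines with
  `stats::optimize`; the tests hold it to 1% of a 1e4-point brute-force
  scan.
* Degenerate inputs abort the attempt rather than guess: fewer than four
  cost points, fewer than two valid fitting points, all-zero error norms,
  or an exhausted replicate all leave the unscaled chunk official.
* The test suite characterises the benchmark on 500-minute runs (about
  2e7 events each) and validates spectra and distributions on a
  1e5-minute downscaled run against a 3e4-minute original-constant run
  (about 1e9 events), sizes chosen so the full suite completes within tens
  of minutes on one core while leaving the headline quantities'
  Monte-Carlo error well inside the asserted bands.

## Known limitations

* Fast/slow partitioning is user-supplied (via the network definition);
  automatic classification is out of scope, as is re-increasing constants
  once reduced, non-mass-action kinetics, and spatial models.
* The error metric is trajectory-based (CRN interarrival differences), so
  its absolute scale depends on the fast-noise coupling of each slow
  channel; windows in which a slow channel barely fires contribute no
  information and are excluded per attempt.
* `detect_df_max` assumes the replicate grid is uniform in `log(df)`,
  which `generate_replicates` guarantees.
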