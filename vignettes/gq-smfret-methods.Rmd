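---
title: "Models and methods behind gqfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gqfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqfret)
```

# The model

`gqfret` treats a single surface-immobilised GQ molecule as a
three-state continuous-time Markov chain over the conformations
unfolded (UF), parallel (P) and antiparallel (AP), with six
non-negative transition rates labelled `P_AP, P_U, AP_P, AP_U, U_P,
U_AP` (units 1/s; `U` denotes the unfolded state in rate notation).
Each state maps to a FRET efficiency center; the camera integrates the
donor and acceptor channels over frames of `dt` seconds (default 0.1 s,
the 100–200 ms regime of prism-TIRF instruments), and

```
E = acceptor / (donor + acceptor)
```

is the per-frame FRET estimate. The model's assumptions, in decreasing
order of importance:

* **Markovian, exponential dwells.** Sojourn times in each state are
  exponential with the state's total exit rate; branch probabilities
  are rate ratios. This is the standard description of two-color
  smFRET folding data at second-scale kinetics.
* **Discrete, well-separated FRET levels.** Conformational exchange is
  slow relative to `dt`, so a frame is dominated by one state; frames
  are assigned the state occupying the majority of the frame interval.
* **Static conformers in histogram experiments.** Population
  histograms pool thousands of molecules, one FRET value per molecule;
  a molecule's conformer is drawn once from the equilibrium fractions
  (snapshot mode). Dynamic exchange during the short scoring window is
  ignored there — it is the regime the dwell-time analysis covers.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| P center | 0.55 | FRET | mid-FRET signature of the parallel fold |
| AP center | 0.75 (0.70 for the telomere-repeat loops) | FRET | high-FRET signature of the antiparallel fold |
| UF center | 0.2–0.4 by overhang length | FRET | longer unfolded ssDNA lowers E |
| `fret_sd` | 0.05 | FRET | population peak width; reproduces typical histogram peaks |
| `dt` | 0.1 | s | camera frame time |
| `total_intensity` | 1000 | a.u. | summed channel brightness |
| `noise_scale`, `noise_floor` | 3, 5 | a.u. | per-channel sd `3*sqrt(mean)+5`, calibrated so per-frame FRET sd is about 0.05 at brightness 1000 |
| `bleach_rate` | 0.01 | 1/s | single-step photobleach; ~55% of molecules survive a 60 s movie |
| `bin_width` | 0.02 | FRET | histogram resolution, ~sd/2 |
| `min_dwell` (despike) | 2 | frames | noise-spike width merged away during state assignment |
| `min_frames` (rates) | 3 | frames | shortest dwell entering a duration mean |
| label tolerance | 0.08 | FRET | component-to-state matching window; covers the 0.70 vs 0.75 AP ambiguity |

Per-construct values (conformer fractions, the six rates, initial
folding rates, quenching Vmax and Kd) live in `gq_registry()`, each
tagged `"paper"` (taken from the printed analysis of this system) or
`"assumed"` (a realistic default chosen once). Tests treat only
`"paper"`-tagged values as external facts.

# What the simulator emulates — and what it does not

The generator reproduces the statistical structure the analysis
relies on: exponential dwells from exact Gillespie sampling, majority
binning to frames, shot-noise-like channel noise, molecule-to-molecule
center heterogeneity (snapshot mode), single-step photobleaching, and
buffer-flow experiments in which the molecule idles unfolded until K⁺
arrives, folds after an exponential latency with a construct-specific
rate into a construct-specific first state (parallel for single-nt-loop
constructs, antiparallel for the 2–5 nt first-loop series), then
follows the six-rate chain.

It deliberately does **not** model EMCCD camera statistics, spectral
crosstalk or the detection gamma factor, triplet blinking, sub-frame
intensity averaging at state boundaries, flow-equilibration dead time
after manual buffer injection, or non-Markovian/hidden heterogeneity.
A green recovery test therefore establishes that the analysis inverts
the stated generative model at realistic noise — not that it is robust
to every instrumental artifact of real microscope data.

# Numerical and statistical choices

**Histogram mixture fits.** Fits minimise a chi-square objective on the
binned densities: residuals weighted by `1/(counts+1)`, the Poisson
variance approximation that peak-fitting software applies by default.
Plain unweighted least squares was measurably worse (about 20% higher
spread on the recovered parallel fraction of strongly overlapping
mixtures) and made component-count selection impossible: an extra free
Gaussian removes 30–40% of a pure single peak's residual merely by
chasing bin noise, so any fractional-RSS rule either overfits clean
peaks or underfits real ones. Component count is instead chosen by a
nested-model chi-square test: an extra component (3 parameters) must
improve the objective by `qchisq(0.999, 3) ≈ 16.3`. Multi-start
initialisation (canonical FRET levels plus seeded random restarts)
makes fits deterministic; sds are bounded to [0.01, 0.15] to prevent
component collapse; ties between equal-objective starts keep the first.
Components sort by mean; labels attach to the nearest expected center
within ±0.08, anything further is `"unknown"` and folds into UF with a
warning.

**State assignment and dwell times.** Thresholds sit at the midpoints
between adjacent centers. Short sojourns are handled asymmetrically,
which matters: a short excursion *returning to the same state* is
almost always a noise spike and is merged away (up to `min_dwell = 2`
frames); a short sojourn *between two different states* is a genuine
transit whose transitions are kept even though its duration is
unresolvable. Merging everything (the naive rule) converts real
P→U→AP transits into fake direct P↔AP transitions and inflated those
rates by 10–15% in recovery runs. Rate estimation then uses only
resolvable dwells (`min_frames = 3` frames) for the duration mean, with
the truncation-aware correction

```
exit_rate = 1 / (mean(resolvable dwells) − (min_frames − 1/2) · dt)
```

— by memorylessness, discarding dwells shorter than the resolution
shifts the surviving mean up by exactly the truncation point, and the
frame count of a dwell is its duration rounded to frames, putting the
truncation point at `(min_frames − 1/2)·dt`. The classic `dt/2`
correction is the `min_frames = 1` special case; with `dt/2` alone the
fast-exiting unfolded state came back ~9% slow. Branch rates split the
exit rate by the transition counts of *all* completed sojourns. First
and last sojourns of each trace (and sojourns bordering invalid
stretches) are censored.

**Two finite-window effects worth knowing about.** (1) Dwells that
*complete* inside an observation window are a right-censoring-biased
sample — long dwells preferentially end as the censored last sojourn —
so dwell means are biased short by roughly a factor `(1 − mean/T)`.
Recovery tests use windows ≥ 16× the mean dwell; the residual few
percent is part of the quoted ±15% recovery envelope. (2) In flow
experiments a first fold that lasts under the 3-frame detection guard
is missed and the molecule is re-detected at its next folding event
(or censored); at the registry's slow unfolding rates this touches
<1% of molecules but is the main contamination of the latency mean.

**Flow analysis.** The flow onset is read from the simulation manifest
when present; otherwise a two-segment change point on the FRET series
(accepted only if it removes ≥30% of the single-segment RSS, else an
error). Folding latency is the first run of ≥3 frames above the UF/P
midpoint; the rate is `1/mean(latency)` with no discretisation
correction — majority binning makes the measured latency mean-unbiased.
Molecules that never fold are reported censored, never dropped
silently.

**Bleach detection.** The reference brightness is the median of the
frames above the total-intensity midrange, which stays anchored to the
bright cluster even for molecules that bleach very early; the bleach
frame is the first of ≥5 consecutive frames below half the reference.

**Hill and saturation fits.** The Hill fit is deterministic multi-start
L-BFGS-B over `k` (log grid across the observed concentrations) and
`n ∈ {0.5, 1, 2}`, with bounds `n ∈ [0.2, 6]`, `Vmax ∈ (0, 120]` (the
soft 120 ceiling flags pathological curves). "Taking an inverse of the
fluorescence reading" is implemented as the complement
`q = 100 (1 − F/F0)` — the only reading consistent with a percentage
quenching scale; `1/F` has the wrong units and range. The
double-exponential saturation fit exploits linearity in the two
amplitudes: an exhaustive log-grid over the two scales with an exact
non-negative amplitude solve, polished by a full 4-parameter
optimisation. Note the best double-exponential approximation of a
noiseless Hill (n = 1) hyperbola saturates ~2.3% below the true
asymptote — an inherent model mismatch, frozen into the tests, not a
fitting failure.

**Equilibrium solve.** `ctmc_equilibrium()` solves the generator's
null space with a sum-to-one constraint. It errors only when the
positive-rate digraph has more than one closed communicating class
(no unique stationary distribution); chains with transient states but
one closed class are legitimate and get zeros on the transient states.

# Decisions on open questions

* **Per-molecule vs per-frame histograms.** Histograms use one value
  per molecule (mean of the first 10 valid frames); the reduction is
  exposed so per-frame pooling can be swapped in.
* **Motif scanning.** Only the single-stranded overhang is scanned,
  on the sense strand, with greedy maximal G-runs and leftmost
  tie-breaking; alternative registrations exist for G-runs longer than
  3 (and the stem junction could in principle contribute a register),
  but the packaged constructs are unambiguous under this rule except
  c-Myc, whose G-adjacent loop is taken from the printed spacing.
* **No flow dead time.** The simulator models no flow-equilibration
  delay; short-loop initial folding rates in real data are
  correspondingly underestimated relative to this idealisation.

# Known limitations

* No gamma correction or spectral crosstalk in FRET computation.
* Threshold state assignment, not an HMM — adequate at these
  signal-to-noise ratios and dwell times, and deliberately parallel to
  how dwell times are measured by inspection; an HMM would be the
  natural extension for faster kinetics.
* Rates for near-static constructs (exchange ~0.01 1/s) are
  window-limited upper bounds: their dwells rarely complete within a
  trace, which is exactly why dwell collection concentrates on the
  dynamic constructs.
* The Gaussian-mixture surface quantifies P/AP/UF only; parallel vs
  hybrid topologies share the mid-FRET level and are not
  distinguishable here (circular dichroism settles that distinction,
  outside this package's scope).
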