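---
title: "Methods: folding-state analysis of smFRET trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: folding-state analysis of smFRET trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretfold)
```

This vignette is the package's account of its models and estimators: what is
assumed, which defaults matter, where the design was genuinely open and what
was decided, and what the synthetic data do and do not establish about real
recordings.

## The folding model

RNA G-quadruplex folding is represented as a first-order Markov chain over
ordered states — ssRNA, G-hairpin, G-triplex, G4 — observed through Gaussian
FRET emissions. The assumptions, in decreasing order of physical confidence:

* **Discrete states, memoryless kinetics.** Dwell times are geometric at the
  frame scale (100 ms default). Real folding may have non-exponential dwells;
  nothing downstream depends on dwell shape except the HMM's transition
  estimates.
* **Birth–death topology.** Transitions occur only between adjacent states in
  the pathway: direct ssRNA↔G4 jumps are excluded by construction. This is
  the default generator topology, and the transition-density module tests it
  as a falsifiable property (off-adjacent mass < 1%).
* **Monotone emission order.** FRET means increase strictly with folding
  progress — the fully folded state is most compact. Default means are the
  marked state values of the three-layer construct family: 0.32 / 0.50 /
  0.74, plus 0.92 for the well-folded quadruplex, with per-state s.d. 0.06.
* **Gaussian emissions clamped to [0, 1].** Latent FRET is drawn Gaussian and
  *clamped* at the boundaries rather than rejection-truncated. At mean 0.92,
  s.d. 0.06, clamping biases the realized mean by about −0.003 (rejection
  truncation would bias it by −0.011), and the analysis clamps observations
  to the same domain before fitting, so generator and estimator agree.

### Potassium dependence

No kinetic rates are published for these constructs, so the K⁺→rate mapping
is a declared stand-in, not a fitted physical model: all folding (forward)
probabilities are scaled by a Hill factor `c^h / (c^h + K½^h)` of the KCl
concentration with `h = 2`, `K½ = 30 mM` for three-layer constructs and
`150 mM` for two-layer ones (two-layer quadruplexes need higher K⁺ to fold),
a per-frame folding ceiling of 0.15, a floor of 1e-4 (keeping the chain
irreducible at 0 mM while the unfolded state dominates), and
concentration-independent unfolding at 0.05 per frame. The construction
guarantees, provably rather than empirically, that stationary folded
occupancy is non-decreasing in KCl and negligible at 0 mM. Simulator rates
must not be read as estimates of the real systems.

### Photophysics

Intensities partition a fixed photon budget (default 1000 counts/frame)
between channels by the latent FRET value, with additive Gaussian channel
noise (s.d. 20), a background offset (10), and single-step irreversible
photobleaching with geometric waiting times (default 5e-4 per frame per
channel). After an acceptor bleach the acceptor falls to background and the
donor rises to the full budget; after a donor bleach both fall to
background. Blinking is off by default — the experimental oxygen-scavenger +
Trolox system suppresses it — but is available via `blink_prob`. Dye
stoichiometry artifacts (same-color double labelling, FRET-invisible
molecules) are not simulated: only FRET-active molecules are generated.

### Seeding

One master seed; per-molecule path and emission seeds derive from it by a
fixed splitting rule, so molecule *i* is identical regardless of how many
molecules are simulated, and `(model, config, seed)` determines every byte
of output.

## Trace processing

`E = I_A/(I_D + I_A)` after clamping channels at zero; frames with total
intensity below a floor (default 100 counts = 10% of the default budget) are
marked invalid rather than divided. No gamma, leakage, or
detection-efficiency corrections: the raw proximity ratio is the reported
scale, and corrections would move it.

Bleach detection compares flanking window means (half-width 5 frames)
against `z = 4` times the frame-noise standard error, with the frame noise
estimated robustly from first differences (`mad(diff(x))/√2`). Donor
bleaches are sought on the total intensity, acceptor bleaches on the
acceptor channel away from donor events. A candidate step only counts as a
bleach if the signal after it falls below 15% of its level just before:
folding transitions also step the acceptor channel, but only a bleach
collapses it to background. Traces are truncated at the first bleach;
molecules are rejected for < 30 usable frames, more than one bleach step per
channel (multi-fluorophore), or no valid frames, with machine-readable
reasons.

Histograms pool the *earliest* `min(50, usable)` frames of each accepted
molecule, 30 minimum. Which 30–50 frames to select was an open choice; the
earliest-frames rule is deterministic and independent of every downstream
fit, which is why it was chosen. No molecule can dominate a histogram.

## Hidden Markov modelling

A single Gaussian-emission HMM is shared across all traces of a condition
(traces enter the likelihood as independent sequences), matching the pooled
histograms; per-trace fitting is available by calling `baum_welch_fit()` on
one molecule. The estimator is maximum-likelihood Baum–Welch: the published
idealizers in this field are often variational-Bayes tools with unstated
settings, and a fully specified ML estimator can be tested exactly against
brute-force path enumeration, which the suite does at 1e-9 log tolerance.

Numerical choices:

* Scaled forward–backward with per-(trace, frame) log-space shifts of the
  emission densities, so arbitrarily unlikely observations cannot underflow
  even on 10⁵-frame traces.
* Initialization: means at evenly spaced quantiles of the pooled
  observations; s.d. at pooled s.d./K (floored); sticky transitions
  (self-probability 0.95); restarts jitter the means with seed-controlled
  Gaussian noise (s.d. 0.03). The first restart is deterministic. Default 5
  restarts: with quantile initialization on well-separated 1-D emissions the
  likelihood surface is benign and restarts almost never change the optimum.
* `sd_floor = 0.01` FRET units prevents variance collapse onto single
  observations.
* Empty-state collapse (responsibility mass < 1e-6) triggers perturbed
  restarts, then an error.
* Models are returned in canonical ascending-mean order; Viterbi ties break
  toward the lower state index.
* State count by BIC with `p = K² + 2K − 1` free parameters over K = 1…5.
  The selection fit uses a looser EM tolerance (1e-4 versus 1e-6) because
  BIC gaps between state counts are orders of magnitude larger than the
  flat tail of the likelihood climb.

## Population decomposition

Histograms use 0.02-wide half-open bins on [0, 1] (resolving peaks separated
by ≥ 0.08). The decomposition itself is fitted by EM on the *raw pooled
samples*, not least squares on binned counts: the binned and sample-based
fits agree to within a bin width, and the sample-based likelihood needs no
binning choice. Component widths are bounded to [0.01, 0.15] so no single
broad component can swallow the histogram; centers can be pinned within
±0.05 of the HMM means, which the pipeline does by default to stabilize
4-component fits.

A component that a condition does not populate keeps its (constrained)
center and width at vanishing weight rather than aborting the fit. This is
deliberate: a shared-K titration legitimately empties states at the
concentration extremes — at 0 mM KCl there simply is no folded population —
and the correct report is a ≈0 fraction, not a missing condition.

Fractions are normalized peak areas; the lowest-center component is labelled
unfolded, the highest folded, interior ones intermediate. Whether published
titration fractions count intermediates in either pool is not always
explicit; this package reports all components and reserves
"folded"/"unfolded" for the extremes. Confidence intervals are
molecule-level bootstraps (resample molecules, repool, refit from the
point-estimate parameters; 200 replicates by default), and condition
comparisons report per-state fraction changes with bootstrap intervals on
the change.

## Transition density plots

TDP coordinates are the fitted state means of the flanking segments, not raw
pre/post frame values: idealized coordinates give crisp clusters, raw ones
smear them with emission noise. The grid is 50×50 on [0, 1]² with an
optional separable Gaussian kernel (default bandwidth 0.02). The
detailed-balance score `z = (n_ij − n_ji)/√(n_ij + n_ji)` is the package's
equilibrium diagnostic: stationary birth–death dynamics keep |z| ≤ ~3 on
populated adjacent pairs, and a driven process (helicase unwinding) breaks
the symmetry.

## MST dose-response

`Fnorm` is reported in per-mil, hot window over cold window, with the
vendor-style defaults: cold = final 1 s before laser-on, hot = final 1 s of
the 30 s laser-on phase (both configurable; the published window placements
are not stated). The binding model is a Hill curve with free baseline,
amplitude and coefficient (fixable to 1), fitted by Levenberg–Marquardt
least squares with 8 log-spaced EC50 starts across the tested range.
Degenerate inputs are flagged rather than fitted: flat curves return a
`no_binding_signal` flag, and EC50 estimates outside the tested range carry
an `ec50_outside_range` warning. Confidence intervals are residual
bootstraps (200 replicates), always widened to contain the point estimate.
In recovery tests, "2% noise" means Gaussian noise with s.d. equal to 2% of
the Hill amplitude — the signal's dynamic range, not the absolute Fnorm
level.

## What the simulator does and does not establish

Passing the recovery suite shows the estimators are consistent with their
own generating assumptions at realistic sizes: Gaussian emissions, discrete
Markov states, single-step bleaching, no blinking, no baseline drift, no
dye stoichiometry artifacts. Real recordings violate several of these —
non-exponential dwells, correlated noise, spectral cross-talk,
gamma-factor asymmetry — and nothing here measures robustness to those
violations. The simulator is a test harness and a null model, not evidence
about any specific RNA.

## Problem sizes

The package's own validation runs at the following sizes, chosen to mirror
typical per-condition experiments while keeping the full suite quick:
state-mean recovery at 300 molecules × 500 frames; BIC state-count
selection over 20 replicates of 40 molecules × 100 frames per
configuration; detailed-balance checks on 10⁵ pooled stationary frames;
titrations at 60 molecules per concentration; EC50 recovery over 100
replicate 12-point curves. Oracle equivalence (forward likelihood and
Viterbi against exhaustive path enumeration) runs on 100 random instances
with K ≤ 3 and length ≤ 8, where enumeration is exact.

## Known limitations

* No dwell-time distribution fitting or rate-constant extraction; the HMM's
  transition matrix is the only kinetic summary.
* No 2-D (donor, acceptor) emission model or photon-level likelihoods.
* No thermodynamic ΔG or Hill analysis of the K⁺ titration: fractions only.
* The mixture and HMM share the Gaussian-emission assumption, so they are
  not mutually independent checks; the independent checks are the
  enumeration oracles, conservation identities, and an external mixture
  implementation in the test suite.
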