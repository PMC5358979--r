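---
title: "Models and methods: smFRET kinetics of DNA-bending 5' nucleases"
author: "fenkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: smFRET kinetics of DNA-bending 5' nucleases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fenkin)
```

# The kinetic scheme

`fenkin` analyzes single-molecule FRET experiments on enzymes that bend DNA
junctions as part of substrate recognition — flap endonuclease 1 (FEN1) being
the prototype. The working model is a two-conformer scheme with an incision
branch:

* **Unbent (extended) DNA** binds enzyme and bends in one apparent step with
  pseudo-first-order rate `k_on * conc` (`k_on` in M⁻¹s⁻¹, `conc` in nM;
  1 nM = 1e-9 M). Because bending and binding are not resolved separately,
  the measured association rate is `k_on-bending`.
* **Bent DNA** either relaxes back (rate `k_off`, the unbending/dissociation
  rate) or, with catalytic metal present, progresses through `n_step`
  sequential first-order steps of rate `k_step` each, ending in 5'flap
  incision. The mean bent-state lag before incision is
  `tau_avg = n_step / k_step` and the apparent single-turnover rate is
  `k_STO = 1 / tau_avg`.
* Incision releases the 5'flap together with the donor dye: the donor channel
  drops to background in a single frame step. Photobleaching of either dye
  terminates the usable record; hazards `kb_d`, `kb_a` run from the start of
  illumination.

A gamma-distributed lag with shape near `n_step` follows from the sequential
chain; a lag histogram that rises and then decays (shape > 1) is the
signature of at least two sequential steps after bending, which is why the
default is `n_step = 2` with `k_step = 12.5 s⁻¹` (mean lag 160 ms,
`k_STO = 6.25 s⁻¹`). A single rate-limiting step would give a pure
exponential decay (shape 1), which `fit_gamma()` flags.

The two labeling schemes are kept explicit throughout, because they invert
the sign of the FRET change: with the donor on the 5'flap (`"flap"`), bending
*lowers* E; with both dyes in the duplex arms (`"dsdna"`), bending *raises*
E (presets: unbent 0.27, bent 0.54). Silent inversion of the bent fraction
is the classic failure mode of histogram analyses, so the orientation is an
argument (`bent = "high"`/`"low"`), never a guess.

# What the simulator does and does not emulate

`simulate_state_path()` draws exact event times for the scheme above
(competing exponential risks, Gillespie style). `emit_trace()` renders a path
into camera frames: each frame is split into 10 sub-intervals, state
occupancies over the sub-intervals set the expected donor/acceptor fluxes,
per-frame Gaussian jitter of SD `sigma_E` models conformational and spectral
width beyond shot noise, and both channels are Poisson counts on top of
constant backgrounds. Frames straddling transitions therefore show averaged,
intermediate FRET — the averaging artifact that limits all frame-based
idealization and drives several estimator choices below.

Defaults the data do not pin down (total intensity 400 counts/frame,
backgrounds 15/frame, bleaching hazards 0.02 s⁻¹) are free parameters of the
emission layer, chosen to give a signal-to-noise ratio around 5 on the
apparent FRET, typical of oxygen-scavenged TIRF recordings; they are recorded
in every trace's metadata and in YAML configs. Dye blinking is omitted
(triplet quenchers suppress it in well-run experiments). Burst
simulation draws log-normal transit durations rather than diffusing molecules
through a 3-D excitation volume; camera point-spread functions, spot finding
and channel registration are out of scope — traces enter as per-frame
channel counts.

Consequences for interpretation: passing parameter recovery demonstrates the
*analysis* is unbiased for data obeying the model (Markovian two-state
kinetics, Gaussian-on-E emission, Poisson counts). It cannot certify
robustness to non-idealities the generator lacks — blinking, slow baseline
drift, heterogeneous molecules, or gamma-factor miscalibration.

# Idealization: maximum-likelihood HMM

Trajectory idealization uses a two-state hidden Markov model fitted by
Baum–Welch EM with Gaussian emissions on apparent FRET, then Viterbi
decoding (`fit_two_state_hmm()`, `viterbi_path()`). Maximum likelihood
replaces the variational-Bayes machinery of the usual tools deliberately:
for a fixed two-state segmentation the posterior decode is what matters, ML
EM reproduces it, and an exhaustive-enumeration oracle (all `2^T` paths on
short traces) can verify both the forward likelihood and the Viterbi argmax
exactly — which the test suite does.

Numerical choices:

* initialization at the 20th/80th percentiles of E; convergence when the
  log-likelihood gain is below 1e-6 or 500 iterations;
* a variance floor of 1e-4 prevents degenerate collapse on noiseless or
  repeated values;
* states are reported ordered by mean, and ties in the Viterbi recursion
  prefer the current state (hysteresis), making decodes deterministic;
* the log-likelihood is recorded per iteration and asserted non-decreasing.

The usable region of a trace ends at the first loss of either dye
(`find_bleach_point()`): donor loss kills the total signal, while acceptor
bleaching leaves the donor bright but collapses E to a spurious low value
that would masquerade as a state. Both are detected by a 5-frame running
median falling permanently below background + 3 SD.

Trace screening (`screen_trace()`) mirrors standard practice: exclusion for
aberrant brightness (total intensity > 3 MAD from the median for > 10% of
frames, or any single-frame excursion beyond 5 MAD — thresholds that are this
package's concrete reading of "aberrant", since the practice is usually left
unquantified), a minimum FRET change of 0.2 between fitted states, and
anti-correlated channel changes at decoded transitions.

# Dwell-time kinetics and censoring

`extract_dwells()` distinguishes interior dwells from censored ones, and
left- from right-censoring: a trace's first segment began before acquisition
(left-censored — no usable exposure), while last segments and dwells cut by
incision or bleaching are right-censored (exposure without an event).
`fit_exponential()` offers:

* `hist_lsq` — least-squares single-exponential on the dwell histogram
  (Freedman–Diaconis bins), the conventional workflow in the field;
* `mle` — the conditional maximum-likelihood estimate `1/(mean − t_min)`
  given the missed-event guard that discards dwells shorter than 2 frames
  (`t_min = 2 dt`); it reduces to `1/mean` when no frame interval applies;
* `mle_censored` — `events / total exposure`, additionally counting
  right-censored exposure. This is the default in the pipeline wrappers:
  with 60 s records and bleaching hazards of 0.02 s⁻¹ an appreciable share
  of dwells is right-censored, and interior-only estimators are then
  length-biased (long dwells preferentially hit the record boundary).

Frame-based detection has a dead time: an excursion confined to less than
half a frame can never claim a frame in the decode, and detection becomes
certain only around one full frame — so the effective dead time is
`0.75 dt`. An undetected gap merges its two flanking dwells and inflates the
opposite state's mean. `correct_missed_events()` inverts this first-order
merging model jointly for both rates by fixed-point iteration; at the highest
concentration of the standard series (50 nM, unbent dwells ≈ 0.14 s against
50 ms frames) the correction moves the unbending rate by ~20% and is what
keeps it concentration-independent, as a dissociation rate must be.

`fit_concentration_series()` then fits a weighted line (weights `1/SE²`,
intercept reported rather than forced through the origin) to
`k_bending` versus concentration: the slope, converted by 1 nM = 1e-9 M,
is `k_on` in M⁻¹s⁻¹; `k_off` is the plain mean of the per-concentration
unbending rates; and `K_d = k_off/k_on` holds as an identity of the fit
object. Frame intervals are an instrument choice made by the experiment
design: the bending series runs at `dt = 0.05 s` (the cleavage-assay
resolution) because at 50 nM the unbent dwells are ~3 frames even then, and
the fast single-flap substrate (`k_off = 23.3 s⁻¹`) requires the confocal
5 ms mode with recording at lower enzyme concentration (10 nM), where unbent
dwells remain resolvable and bent dwells are abundant.

# Histogram equilibria and isotherms

`fit_mixture()` is a one/two-component Gaussian EM on raw per-molecule or
per-burst FRET values (binning is for display only; report histograms use
0.02-wide bins). Overlapping components (mean separation below the larger
SD) trigger a documented fallback to one component — a two-component weight
split is meaningless there. The bent fraction at each enzyme concentration
feeds `fit_langmuir()` (`fraction = F/(F + K_d)`), which is depletion-free
and valid because the immobilized substrate (~0.1 nM) sits far below the
K_d. Bulk titrations at comparable substrate and enzyme concentrations use
`fit_quadratic_isotherm()` instead — the exact bimolecular closed form
(the algebraically correct root; the limit `S -> 0` recovers the hyperbola,
which the tests assert). Lifetime-FRET support (`fit_decay()`,
`lifetime_fret()`) fits IRF-convolved bi-exponentials with Poisson weights
and computes `E = 1 − tau_DA/tau_D` from amplitude-weighted lifetimes,
clipping negative apparent transfer to zero with a warning.

# Cleavage classification and lag analysis

`classify_trace()` reproduces the five-category bookkeeping of
single-turnover cleavage fields of view (aberrant; acceptor bleach first;
bend-then-donor-loss; donor loss without a resolved bend; never bent). Only
category c — bent immediately before a single-step donor loss, with the 0.2
FRET change and anti-correlation checks passed — enters lag analysis. Two
regimes are handled: when the live region is long, the HMM decode and full
screen apply; when cleavage truncates the record after a handful of frames
(the cognate case), a threshold rule with the 0.2 minimum FRET change reads
bent frames directly, since no 20-frame HMM fit is possible — this mirrors
the manual frame counting such data historically received. Rare traces that
bent but never lost the donor are filed under category e with their bent
flag preserved in the classification details.

Boundary frames get majority-rule treatment at both ends of the counted lag:
the entry frame counts only if mostly bent (via its averaged E), and the
frame straddling the donor-loss step counts only if its *total* intensity
exceeds half a typical live frame — E alone cannot decide there, because a
mostly-dark frame shows background-dominated mid-range E. Without this rule
the counted lag is biased upward by nearly half a frame. For noncognate
substrates showing abortive bending, only the final bent segment before
donor loss is the lag; earlier bends belong to the dwell analysis.

`fit_gamma()` fits the lag distribution by gamma MLE; `tau_avg` equals the
sample mean (a property of the gamma MLE), `k_STO = 1/tau_avg`, and errors
come from a seeded 1000-resample nonparametric bootstrap (the bootstrap of
`tau_avg` reduces to bootstrap means; the shape uses a closed-form MLE
approximation for speed). The viscosity titration regresses the relative
slowdown `k_STO(1)/k_STO(eta)` on relative viscosity (each replicate
normalized at `eta = 1`), so a purely viscosity-limited conformational step
gives slope 1 in the Kramers sense; plotting conventions for relative rates
vary between this and its reciprocal, so `response = "direct"` is available
and the slope magnitude is what is reported either way. The generator realizes a linear slowdown law,
`tau(eta) = tau1 * (1 + slope*(eta − 1))`.

# Burst analysis

`bin_stream()` bins photon timestamps into half-open 0.5 ms bins (a photon
exactly on a boundary belongs to the later bin; counts are conserved and
asserted so). `find_bursts()` takes maximal runs of bins above background +
2 Poisson SD as candidates and keeps those with integrated counts strictly
above 35 — the count floor is per burst, not per bin, which is the reading
that makes a "35 total counts" criterion meaningful at ~1.5 ms transits. The
run-detection edge rule is this package's choice; only the bin width and the
35-count floor are fixed parts of the protocol this reproduces. Per-burst FRET uses
integrated channel counts, and `burst_histogram()` fits the burst histogram
via `fit_mixture()`, reporting means both as fractions and percentages.

# The ABF free-energy engine

`make_reference_potential()` builds an analytic bending-angle landscape on
θ ∈ [80°, 180°]: a shallow quadratic around the extended conformer at 165°
(zero reference; ≤ 2 kcal/mol out to 140°, like plain duplex DNA), a cosine
ramp to a barrier of configurable height (default 14 kcal/mol) at 100° where
junction base stacking must break, and a shallow bent well beyond. The
maximum minus the 165° minimum equals the configured barrier exactly, by
construction.

`run_abf()` preserves the ABF machinery — nine windows with harmonic
confining walls (k = 50 kcal/mol), 0.2° force-accumulation bins, a bias
ramped linearly until 2000 samples per bin, and PMF reconstruction by
trapezoidal integration of the per-bin mean forces
(`integrate_pmf()`, `barrier_height()`) — while replacing the molecular
degrees of freedom with overdamped Langevin dynamics on θ at 300 K. The
integrator is a sampling engine, not molecular dynamics: friction and time
step are reduced units chosen so a window diffuses in a small fraction of
the default 1e6 steps (noise per step ≈ 0.05°, drift ≪ noise everywhere,
stable against the stiffest wall curvature). Window edges are snapped to the
bin grid, so concatenated windows share bin boundaries and integration needs
no stitching constants. Bins never visited after a full run abort the
integration with their locations listed. Because the instantaneous force at
a given θ is deterministic here, converged profiles are accurate to within
the bin-discretization error (RMSD ≲ 0.01 kcal/mol on defaults); the
engine's statistical behavior (ramp, staircase exploration of steep windows,
seed independence) is what the tests exercise.

# Problem sizes and reproducibility

The recovery analyses run at the scale such experiments are actually performed: 200 molecules
per concentration over 5–50 nM at 60 s / 50 ms for the bending series; 8
concentrations × 300 molecules for the isotherm; 700 cleavage traces at
50 ms (yielding ≈ 500 category-c lags); 500 confocal traces at 5 ms for the
fast single-flap substrate; 3 × 4 lag sets of 300 for the viscosity
titration; 2000 transits for the burst pipeline; 9 × 1e6 Langevin steps for
the ABF profile. Every stochastic routine takes a seed, seeded runs are
bit-reproducible, and `scripts/acceptance.R` derives per-analysis sub-seeds
from one integer.

# Known limitations

* Two states only: no state-number selection, no multi-exponential dwell
  models, no hierarchical/global fitting across molecules.
* Apparent FRET throughout — no gamma-factor or cross-talk correction and no
  distance conversion.
* The missed-event correction is first-order (geometric merging); at rates
  approaching one event per frame it degrades, and the honest remedy is a
  shorter frame time, as the fast-substrate analysis does.
* The ABF engine's dynamics are a 1-D methodological stand-in: it validates
  the estimator (binning, ramp, walls, integration), not any molecular force
  field.
* Category e conflates "never bound" with the rare "bent but uncleaved"
  record; the classification details retain the distinction.
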