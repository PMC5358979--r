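# fenkin — single-molecule FRET kinetics of DNA-bending 5' nucleases

Structure-specific 5' nucleases such as flap endonuclease 1 (FEN1) recognize
their DNA substrates not by sequence but by shape: the enzyme bends the
ss/dsDNA junction by roughly 100°, the bent DNA orders disordered protein
segments, and only a substrate that passes every conformational check is
incised. Single-molecule FRET (smFRET) resolves this choreography directly —
DNA bending appears as discrete transitions in the apparent FRET efficiency
`E = I_A / (I_A + I_D)` of a donor/acceptor pair on the DNA, and 5'flap
cleavage appears as abrupt donor loss.

`fenkin` implements the complete analysis chain for such experiments, plus a
stochastic simulator so that every stage can be validated by parameter
recovery:

* **Simulation** — Gillespie-style state paths for the scheme
  `unbent --(k_on·[E])--> bent --(k_off)--> unbent`, with the bent state
  feeding an `n`-step incision chain of per-step rate `k_step` (mean lag
  `tau_avg = n/k_step`, single-turnover rate `k_STO = 1/tau_avg`); Poisson
  camera frames with frame-averaged emission, shot noise, background and
  photobleaching; diffusing-molecule photon bursts; TCSPC decay histograms.
* **Idealization** — a maximum-likelihood two-state hidden Markov model
  (Baum–Welch EM with Gaussian emissions on `E`, Viterbi decoding) plus the
  standard trace filters: aberrant-brightness exclusion, a minimum FRET
  change of 0.2, and donor/acceptor anti-correlation at transitions.
* **Dwell-time kinetics** — censoring-aware exponential rate estimation
  (histogram least squares, plain and censored MLE, missed-event correction),
  the concentration series `k_bending = k_on·[E] + c` giving `k_on` from the
  slope, `k_off` as the mean unbending rate, and `K_d = k_off/k_on`;
  Michaelis–Menten fits of bulk initial rates.
* **Equilibria** — Gaussian-mixture fits of FRET histograms, Langmuir
  isotherms of the bent fraction, the exact bimolecular (quadratic) isotherm
  `E = E0 + (Ef−E0)·[(S+F+K_d) − √((S+F+K_d)² − 4SF)]/(2S)`, and
  lifetime-FRET `E = 1 − τ_DA/τ_D` with IRF-reconvolution decay fits.
* **Cleavage analysis** — the five-category trace classification, bent-state
  lag extraction, gamma fitting (`tau_avg`, `k_STO`, bootstrap errors), donor
  loss accounting across Mg²⁺/Ca²⁺ conditions, and the viscosity-dependence
  regression of relative `k_STO`.
* **Burst analysis** — photon binning (0.5 ms), burst search above a
  35-count floor, per-burst FRET and Gaussian histogram fits.
* **Free-energy reconstruction** — a one-dimensional adaptive-biasing-force
  (ABF) engine on the DNA bending angle: windowed overdamped Langevin
  sampling with 0.2° bins, a 2000-sample bias ramp and 50 kcal/mol walls,
  integrated to a potential of mean force with its bending barrier.

## Worked example

Simulate one equilibrated-substrate molecule at 20 nM enzyme, idealize it,
and estimate the unbending rate; then run the full concentration series:

```r
library(fenkin)

model <- kinetic_preset("EQ_DF61_dsdna", conc = 20)
trace <- emit_trace(simulate_state_path(model, 60, seed = 1), model,
                    dt = 0.05, seed = 2)
fit <- fit_two_state_hmm(trace)
fit
#> Two-state HMM fit: mu = 0.295 / 0.536 (sigma 0.059 / 0.053), logL = 1058.68, 14 iter

path <- viterbi_path(trace, fit)
attr(path, "dt") <- trace$dt
fit_exponential(extract_dwells(path, "BENT"), "mle_censored", dt = 0.05)
#> k = 0.3416 +/- 0.1 s^-1 (mle_censored, n = 12)

set.seed(3)
series <- bending_series_experiment(kinetic_preset("EQ_DF61_dsdna"),
                                    concs = c(5, 10, 20, 50), n_traces = 50)
series$fit
#> k_on  = 1.3e+08 +/- 2.7e+06 M^-1 s^-1
#> k_off = 0.449 +/- 0.0085 s^-1
#> K_d   = 3.45 nM (= k_off / k_on)
```

The fitted state means land on the generating FRET values (0.27/0.54); a
single molecule gives a noisy rate (12 dwells), while the pooled series
recovers the generating `k_on = 1.4e8 M⁻¹s⁻¹` and `k_off = 0.45 s⁻¹` and
their ratio, the bending dissociation constant, at a few percent.

See `vignettes/fen1-smfret-kinetics.Rmd` for the models, assumptions, and
numerical choices behind each stage.

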