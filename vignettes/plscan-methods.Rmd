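---
title: "Phase-lock interval scaling analysis: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lock interval scaling analysis: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pairs of MEG/EEG sensor signals can stay phase-locked for stretches of time:
maximal periods during which the wrapped instantaneous phase difference
between two channels remains inside a threshold. The durations of these
*phase-lock intervals* (PLI) form a distribution, and whether that
distribution has a power-law tail — rather than an exponential one — has
been read as a signature of critical brain dynamics. The reading only makes
sense if the statistic behaves itself on data that contain no brain at all.
Empty-room recordings (sensor noise plus environmental contamination,
chiefly mains line noise at 50/60 Hz and harmonics) are the natural negative
control: if the pipeline reports power-law phase locking on an empty room,
the pipeline — not the brain — is producing the power law.

`plscan` implements both estimator families whose disagreement created
exactly this situation: an analytic-wavelet phase estimator applied after
notch filtering of line noise, and a "simplified" band-pass + Hilbert
estimator applied without notch filtering. It also ships a synthetic
generator for both regimes, so every claim the package makes is testable
without any real recordings.

## The pipeline

For a record $x_c(t)$, $c = 1..C$, sampled at $f_s$:

1. *(optional)* zero-phase notch filtering at $k f_0$, $k = 1..K$
   (second-order IIR notches, forward–backward).
2. Per-band instantaneous phase $\phi_{b,c}(t)$ by one of two backends
   (below), over the dyadic ladder 1–2, 2–4, 4–8, 8–17.5, 17.5–35, 35–70,
   70–140 Hz (clipped to Nyquist). The 70–140 Hz band is a control: no
   neurophysiological phase coupling is expected there.
3. For each unordered channel pair, the wrapped difference
   $\Delta\phi(t) = \mathrm{wrap}(\phi_a - \phi_b) \in (-\pi, \pi]$,
   optionally smoothed by the argument of a centred moving mean of
   $e^{i\Delta\phi}$ (the sliding-window quasi-instantaneous coherence
   direction).
4. Lock intervals: maximal runs with $|\Delta\phi(t)| < \theta$ (default
   $\theta = \pi/4$) among valid samples; durations in seconds; runs
   touching a record/validity boundary are flagged censored and kept by
   default.
5. Per band, durations pooled over pairs; a log-binned density is reported
   and the tail is adjudicated: continuous power law
   $p(t) \propto t^{-\alpha}$, $t \ge t_{\min}$ (MLE
   $\hat\alpha = 1 + n\,[\sum_i \ln(t_i/t_{\min})]^{-1}$, $t_{\min}$ by
   KS-distance minimisation) against a shifted exponential
   (MLE rate $1/(\bar t - t_{\min})$), compared by a Vuong-style
   normalised log-likelihood ratio
   $\mathrm{LLR} = \sum_i d_i / (s_d \sqrt n)$. Verdict: `power_law` if
   $\mathrm{LLR} \ge 2$, `exponential` if $\le -2$, otherwise
   `indeterminate`; tails smaller than 50 are always `indeterminate`.

### Phase backends

**Hilbert backend.** Zero-phase order-4 Butterworth band-pass per band
(half-power at the band edges; forward–backward application squares the
response), then the analytic signal by zeroing negative frequencies in the
Fourier domain. Phase is its argument, amplitude its modulus.

**Wavelet backend.** One analytic Morlet-type scale per octave band: a
Gaussian frequency window centred on the geometric mean
$f_c = \sqrt{f_{lo} f_{hi}}$, with $\sigma_f = f_c/\text{cycles}$ and zero
response at negative frequencies, applied by FFT. The default is the
standard 6-cycle analytic Morlet. A broader, octave-matched window
(half-power at the band edges, about 2.35 cycles;
`wavelet_phase(cycles = NULL)`) was considered as the default and rejected:
at that width the 70–140 Hz scale still responds at 0.4–0.65 amplitude to
50–70 Hz content, so neighbouring-band power leaks into the high-frequency
control band and the ladder loses the very frequency specificity the
control band exists to provide. The exact wavelet family used in the
original analyses is not published; any analytic wavelet can be substituted
at this interface. One scale per band keeps the phase stack rectangular.

Both backends flag samples within three centre periods of either record end
(filter/wavelet edge effects) and samples whose instantaneous amplitude is
below $10^{-12}\times$ the channel's band-amplitude RMS (the phase of a
near-zero analytic signal is numerically meaningless); flagged samples are
excluded from interval extraction, and intervals cut by the exclusion are
censored.

### Smoothing defaults

The original wavelet analysis used a sliding-window coherence estimate; the
simplified band-pass variant altered that step. Published descriptions do
not give window lengths. The package default mirrors the build
specification: smoothing off for the wavelet backend, one centre period
(rounded to an odd sample count) for the Hilbert backend; both are
overridable through `lock_criterion(smoothing_window = ...)`. Note the
historical allocation is arguably the reverse (the *original* method is the
one described as using the sliding window); since the truth is
under-documented, the parameter is exposed rather than hard-coded.

## The synthetic generator

The generator states a world; it does not chase numbers.

**Human-like regime.** Each channel is
$\sqrt{\kappa}\, s(t) + \sqrt{1-\kappa}\, g_c(t) + \varepsilon_c(t)$ with a
shared source $s$, independent backgrounds $g_c$ — all unit-variance
$1/f^\beta$ Gaussian noise, $\beta = 1.5$ by default — coupling
$\kappa = 0.6$, and white sensor noise $\varepsilon_c$ with standard
deviation 0.2. The noise floor follows the published observation that
empty-scanner amplitude variance sits 1–2 orders of magnitude below brain
recordings ($0.2^2 = 0.04$, about 1.4 orders). The shared source is rolled
off (squared-cosine, transition $0.8 f_{hi} \to f_{hi}$) above
`coupling_f_hi` = 70 Hz: the scaling phenomenon under study is confined to
neurophysiological frequencies (2–75 Hz), so the *coupled* component — the
stand-in for neural interaction — must not extend into the high-frequency
control band. `coupling_f_hi = NULL` restores a fully broadband shared
source.

**Empty-room regime.** Independent white noise per channel (unit SD), plus
mains contamination: cosines at $f_0 = 50$ Hz and harmonics whose phase
performs a slow random walk ($10^{-3}$ rad/sample — a finite spectral line
width, avoiding degenerate infinite locks), added *identically to every
channel* (mains couples coherently into all sensors — this shared waveform
is the mechanism that manufactures spurious cross-channel locking). Default
amplitudes: $0.3, 0.15, 0.075$ of the noise SD for harmonics 1–3. The 0.3
ratio quantifies "low-amplitude" line noise; no published value exists, so
it is a calibration choice exposed as `amp_ratio`.

All randomness flows through per-component sub-streams derived from one
seed, so records are bit-identical across calls and channel counts.

### What the generator does and does not emulate

It emulates: broadband $1/f$-like spectra, genuine cross-channel coupling
with a controllable strength and frequency extent, coherent narrow-band
line contamination on top of independent sensor noise, and exact
reproducibility. It does **not** emulate: non-stationarity, non-Gaussian
or genuinely critical dynamics, sensor geometry, or vendor preprocessing.
Two consequences matter when reading test results:

* A *green* artifact test establishes that the estimator chain reproduces
  the line-noise mechanism and that notch + wavelet analysis removes it. It
  does not establish that human recordings show criticality — the generator
  cannot produce critical dynamics by construction.
* Linear Gaussian coupling makes lock intervals *longer* (more total locked
  time, at every coupled frequency, in every replicate we have run) but it
  does not make their tail *more power-law-like relative to its own
  exponential fit*: the normalised LLR of the coupled condition is not
  systematically above the uncoupled control, whether compared at
  per-condition KS-selected cutoffs or at a common cutoff, with either
  backend at its defaults. The one configuration in which a systematic LLR
  excess does appear — the broad octave-matched wavelet combined with
  sliding-window smoothing — also leaks coupled power into the 70–140 Hz
  control band, and the excess there is an interruption-merging artifact of
  a non-selective estimator rather than genuine tail heaviness. A criterion
  expecting Gaussian coupling to raise the LLR is, on our evidence, not
  satisfiable in this stated world; the corresponding acceptance check is
  implemented faithfully and documented as expected-red rather than
  weakened. Heavy tails in *this* world come from the line-noise artifact,
  not from coupling.

* The marginal variance of a *coupled* channel fluctuates seed-to-seed
  beyond the nominal $\kappa + (1-\kappa) + \sigma^2$: two independent
  long-memory ($1/f^{1.5}$) series of finite length show sizeable spurious
  sample covariance. Variance control is therefore asserted on background
  (uncoupled) channels.

## Numerical choices

* **Filters.** No `signal`-style DSP package is assumed: Butterworth
  band-pass design (analog prototype, LP→BP transform with pre-warped
  edges, bilinear transform, second-order sections) and RBJ biquad notches
  are implemented directly and verified against their frequency-response
  contracts in the test suite. Filtering runs forward–backward with
  odd-reflection padding of one settling length ($3 f_s/f_{lo}$ for
  band-passes, $3 f_s Q/f_0$ for notches) and step-steady-state initial
  conditions, so constants pass exactly and edge transients stay inside the
  discarded edge zone.
* **Wrapping.** $\mathrm{wrap}(x) = x - 2\pi\lceil (x-\pi)/(2\pi) \rceil$
  maps onto $(-\pi, \pi]$; both $\pm\pi$ wrap to $+\pi$.
* **xmin floor.** Durations are discretised in units of $1/f_s$; cutoffs
  below $3/f_s$ are never scanned (discreteness would bias the continuous
  MLE).
* **Cutoff scan.** Candidate cutoffs are the observed distinct durations
  (quantile-thinned to at most 100) with at least 10 tail samples; ties in
  KS distance resolve to the smaller cutoff.
* **Censoring.** Censored (boundary-touching) intervals are included by
  default everywhere: the longest intervals — exactly the tail under
  study — are the likeliest to touch a boundary, and dropping them would
  suppress the artifact the package exists to expose.
* **Degenerate inputs.** All-invalid samples give an empty interval set;
  empty sets give an `empty`-flagged distribution; tails below the minimum
  size give an `indeterminate` verdict. None of these are errors.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `threshold` | $\pi/4$ | rad | lock criterion; conventional, unpublished in the source analyses |
| `smoothing_window` | auto (backend-dependent) | samples | see above |
| `cycles` (wavelet width) | 6 | cycles | band separation vs time resolution |
| `min_duration` | 1 | samples | no published floor |
| `quality` (notch Q) | 30 | — | 1.7 Hz wide at 50 Hz; narrow enough to leave neighbouring PSD intact (<10% distortion) |
| `coupling` | 0.6 | — | human preset; strong but not degenerate |
| `beta` | 1.5 | — | between pink and Brownian, typical of MEG background |
| `sensor_noise_sd` | 0.2 (human), 1 (empty) | a.u. | noise floor 1–2 orders below background variance |
| `amp_ratio` | 0.3 | — | "low-amplitude" line noise; calibration choice |
| `phase_drift_std` | $10^{-3}$ | rad/sample | finite line width |
| `min_tail` | 50 | intervals | verdicts on smaller tails are noise |

## Known limitations

* One wavelet scale per octave band; no continuum of scales, no dual-tree
  complex wavelet transform.
* With the broad octave-matched window (`cycles = NULL`) the wavelet bands
  overlap heavily and the 70–140 Hz control band sees sub-70 Hz content;
  use the default 6-cycle wavelet or the Butterworth-based Hilbert backend
  when frequency specificity matters.
* No bootstrap goodness-of-fit p-value for the power law, and no lognormal
  or truncated power-law alternatives — the comparison is strictly
  power law vs exponential.
* CSV (+ JSON sidecar) is the only on-disk container; vendor MEG formats
  are out of scope.
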