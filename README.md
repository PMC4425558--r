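# plscan

Phase-lock interval (PLI) scaling analysis for multichannel
neurophysiological time series — and a sanity-check harness for it.

## What problem this addresses, and for whom

A pair of MEG/EEG channels is *phase-locked* while the wrapped difference
of their instantaneous phases stays inside a threshold
(|Δφ| < θ, default θ = π/4). The durations *t* of these maximal lock
intervals form a distribution; a power-law tail
p(t) ∝ t^(−α) — rather than an exponential one — has been interpreted as
a marker of critical brain dynamics. That interpretation collapses if the
same pipeline reports power laws on *empty-room* recordings (no subject;
only instrument noise and mains line contamination at 50/60 Hz and
harmonics, which couples coherently into every sensor).

`plscan` is for researchers who want to (a) run the PLI analysis with
either of the two estimator families whose disagreement created this
controversy — the original analytic-wavelet phase estimator with notch
preprocessing, and the simplified band-pass + Hilbert estimator without —
and (b) verify, on fully synthetic data, that apparent empty-room scaling
is a line-noise artifact of the simplified pipeline and disappears under
notch filtering plus the wavelet estimator.

## The statistic at its core

Per frequency band (dyadic ladder 1–2 … 70–140 Hz) and channel pair:

* instantaneous phase φ_b,c(t) from an analytic wavelet coefficient or a
  band-passed analytic (Hilbert) signal;
* lock intervals = maximal runs of |wrap(φ_a − φ_b)| < θ;
* tail model comparison on pooled durations: continuous power-law MLE
  α̂ = 1 + n [Σ ln(t_i/t_min)]⁻¹ with t_min chosen by KS-distance
  minimisation, against a shifted-exponential MLE, decided by a
  Vuong-style normalised log-likelihood ratio (≥ +2 power law, ≤ −2
  exponential, otherwise indeterminate).

## Worked example

```r
library(plscan)

# an empty room with a shared 50 Hz mains line (amplitude 0.3 x noise SD)
cfg <- generator_config("empty_room", n_channels = 4, duration = 300,
                        fs = 600, seed = 11)

# the simplified pipeline, no notch: the line band locks far too much
res  <- run_condition(cfg, method = "hilbert")
# the original pipeline: notch the line, then wavelet phase
res2 <- run_condition(cfg, method = "wavelet", notch = notch_spec(50))

summary_table(list(res, res2))[band == "35-70Hz"]
#>        condition    band n_intervals total_locked_s   alpha  xmin       llr       verdict
#> 1:       hilbert 35-70Hz       23172        719.455 6.42487 0.115 -1.49878 indeterminate
#> 2: wavelet+notch 35-70Hz       18039        446.080 6.73465 0.090 -2.15612   exponential
```

Reading: without the notch, the shared 50 Hz line inflates total locked
time in its band from the ~25% chance level (about 450 s pooled over 6
pairs) to 719 s, and drags the tail away from exponential
(`indeterminate`). After notch + wavelet analysis the excess locking is
gone (446 s), the band is judged `exponential`, and no band anywhere in
the ladder is judged `power_law` — the empty room behaves like noise, as
it should. On the synthetic "human" preset (coupled 1/f background,
`generator_config("human")`), locked time instead exceeds the uncoupled
control in every 2–70 Hz band while the 70–140 Hz control band stays
clean (see the methods vignette for what that does and does not
establish).

The full six-cell comparison (both backends × {human, empty+line,
empty+notch}) is one call:

```r
grid <- run_grid(default_grid_conditions(seed = 1))
write_grid_results(grid, "gridout/")   # results.json, summary.tsv, per-cell TSVs
```

or from the shell:

```sh
exec/plscan simulate --preset empty-room --line-freq 50 --seed 1 -o rec.csv
exec/plscan analyze rec.csv --method hilbert --notch off -o out.json
exec/plscan grid --seed 1 -o gridout/
exec/plscan report gridout/
```

## Package layout

* `R/synthgen.R` — synthetic human / empty-room generator, line-noise model
* `R/filters.R` — notch and Butterworth band-pass design (SOS, zero-phase)
* `R/phase.R` — wavelet and Hilbert phase backends
* `R/intervals.R` — lock-interval extraction, pooling, log-binned densities
* `R/scalingfit.R` — power-law / exponential tail fits and verdicts
* `R/pipeline.R` — condition runner, grid, JSON/TSV reports
* `exec/plscan` — command-line interface
* `vignettes/plscan-methods.Rmd` — models, assumptions, limitations
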