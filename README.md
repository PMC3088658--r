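# doubletcode

Analysis of temporal coding by short spike doublets in sensory
interneurons, for electrophysiologists and computational neuroscientists
studying whether fine spike-timing patterns carry stimulus information that
linear (rate-based) reconstruction misses.

The motivating system is the pair of wind-sensitive giant interneurons of
the cricket cercal organ driven by 10–200 Hz band-passed Gaussian
white-noise air currents, but every stage is generic: spike-time tables in,
tibbles out.

## What it computes

**Spike statistics.** ISI histograms at 0.1 ms resolution; the relative
refractory period fit as a Normal CDF ("recovery function",
`P(fire) = Φ((t − μ)/σ)`, pooled-data values μ = 2.5 ms, σ = 0.2 ms); a
Bonferroni-corrected binned independence test of consecutive ISI pairs.

**Doublet precision.** Detection of repeatable doublet events in
frozen-noise rasters; onset jitter and within-doublet correlation, with the
pooled exponential models

    jitter(ISI) = x1 exp(−ISI/x2) + x3            (x = −1.0, 4.8, 1.1 ms)
    R(ISI)      = x1 exp(−ISI/x2) + x3 exp(−ISI/x4)   (x = 2.3, 1.7, 0.2, 28.9)

plus two estimators of single-spike latency SD: a raster (frozen-noise)
estimator and an iterative "dejittering" alignment for non-repeated data.

**Timing models and information.** Three models of within-doublet
variability (independent spikes; independent plus refractory displacement;
data-matched, `t2 = ISI + R·t1 + ε`, `ε ~ N(0, σ₀²(1−R²))`), their Gaussian
conditional entropies and ISI-weighted information rates; direct-method
information via binary context-tree weighting (CTW, compiled); and the
linear lower bound `−∫ log₂(1 − γ²(f)) df` from multitaper coherence.

**Stimulus models and decoding.** Pattern-conditioned Gaussian stimulus
models over the 50 ms window before a pattern (singlet STSM, doublet DTSM
per ISI); the synthetic doublet model (sDTSM) built from offset-summed
singlet models with a generalized-variance volume constraint;
cross-validated log-likelihood-ratio (LLR) tests with an exact
finite-sample estimation-bias correction; an offset scan producing the
best-offset csDTSM; and iSTAC — the orthonormal subspace maximizing the
Kullback–Leibler divergence between data and synthetic models — with the
subspace-corrected mcsDTSM.

A synthetic-data module (`generate_stimulus()`, `encode()`,
`frozen_noise_session()`) generates band-limited Gaussian stimuli and
surrogate spike trains: an exponential-nonlinearity LNP encoder with
Normal-CDF refractory recovery whose `burst_gain = 0` setting is an exact
linear-superposition negative control, while `burst_gain > 0` converts
sharp stimulus deflections into doublets carrying a distinct code.

## Worked example

```r
library(doubletcode)

stim  <- generate_stimulus(1800 * 1000, seed = 101)   # 30 min, 10 kHz
train <- encode(stim, encoder_spec(burst_gain = 3), seed = 202)
train
#> <spike_raster> 64765 spikes, 1 trial(s), 1800.0 s each

isi_histogram(train)
#> <isi_histogram> 59915 ISIs < 70 ms (92.5% of all), bin 0.1 ms

# pattern-conditioned models and the doublet-vs-synthetic LLR at 3 ms ISI
ens  <- collect_isolated_patterns(train, stim)
rs   <- fit_reduced_space(stim)
stsm <- fit_gaussian_model(ens$singlet$segments, "STSM")
eb   <- ens$doublet[["3"]]
res  <- llr_test(
  eb$segments, eb$folds,
  fit_a = function(tr) fit_gaussian_model(tr, "DTSM", 3),
  fit_b = function(tr) synthesize_doublet_model(
    stsm, 3, fit_gaussian_model(tr, "DTSM", 3), rs),
  reduced_space = rs, isi_ms = 3)
res
#> <llr_result> mean 0.339 [0.287, 0.391], n = 1247 (7 outliers removed)
```

The positive mean LLR (natural-log units per held-out stimulus segment,
with a 95% confidence interval excluding zero) says that 3 ms doublets are
better explained by their own conditioned stimulus model than by the
offset-sum of single-spike models: the doublet is a codeword of its own.
Running the same test on the `burst_gain = 0` control yields means near
zero at ISIs away from the refractory floor, and
`fit_llr_decay()` on the full LLR-vs-ISI table recovers the few-ms decay
constant of the doublet channel. `run_full_pipeline(pipeline_config())`
chains all stages on a desk-scale synthetic session and returns the
headline numbers (mean rate, recovery fit, direct vs linear information,
LLR table, iSTAC summary) as one report list.

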