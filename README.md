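# wardwalk

Hospitals with long-stay referrals often see their daily census (the
number of occupied beds, **InP**) meander between nearly full and half
empty over months. Read with everyday statistics, those meanders look like
seasonality, demand cycles, or administrative failure. `wardwalk`
implements the alternative diagnosis: the census is a **Brownian random
walk** generated by the random lag between discharges and the admissions
that refill them, and the right way to show it is fractal-dimension
analysis with distribution-free significance testing.

The package is aimed at biostatisticians and health-operations analysts
working with command-panel style daily count series (admissions `Adm`,
discharges `Dis`, census `InP`), and at anyone who needs a
finite-sample-calibrated random-walk vs white-noise classifier for short
integer-valued time series.

## The method

**Sevcik dimension.** A waveform of N points is mapped into the unit
square (x* = x/(x_max − x_min) with the abscissa 0..N−1,
y* = (y − y_min)/(y_max − y_min)); with L the embedded polyline length and
N′ = N − 1,

    D_s = 1 + (ln L − ln 2) / ln(2N′),
    var(D_s) = Σ_i (Δy_i − Δȳ)² / [L · ln(2N′)]²,

where Δy_i are the embedded segment lengths. D_s converges to the
Hausdorff–Besicovitch dimension only as N′ → ∞ (white noise → 2, Brownian
walk → 1.5) and *underestimates* it at finite N, so `wardwalk` always
compares an observed series against Monte Carlo ensembles of white and
Brownian standards generated at exactly the observed length
(`calibrate()`).

**Vysochanskij–Petunin comparison.** Dimension differences are tested
without assuming the sampling law of D_s: for unimodal X with finite
variance, P(|X − μ| ≥ λσ) ≤ 4/(9λ²) whenever λ > √(8/3). With
λ = |ΔD̄_s| / √(var₁ + var₂), the one-tailed rule declares significance at
α = 0.05 when λ ≥ √(40/9) ≈ 2.108 (two-tailed: √(80/9) ≈ 2.981); for
λ ≤ √(8/3) only the bound 1/6 ≤ P ≤ 1 exists and no difference is claimed.

**Supporting toolbox.** Runs about the median (exact combinatorial tail
for small samples), Hodges–Lehmann medians with signed-rank CIs, Theil
regression with tie-corrected Spearman correlation, Jarque–Bera, the
two-sample Smirnov test, Hann-windowed spectral densities with log-log
Theil slopes (white ≈ 0, Brownian ≈ −2), and a seeded synthetic hospital
generator (Poisson discharges, per-slot geometric refill lag, injectable
year-boundary spikes and recording gaps) so the whole pipeline is testable
without any hospital's data.

## Worked example

The numbered scripts under `analysis/` run the full study on a synthetic
hospital (`Rscript analysis/01_simulate.R` … `06_spectra.R`), writing
tables under `results/`. Condensed, the core of it is:

```r
library(wardwalk)

cfg <- hospital_config(inject_newyear_spike = TRUE, inject_gap = c(28, 9))
sim <- simulate_hospital(cfg, seed = 3)
report <- run_pipeline(sim$series, M = 100, seed = 20240501)
print(report)
```

which prints (exact output):

```
Census analysis report (1329 days)
  occupancy median 71.1% (70.5-71.9%), range 30.7-95.3%
  Ds(Adm  ) = 1.58711 +- 0.00285
  Ds(Dis  ) = 1.61821 +- 0.00266
  Ds(InP  ) = 1.30923 +- 0.00272
  Ds(DInP ) = 1.58298 +- 0.00270
  Ds(DDiAd) = 1.58277 +- 0.00271
  Ds(Xi   ) = 1.30707 +- 0.00273
  InP vs Xi: lambda = 0.561, not significant
```

Reading it: the census (`InP`, D_s ≈ 1.31) sits in the Brownian
calibration band (ensemble mean 1.29) and far below the white band
(1.60), while its daily increments (`DInP`) and the daily
admissions-minus-discharges difference (`DDiAd`) are white-like. `Xi` is
the walk rebuilt by accumulating `DDiAd`; its dimension is statistically
indistinguishable from the census's (λ = 0.56 ≤ √(8/3), corollary regime),
so the census fluctuations are fully explained by the discharge-to-
admission lag — shrink the lag and the meanders (and the empty-bed
stretches) shrink with it. The spectral check agrees: log-log slopes
≈ −2.0 for `InP`/`Xi`, ≈ 0.0 for the difference series, with no dominant
peak, i.e. no real periodicity.

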