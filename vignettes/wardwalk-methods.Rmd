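---
title: "Random walks in hospital bed occupancy: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random walks in hospital bed occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardwalk)
```

## The problem

A mid/long-stay hospital logs three daily integer series: admissions
(`Adm`), discharges (`Dis`) and the census of in-patients (`InP`). Over a
few years the census appears to cycle between near-full and half-empty.
`wardwalk` tests a specific mechanism for those meanders: each discharge
frees a bed that is refilled only after a random referral delay, so the
census integrates the daily admission–discharge imbalance and behaves as
a Brownian random walk. A walk has no periodicity and no trend, yet
produces convincing-looking pseudo-cycles and pseudo-trends; treating
them as real leads to wrong operational conclusions.

The decisive empirical check is constructive: accumulate the daily
admissions-minus-discharges difference (`DDiAd`) into the walk
`Xi[1] = 0, Xi[i] = Xi[i-1] + DDiAd[i]`. On conservation grounds `Xi`
equals `InP` up to its initial value wherever the records are clean, and
the analysis asks whether the two are statistically indistinguishable as
waveforms.

## The dimension estimator

For a waveform of `N` points at unit abscissa spacing, the curve is
embedded in the unit square; the printed normalization divides the
abscissa by its range without subtracting the minimum, so the package
requires the abscissa to start at 0 (it uses `0..N-1`), which makes the
two forms identical. With `L` the embedded polyline length and
`N' = N - 1`,

$$D_s = 1 + \frac{\ln L - \ln 2}{\ln (2N')},\qquad
\mathrm{var}(D_s) = \frac{\sum_i (\Delta y_i - \overline{\Delta y})^2}
{\left[L\,\ln(2N')\right]^2},$$

where the $\Delta y_i$ are the embedded segment lengths. The variance
expression as usually printed carries an $N'$ inside and outside the sum;
we adopt the grouping in which the two cancel. This was validated before
freezing: it reproduces the published single-trace spread of a
10^4-point standard-Gaussian trace (we measure s(D_s) ≈ 7.6e-4) and the
ensemble spread at N = 1329, which the alternative groupings miss by
orders of magnitude.

Degenerate input: a flat waveform has no embedding; `sevcik_dimension()`
returns `Ds = 1, var = 0` with a warning, since a constant line is
topologically one-dimensional.

### Finite-length calibration

$D_s \to D_h$ only as $N' \to \infty$ (white noise: 2; Brownian walk:
1.5) and underestimates it at any finite length. Dimensions are therefore
never compared across lengths; every observed series is judged against
`calibrate()` ensembles of M seeded standards at exactly the observed N.
The ensemble records the mean, the between-trace variance (denominator
M − 1), the mean within-trace variance, and their sum, which is the
variance used in comparisons. At N = 1329 and M = 100 the white ensemble
mean is ≈ 1.60 and the Brownian ≈ 1.29 — far from 2 and 1.5, which is the
whole point of matched-length calibration.

## The significance rule

The sampling law of $D_s$ is unknown, so differences are tested with the
Vysochanskij–Petunin inequality: for unimodal $X$ with finite variance,
$P(|X-\mu| \ge \lambda\sigma) \le 4/(9\lambda^2)$ for
$\lambda > \sqrt{8/3}$. With
$\lambda = |\Delta \bar D_s| / \sqrt{\mathrm{var}_1 + \mathrm{var}_2}$
the one-tailed rule at $\alpha = 0.05$ requires
$\lambda \ge \sqrt{40/9} \approx 2.108$; the two-tailed threshold is
$\sqrt{80/9} \approx 2.981$. Below $\sqrt{8/3}$ the theorem gives no
point bound; only $1/6 \le P \le 1$ holds (the corollary regime) and the
comparison is reported as "not significant" with that interval, never as
a point p-value. One printed derivation of the intermediate
$\epsilon$-expression in the source material is typographically garbled;
the package derives the rule only from the inequality itself and the
one-/two-tail inversion above. The test is deliberately conservative:
anything it declares significant would also be declared significant by a
z-test at the same level (property-checked in the suite).

A documentation wrinkle: published dimension tables of this method label
a column "var" whose magnitudes match the *standard deviation*
$\sqrt{\mathrm{var}(D_s)}$ at N = 1329. `sevcik_dimension()` therefore
returns both `varDs` and `sDs`, and comparisons consume variances
explicitly, so either reading can be formed.

## The synthetic hospital

No real hospital feed ships with the package; a generative model stands
in for it and defines the study conditions.

* **Mechanism** — daily discharges are Poisson; each discharged slot
  schedules exactly one admission after a lag from the configured family
  (geometric by default); arrivals defer to the next day if the ward is
  full; the pending pipeline is pre-seeded at its stationary rate so the
  census starts in equilibrium. This is the minimal model in which the
  census is a lag-driven walk while `DDiAd` stays white.
* **Defaults** — 192 beds, 1329 days, target census 150 (the scale of
  the study the package re-examines); 3.5 discharges/day, i.e. a mean
  length of stay of ≈ 43 days, realistic for a mid/long-stay facility;
  geometric refill lag with mean 150 days. The lag scale was chosen once,
  at design time, as the smallest at which the simulated census
  reproduces the observed structure — census dimension ≈ 1.34 (inside
  the Brownian band at N = 1329), white-like `DDiAd` (≈ 1.60), occupancy
  wandering over roughly half the capacity range — and has not been
  revisited since. A shorter lag (stronger mean reversion) pushes the
  census dimension up towards the white band; `lag_mean = 0` pins the
  census exactly.
* **Artifacts** — optional injection of the two defects the cleaning
  stage must repair: impossible (> 900) admission/discharge counts on
  the two year-boundary days, and a 9-day contiguous recording gap.
* **What it does not emulate** — real series carry calendar structure
  (weekday admission patterns), heavy-tailed length-of-stay mixtures
  across units, and correlated transcription errors. Passing tests on
  the generator therefore shows the *pipeline* behaves as specified under
  the stated mechanism, not that any particular hospital is a pure walk.

Seed handling: every generator call takes one integer seed and uses a
private Mersenne-Twister stream (the ambient RNG state is saved and
restored); an analysis derives per-component seeds from a single master
seed via `derive_seed(master, offset)` with fixed documented offsets.
Identical seeds reproduce the serialized CSV byte-for-byte.

## Cleaning rules

* **Year-boundary repair** — any count exceeding the bed capacity is
  impossible; it is replaced by the mean of the flanking days and
  flagged. If two adjacent days are both impossible the rule cannot apply
  (a flank would itself be suspect) and the function errors rather than
  guesses; boundary days likewise.
* **Gap bridging** — a contiguous missing run is filled by applying the
  constant daily change `(y_after - y_before)/gap_len` cumulatively, so
  the last gap day reaches the first observed value after the gap.
  Bridged values are kept as reals (not rounded) so telescoping
  identities stay exact; the days are flagged.
* Cleaning is idempotent, touches only flagged days, and logs every
  action (day, rule, column, old, new) to a JSON cleaning log.
* The difference convention is `dy[1] = 0`, `dy[t] = y[t] - y[t-1]`; the
  `DDiAd` sign is admissions − discharges — the source material states
  both signs in different places, and only this one makes the
  reconstructed walk rise with admission surpluses.

## Spectral classification

`spectral_density()` removes the mean (otherwise the DC term dominates a
windowed transform), applies a Hann taper by default (the source material
names both Hann and Hamming in different places; Hamming is available via
a flag), zero-pads to the next power of two and reports
$\psi_f = a_f^2 + b_f^2$ on frequencies (0, 0.5] cycles/sample. The
log-log Theil slope is fit over the band excluding the top decade of
frequencies, which is contaminated by discrete-sampling artefacts; white
noise gives slope ≈ 0, a walk ≈ −2 (the 1/f² law). `classify_series()`
labels a series white- or Brownian-like only when the spectral slope and
the calibrated-dimension position agree, returns "indeterminate"
otherwise, and annotates genuinely periodic signals via a dominant-peak
check (a peak away from the lowest bins towering > 100× over its local
background — a global peak-to-median test would misfire on 1/f² spectra,
whose lowest bin legitimately dominates).

## Nonparametric toolbox choices

* **Runs test** — ties with the median are discarded; the exact
  combinatorial run-count law is used up to n_used = 40 (cheap and
  stable there) and the continuity-corrected normal approximation
  beyond; both `P(R <= obs)` (the walk/trend-sensitive tail used here)
  and the two-sided p are reported, since prose descriptions of this
  test's tail convention are commonly self-contradictory.
* **Hodges–Lehmann** — median of all Walsh averages; CI from signed-rank
  critical order statistics (exact to n = 50, normal beyond). Checked
  against the reference signed-rank implementation and by a coverage
  simulation (93–97% at nominal 95%).
* **Theil regression** — median of pairwise slopes with the rank-based
  slope interval; intercept as the median residual with a
  Hodges–Lehmann interval; Spearman's rho as the Pearson correlation of
  mid-ranks (the standard tie correction) with the large-sample t
  approximation. Consistent under Cauchy noise, where least squares is
  not.
* **Jarque–Bera** implemented from sample moments (χ²₂ reference);
  the two-sample Smirnov test delegates to the standard `ks.test`
  implementation. Daily means per unit (mean length of stay) are ratios
  of random quantities and can be Cauchy-like — without moments — which
  is why location and trend are always reported as medians and rank
  statistics; the Cauchy closed forms are included and
  `gen_cauchy()` exists to exercise exactly this failure mode.

## Problem sizes and determinism

The test suite and the acceptance script run calibrations at M = 100,
N = 1329 (the study scale; a full ensemble takes well under a second),
single traces at N = 10⁴, and simulation batches of 20 seeds — sizes at
which every stochastic check has comfortable margin. All stochastic
tests fix their seeds; reports are byte-reproducible given (input,
seed).

## Known limitations

* The census loader supports the canonical CSV dialect; spreadsheet
  workbooks are expected to be exported to CSV first.
* `classify_series()` needs ≥ 256 points; short unit-level series can
  only use the runs/trend tools.
* The exact runs distribution assumes exchangeability given the
  above/below counts; heavy tie structure (narrow integer ranges)
  reduces power, which is reported via `n_used`.
* The V-P rule is conservative by construction: real differences of
  modest size will often land in "not significant". That is the intended
  trade-off for distribution freedom.
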