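# locodyn

Analysis of intermittent locomotor dynamics in long actigraphy-style
recordings: circadian/ultradian rhythm quantification by Morlet wavelet
spectra, scale-invariant bout-duration statistics, and a stochastic
priority-queuing model of behavioral organization. The package is aimed at
behavioral chronobiologists and computational neuroscientists who work with
continuous activity recordings (e.g. piezoelectric cage sensors in mice)
and want objective, reproducible measures of rhythmicity and
intermittency.

## What it computes

**Activity extraction.** A raw sensor signal is converted to an activity
series by windowed linear detrending and local (population) variance;
records are normalized by their mean ("nVar") and thresholds are defined
as multiples of the mean non-zero activity level.

**Rhythms.** The Morlet continuous wavelet transform (ω₀ = 6, 16 voices
per octave) gives a unit-area spectral density over 10⁻⁵–10⁻² Hz. From it:
the circadian period *T*<sub>cir</sub> (dominant peak in 1.0–2.0 × 10⁻⁵
Hz; `NA` when the peak is extinct), band areas *A*<sub>cir</sub> and
*A*<sub>ult</sub> (2.0 × 10⁻⁵–1.1 × 10⁻⁴ Hz), and the ratio
*R* = *A*<sub>ult</sub>/*A*<sub>cir</sub>.

**Behavioral organization.** Resting bouts (activity continuously at or
below threshold) have mean-rescaled cumulative distributions following a
power law, *P*(≥ *x*) ∝ *x*<sup>−γ</sup>, fitted over *x* ∈ [0.2, 20];
active bouts follow a stretched exponential,
*P*(≥ *x*) = exp(−(*x*/*x*₀)<sup>β</sup>), fitted over [0.1, 10]. Both
fits use orthogonal distance regression with Levenberg–Marquardt
minimization and multi-start local-minimum selection. Lower γ = fatter
tail = more intermittent behavior. A threshold sweep (0.6–1.8 × the mean
non-zero level) checks robustness.

**Mechanistic model.** A priority queue of *L* = 10 demands, executing one
per step with probability ∝ *x*<sup>α</sup>, produces waiting times with
cumulative tail exponent 1/α: proportional choice (α = 1) matches the
observed resting-duration exponent near 1, preferential choice (α = 2)
the fatter tails of more intermittent phenotypes.

**Synthetic generator.** `generate_series()` produces telegraph-process
recordings with prescribed γ, β, circadian/ultradian structure, and a
ground-truth log, with presets (`wt`, `per2`, `clock`, `bmal1`) spanning
rhythmic, shifted-period, long-period and arrhythmic scenarios.

## Worked example

```r
library(locodyn)

## a 3-day synthetic recording at 0.1 s resolution, rhythmic scenario
ser <- generate_series(locomotor_preset("wt", dt = 0.1, seed = 42))

ds <- extract_durations(ser, multiplier = 1)
ds
#> <duration_sample> threshold 0.236 (m = 1)
#>   resting: n = 80402, mean <a_r> = 2.665 s
#>   active : n = 80403, mean <a_a> = 0.559 s

fit_power_law(rescaled_cumulative(ds$resting))
#> <powerlaw_fit> P(>=x) = 0.09673 * x^-0.9521   (chi2 = 0.00209, 40 pts on [0.2, 20])

fit_stretched_exp(rescaled_cumulative(ds$active))
#> <stretchexp_fit> P(>=x) = exp(-(x/0.5721)^0.5725)   (chi2 = 0.0387, 41 pts on [0.1, 10])
```

The recovered exponents (γ̂ = 0.952, β̂ = 0.573) sit on the generator's
true values (γ = 0.95, β = 0.59) to within estimator noise. The spectral
side of the pipeline, on a 60 s version of the same scenario:

```r
rs <- run_spectrum(list(wt = generate_series(locomotor_preset("wt", dt = 60, seed = 42))))
rs$individual
#>   id group  T_cir_h      A_cir      A_ult        R error
#> 1 wt   all 24.39239 0.02699005 0.04915036 1.821055  <NA>
```

The circadian period is recovered within one scale-grid step of the true
24 h. Finally the queue model in the proportional regime:

```r
wt <- simulate_queue(L = 10, alpha = 1, steps = 1e5, seed = 1)
fit_power_law(waiting_time_distribution(wt), range = c(2, 200))
#> <powerlaw_fit> P(>=x) = 1.981 * x^-1.0989   (chi2 = 0.0103, 199 pts on [2, 200])
```

a tail exponent near the analytic 1/α = 1.

Cohort-level runners (`run_spectrum()`, `run_behavior()`) take named lists
of series plus group labels and return per-individual tables, group
mean ± SEM summaries, threshold-sweep tables and standard ANOVA/post-hoc
comparisons.

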