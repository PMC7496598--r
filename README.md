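# hrbias

Autocorrelation-aware home-range estimation, and the allometry of the bias
you get when you ignore autocorrelation.

## The problem

Animal space requirements are usually quantified as a home range: a quantile
region (typically 95%) of a utilization density estimated from tracking
data. Conventional kernel density estimation (KDE) assumes independent
locations, but GPS tracks are autocorrelated: positional correlation decays
over the range-crossing time τ<sub>p</sub>, so the information content of a
track is not its n fixes but the effective sample size

> N<sub>area</sub> ≈ T / τ<sub>p</sub>,

the number of range crossings in a sampling span T. Because home-range area
H scales with body mass M as a power law H = B₀M<sup>b</sup>, and larger
ranges take longer to cross, τ<sub>p</sub> grows with mass faster than
tracking durations do — so N<sub>area</sub> *falls* with mass, and the
familiar negative bias of conventional KDE is systematically worse for
large-bodied species. Underestimated space needs are a worst case for
area-based conservation, and mass-dependent bias also distorts the scaling
exponent b itself (superlinear scaling, b > 1, can be flattened to look
linear).

`hrbias` implements the full machinery to quantify and correct this:

* **Movement models** — IID, Ornstein–Uhlenbeck (OU), and OU-foraging (OUF)
  continuous-time processes fitted by exact maximum likelihood (O(n)
  state-space filters), AICc selection, τ<sub>p</sub> and N<sub>area</sub>
  extraction, exact simulation.
* **Variogram screening** — empirical semivariograms and an automated
  range-residency check (asymptote test) that gates which tracks are
  eligible for home-range estimation at all.
* **Home ranges** — conventional KDE with Gaussian-reference bandwidth
  Σ̂·n<sup>−1/3</sup>, and autocorrelation-informed AKDE using
  N<sub>area</sub> in place of n, plus a small-sample bias correction;
  contour areas and point-inclusion queries on a density grid.
* **Block cross-validation** — half-sample splits at the temporal midpoint,
  a Bhattacharyya-distance comparability gate, held-out inclusion
  percentages, and the contour-ratio bias statistic.
* **Thinning** — model-informed thinning to independence (gap
  3τ<sub>p</sub> = τ<sub>p</sub>ln 20), residual lag-1 autocorrelation, and
  data-loss accounting.
* **Allometry** — Grafen branch lengths, Brownian phylogenetic covariance,
  phylogenetic GLS regression, intercept/linear/logistic bias-versus-mass
  model comparison under QAICc, superlinearity tests, and the `HRcorrect`
  factor 1/(1 − u(M)) for correcting conventional estimates.
* **Synthetic study generator** — a body-mass spectrum of species
  (0.4–4000 kg) with the generating laws above, tracks, covariates and a
  phylogeny, so the entire pipeline runs end to end with no external data.

## Worked example

Simulate two months of hourly fixes from an OU process with a 2-day
range-crossing time, fit and select a movement model, and compare
conventional and autocorrelation-informed home ranges:

```r
library(hrbias)
m  <- movement_model("OU", mu = c(0, 0), sigma = 4e6, tau_p = 2 * 86400)
tr <- simulate_track(m, seq(0, 60 * 86400, by = 3600), seed = 7, id = "demo")
fit <- fit_movement(tr)          # AICc selection among IID / OU / OUF
summary(fit)
#> OUF movement model (fitted)
#>   mean: (171.3, 175.1) m
#>   sigma: [3.647e+06, -2.616e+04; 3.695e+06] m^2
#>   tau_p: 1.752 days
#>   ...
#>   model selection (AICc):
#>     IID    51621.18 (delta 8856.62)
#>     OU     42764.80 (delta 0.24)
#>     OUF    42764.56 (delta 0.00)

effective_sample_size(fit, tr$schedule)
#> [1] 34.23992        # 1441 fixes are worth ~34 independent ones

hr_kde  <- kde(tr, correction = TRUE)
hr_akde <- akde(tr, fit, correction = TRUE)
area_at_quantile(hr_kde, 0.95)   #  64.97 km^2  (conventional)
area_at_quantile(hr_akde, 0.95)  #  90.16 km^2  (autocorrelation-informed)
pi * qchisq(0.95, 2) * 4e6 / 1e6 #  75.29 km^2  (truth)
```

Half-sample block cross-validation scores how well each estimate predicts
the animal's later locations — conventional KDE's 95% contour captures only
~90% of the held-out half, while AKDE is close to nominal:

```r
crossval_track(tr, quantiles = 0.95, seed = 1)
#>   method    q inclusion_pct bias_ratio   N_area gate
#> 1    KDE 0.95          89.5       1.56     16.0 pass
#> 2   AKDE 0.95          94.6       1.04     16.0 pass
```

The study-level driver runs the whole analysis (screening, fitting, three
estimators, cross-validation, thinning, species aggregation, phylogenetic
regressions) over a synthetic body-mass spectrum:

```r
res <- run_study(study_config(synth = synth_config(seed = 1), seed = 1))
summary(res)   # coverage medians, mass-band bias, allometric exponents
```

On the default 40-species × 3-individual spectrum this reproduces the
mechanism: conventional-KDE held-out inclusion declines with body mass
(median 84.5% at the 95% contour) while AKDE stays calibrated (median
95.9%); small species (<10 kg) are underestimated by ~16% on average and
large ones (>100 kg) by ~51%; and the fitted allometric exponent rises from
1.00 (KDE) to 1.12 (AKDE) — the generating value is 1.1.

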