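# spectac

Quantification of radiolabel clearance from injected myocardium in
dynamic SPECT studies, for researchers tracking In-111-labeled cells (or
free In-111-tropolone calibration injections) in the heart.

When label is injected intramyocardially, the decay-corrected signal
washes out biexponentially,

    f(t) = a·exp(−b·t) + c·exp(−d·t),      b > d > 0,  a + c = 100%,

where the short component (T½ˢ = ln2/b, ~0.25–4.4 h) is early mechanical
loss of injectate and the long component (T½ˡ = ln2/d, hundreds to
thousands of hours) is leakage of protein-bound label from viable tissue.
To read In-111 activity as a viability marker, a compartment model
separates label inside viable cells — lost at rate k_death + C, with C
the leakage coefficient — from interstitial label cleared by the debris
impulse response function (DIRF); the measured signal is the
intracellular term plus the convolution of the cellular efflux with the
DIRF, and inverting this model yields the viable-cell half-life with a
validity window (20 h to a 60- or 37-day preset) outside which the
estimate is flagged.

The package covers the full pipeline:

- `simulate_tac()`, `simulate_dynamic_spect()`,
  `simulate_wholebody_pair()`, `make_cohort()` — synthetic TACs, phantom
  image series with Poisson noise and In-111 decay, wholebody
  biodistribution scans, and whole cohorts, so everything is testable
  without scanner data
- `build_mask()`, `extract_tac()`, `decay_correct()` — ≥30%-of-max VOI
  masking frozen on the first frame, TAC extraction, decay correction
- `fit_biexponential()`, `half_life()`, `normalize_fractions()` —
  constrained washout fits with monoexponential fallback
- `forward_model()`, `invert_viability()`, `leakage_to_dirf_ratio()` —
  the convolution-based viability model
- `compute_hwb()`, `hwb_timeseries()` — heart:wholebody retention ratios
- `summarize_group()`, `mann_whitney()`, `bonferroni()`,
  `build_report()` — mean ± SEM summaries, exact nonparametric
  comparisons, and the assembled cohort report
- `canine_fit_table()`, `canine_hwb_table()` — the packaged reference
  tables from a 19-injection canine study (9 epicardial, 10 endocardial)

## Worked example

Simulate a noisy injection TAC from the first epicardial reference
subject's parameters, refit it, and estimate the viable-cell half-life:

```r
library(spectac)

p <- clearance_params(a = 37.9, b = 0.3712, c = 62.1, d = 0.0012930)
x <- simulate_tac(p, acquisition_schedule(), noise = "poisson",
                  peak_counts = 1e4, seed = 42)
f <- fit_biexponential(decay_correct(x), weights = "poisson")
f
#> Biexponential fit: a%=37.1 b=0.4099/h c%=62.9 d=0.001182/h
#>   T1/2 short = 1.69 h, T1/2 long = 586 h (rss 0.0581)

inv <- invert_viability(decay_correct(x), C = log(2) / 1434,
                        dirf_half_life = 18)
sprintf("viability T1/2 = %.0f h, valid = %s",
        inv$viability_half_life, inv$valid)
#> "viability T1/2 = 469 h, valid = TRUE"
```

The fit recovers the generating fractions (37.1% vs 37.9% short) and
rates within the counting noise; the long half-life estimate (586 h vs
the true 536 h) carries the expected uncertainty of three weekly late
points at ~10² counts. The inversion then attributes the long-component
washout to cell death after removing the leakage (C) and interstitial
(DIRF) contributions, and the estimate falls inside the 20 h–60 d
validity window.

Group summaries reproduce the reference study's reported values from the
packaged table:

```r
fits <- canine_fit_table()
summarize_group(half_life(fits$d_per_hour[fits$group == "endocardial"]),
                "endocardial", "T1/2 long")
#> endocardial T1/2 long: 1567 +/- 470.2 (n = 10, mean +/- SEM)
```

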