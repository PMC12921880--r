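# dcfbiodeg

Quantitative analysis of bench-scale pharmaceutical biodegradation
experiments, with diclofenac (DCF) as the reference compound. The package
takes the tabular outputs such experiments produce — concentration time
series, growth-inhibition dose ladders, bioluminescence dilution series,
metabolite time courses and amplicon (ASV) count tables — and turns them
into the quantities a biodegradation study reports:

- **Degradation kinetics.** Simple First-Order (SFO) decay
  `M_t = M0·e^(−kt)` and the biphasic Hockey-Stick (HS) model (fast rate
  `k1` until a breakpoint `tb`, slower rate `k2` after), fitted by bounded
  multi-start least squares; half-lives `DT50 = ln 2 / k` (SFO) or
  `tb + (ln 2 − k1·tb)/k2` (HS, slow branch); FOCUS-style χ² error
  assessment (the minimum measurement-error percentage at which a χ² test
  on scaled residuals passes at α = 0.05) and model selection by scaled
  error.
- **Growth inhibition IC50.** Viability (`100·OD600_treated/OD600_control`)
  regressed on log10 dose with a second-order polynomial
  `y = a·u² + b·u + c`, inverted at y = 50; out-of-range solutions are
  flagged as extrapolated.
- **Ecotoxicity (Microtox-style).** Luminescence inhibition after 15 min
  contact, gamma = lost/remaining light, EC50 (% v/v) from the
  log10(gamma) ~ log10(dilution) regression, Toxic Units `TU = 100/EC50`,
  and Persoone hazard classification.
- **Metabolite time courses.** First detection, peak, final residue and
  persistence for quantified (µg/L, with LOQ) and peak-area-only analytes.
- **Community shifts.** Seeded rarefaction, alpha diversity (richness,
  Shannon, inverse Simpson), genus-level composition with an NA category
  and display threshold, and Venn-style ASV overlap between paired
  before/after samples.
- **Synthetic data.** Seeded generators emulating each assay's design
  (the 9-point sampling schedule, the 10–5000 mg/L dose ladder, the 1:2
  dilution series, a dominance-shift ASV scenario), so every stage of the
  pipeline can be exercised and validated without laboratory data.

All user-facing functions take a data frame first and return tibbles;
fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(dcfbiodeg)

# A noisy biphasic degradation series on the standard sampling schedule
ser <- gen_degradation(model = "hs", sd = 0.2, seed = 42)
best <- select_model(fit_kinetics(ser))
best
#> <kinetic_fit> HS model
#>   parameters:  m0_hat = 10.27, k1_hat = 1.143, k2_hat = 0, tb_hat = 0.9264
#>   DT50 = 0.6066 days
#>   SSR = 0.1142, R2 = 0.9972, chi2 = 0.244 (err 15%), scaled error = 2.23%
```

The selected model is the hockey-stick: an initial fast phase
(`k1 ≈ 1.14 d⁻¹`, close to the generating 1.05 d⁻¹) up to a breakpoint
near 0.93 d, then essentially no further decay. The half-life of 0.61 d is
reached within the fast phase, and the scaled error of 2.2% means the fit
would pass the χ² test even if measurements were only good to ±2.2%.

```r
# Triplicate Microtox-style assay
microtox(gen_microtox(ec50_true = 15.2, cv = 0.05, replicates = 3, seed = 42))
#> # A tibble: 1 × 6
#>   ec50_mean ec50_sd tu_mean tu_sd hazard_class   n_replicates
#>       <dbl>   <dbl>   <dbl> <dbl> <chr>                 <int>
#> 1      15.6     0.2     6.4   0.1 acute toxicity            3
```

An EC50 of ~15.6% v/v (sample dilution halving the light output) converts
to ~6.4 toxic units — "acute toxicity" on the Persoone scale.

```r
# Dose-response IC50
fit_quadratic_logdose(gen_dose_response(sd = 5, seed = 42))
#> <quad_dose_fit> viability = a*log(C)^2 + b*log(C) + c
#>   a = -5.874, b = -3.059, c = 103.4 (log base 10), R2 = 0.9833
#>   IC50 = 584.4 mg/L [ok]

# Community shift: before/after ASV tables with a dominance sweep
tabs <- gen_asv_tables(seed = 42)
alpha_diversity(tabs$counts)
#> # A tibble: 2 × 4
#>   sample_id richness shannon inv_simpson
#>   <chr>        <dbl>   <dbl>       <dbl>
#> 1 before         111    4.57        84.5
#> 2 after           59    2.95        14.5
```

Richness collapses from 111 to 59 ASVs while one genus sweeps to ~89% of
the community — the signature of strong selective pressure during the
incubation.

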