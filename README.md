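# ftirfg

Functional-group quantification of aerosol deposits on PTFE filters from
transmission-mode mid-infrared (FTIR) spectra.

Household fuel burning is a major source of fine-particle (PM2.5)
exposure. Thermal–optical carbon analysis of such emissions is slow and
destructive; FTIR scans of the same gravimetric filters take minutes, are
non-destructive, and resolve the *organic functional groups* — aliphatic
CH, aromatic CH, alcohol COH, carboxylic acid, non-acid carbonyl — that
make up the organic matter. `ftirfg` implements the full post-processing
chain for such spectra, for laboratory and exposure scientists who have
sample and blank filter scans plus per-test metadata:

1. **Baseline correction** by penalized smoothing splines fitted to
   absorption-free anchor windows; the 4000 cm⁻¹ baseline value is kept as
   an elemental-carbon (EC) diagnostic.
2. **Blank subtraction**: a scaled, baseline-corrected blank — matched by
   PTFE peak intensity near 1150 cm⁻¹ — removes the membrane bands; the
   scale *s* ≥ 0 minimises the squared residual over 1300–1000 cm⁻¹.
3. **Multi-peak fitting**: bounded nonlinear least squares of Gaussian
   bands plus a local residual-baseline term, per spectral region.
4. **Beer–Lambert calibration**: band response = ε · (mol of bond); the
   aromatic CH out-of-plane (OOP) band at 750 cm⁻¹ is calibrated on
   anthracene (C₁₄H₁₀) standards by peak *height* (default ε = 0.017 AU
   per µmol CH).
5. **Composition**: OC = Σ mᵍ·(C per bond)·12.011, OM = Σ mᵍ·(OM mass per
   bond), OM/OC, a PAH mass estimate from the OOP band assuming C/H = 1.4
   (anthracene-like), back-filter artifact correction, and emission
   factors in mg per MJ of energy delivered.
6. **Chemometrics**: NIPALS PLS1 of reference scalars (thermal–optical OC,
   GC–MS PAH sums) on the spectra matrix, with variable-importance-in-
   projection (VIP) scores, VIPⱼ = √(p·Σₐ SSYₐ (w_{aj}/‖wₐ‖)² / Σₐ SSYₐ),
   to attribute influential group frequencies.

A forward-model synthetic generator (`generate_study()`) emulates
EC-dependent baselines, PTFE interference, fuel-archetype band patterns
(red oak, kerosene, charcoal, alcohol, LPG) and collocated pseudo-reference
tables with controllable bias and noise, so the entire chain is testable
without laboratory data.

## Worked example

```r
library(ftirfg)

# a synthetic study: 12 samples, mixed fuels, default noise conditions
study <- generate_study(12, seed = 421, n_blanks = 3)
res   <- run_study(study)

res$oc_regression
#> # A tibble: 1 × 3
#>   slope r_squared     n
#>   <dbl>     <dbl> <int>
#> 1 0.602     0.877    12

dplyr::select(res$composition, id, fuel, oc, om, om_oc, pah_mass, ef_om)[1:5, ]
#> # A tibble: 5 × 7
#>   id    fuel        oc    om om_oc pah_mass ef_om
#>   <chr> <chr>    <dbl> <dbl> <dbl>    <dbl> <dbl>
#> 1 S001  charcoal  38.1  65.4  1.71     8.50 12.0
#> 2 S002  red_oak   27.1  42.8  1.58    11.2  10.6
#> 3 S003  charcoal  39.8  55.4  1.39    17.5   2.44
#> 4 S004  red_oak   28.2  53.1  1.88     8.57 22.1
#> 5 S005  kerosene  23.0  39.4  1.71    12.0   1.54
```

`oc` and `om` are µg on the filter; `om_oc` is their ratio; `pah_mass` is
the OOP-band aromatic/PAH estimate (µg); `ef_om` is the OM emission factor
in mg MJ⁻¹. The OC regression slope of 0.602 says functional-group OC
recovers ~60 % of the (synthetic) thermal–optical reference — the
generator's default unmeasured-carbon excess — with R² = 0.88 at the
default reference noise.

```r
res$pah_comparison
#> # A tibble: 1 × 4
#>   slope r_squared ratio_of_totals     n
#>   <dbl>     <dbl>           <dbl> <int>
#> 1  20.3     0.973            21.8     7
```

The infrared PAH estimate sits about twenty-fold above the summed GC–MS
panel — the OOP band responds to all aromatic CH, not only the targeted
compounds — while correlating tightly with it.

```r
cal <- build_calibration(generate_standards(n = 12, rel_noise = 0.12, seed = 42),
                         response_kind = "height")
cal
#> <ftir_calibration> rCH_oop_750 (height): absorptivity 0.01858 per umol
#> (R^2 = 0.985, n = 12, through origin)
```

Fitted objects have `tidy()`/`glance()` methods and `autoplot()` plots
(spectra, calibrations, VIP score traces). A thin command-line wrapper is
installed as `exec/ftirfg` (`ftirfg simulate ...`, `ftirfg run ...`).

## The methods vignette

`vignettes/methods.Rmd` documents the model and its assumptions, the
numerical design (anchor windows, spline stiffness cap, the quadratic
residual-baseline term, the optimizer, the doublet-based acid-OH route),
what the synthetic generator does and does not emulate, and known
limitations.
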