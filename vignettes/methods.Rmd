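---
title: "Quantifying functional groups in filter-deposit infrared spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying functional groups in filter-deposit infrared spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirfg)
```

## The measurement problem

Fine particles collected on PTFE membrane filters can be scanned by
transmission-mode mid-infrared spectroscopy in minutes, non-destructively.
The absorbance spectrum $A(\tilde\nu)$ over 4000–400 cm$^{-1}$ superimposes
three contributions:

* a smooth **baseline** from light scattering by the membrane and the
  particles, plus the broad electronic-transition absorption of elemental
  carbon (EC), which rises toward high wavenumber;
* strong **PTFE membrane bands** concentrated in 1300–1000 cm$^{-1}$;
* the **vibrational bands of organic functional groups** (FGs) in the
  deposit — aliphatic CH (aCH), aromatic CH (rCH), alcohol COH (aCOH),
  carboxylic acid (COOH), non-acid carbonyl (naCO), and minor bands
  (aromatic ring C=C, lignin ring stretch, inorganic nitrate).

`ftirfg` separates these contributions, converts band responses to moles of
bond via Beer–Lambert calibrations, and aggregates bond moles into organic
carbon (OC), organic matter (OM), OM/OC, an aromatic/PAH mass estimate and
per-megajoule emission factors. A partial least squares module attributes
scalar reference measurements (thermal–optical OC, GC–MS PAH sums) to the
spectral regions that drive them.

All spectra live on a canonical descending grid, 4000 to 400 cm$^{-1}$ at
4 cm$^{-1}$ spacing (901 points), matching acquisition at 4 cm$^{-1}$
resolution; readers resample onto it by linear interpolation, never
extrapolating.

## Baseline correction

`fit_baseline()` fits a penalized cubic smoothing spline to the spectrum
restricted to *anchor windows* — regions free of organic absorption — and
evaluates it over the whole grid. The default windows are 4000–3750,
2750–2500, 1900–1800, 980–900 and 680–620 cm$^{-1}$; they avoid every band
in the default band table. When the dimerised carboxylic-acid OH signature
is present (screened by `detect_acid_signature()`, which requires *both*
2600 and 2400 cm$^{-1}$ doublets to stand above their flanking levels by
three times the noise), the 2750–2500 cm$^{-1}$ window sits on the broad
acid OH and is dropped.

Two numerical choices matter:

* **Penalty selection.** `smoothing = "auto"` uses generalized
  cross-validation, but when the anchors are several disjoint windows the
  effective degrees of freedom are capped at $2 n_\mathrm{windows} + 2$. A
  near-interpolating spline translates any small trend at a window edge
  (for instance the far tail of the 3500 cm$^{-1}$ band touching the
  4000–3750 window) into a several-fold larger overshoot across the
  unanchored gap; the cap keeps the baseline stiff between anchors, and
  the residual smooth error is absorbed downstream (next section). With a
  single contiguous anchor region GCV is left alone, so a smooth
  anchor-only signal is reproduced essentially exactly.
* **The 4000 cm$^{-1}$ baseline value** is recorded per sample. Because EC
  absorbs via electronic transitions, this value carries EC information;
  `ec_baseline_regression()` fits `baseline_at_4000 ~ EC + OC` by ordinary
  least squares as a diagnostic (not a calibrated EC estimator).

Negative absorbances after correction are preserved — clipping would bias
every subsequent least-squares fit — and the fraction of negative points is
reported as a quality flag.

## Blank subtraction

Each baseline-corrected sample is paired with the library blank whose PTFE
reference peak (maximum over 1200–1100 cm$^{-1}$) is closest in height;
ties break to the lexicographically smallest blank id. The blank scale $s$
minimises the squared residual over the full PTFE window 1300–1000
cm$^{-1}$, constrained $s \ge 0$; using the whole window exploits all PTFE
band structure and is more noise-robust than a single peak-height ratio,
which is retained as a diagnostic. The PTFE window is excluded from all
downstream functional-group reporting and from the PLSR spectra matrix.

## Multi-peak fitting

`fit_window()` fits a sum of Gaussians plus a *local quadratic
residual-baseline* term by bounded nonlinear least squares. Band centers
are constrained to $\pm 10$ cm$^{-1}$ of their nominal positions
($\pm 15$–$20$ for the carbonyl and the broad OH bands), widths to
per-band-class intervals, and amplitudes to be non-negative. The reported
area is $a\,\sigma\sqrt{2\pi}$ exactly; the out-of-plane (OOP) aromatic CH
band at 750 cm$^{-1}$ reports fitted peak *height*, matching its
calibration, while all other bands report area.

Numerical design, in the order the problems were encountered:

* The residual-baseline polynomial is **quadratic**, not linear: the
  smooth error the global spline leaves between anchor windows is curved,
  and a linear term leaves a systematic 0.3–1.6 % bias in recovered OC on
  noiseless synthetic samples; the quadratic reduces it below 0.1 % for
  most samples. Its coefficients are capped at $0.02 + 0.05 \max|A|$ so
  the polynomial cannot trade against genuinely broad bands, and they are
  reported for QC.
* The optimizer is **L-BFGS-B with an analytic gradient, polished by
  Levenberg–Marquardt**. Bound clamping can stall the LM path with
  parameters jammed at their bounds; L-BFGS-B handles the box constraints
  properly and LM then sharpens the optimum and provides standard errors.
  Two starts are tried (residual baseline at the lower decile of the
  window, and at zero) and the lower-deviance solution kept.
* Fitting proceeds region by region — 3700–3100, 3100–2300, 1850–1350,
  900–650 cm$^{-1}$ — with the CH/acid region first. The fitted broad acid
  OH Gaussian is subtracted from the other regions before they are fitted
  because its tail reaches into the 3700–3100 cm$^{-1}$ window. The
  CH/acid region extends to 2300 cm$^{-1}$ so the 2400 cm$^{-1}$ doublet
  has support on both flanks.
* Non-convergence is flagged on the result, never thrown, so one refractory
  sample cannot abort a study.

## Calibration and the acid-OH route

`build_calibration()` fits a through-origin line (a blank filter carries no
analyte) of band response on moles of bond; the slope is the empirical
absorptivity under the package normalization (response per µmol of bond on
the filter; the printed unit convention of height-based absorptivities is
treated as an empirical response-per-mole constant rather than resolved
dimensionally). Weighted least squares with $1/x^2$ weights is the default
because deposit standards span decades of loading and their response errors
are predominantly multiplicative; unweighted OLS, dominated by the heaviest
standards, is available as an option. The anthracene route for the OOP
band is: areal loading × deposit area ÷ M(C$_{14}$H$_{10}$) × 10 CH bonds
per molecule (`anthracene_ch_umol()`), giving the shipped default
absorptivity of 0.017 AU per µmol CH. The other groups ship configurable
placeholder absorptivities with provenance noted in the table; they are
meant to be replaced by laboratory values.

One identifiability decision: the carboxylic acid OH is **quantified from
the sharp dimer doublets at 2600 and 2400 cm$^{-1}$, not from the broad
3400–2400 cm$^{-1}$ envelope**. Over a single fit window a Gaussian with
$\sigma \sim 200$ cm$^{-1}$ is nearly collinear with the local
residual-baseline polynomial: on noiseless synthetic data its fitted area
moved by 30–40 % between equivalent-residual solutions while the doublet
areas were stable to better than 0.1 %. The broad envelope is still fitted
(and tail-subtracted) but not used as the quantifier.

## Composition

The attribution table converts moles of bond to carbon and OM mass with
minimal structural assumptions: aCH as methylene (0.5 C, 7.014 g per mol
bond), rCH with an effective C/H of 1.4 (anthracene-like, 17.823 g),
aCOH/COOH/naCO each one carbon plus their O/H payloads (29.018, 45.017,
28.010 g). Every row satisfies `om_mass > 12.011 × carbon`, which makes
OM ≥ OC a theorem for any non-negative abundance vector; outputs record a
hash of the table in force. Total fitted carbonyl is split by
`apportion_carbonyl()`: the acid OH abundance caps the carboxylic share
(`cooh = min(carbonyl, acid_oh)`), conserving carbonyl moles.

PAH mass is `umol(rCH) × (1.008 + 1.4 × 12.011)` µg; the 1.4 is
anthracene's own C/H molar ratio and is deliberately conservative. Back-
filter artifact corrections keep negative results (flagged); emission
factors scale the deposit by `tunnel_flow / sample_flow` (unit conversion
internal) and divide by the energy delivered to the pot, in mg MJ$^{-1}$.

## PLSR and VIP

`fit_plsr()` is a mean-centred NIPALS PLS1. X is *not* variance-scaled:
absorbance magnitudes are physically meaningful and unit-scaling would
inflate noise-only wavenumbers. `n_components = "cv"` selects the count by
5-fold cross-validation (fold assignment from an explicit recorded seed)
with a one-standard-error parsimony rule. VIP scores follow
$\mathrm{VIP}_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}$,
so $\sum_j \mathrm{VIP}_j^2 = p$ identically; wavenumbers above the
conventional threshold 1 are merged into contiguous influential intervals
and annotated with overlapping band names by `band_report()`. With as many
components as the rank of X, the NIPALS predictions coincide with ordinary
least squares, which the tests use as an independent oracle.

## The synthetic-data generator

`generate_study()` is first-class, tested code that forward-models every
structure the analysis must invert:

$$A(\tilde\nu) = \underbrace{b_0 + b_1 u + b_2 u^2 +
(\alpha_{EC}\,EC + \alpha_{OC}\,OC_{tot})(0.4 + 0.6u)}_{\text{baseline},\;
u = \tilde\nu/4000} \; + \; s\,\mathrm{PTFE}(\tilde\nu) \; + \;
\sum_g m_g\,\varepsilon_g\,\phi_g(\tilde\nu) \; + \; \epsilon$$

with $\alpha_{EC} = 2.2\,\alpha_{OC}$ (so the EC-baseline diagnostic has a
known recoverable answer), a fixed PTFE band cluster confined to 1300–1000
cm$^{-1}$ with lognormal intensity, Gaussian FG bands using the same
absorptivity constants the quantification applies, and white noise.
Abundances are lognormal — positive and right-skewed, as emission-factor
distributions are. Fuel archetypes encode the qualitative band patterns of
combustion aerosol: red oak dominated by alcohol OH with lignin and
occasional nitrate bands; kerosene dominated by aromatic CH with a frequent
dimerised-acid signature; charcoal with strong aliphatic CH and high,
variable EC (set so its EC/TC ratio centres near 0.58); alcohol and LPG at
near-blank level. The default mix draws fuels in proportion 69 : 56 : 21 :
3 : 3 (red oak : charcoal : kerosene : alcohol : LPG).

Because functional-group analysis sees only part of the organic carbon
(uncharacterised groups, skeletal carbon), each sample carries
`oc_total = oc × (1 + oc_excess)` with `oc_excess = 0.67` by default; the
baseline and the pseudo-thermal-optical reference OC are tied to the
total, so the default-condition study reproduces the structure of a
collocated comparison in which FG OC recovers roughly 60 % of reference
OC. The pseudo-GC–MS PAH sum is the infrared PAH mass divided by 19.6 (a
targeted compound panel captures a small fraction of total aromatic mass),
restricted to kerosene and red-oak samples. Reference noise defaults are
15 % (OC), 10 % (EC) and 15 % (PAH), relative lognormal; spectral noise
defaults to 0.002 AU, about 2 % of a typical maximum band height.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: non-Gaussian line shapes and band asymmetry,
instrument line-shape and apodization effects, water vapour and CO$_2$
interference, filter-to-filter PTFE band-shape variation (the template is
shared, which is why blank scaling recovers exactly), levoglucosan and
other fine structure, and real covariance between groups within a source.
Recovery results on the generator are therefore a *consistency* check of
the inversion chain, not a validation of the spectroscopy.

## Problem sizes and determinism

The test suite and the acceptance script use studies of 20–60 samples with
a 6-blank library, 12-standard calibrations, and 1000-draw property checks;
a 60-sample study runs in well under a minute on one CPU. Every stochastic
step takes an explicit integer seed (samples derive per-sample seeds from
the study seed), and identical seeds give bit-identical datasets, so
re-running a pipeline with its archived config reproduces its outputs
exactly.

## Known limitations

* The broad acid-OH envelope is intrinsically hard to separate from
  baseline curvature; its fitted area should be treated as qualitative.
* The aCH/aCOH/carbonyl absorptivities shipped are placeholders; OC and
  OM/OC from real spectra are only as good as the calibration table
  supplied.
* EC is an external (thermal–optical) input; the baseline regression is a
  diagnostic, not an EC estimator.
* The carbonyl apportionment rule is a hard cap, not a fitted model; it is
  exact only when acid OH is measured without error.
* Gaussian profiles only; Lorentzian/Voigt shapes are out of scope.
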