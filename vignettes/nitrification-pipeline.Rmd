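---
title: "Methods: from raw isotope readings to seasonal drivers of ammonia oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw isotope readings to seasonal drivers of ammonia oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrifyr)
```

`nitrifyr` computes in-situ ammonia-oxidation (AO) rates from single
end-point ¹⁵N-NH₄⁺ tracer incubations and everything that surrounds them in
a seasonal lake campaign. This vignette is the package's own account of the
models it implements, the assumptions they carry, the numerical choices
made where the design was genuinely open, and what the synthetic generator
does and does not establish about real data.

## The tracer model

An incubation bottle holds an NH₄⁺ pool of which a fraction
`α = spike / (spike + ambient)` is ¹⁵N-labelled, and an NO₂⁻ pool of
`NO₂⁻(i)` µmol L⁻¹ (ambient plus a 0.25 µmol L⁻¹ unlabelled carrier, which
enlarges the receiving pool so the new ¹⁵NO₂⁻ is measurable and dilution by
consumption matters less). Ammonia oxidation transfers N from the NH₄⁺ pool
into NO₂⁻ at the unknown rate `r`; a fraction `α` of the transferred atoms
are ¹⁵N, so over an incubation of `t` days the atom-fraction excess of the
NO₂⁻ pool grows by `r·t·α / NO₂⁻(i)`. The azide method then converts NO₂⁻
to N₂O for isotope-ratio analysis, pairing each NO₂⁻-derived N atom with an
unenriched azide N atom: the enrichment measured on N₂O is half that of the
nitrite, which is the single factor 2 in the rate equation

```
r = 2 · [n¹⁵(f) − n¹⁵(i)] · NO₂⁻(i) / (t · α)
```

with `n¹⁵` the atom fraction on the N₂O measurement scale.

Assumptions inherited from the field protocol, and kept here:

* `α` is constant over the 3–4 h incubation (no NH₄⁺ regeneration
  correction);
* the **initial** NO₂⁻ concentration is used, because NO₂⁻ often declines
  during incubations, and NO₂⁻ consumers are taken to be isotope-neutral on
  the δ¹⁵N scale;
* ¹⁵N passed on to NO₃⁻ by nitrite oxidation is ignored, which biases rates
  low;
* a negative raw estimate means the nitrite pool ended isotopically lighter
  than it started — analytically indistinguishable from zero activity — and
  is reported as a non-detect with `rate = 0`. Zero itself is a valid
  detected rate. Detection is purely sign-based; the instrument detection
  limit (~2 nmol N per aliquot) is documented but not enforced, mirroring
  the protocol.

All isotope arithmetic runs on the atom-fraction scale (`R_air = 0.0036765`
for ¹⁵N/¹⁴N of atmospheric N₂), converting from δ¹⁵N once on input; the
δ↔atom-fraction maps are exact inverses, so unit bookkeeping cannot drift.

### Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| spike design | µmol L⁻¹ | 5% of ambient, floor 0.05 | keeps the tracer a small perturbation; the floor engages below 1 µmol L⁻¹ ambient |
| over-spike flag | spike/ambient | 0.15 | additions above 15% of ambient may stimulate AO |
| carrier | µmol L⁻¹ | 0.25 | enlarges the NO₂⁻ receiving pool |
| incubation | h | 3–4 (validated ≤ 24) | short enough that regeneration is minor |
| δ¹⁵N precision | ‰ (1σ) | 6.8 | stated replicate reproducibility |
| NH₄⁺, NO₂⁻ precision | µmol L⁻¹ (1σ) | 0.2, 0.06 | stated spectrophotometric precision |

Uncertainty is propagated by seeded Monte Carlo (default 1000 draws):
independent Gaussian perturbations of every bottle δ¹⁵N and of the NH₄⁺ and
NO₂⁻ concentrations, truncated at their physical bounds, re-evaluated
through the full equation. The reported SD is that of the *raw* (signed)
rate: clipping non-detects to zero inside the Monte Carlo would understate
the uncertainty of estimates near the detection boundary.

### Calibration

Runs are calibrated against four internal NO₂⁻ standards (δ¹⁵N −76.9,
−35.6, 1.7, 36.7‰) by OLS of known on measured. With two standards the fit
is exact and the residual SD is reported as zero; with three or more the
residual SD uses n−2 degrees of freedom. Calibration is applied on the δ
scale before conversion to atom fractions; duplicate bottles are averaged
on the atom-fraction scale after calibration, and per-bottle values remain
available to the Monte Carlo.

## Dissolved N₂O from headspace equilibration

A 1.12 L bottle is filled with lake water, 0.12 L is replaced with ambient
air, and the bottle is shaken to equilibrium. Writing the mass balance over
the sealed bottle (dissolved-in + introduced-air N₂O = dissolved-at-
equilibrium + headspace N₂O) and solving for the unknown initial
concentration gives

```
C_water = K₀(T_eq)·x_hs·P + (x_hs − x_air)·P·V_h / (R·T_eq·V_w)
```

Choices: the Weiss–Price (1980) N₂O solubility function at salinity 0; an
ideal-gas headspace with `R = 0.08206 L atm mol⁻¹ K⁻¹`; dry-air mixing
ratios without water-vapour correction (the stated precision does not
warrant one). Every solved record can be re-checked by the forward balance
(`n2o_balance_residual()`), which closes to rounding error by construction.

The saturation deviation is `ΔN₂O = C_water − C_eq` with
`C_eq = K₀(T_insitu)·x_air·P`. Under ice the lake cannot exchange with the
atmosphere, so all under-ice samples of a winter reuse the `C_eq` of that
winter's first under-ice sample; a winter's first sample necessarily uses
itself and is flagged along with the rest. ΔN₂O is reported both in
nmol L⁻¹ and as a ppm-equivalent mixing-ratio deviation
(`ΔN₂O / (K₀(T_insitu)·P)`), because field reports commonly print the
latter; neither convention is guessed to be "the" intended one. Replicate
vials are averaged on the mixing-ratio scale before solving.

## Chlorophyll a

The monochromatic (Lorenzen) acidification form:
`26.7 · [(A665 − A750)_before − (A665 − A750)_after] · v_extract /
(v_filtered · path)`, in µg L⁻¹ with `v_extract` in mL, `v_filtered` in L
and the cuvette path in cm. The 750 nm reading removes turbidity and
cancels exactly when unchanged by acidification. Extract volume and path
length are required inputs rather than assumed constants. Negative results
are clipped to zero with a flag. Phaeopigments are not reported.

## Drivers analysis

* **Seasonal contrasts**: Kruskal–Wallis omnibus, then pairwise Dunn tests
  (large-sample z on mean ranks with tie correction) with Holm adjustment,
  summarised as a compact letter display (insert-and-absorb).
* **Depth and diel contrasts**: classical paired *t*. Identical pairs
  return `t = 0, p = 1`; a constant non-zero difference has zero variance
  and is refused rather than reported as infinite evidence.
* **Forward-selection regression**: greedy entry by smallest partial-F
  p-value, threshold 0.05 (the selection criterion is a package decision;
  nothing in the protocol fixes it). Covariates are standardised
  internally; right-skewed covariates (moment skewness > 1) are first
  transformed by `log10(x + m/2)` with `m` the smallest positive value, and
  the transformation applied to each column is recorded in the output.
  Which variables "should" be transformed is undocumented upstream, so the
  rule is deterministic and reported rather than inferred.
* **Univariate regression tree**: CART with the anova rule via `rpart`
  (numeric splits at midpoints between sorted unique values, factor splits
  over level subsets), minimum leaf size 3, cost-complexity pruning to the
  size with the lowest seeded 10-fold cross-validation error. The *global*
  CV minimum is used, not the 1-SE rule, matching the "lowest
  cross-validation error" selection. Tree R² is computed on the training
  response; the CV error curve is kept in the result for inspection.
* **Pearson correlation** for the rate–(NO₃⁻+NO₂⁻) association, which is
  deliberately excluded from the regression covariates (it is the product
  of nitrification, not a candidate driver).

## The synthetic generator

The generator exists so that every stage of the pipeline is verifiable
against planted truths; it is statistical, not a process-based lake model.

`simulate_incubation()` inverts the tracer model exactly when all biases
and noise are off (round-trip error below 10⁻⁹ relative), and implements
the two methodological caveats as switches:

* **regeneration** adds unlabelled NH₄⁺ at a constant rate ρ with
  instantaneous mixing, so `α(t) = spike/(N₀ + ρt)`; the label transfer
  integral has the closed form `(spike/ρ)·log(1 + ρt/N₀)`, and the
  single-α estimator is biased low, monotonically in ρ;
* **over-spike stimulation** multiplies the realised rate by
  `1 + s·spike/ambient`, biasing estimates high, monotonically in `s`;
* first-order NO₂⁻ consumption (isotope-neutral on δ¹⁵N; the fractionation
  itself is not modelled) shrinks the receiving pool — with consumption
  active the transfer integral is evaluated by quadrature instead of the
  closed form.

`simulate_year()` draws a 13-month campaign: `n_dates` dates × two depths
(10% and 1% surface light) × day/night, 48 samples at the default 12 dates.
The seasonal skeleton is: ice cover Dec 10–Apr 13 (winter); spring from
ice-out to the end of May (stratification onset); summer June–September;
autumn from October to ice-on. NH₄⁺ means are 2.8 (winter), 2.0 (spring),
0.4 (summer) and 1.5 (autumn, overturn entrainment) µmol L⁻¹; NO₃⁻+NO₂⁻
ramps under ice to a 3.3 µmol L⁻¹ peak shortly after ice-out and declines
through summer; chlorophyll a is 0.4 µg L⁻¹ under ice versus 4.0 in summer;
the ppm-equivalent N₂O saturation deviation builds from 0.02 to 0.12 under
ice and hovers near zero in open water, clamped to [−0.06, 0.12]. Within-
season SDs (NH₄⁺ 0.3, rate 40, chl a 0.3) are free parameters chosen as
plausible field scatter — no upstream source states them. The AO–NH₄⁺ link
is offered in two monotone forms: Michaelis–Menten-like saturation
(default, `r_max = 350`, `K_m = 1.5`) and a step at 2.6 µmol L⁻¹ between 50
and 230 nmol L⁻¹ d⁻¹; the step form is the one with a planted change point
and is what the tree-recovery checks use. Under-ice night samples are
generated even though a field campaign would sample only by day under ice:
light is zero under ice either way, and the balanced design keeps paired
contrasts simple.

What passing these checks shows — and does not. The generator draws
independent Gaussians around seasonal means; real campaigns have serial
correlation between monthly visits, depth-coupled profiles, non-Gaussian
rate scatter and missing visits (thin-ice months). Recovery of planted
structure here demonstrates that the estimators are implemented correctly
and behave as documented under realistic magnitudes, not that they would
achieve the same power on any particular field dataset.

## Numerical notes and degenerate inputs

* δ¹⁵N below −1000‰, atom fractions outside [0, 1), non-positive NO₂⁻ or
  incubation times outside (0, 24] h are rejected with specific errors.
* Monte-Carlo perturbations truncate at physical bounds (δ ≥ −1000‰,
  NH₄⁺ ≥ 0, NO₂⁻ > 0).
* A headspace record whose mass balance solves negative (headspace reading
  below what the introduced air alone would give) is refused with the
  offending record index.
* Constant responses give single-leaf trees; all-tied group data and
  zero-variance correlations are refused; collinear regression candidates
  are skipped with a warning.
* Fixture bundles from `make_fixture_suite()` are byte-identical for
  identical seeds; every stochastic function takes an explicit seed.

## Problem sizes

The verification suite uses the sizes at which the checks are sharp but
quick: 1000 random configurations for the rate-equation oracle, 100 seeded
replicates for bias directions, parameter recovery and the drivers-recovery
rates (n = 48 per replicate), and 200 random records for the headspace
forward balance. The full suite runs in about half a minute;
`scripts/acceptance.R` regenerates the headline numbers in well under a
minute.

## Known limitations

* Rates are single end-point estimates; no time-course fitting.
* No NH₄⁺-regeneration correction is applied to estimates (only simulated),
  matching the protocol's stated choice.
* No air–water gas flux, no denitrification source attribution for N₂O.
* The ppm units of ΔN₂O are reported alongside nmol L⁻¹ precisely because
  the field convention is ambiguous.
* The seasonal generator's covariances are independent by construction;
  do not use it to benchmark methods whose power depends on autocorrelation.
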