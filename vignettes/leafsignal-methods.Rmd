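---
title: "Insect-perceived leaf colour and plant defence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insect-perceived leaf colour and plant defence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafsignal)
```

`leafsignal` implements a complete analysis chain for testing whether leaf
colour, *as an insect sees it*, carries information about plant chemical
defence and predicts herbivory. This vignette is the package's account of
the science inside each stage: the models, their assumptions, the
parameters that matter, and the choices we made where the method left room.

## 1. From spectra to insect colour channels

### Reflectance spectra

The raw observable is a reflectance spectrum on 300–700 nm, measured
against a barium-sulphate white standard. Reflectance is therefore unitless
and may exceed 1 (specular, waxy leaves); the package deliberately does not
clamp values to [0, 1], and downstream code tolerates values above 1.
Missing readings are dropped (and counted), never interpolated.

Two optional pre-processing steps mirror common practice:

- **Piecewise cubic smoothing** (`smooth_piecewise_cubic()`): a
  least-squares cubic regression spline with knots at the boundaries of 30
  equal sections spanning 300–800 nm, fitted by minimising the total
  squared deviation. The method description this follows does not say
  whether the per-section cubics are independent or continuous; we chose a
  C2-continuous spline (B-spline basis), the standard reading, which also
  guarantees the nested-model property that the spline's residual sum of
  squares can never exceed that of a single global cubic. When the data
  stop at 700 nm the available range is used, with a warning. It is also
  not documented whether published spectra were smoothed before receptor
  modelling or only for display; smoothing is therefore exposed as an
  optional step, off by default.
- **Peak normalization** (`normalize_to_peak()`): division by the maximum
  reflectance within 550 ± 30 nm, the chlorophyll reflectance peak, making
  curve *shape* comparable across leaves of different overall intensity.

### Receptor model

Insect photoreceptor sensitivities are built from a single number per
receptor — the peak wavelength $\lambda_{\max}$ — using the A1
visual-pigment nomogram (Govardovskii-type template), alpha band only. The
template constants are transcribed once and unit-tested against an
independent re-evaluation. We omit the beta band: its short-wavelength
shoulder is small, and every analysis here compares catches *between
leaves*, where a constant template distortion cancels in rank terms.
Screening-pigment optics of pierid red receptors and ocular media
transmission are likewise out of scope; the nomogram-at-$\lambda_{\max}$
curve is a stated approximation of the measured sensitivities.

Defaults: aphid UV/B/G at 325/460/530 nm (Myzus-type eye physiology);
butterfly pale-red and deep-red at 620/640 nm. The butterfly's UV/B/G peaks
are not fixed by the system this package models; the defaults 360/450/563
nm are configuration sourced from pierid eye-physiology literature and are
overridable (`receptor_set(..., overrides = c(G = 560))`).

The quantum catch is the trapezoidal integral of reflectance × illuminant ×
sensitivity on the shared 1-nm grid; it is linear in reflectance, so all
catch *ratios* are invariant to uniform scaling of the spectrum
(illumination intensity). Colour channels are `bg_ratio` ($Q_B/Q_G$),
`prg_ratio`, `drg_ratio` (butterfly only), and `brightness` ($Q_G$, the
achromatic channel). No von Kries adaptation is applied: the analyses use
raw catch ratios.

**Illuminant.** The measurement protocol this emulates does not state an
illuminant, and all headline quantities are within-study comparisons, so
the default is the minimal assumption: a flat equal-quanta spectrum. CIE
D65 (converted to relative quanta) is available by flag, and the package's
property tests require the qualitative results — ratio invariances and
archetype orderings — to hold under both.

## 2. Synthetic data: what it emulates, and what it does not

No plant-level data are deposited with the study this package re-implements,
so the generator is a first-class module that reproduces the *statistical
structure* the analyses assume.

**Spectra.** Three archetypes anchor the generator: a bluish leaf with
elevated broadband 400–500 nm reflectance (waxy epidermis), a green
chlorophyll-dominated leaf, and a reddish leaf with elevated reflectance
above ~550 nm (long-wavelength reflecting pigments). Each spectrum is a
chlorophyll-style base curve (green peak near 550 nm, absorption troughs
near 430 and 668 nm, red edge near 700 nm) plus continuous wax and pigment
amplitudes whose means depend on the archetype, plus smooth random
heterogeneity (a few narrow random bumps) and multiplicative log-normal
noise, clipped to [0, 1.2]. Amplitudes are continuous and correlated
through a shared "colourfulness" factor, so archetypes overlap — as real
plants do — while their medians stay ordered (bluish leaves have the
highest blue:green channel, reddish the highest deep-red:green). The
independent variation in red-edge position and trough depth exists so the
two red channels, whose receptors lie only 20 nm apart, are strongly but
not perfectly correlated, matching the observation that the three butterfly
channels carry partly independent information. This is an additive
band-shape model, not a radiative-transfer simulation: absolute reflectance
levels, specular/diffuse geometry and induced colour dynamics are not
modelled, so passing tests validate the *analysis machinery*, not leaf
optics.

**Survey structure.** Twelve populations in four counties (three each), a
range of 41–50 plants per population, two surveys (the second relocating
304 plants), a glucosinolate assay subset of 129 plants spread over
populations and a C:N subset of 179. The per-population range is set so the
expected total (~546) matches the first-survey size of the study (548) even
though its stated per-transect range was wider. The cabbage aphid is absent
from one county (Kent) and scored only in the first survey; the butterfly
is scored only on the relocated subset.

**Chemistry.** Eight glucosinolates (five aliphatic, three indole) get
log-normal marginals at realistic concentration scales — the true field
marginals are unpublished, so log-normality is an assumption and labelled
as such. Rank correlation with the colour channels is imposed by a Gaussian
copula over normal scores of the channel ranks: for target Spearman vector
$\rho_s$, the latent coefficient vector is $R^{-1}\rho_p$ with
$\rho_p = 2\sin(\pi\rho_s/6)$ and $R$ the empirical correlation of the
channel scores. Rank-level control is the faithful choice because the
correlation screen itself is rank-based. Class totals are sums of
constituents, so the totals' correlations emerge rather than being set.
Default targets follow the field sign pattern (red:green channels mostly
positive with glucosinolates, gluconapin negative, blue:green weak); the
two red channels' targets are kept close to each other because their
near-collinearity in synthetic spectra makes strongly divergent targets
geometrically unreachable. If requested targets imply a latent variance
above 1 the builder shrinks them proportionally with a warning (preserving
the pattern), and targets that are grossly inconsistent with the channel
dependence (implied variance > 2, e.g. |ρ| near 1 against several
correlated channels) are an error.

**Presence.** Herbivore presence is Bernoulli under a logistic model:
intercept at the configured base rate, a single standardized colour channel
as fixed effect, and independent normal random intercepts for county
(SD 0.3) and population (SD 0.5). The fixed effect is sized from the target
marginal $R^2$ by inverting
$R^2 = \beta^2 / (\beta^2 + \sigma^2_{pop} + \sigma^2_{county} + \pi^2/3)$;
the default 0.04 encodes the study's central quantitative finding that
colour effects on presence are real but small (< 5% of latent variance).

**Experiments.** Choice trials are Bernoulli draws with randomized sides.
Performance tables use the published group means with SEM-implied SDs
(growth rate 12.46 vs 10.42 mg/mg/day, pupal mass 146.9 vs 129.2 mg), two
larvae per plant, and log-normal aphid counts; masses are truncated at a
small positive floor.

## 3. Statistical stages

**Correlation screen.** Spearman's ρ with average ranks and
pairwise-complete deletion; p-values from the large-sample t approximation
(`cor.test(exact = FALSE)`), with an exact-enumeration oracle reserved for
the test suite at small n. Multiplicity is controlled per screen family by
the Benjamini–Hochberg step-up rule; the FDR level is a parameter with
documented defaults of 0.05 for correlation screens and 0.1 for the
presence models (a deliberately more permissive level, because field
colour effects are expected to be small). Whether the original families
were per-table or global is not fully specified; per-family is implemented.

**Presence GLMMs.** `lme4::glmer` with binomial errors and random
intercepts for population nested in county, fitted by Laplace-approximate
*maximum likelihood* (not REML) precisely so that deviance differences
between nested fits are valid likelihood-ratio statistics. Colour
predictors are z-scored before fitting for conditioning (the original
analysis does not say whether it transformed them; estimates are reported
on both scales, so the choice is inspectable). The colour term is tested by
the change in deviance on its removal against $\chi^2_1$, floored at zero.
Degenerate responses (all one level) and non-convergence are flagged on the
result, never silent. Marginal $R^2$ uses the logit-scale decomposition
var(fixed predictor) / (var(fixed) + Σ var(random) + $\pi^2/3$).

A note on calibration: the Laplace deviance LRT is known to be slightly
anticonservative for binary responses with few clusters. Under the
package's own survey design (12 populations, 4 counties, ~300 scored
plants) its empirical size at α = 0.05 is about 0.07 — acceptable, and
verified by simulation in the test suite — but users fitting far fewer
populations should not expect nominal size.

**Model selection.** `backward_select()` drops the least significant term
(largest LRT p) while that p exceeds α = 0.05, refitting after each
deletion on a fixed listwise-complete dataset so all nested comparisons use
identical data; ties break toward the term declared later. The VIF screen
(1/(1−R²) from regressing each predictor on the rest, thresholds 3 and 10)
exists because the colour channels themselves are too collinear to enter
one model together — they are fitted one per model instead, with BH across
models.

**Experiments.** Exact two-tailed binomial tests use the doubling rule
min(1, 2·min(P(X≤k), P(X≥k))), which at p₀ = 0.5 reproduces the standard
exact test. Performance responses are compared by one-way LMs at the plant
level (larvae sharing a plant are averaged first); time-to-pupation and
leaf-area responses use a natural-log transform with no offset — a zero is
an error, not log(x+1). Aphid morph proportions use a quasibinomial GLM
with Pearson-χ²/df dispersion and an F test on dropping the group term.
Mann–Whitney and Wilcoxon matched-pairs tests use full enumeration of the
permutation/sign-flip distribution for 12 or fewer observations (valid
under ties; W is the rank-sum-based statistic in the `stats::wilcox.test`
convention) and the tie-corrected normal approximation otherwise. Relative
growth rate is (ln m₂ − ln m₁)/(t₂ − t₁) in mg/mg/day from the first and
last weighing; the source formula's handling of intermediate weighings is
not printed, so the two-point version is implemented and documented, with
replacement larvae excluded.

## 4. Numerical choices and degenerate inputs

- Canonical grid 300–700 nm at 1 nm; resampling is linear interpolation
  and extrapolation is refused.
- Trapezoid integration throughout; oracle comparisons in the tests at
  1e-9 relative tolerance.
- The smoother requires at least 4 points per section (120 for the default
  30) and clips negative fitted reflectance at zero, which can only reduce
  the residual sum of squares against non-negative data.
- `pair_by_rank()` breaks ties by plant id, making the pairing
  deterministic; the partition property (every plant used once, groups
  separated) is tested.
- White-standard normalization refuses wavelengths where white ≤ dark,
  listing them.
- Copula feasibility is decided on the empirical channel correlations of
  the generated sample, so it adapts to the configured archetype mixture.

## 5. Problem sizes used in the tests

The suite sizes its simulations to be decisive but not wasteful: 200
replicates for the LRT size check (binomial 95% CI around 0.05), 100
replicates for marginal-R² recovery (mean within ±0.03 of the configured
0.04), one 500-plant survey for correlation-sign recovery at |ρ| = 0.3
(≥95% of configured signs), 100 spectra per archetype for the channel
orderings under both illuminants, and exhaustive enumeration oracles for
the rank tests at n+m ≤ 8 and the binomial/BH rules. Every stochastic test
fixes its seed.

## 6. Known limitations

- The receptor model is a template approximation; measured sensitivities
  with screening pigments would shift absolute ratios (though not
  within-study comparisons).
- The synthetic generator's field-likeness is structural, not
  biophysical; effect sizes are configured, not discovered.
- Spatial structure beyond nested random intercepts (and any
  autocorrelation within transects) is not modelled, and interaction terms
  are excluded from the global presence models by design.
- The published field test statistics (e.g. the Table of colour-chemistry
  correlations) depend on undeposited data; the package validates its
  machinery with oracles and parameter-recovery simulations instead of
  attempting to reproduce those numbers.
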