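---
title: "Characterizing reversible enzyme inhibitors with inhibikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing reversible enzyme inhibitors with inhibikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibikit)
library(dplyr)
```

inhibikit analyzes the five bench assays that together characterize a
reversible small-molecule enzyme inhibitor — the workflow used to profile
flavonoid inhibitors of acetylcholinesterase (AChE) such as quercetin, with
galantamine hydrobromide as the comparator drug. Every stage takes a tidy
table in, returns a fit object with `tidy()`/`glance()`/`autoplot()`
methods, and is paired with a seeded synthetic-data generator carrying known
ground truth, so the whole pipeline is verifiable by parameter recovery.

## The models

**Dose–response (IC50).** Relative activity $A$ versus inhibitor
concentration $[I]$ is fit with the four-parameter logistic

$$A([I]) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + ([I]/\mathrm{IC}_{50,\mathrm{app}})^{h}}.$$

The bottom plateau is free by default because partial inhibitors leave a
residual activity floor (quercetin stabilizes AChE near 25% activity); a
fixed-zero floor would bias the potency estimate low. Two IC50s are emitted:
the 4PL midpoint `ic50_app` and the operational `ic50`, the concentration
where the fitted curve crosses 50% activity. The assay convention reports
the crossing; the two coincide only when the floor is zero. Concentrations
are handled on a log scale internally (the parameter actually optimized is
$\log \mathrm{IC}_{50,\mathrm{app}}$) for conditioning across decades;
initialization is top = max activity, bottom = min activity, hill = 1, and
the midpoint at the concentration nearest half-range, which is robust for
any monotone series.

**Reversibility.** For a reversible inhibitor, initial rate versus enzyme
concentration at fixed $[I]$ is a straight line through the origin whose
slope falls as $[I]$ rises; an irreversible titrant instead shifts the lines
right (positive, growing x-intercepts). The verdict "reversible" requires
(i) every intercept's confidence interval to cover zero and (ii) a falling
slope trend. Two statistical choices matter here and are deliberate:

* The origin test is *family-wise*: with $L$ inhibitor levels each tested at
  95%, the joint probability that all intercepts pass is only $0.95^L$
  (about 77% at five levels), so a per-line 95% rule would routinely call
  genuinely reversible data "inconclusive". The per-line intervals are
  Bonferroni-widened to $1 - 0.05/L$ so the joint statement holds at 95%.
* "Slopes decrease" is a one-sided trend test (regression of line slopes on
  $[I]$) plus a check that no adjacent pair increases significantly, rather
  than strict ordering of point estimates: near-equal slopes at neighbouring
  inhibitor levels swap order by chance under a few percent of noise.

**Mixed-inhibition mechanism.** The rate law with inhibitor binding to both
free enzyme (constant $K_i$) and the ES complex (constant $\alpha K_i$) is

$$v = \frac{V_m [S]}{K_m\left(1 + \frac{[I]}{K_i}\right) +
[S]\left(1 + \frac{[I]}{\alpha K_i}\right)}.$$

`fit_lineweaver_burk()` runs OLS of $1/v$ on $1/[S]$ per inhibitor level;
under this law the LB slope is $(K_m/V_m)(1 + [I]/K_i)$ and the intercept
$(1/V_m)(1 + [I]/\alpha K_i)$, so `secondary_replots()` regresses both on
$[I]$ and reads $K_i$ and $\alpha K_i$ off as intercept/slope ratios. The
replot route is the bench convention and is what the report quotes;
`fit_mixed_direct()` (Levenberg–Marquardt on the raw rates, initialized from
the replots) is emitted alongside as a cross-check because reciprocal
transformation distorts the noise structure. The two agree exactly on
noiseless data. Mechanism labels use operational windows on
$\alpha = \alpha K_i / K_i$: $[0.8, 1.25]$ noncompetitive, $> 20$
competitive-like, otherwise mixed; the literature draws no numeric boundary,
so the windows are stated here once and logged in every report.

**Inactivation kinetics.** Prolonged exposure drives activity down as a
first-order, single-phase decay; `fit_inactivation()` takes the slope of
$\ln A$ on $t$, and `transition_free_energy()` converts the rate constant by
$\Delta\Delta G^\circ = -RT \ln k$ (kJ/mol, natural log,
$R = 8.314\ \mathrm{J\,mol^{-1}\,K^{-1}}$, default $T = 298.15$ K). Long
time courses plateau at a residual activity that a pure exponential cannot
represent, so the default fit window is 0–1800 s — the decaying phase — and
is user-overridable. The windowing choice is the package's own: activity
records do not usually state whether the plateau was excluded, and fitting
through it flattens $k$ (the test suite demonstrates the size of that bias).

**Fluorescence binding analysis.** Raw titration fluorescence is
inner-filter corrected, $F_c = F_m e^{(A_1 + A_2)/2}$ by default; a base-10
dialect is selectable because both forms circulate, and the dialect used is
recorded on the series and in reports. Then:

* Stern–Volmer: OLS of $F_0/F$ on $[Q]$ (mol/L) with a *free* intercept;
  a fitted intercept off unity by more than 5% flags a miscalibrated or
  non-linear series. $K_q = K_{SV}/\tau_0$ with $\tau_0 = 10^{-8}$ s, the
  canonical biopolymer fluorescence lifetime (configurable). Quenching is
  classified "static" only if the smallest $K_q$ clears the diffusion limit
  of $2.0 \times 10^{10}\ \mathrm{L\,mol^{-1}\,s^{-1}}$ *and* $K_{SV}$ falls
  with temperature (a ground-state complex dissociates when warmed).
* Double-log: $\log_{10}\frac{F_0 - F}{F} = \log_{10} K_a + n \log_{10}[Q]$
  gives the binding constant and site number. Quencher concentrations are
  converted to mol/L before the fit — $K_a$'s units demand it.
* van't Hoff: OLS of $\ln K_a$ on $1/T$ yields $\Delta H^\circ$ (slope) and
  $\Delta S^\circ$ (intercept), assuming temperature-independent enthalpy
  over the narrow 25–37 °C range. $\Delta G^\circ$ is emitted both as
  $\Delta H^\circ - T\Delta S^\circ$ and as $-RT \ln K_a$; the two differ
  only by lack of fit. Sign heuristics label the dominant forces (both
  negative: hydrogen bonding + van der Waals; both positive: hydrophobic;
  $\Delta H^\circ < 0 < \Delta S^\circ$: electrostatic).

Temperatures are stored in kelvin throughout (readers convert °C);
concentrations are canonicalized to µM (substrate mM, enzyme nM) at read
time, since mixed-unit tables are the single most common source of silent
$10^3$ errors in this analysis.

**Combination index.** For a dose pair $(D_1, D_2)$ jointly producing $X\%$
inhibition, with single-agent doses $(D_X)_1, (D_X)_2$ at the same level,

$$CI = \frac{D_1}{(D_X)_1} + \frac{D_2}{(D_X)_2},$$

with $CI < 0.9$ synergism, $0.9$–$1.1$ additive (boundaries inclusive —
the conventional wording "0.9–1.1 indicates additive" reads as a closed
interval), $> 1.1$ antagonism. `build_isobologram()` accepts measured
equi-effective pairs directly (the bench procedure) or a model surface for
validation: `loewe_surface()` defines $X(d_1, d_2)$ by
$d_1/D_1(X) + d_2/D_2(X) = \lambda(X)$, where $\lambda \equiv 1$ is exact
Loewe additivity (every isobole point has $CI = 1$, the key structural
test) and $\lambda < 1$ builds synergy of known size. Isobole points are
solved by bisection on the monotone surface (bracket $[0, 3 D_X]$, relative
tolerance $10^{-6}$); a drug-B fraction that alone meets the level yields
the degenerate single-agent point with $CI = 1$.

## The synthetic-assay generators

`quercetin_ache_preset()` freezes one coherent truth set drawn from the
published characterization of quercetin–AChE: IC50 4.59 µM over a 25%
activity floor (galantamine 0.29 µM), $K_i$ 6.17 µM and $\alpha K_i$
19.53 µM, the inactivation ladder $4.18$–$6.41 \times 10^{-4}\ s^{-1}$
over 1.5–15 µM, $K_{SV}$ 6.21/4.81/3.33 and $K_a$ 5.52/3.52/2.05
($\times 10^4$ L/mol) with $n$ 0.75/0.69/0.67 at 25/31/37 °C, and an
interaction map synergistic at the 30/50% inhibition levels and additive at
70%. Quantities the source system does not report are set once to realistic
assay values: $K_m = 0.12$ mM (acetylthiocholine on electric-eel AChE),
unit $V_m$, $F_0 = 1000$ a.u., inactivation plateau 0.25.

Noise is multiplicative gaussian by default — constant coefficient of
variation matches plate-reader and fluorometer error — with an additive
option. Seeds are mandatory arguments; generators restore the caller's RNG
state, and regeneration from the recorded manifest is bit-identical.

One subtlety is deliberate: the Stern–Volmer and double-log mean models,
$F = F_0/(1 + K_{SV}[Q])$ and $F = F_0/(1 + K_a [Q]^n)$, are mutually
inconsistent except at $n = 1$, yet bench practice applies both estimators
to the same titration. The generator therefore exposes both modes; recovery
tests pair each estimator with its matching mode, and the end-to-end
pipeline fixture uses $n = 1$, where the two coincide.

What passing recovery tests do **not** show about real data: the generators
draw independent gaussian errors on an exactly-correct mean model. Real
assays add substrate depletion during the "initial" rate window, pipetting
correlation across a dilution series, temperature drift, inner-filter
nonlinearity beyond the absorbance range, and model misspecification (e.g.
genuinely biphasic inactivation). Recovery results bound estimator error
under the stated noise, not assay systematics.

## Study sizes and numerical behaviour

The recovery studies use the design a bench protocol of this kind would
produce, and these are the sizes the test suite and the acceptance script
run: 50 dose-response replicates (8 concentrations, 0.5–80 µM, 3% noise);
100 kinetic replicates (5 substrate levels 0.05–1 mM × 4 inhibitor levels
0–12 µM, 2% noise); 50 titrations (11-point ladder 0–8 µM, 1% noise). At
those sizes the mean recovered IC50, $K_i$, $\alpha K_i$ and $K_a$ all land
within ~1% of truth, comfortably inside the 5–10% acceptance bands the
package holds itself to.

Two Monte-Carlo facts set the test tolerances (both measured with the
package's own generators): per-replicate $\Delta H^\circ$ from three
temperatures spanning 12 K carries ~12% spread at 1% fluorescence noise, so
means over tens of replicates are asserted at the few-percent level, not
1%; and $K_a = 10^{\mathrm{intercept}}$ exponentiates an extrapolation of
~5.6 decades in $\log_{10}[Q]$, so its per-fit median error (~5%) runs
higher than $K_{SV}$'s (~2.4%) at the same noise while its mean stays
unbiased.

Degenerate inputs are handled explicitly: activity never crossing 50% flags
the operational IC50 undefined but still returns curve parameters; zero
rates name the offending row before reciprocals are taken; $F \ge F_0$
points are dropped with a warning in log–log space; non-decaying activity
reports "no inactivation" with $k = 0$; non-positive replot-derived
constants are flagged mechanism-inconsistent rather than silently returned.

## Worked example

```{r example}
preset <- quercetin_ache_preset()

# dose-response at 3% noise
d <- gen_dose_response(preset$dose_response, c(0.5, 1, 2, 4, 8, 16, 40, 80),
                       noise_sigma = 0.03, seed = 101)
tidy(fit_ic50(d))

# mechanism from a 5 x 4 kinetic design at 2% noise
k <- gen_kinetics(preset$kinetics, s_grid = c(0.05, 0.1, 0.25, 0.5, 1),
                  i_grid = c(0, 4, 8, 12), noise_sigma = 0.02, seed = 101)
rp <- secondary_replots(fit_lineweaver_burk(k))
tidy(rp)
rp$mechanism

# three-temperature binding thermodynamics (noiseless ladder)
th <- vant_hoff(preset$titration[, c("temperature", "ka")])
tidy(th)
th$dg_by_temp
th$force_type

# Loewe-additive surface: every isobole point has CI = 1
surf <- gen_combination_surface(preset$dose_response,
                                preset$comparator_dose_response)
build_isobologram(surf, level = 50)$pairs$ci
```

## Limitations

No tight-binding (Morrison) or slow-binding corrections; no substrate
inhibition; no biphasic dose–response or inactivation models beyond window
restriction; no modified (fractional-accessibility) Stern–Volmer, no
synchronous/3D fluorescence, no FRET; combination analysis is CI-only (no
Bliss independence, no median-effect $D_m/m$ modelling). Dilution during
titration (≤ 0.4% for 10 × 1 µL additions into 2.5 mL) is neglected by
default. These exclusions keep each reported constant on the estimator its
field convention defines.
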