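# inhibikit

Tidy characterization of reversible enzyme inhibitors from standard bench
assays. The package covers the full workflow used to profile small-molecule
inhibitors of enzymes such as acetylcholinesterase (AChE):

* **Potency** — IC50 by four-parameter logistic fit of relative activity vs
  inhibitor concentration, with a free residual-activity floor and the
  operational 50%-crossing IC50 alongside the curve midpoint;
* **Reversibility & mechanism** — rate-vs-[E] line analysis (origin test +
  slope trend), Lineweaver–Burk double-reciprocal fits, secondary replots
  for the mixed-inhibition constants *K*ᵢ and *αK*ᵢ, and a direct nonlinear
  fit of `v = Vm·[S] / (Km·(1 + [I]/Ki) + [S]·(1 + [I]/αKi))` as cross-check;
* **Inactivation kinetics** — first-order semilog fits of activity decay and
  transition free-energy changes, ΔΔG° = −RT·ln k;
* **Binding spectroscopy** — inner-filter correction, Stern–Volmer quenching
  constants (`F0/F = 1 + KSV[Q]`, `Kq = KSV/τ0`) with static/dynamic
  classification against the 2×10¹⁰ L mol⁻¹ s⁻¹ diffusion limit, double-log
  binding fits (`log((F0−F)/F) = log Ka + n·log[Q]`), van't Hoff
  thermodynamics (ΔH°, ΔS°, ΔG°) and binding-force classification;
* **Synergy** — dose-normalized isobolograms and the combination index
  `CI = D1/(DX)1 + D2/(DX)2` (< 0.9 synergism, 0.9–1.1 additive, > 1.1
  antagonism), for measured equi-effective pairs or model surfaces;
* **Synthetic assays** — seeded generators for all five assay classes with
  known ground truth (including a quercetin–AChE preset), so every stage is
  verifiable by parameter recovery.

Everything takes a data frame and returns a tibble-backed fit object with
`tidy()`, `glance()` and `autoplot()` methods; `run_pipeline()` drives all
stages over a directory of assay tables and writes a combined report.

## Worked example

```r
library(inhibikit)
preset <- quercetin_ache_preset()

# --- potency: 4PL fit of a synthetic dose-response at 3% noise
d <- gen_dose_response(preset$dose_response, c(0.5, 1, 2, 4, 8, 16, 40, 80),
                       noise_sigma = 0.03, seed = 101)
tidy(fit_ic50(d))
#>   term     estimate std.error units
#> 1 top       101.        5.64  "%"
#> 2 bottom     25.0       1.65  "%"
#> 3 hill        0.959     0.117 ""
#> 4 ic50_app    2.22      0.354 "uM"
#> 5 ic50        4.69      0.199 "uM"
```

The inhibitor leaves ~25% residual activity (the fitted floor), so the
operational IC50 (4.69 µM here, truth 4.59) sits above the curve midpoint.

```r
# --- mechanism: Lineweaver-Burk secondary replots at 2% noise
k <- gen_kinetics(preset$kinetics, s_grid = c(0.05, 0.1, 0.25, 0.5, 1),
                  i_grid = c(0, 4, 8, 12), noise_sigma = 0.02, seed = 101)
rp <- secondary_replots(fit_lineweaver_burk(k))
tidy(rp)
#>   term     estimate std.error units
#> 1 ki          6.29      0.291 "uM"
#> 2 alpha_ki   17.5       1.23  "uM"
#> 3 alpha       2.79     NA     ""
#> 4 km          0.123    NA     "mM"
#> 5 vm          1.02     NA     "rate"
rp$mechanism
#> [1] "mixed"
```

*K*ᵢ < *αK*ᵢ: the inhibitor binds free enzyme more tightly than the
enzyme–substrate complex — a mixed mechanism (α ≈ 2.8 falls outside the
noncompetitive window around 1).

```r
# --- inactivation energetics and binding thermodynamics
transition_free_energy(c(4.18e-4, 6.41e-4), 298.15)
#> [1] 19.28528 18.22547     # kJ/mol: faster inactivation, lower barrier

th <- vant_hoff(preset$titration[, c("temperature", "ka")])
tidy(th)
#>   term  estimate std.error units
#> 1 dh       -63.4      4.08 kJ/mol
#> 2 ds      -122.      13.4  J/(mol K)
th$force_type
#> [1] "hydrogen bonds + van der Waals"
```

Both ΔH° and ΔS° negative: exothermic, enthalpy-driven binding dominated by
hydrogen bonds and van der Waals contacts, spontaneous (ΔG° ≈ −27.1 kJ/mol
at 25 °C) across the measured range.

```r
# --- synergy: a Loewe-additive surface puts CI = 1 on every isobole point
surf <- gen_combination_surface(preset$dose_response,
                                preset$comparator_dose_response)
build_isobologram(surf, level = 50)$pairs$ci
#> [1] 1 1 1 1
```

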