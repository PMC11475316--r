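# mmoct — quantitative multimodal OCT analysis

`mmoct` is an R package for turning multimodal optical coherence tomography
(OCT) data of soft tissue into quantitative diagnostic criteria. It was
built around the workflow used to grade endometrial tissue — normal
endometrium, hyperplasia (including the precancer EIN) and endometrial
cancer subtypes — but every stage is generic:

* **Cross-polarization OCT → attenuation maps.** Co- and cross-polarized
  intensity channels are compensated for additive noise and instrument
  sensitivity and converted to per-pixel depth-resolved attenuation
  coefficients, `μ̂[i] = I[i] / (2Δ Σ_{j>i} I[j])` with Δ the axial pitch in
  mm of tissue depth, plus a geometric tail completion for the finite scan
  and lateral speckle averaging. Rendered 0–12 mm⁻¹, blue → red.
* **Compression elastography → stiffness maps.** Interframe axial strain by
  the unwrap-free vector method (lag-q phasor averaging), cumulative strain,
  stress calibration from a pre-calibrated linear reference silicone layer
  (σ = E_ref · ε_ref), and the tangent Young's modulus dσ/dε at 1 kPa
  applied stress from a windowed least-squares fit. Rendered 0–600 kPa,
  blue = stiff.
* **Region statistics.** Random non-overlapping 10×10 regions in the tissue
  projection, Me [Q1; Q3] descriptives, pairwise two-sided Mann–Whitney U
  tests (exact by full enumeration for small groups, ties included) with
  per-modality Bonferroni correction.
* **Diagnostics.** ROC curves by full threshold sweep (AUC equals the
  pairwise-comparison probability exactly), Youden-index operating points,
  sensitivity/specificity in percent.
* **Phantoms with ground truth.** A speckle phantom generator (Beer–Lambert
  decay per layer per channel, fully developed speckle, noise floor,
  sensitivity roll-off; compression series with linear or exponential
  stress–strain laws under a phase-wrap-safe loading schedule) stands in
  for clinical data, so every estimator is validated against known truth.

See `vignette("mmoct-methods")` for the models, parameter defaults and the
reasoning behind the numerical choices.

## Worked example

Simulate an EIN-like sample (attenuation medians and tangent stiffness
taken from the package's built-in reference table), then run both
quantitative chains:

```r
library(mmoct)

spec <- phantom_spec_from_reference("EIN", seed = 42, width_px = 128,
                                    noise_floor = 1e-4)
spec
#> OCT phantom spec: 256 x 128 px (depth x lateral), pitch 0.0066 mm/px (air), n = 1.40
#>   reference silicone: 48 px, E_ref = 100 kPa
#>   layer 'EIN': 200 px, mu_co = 3.14, mu_cross = 2.02 1/mm, exponential law (tangent@1kPa = 172 kPa)

gen <- generate_cpoct_stack(spec)
att <- estimate_attenuation(compensate_signal(gen$stack, noise_floor = 1e-4), "co")
att
#> attenuation_map: 256 x 128 px (co), 67.1% valid, median 2.82 1/mm

ser <- generate_compression_series(spec, seq(0, 1.68, by = 0.12))
stiff <- estimate_stiffness(ser$series)
stiff
#> stiffness_map: 256 x 128 px (stiffness), 78.1% valid, median 172 kPa
```

The whole-map attenuation median (2.82 mm⁻¹) mixes in the silicone pad on
top; restricted to the tissue rows it is 3.10 mm⁻¹ over 15,833 valid pixels
— within 1.3% of the generating value 3.14 mm⁻¹ (the estimator's
discretization bias is ≈ μΔ ≈ +1.5% and speckle-median bias ≈ −2%). The
stiffness median recovers the generating tangent modulus, 172 kPa, exactly
to the printed precision.

Group statistics and threshold selection on a reference-matched cohort:

```r
tab <- simulate_reference_cohort(100, classes = c("proliferative", "non_atypical",
                                                  "EIN", "EC_low"),
                                 modalities = "stiffness", seed = 7)
describe_mq(tab$value[tab$tissue_class == "EIN"], digits = 0)$label
#> [1] "166 [111; 285]"

roc <- roc_analysis(tab, standard_contrasts("stiffness")$ein_vs_benign)
roc
#> ROC: 100 positive vs 200 negative (higher is positive), AUC = 0.906
#>   threshold 109.9 (youden): Se = 77.0%, Sp = 92.0%
```

So on this simulated cohort, a stiffness threshold of ~110 kPa separates
EIN from benign tissue with 77% sensitivity and 92% specificity; the
interquartile label reproduces the generating distribution ("172 [124;
305]" in the reference table) up to sampling noise.

The full pipeline — phantom cohort, both map types, measurement table,
comparison matrix, ROC summaries, provenance record — runs from one
configuration object (`run_pipeline(default_config(seed = 1), "out/")`) or
from the thin CLI (`inst/cli/mmoct.R` with subcommands `simulate`, `atten`,
`oce`, `roi`, `stats`, `roc`, `run`).

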