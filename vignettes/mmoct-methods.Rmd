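---
title: "Quantitative multimodal OCT analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative multimodal OCT analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mmoct` implements the quantitative processing chain used to grade soft
tissue — here parameterized for endometrial tissue classes — from two OCT
modalities: cross-polarization structural imaging (co- and cross-polarized
detection channels, converted to depth-resolved attenuation-coefficient
maps) and phase-sensitive compression elastography (converted to tangent
Young's modulus maps via a calibrated reference silicone layer). Region
statistics and ROC threshold selection turn the maps into diagnostic
criteria. Because raw clinical OCT data of this kind are rarely shared, the
package is built around a speckle phantom generator with fully known ground
truth: every estimator in the chain is validated end to end against the
parameters that generated its input.

## The phantom model

A phantom is an axial stack of homogeneous layers. For channel $c$ and
tissue depth $z$ the ensemble-mean intensity is Beer–Lambert,

$$ I_c(z) \;=\; s(z)\, I_0 \exp\!\Big(-2\int_0^z \mu_c(z')\,dz'\Big), $$

with $s(z)$ the instrument sensitivity profile (flat by default; an
exponential roll-off can be enabled to exercise the compensation path).
Fully developed speckle multiplies this mean by the squared magnitude of a
unit-variance circular complex Gaussian — an exponential random variable
with unit mean and unit contrast — independently per pixel; an additive
exponential noise floor models detection noise. Per-pixel independence (no
lateral point-spread correlation) is the simplest model sufficient for
estimator testing; real OCT speckle is laterally correlated over roughly a
resolution cell, which mainly rescales the effective number of independent
samples.

Geometry defaults mirror a common spectral-domain instrument: 256 depth
pixels over ~1.7 mm in air, 512 lateral pixels over 2.4 mm, central
wavelength 1.3 µm. Depth in air converts to tissue depth through the
refractive index `n_tissue`. Instruments specify scan depth in air, and
attenuation tables are in mm$^{-1}$ of tissue, so the conversion matters at
the few-tens-of-percent level; since tissue indices are not usually
reported with the scan geometry we expose `n_tissue` as a parameter with
the typical soft-tissue default 1.4.

Under compression, each layer follows either Hooke's law
$\sigma = E\,\varepsilon$ or the strain-stiffening exponential law
$\sigma(\varepsilon) = (E_\infty/k)\,(e^{k\varepsilon}-1)$, whose tangent
modulus grows linearly with stress, $d\sigma/d\varepsilon = E_\infty +
k\sigma$. The single parameter $k$ controls how fast the tissue stiffens,
which matches the common observation that soft-tissue stress–strain curves
are nonlinear; the generator inverts the law numerically (the tests check
the inversion against the closed form and a bisection oracle). Complex
frames are the same speckle field phase-modulated by
$\exp(i\,4\pi n\, u(x,z)/\lambda)$, where $u$ integrates the per-layer
strains from the surface; compressive strain is positive throughout, which
keeps stress–strain curves in the first quadrant.

## Depth-resolved attenuation

The per-pixel estimator is the standard single-scattering depth-resolved
recursion

$$ \hat\mu[i] \;=\; \frac{I[i]}{2\Delta \sum_{j>i} I[j]},
   \qquad \Delta = \frac{\text{axial pitch in air}}{n_\text{tissue}}, $$

which on an ideal exponential A-scan equals
$(e^{2\mu\Delta}-1)/(2\mu\Delta)\cdot\mu$ — a discretization bias of about
$\mu\Delta$ (≈0.5–2.5% for the geometry above), vanishing as
$\Delta \to 0$. Before the recursion the signal is compensated:
subtract-then-clip of the additive noise floor (clipping keeps the tail sum
non-negative) and division by the sensitivity profile; `noise_floor =
"auto"` estimates the floor per lateral position as the median of the
deepest 5% of pixels.

Two corrections are essential in practice and deserve explanation:

* **Geometric tail completion.** On a finite scan the tail sum misses the
  signal beyond the deepest pixel, inflating every estimate by
  $1/(1-r^{N-i})$ with $r = e^{-2\mu\Delta}$ — several permille at the very
  top of a 256-px scan and unbounded near the bottom. The estimator
  therefore completes the tail with a geometric extrapolation whose decay
  rate is fitted log-linearly to the laterally averaged deepest rows
  (default 48; longer fits average more speckle and stabilize the
  completed mass, which is why the default is not minimal) and whose
  amplitude is set per column. The completion is exact on noiseless
  exponential columns and is skipped when the tail does not decay.
* **Lateral speckle averaging.** Under fully developed speckle the raw
  per-pixel ratio is exponentially distributed around its mean, so its
  median is $\ln 2 \approx 0.69$ of the truth — a raw per-pixel map is
  unusable for median-based quantification. The intensity is therefore
  averaged over a lateral boxcar before the recursion (default 16 px
  ≈ 75 µm; `smooth_lateral = 0` disables it). Averaging $W$ exponential
  pixels gives a Gamma$(W)$ numerator whose median is within
  $\approx 1/(3W)$ of the mean, i.e. ~2% at the default.

Validity is explicit, never silent: pixels whose completed tail falls below
`tail_frac` (default 1%) of the column energy are flagged invalid, as is
the deepest pixel; a zero tail yields an invalid pixel rather than a
division error. For quantification *below* a strongly attenuating layer the
default guard is deliberately conservative — a deep layer under an upper
layer of two-way optical depth $A$ retains only $\sim e^{-A}$ of the column
energy, so deep-layer analyses should relax `tail_frac` (the two-layer
validation uses `2e-4`) and lean on the tail completion, and should widen
the lateral boxcar (the validation uses 64 px) so that the pooled layer
median reflects row centers rather than the speckle mixture.

Layer interfaces appear in the maps with a characteristic signature: the
tail sum at a pixel above a downward attenuation step already integrates
the deeper layer, so $\hat\mu$ relaxes toward the deeper value along the
harmonic ramp $[(1-w)/\mu_1 + w/\mu_2]^{-1}$, $w = e^{-2\mu_1\Delta d}$,
and is flat below the interface. `locate_boundary()` fits exactly this
three-parameter curve to the lateral-median profile, so the whole
high-contrast ramp — not the low-amplitude step at its foot — pins the
boundary row; a plain piecewise-constant changepoint is biased upward by
tens of pixels by the ramp. Maps render with the conventional rainbow
scale, 0–12 mm$^{-1}$, blue = low to red = high, invalid pixels in neutral
grey.

## Compression elastography

Strain estimation follows the vector method: for consecutive frames the
interframe field $b = \overline{a_1} a_2$ is formed, lag-$q$ phasors
$b(z+q)\overline{b(z)}$ are averaged as complex numbers over an
(axial × lateral) window, and the strain is the averaged-phasor argument
scaled by $\lambda/(4\pi n q \Delta z)$. Averaging phasors before taking
the argument is what makes the method unwrap-free; the price is a hard
wrap limit: the per-step strain must keep the lag-$q$ interframe phase
below $\pi$, i.e. $|\varepsilon| < \lambda/(4 n q \Delta z)$ (≈1.2% at the
defaults $q = 4$, 8×8 window, $\lambda = 1.3$ µm). The generator enforces
this contract and rejects series that would wrap, naming the offending
layer and step; the estimator additionally flags pixels whose averaged
argument comes within 5% of $\pi$ and raises a hard error if more than 1%
of analyzed pixels are flagged. The lag trades sensitivity against wrap
risk; both lag and window are exposed parameters. The per-pixel confidence
$|\langle c\rangle| / \langle |c|\rangle$ is 1 on noiseless data and
decreases with additive noise.

Interframe strains accumulate by running summation (valid for the small
per-step strains the wrap limit enforces; no interframe speckle tracking
is performed — a stated limitation for large deformations). The cumulative
strain of the calibrated linear silicone, laterally averaged over the
interior of the reference rows (an 8-px margin avoids windowing
transients), converts to applied stress by Hooke's law; under the uniaxial
contract that stress is depth-uniform, giving every pixel a stress–strain
curve. Stiffness is the **tangent modulus at 1 kPa**, fitted by least
squares to the curve points with stress within ±0.5 kPa — a windowed fit
is reproducible and noise-robust where a two-point difference is not.
Reaching the 1.5 kPa upper window edge with per-step strains below the
wrap limit dictates the default schedule of 14 uniform steps of 0.12 kPa:
with a soft layer (tangent ≈ 15–25 kPa at low stress) a coarser schedule
(e.g. 8 steps of 0.21 kPa) would exceed the wrap limit and is rejected by
the generator. Stiffness maps use the elastography polarity — blue =
stiff, red = soft, 0–600 kPa — deliberately inverted relative to the
attenuation scale, following the field's convention.

## Region statistics

Quantification samples 10 random non-overlapping 10 × 10-px regions inside
the tissue-layer projection (intersected with the map's validity mask) and
uses the region means. Non-overlap is our choice — random placement alone
would double-count pixels in pooled statistics. Descriptives are reported
as Me [Q1; Q3] with linear-interpolation quartiles (R type 7; one
convention had to be pinned for reproducibility), formatted with two
decimals for mm$^{-1}$ and integers for kPa.

Group comparisons use the two-sided Mann–Whitney U test. For groups of at
most 8 the p-value is exact by full enumeration of all group labelings of
the pooled values — ties included, which is why the enumeration is
implemented here rather than delegated (`wilcox.test` falls back to the
approximation under ties); larger groups use the normal approximation with
tie and continuity corrections, which the tests cross-check against
`wilcox.test`. Bonferroni correction multiplies by the number of class
pairs *within one modality*; the family could plausibly span modalities
too, so it is configurable, but per-modality matches how such comparison
matrices are usually read. Region means from the same sample are treated
as independent observations — the pooled-region convention of the
measurement campaigns this emulates; a mixed-effects treatment of
patient-level clustering is out of scope and the caveat stands.

## Diagnostic thresholds

One-vs-rest contrasts (all cancer subtypes vs non-tumorous tissue; EIN vs
benign tissue) are evaluated by a full threshold sweep over the observed
values; a value equal to the threshold is a positive call (a convention
must be pinned for exact tests), and both attenuation and stiffness use
higher-is-positive since both increase toward malignancy. The sweep's
trapezoidal AUC equals the pairwise-comparison probability
$P(\text{pos} > \text{neg}) + \tfrac12 P(\text{pos} = \text{neg})$ exactly,
which the tests verify on random tied data. The operating point maximizes
the Youden index $TPR - FPR$ (ties broken toward higher specificity); a
closest-to-(0,1) policy is available, as the trade-off rule behind
published operating points is often unstated. EIN is counted among the
negatives of the cancer contrast (hyperplasia subsumes it in the usual
grouping); this materially affects specificity, so it is a flag.

The cohort simulator draws class-labelled measurements from log-normal
distributions matched to the built-in reference medians and quartiles
(`endometrial_reference()`; meanlog $= \log Me$, sdlog
$= \log(Q3/Q1)/2z_{0.75}$). It emulates pooled region-mean statistics only
— no imaging, no within-patient correlation — so conclusions drawn from it
are about the statistical machinery, not about tissue.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so each property is
measured with comfortable Monte-Carlo margin: uniform-phantom recovery on
512 × 256-px B-scans (>10⁴ valid pixels per case), the two-layer phantom at
1024 lateral pixels, stiffness recovery over 16 speckle seeds × 3 moduli
(25/122/311 kPa tangents, silicone 100 kPa), Mann–Whitney exactness on 200
random tied instances, AUC equivalence on 1000, type-I rate and the
stiffness-vs-attenuation AUC ordering on 1000/100 replicates. Degenerate
inputs are contracts, not crashes: empty descriptive input, single-frame
series, all-invalid maps, curves that never reach the tangent window
("insufficient compression range"), masks too small for the requested
regions (the feasible count is reported).

## Known limitations

No lateral PSF correlation in the speckle; no birefringence model behind
the cross channel (it is an independent attenuation profile); no
multiple-scattering or confocal-function corrections; no speckle tracking
between frames; stress assumed laterally and depth-uniform (frictionless
uniaxial idealization); pooled-region statistics ignore patient-level
clustering; AUC confidence intervals and cross-validated threshold tuning
are out of scope. Passing phantom tests demonstrates estimator
correctness under the stated models, not performance on clinical data.
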