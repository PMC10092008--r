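---
title: "Quantifying background matching: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying background matching: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camoquant)
```

`camoquant` scores how well an animal matches its background in the three
channels a visually hunting predator uses — colour, luminance and pattern —
and links those scores to field predation data. This vignette records the
models, the conventions chosen where the literature leaves latitude, and
what the synthetic test world does and does not establish.

## Receptor-noise-limited discrimination

Colour discrimination follows the receptor-noise-limited (RNL) model in its
log form. For stimuli $a,b$ with quantum catches $Q_i$ in receptor $i$, the
contrasts are $\Delta f_i = \ln(Q_i^a/Q_i^b)$ and the chromatic distance is
the noise-weighted residual around the best common intensity shift:

$$\Delta S^2 \;=\; \min_c \sum_{i \in \text{chromatic}}
\frac{(\Delta f_i - c)^2}{\omega_i^2}.$$

This variational statement is what the package evaluates for any channel
count; the familiar published quotient formulas for di-, tri- and
tetrachromats are algebraic specialisations of it, implemented separately
and verified equal to the variational solution to $10^{-9}$ in the test
suite. The form makes two properties transparent, both enforced as tests:
$\Delta S$ is symmetric in $a,b$, and adding a constant to all chromatic
log contrasts (an overall intensity change) leaves it unchanged.

Assumptions inherited from the RNL framework: discrimination is limited by
independent Gaussian channel noise; chromatic and achromatic processing are
separate; performance is registered in just-noticeable-difference (JND)
units with $\Delta S < 1$ conventionally indiscriminable. The achromatic
variant $\Delta L = |\ln(Q_D^a/Q_D^b)|/\omega_D$ on the double-cone channel
uses the same log-ratio convention for consistency, but the achromatic use
of RNL lacks strong behavioural validation, so luminance JNDs deserve more
caution than chromatic ones.

**Noise parameters.** Weber fractions scale with relative cone density
$\eta_i$ as $\omega_i = \nu\sqrt{\eta_\max/\eta_i}$, so the most abundant
class carries the reference value $\nu$. The default $\nu = 0.05$ is the
conventional behavioural estimate for birds; the default abundances
(1 : 1.92 : 2.68 : 2.7 for uv/sw/mw/lw) are literature-typical passerine
ratios. Neither is species-certain: `gen_receptor_set()` builds a
blue-tit-*like* fixture with Gaussian sensitivities peaking at
372/449/502/563 nm plus a broad double cone, explicitly a stand-in, and
every downstream function accepts any `receptor_set`. Consequences on real
data depend on the receptor set supplied; absolute JND values from studies
using measured sensitivities are not reproducible with the fixture, and the
package does not claim them.

**Quantum catches** are trapezoid integrals on a common 1-nm grid
(operands linearly resampled; extrapolation refused). Von Kries adaptation
divides each catch by the catch of a perfect white under the same
illuminant, which makes catches exactly invariant to illuminant rescaling —
asserted to $10^{-12}$ in the tests. Zero catches are error states, and
negative pixels produced by a user-supplied camera-to-receptor mapping are
clamped to $10^{-6}$ of the channel maximum (with a count warning) because
log contrasts require positivity.

## Acuity control

Spatial information a receiver cannot resolve must be removed before
pattern or colour statistics are computed. The convention is the minimum
resolvable angle $\text{MRA} = 1/\text{acuity}$ degrees, spanning
$2d\tan(\text{MRA}/2)$ at viewing distance $d$. Each channel is blurred
with a Gaussian of FWHM = one MRA in pixels ($\sigma = \text{MRA}/2.355$,
half-sample-reflected boundaries, which conserve the image mean), then
bilinearly rescaled so one MRA spans 5 px; masks are rescaled
nearest-neighbour so labels stay integers. Defaults follow common practice
for small passerine predators: 6 cycles/degree and viewing distances of
500 and 1000 mm. The blur is applied to the whole image, not per-ROI, so
edge information mixes across the animal outline exactly as it would in
the predator's view. If the computed MRA is under 2 px the scene is
already at receiver resolution; the package warns and applies a minimal
blur rather than inventing detail. The exact blur kernel used by imaging
toolboxes is not published; the convention here is documented and the
parameters (`acuity_cpd`, `distance_mm`, `px_per_mra_target`) are all
exposed.

## Granularity analysis and pattern energy difference

Pattern is quantified by FFT bandpass filtering at octave-spaced scales
(default 2, 4, ..., capped at 1200 px or the image size) and measuring the
"energy" at each scale as the standard deviation of the filtered pixels
within the ROI. Filtering runs on the full image — masked-out pixels are
replaced by the mean of the labelled region first — so ROI boundaries do
not ring; only the measurement is restricted to the ROI. Pattern analysis
uses the luminance (double-cone) channel by default, reflecting the view
that avian pattern perception is double-cone mediated.

**Band construction.** Bands are differences of chained low-pass filters
whose half-power cutoff periods are geometrically centred on the scale
($s/\sqrt{2}$ and $s\sqrt{2}$ for multiplier 2), using super-Gaussian
(order 2) profiles, and the difference is taken in the power domain so the
filter bank is power-complementary: band variances telescope and sum to
the image variance (minus a small residual beyond the coarsest scale; the
finest band is completed to a residual high-pass). Three properties drove
this choice, all regression-tested: a pure sinusoid loads maximally — and
with most of its normalized mass — on the band matching its period; white
noise's band energies recover its total variance within a few percent; and
a constant image has zero energy everywhere. A chain with cutoffs at $s$
and $s/2$ (rather than geometrically centred) mislocates sinusoids by an
octave, and plain-Gaussian shoulders spread a sinusoid's mass over three
bands; both variants were rejected on those grounds.

**PED.** The pattern energy difference between two spectra is the summed
absolute difference across scales. The default compares *raw* energies.
The alternative — normalizing spectra to unit sum first — compares only
spectrum shape, and is available (`normalize = TRUE`, and a mean-per-scale
aggregate) but not default, for a mechanistic reason: the overall pattern
*amplitude* is part of the match. A high-contrast blotchy wing on a
high-contrast blotchy substrate agrees in both shape and amplitude; on a
faint striated substrate it differs mostly in amplitude, which unit-sum
normalization erases. Normalization also decouples PED from viewing
distance, whereas with raw energies acuity blur strips pattern energy from
both regions and PED falls with distance — the behaviour expected of a
perceptual pattern metric. On the synthetic suite the raw-energy default
separates matched from mismatched textures in essentially every replicate
and reproduces the distance effect; the normalized variant does neither
reliably. Published PED values from other toolchains may use either
convention, so outputs record which was used.

## Survival analysis

The predation module wraps the standard `survival` package behind a small
tidy surface: `km_fit()` (product-limit estimates with Greenwood errors),
`cox_fit()` (Efron ties by default — check-time data are heavily tied;
Breslow available and verified equal on tie-free data), and
`logrank_pairwise()` (BH-adjusted). Attack times are recorded as the check
time at which damage was observed, the usual field convention;
interval-censored likelihoods are out of scope. The reference treatment is
the alphabetically first level unless set, and outputs always name it.
Hand-computed product-limit, Greenwood and observed-minus-expected
log-rank oracles in the test suite guard the wrappers. A useful algebraic
fact, also tested: when censoring occurs only at study end, $S(\text{end})
= 1 - \text{events}/n$ and the Greenwood error reduces to the binomial
$\sqrt{p(1-p)/n}$ regardless of how events split across checks — which is
why end-of-study survival probabilities can be recomputed exactly from
published attack counts alone.

## The synthetic world

The generators state a world once and tests live with it:

- **Lichen / moth textures**: thresholded band-filtered Gaussian random
  fields; two tones $0.5 \pm \text{contrast}/2$ plus 3% speckle.
  Characteristic scale defaults to 32 px = 3.2 mm at the default
  10 px/mm — lichen-thallus-sized blotches. Contrast 0.8 (lichen) and 0.9
  (moth): both are high-contrast black-and-white patterns.
- **Bark**: the same construction stretched vertically (anisotropy 4) at a
  finer scale (8 px = 0.8 mm furrow texture) and low contrast (0.25) —
  plain bark is the drabber, finer, striated substrate.
- **Scenes**: 512×512 px at 10 px/mm; the moth is an ellipse of 22 mm
  span (a typical resting wingspan for the modelled species), aspect 0.6;
  label 1 = moth, 2 = background. Channels are per-channel affine maps of
  the grey texture, so chromatic offsets are set exactly and the
  identical-configuration case is a true null.
- **Predation data**: exponential attack times per treatment, recorded at
  the first check among 24/48/72 h, censored at 72 h, 100 replicates per
  treatment — the standard design of model-predation field experiments.

What a green test establishes: the *machinery* is correct (oracle
equalities, metric properties, parameter recovery, direction of the
pattern-matching and distance effects). What it does not: agreement with
any particular field study's absolute JND or PED values, which depend on
real photographs, measured sensitivities and toolbox-specific kernels none
of which are published to desk precision. The synthetic textures also lack
real-world features — illumination gradients, specularity, 3-D shadowing,
within-class reflectance variation — so effect *sizes* on synthetic scenes
are not predictions for real substrates.

## Numerical conventions and degenerate inputs

- Integration: trapezoid, common 1-nm grid; spectra must overlap.
- Ranking ties in `rank_spectral_match()` break by input order (stable
  sort), so results are deterministic.
- All generators are bit-reproducible under fixed seeds and restore the
  caller's RNG state.
- Empty ROIs, all-zero catches, non-overlapping spectra, single-treatment
  Cox fits and event-free Cox fits are errors, not NaNs.
- Zero-energy pattern spectra skip normalization and flag it.
- Output CSVs written by `write_results_csv()` carry the package version
  and a config fingerprint as comment lines.

## Known limitations

- No camera characterisation: the camera-to-receptor mapping must be
  supplied; RAW handling and white-standard detection are out of scope.
- Image I/O is plain-text (ASCII PGM masks, per-channel CSV): adequate for
  the scales involved here, but users with TIFF stacks should convert
  externally.
- Achromatic JNDs inherit the RNL caveat above.
- Mixed-effects inference on JND/PED tables is deliberately not included;
  `summarize_groups()` provides descriptive means ± SE and the tables are
  tidy for whatever modelling framework the user prefers.
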