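# camoquant

Quantifying background-matching camouflage through predator vision, and
relating it to predation outcomes in the field.

`camoquant` is an R package for the common workflow in sensory-ecology
studies of crypsis: a prey animal (say, a moth) is photographed or measured
spectrally against candidate backgrounds (lichen, bark, ...), its
conspicuousness is scored through the visual system of the relevant
predator (a tetrachromatic bird), and the camouflage metrics are compared
with survival of model replicates exposed to wild predators. The package
implements the full chain and ships a synthetic-data module, so the whole
pipeline runs end-to-end with no external data.

## What it computes

**Colour and luminance (receptor-noise-limited model).** Quantum catches
are `Q_i = ∫ R(λ) I(λ) S_i(λ) dλ` for reflectance `R`, illuminant `I` and
receptor sensitivity `S_i`, with optional von Kries normalisation by the
white-point catch. Discriminability between two stimuli uses the log-form
RNL model: with per-receptor contrasts `Δf_i = ln(Q_i^a / Q_i^b)` and Weber
fractions `ω_i`, the chromatic distance is

    ΔS² = min over c of Σ_i (Δf_i − c)² / ω_i²

which reduces to the published closed forms for di-, tri- and
tetrachromats (e.g. dichromat `ΔS = |Δf₁ − Δf₂| / √(ω₁² + ω₂²)`), and the
achromatic distance on the double-cone channel is
`ΔL = |ln(Q_D^a / Q_D^b)| / ω_D`. Both are in just-noticeable-difference
(JND) units; values below ~1 are conventionally indiscriminable. Weber
fractions scale from relative cone densities as `ω_i = ν √(η_max / η_i)`.

**Spatial acuity.** Gaussian acuity control: for a receiver with acuity
`a` cycles/degree viewing at distance `d`, the minimum resolvable angle is
`MRA = 1/a` degrees, spanning `2 d tan(MRA/2)` at the scene. Images are
blurred with a Gaussian of FWHM one MRA and rescaled to 5 px per MRA, so
everything below receiver resolution is removed before measurement.

**Pattern (granularity analysis).** Images are FFT-bandpass filtered at
octave-spaced scales (2, 4, ... up to 1200 px); the pattern energy at each
scale is the standard deviation of the filtered pixels within a region of
interest. The pattern energy difference (PED) between animal and
background ROIs is the summed absolute difference of their energy spectra
— low PED means good pattern matching.

**Survival.** Interval-checked predation data (attacked/censored at 24,
48, 72 h checks) are analysed with Kaplan–Meier estimates (Greenwood
errors), Cox proportional hazards (Efron ties; hazard ratios
`exp(coef)`), and pairwise log-rank tests with Benjamini–Hochberg
adjustment.

## Worked example

A high-contrast blotchy "moth" (characteristic scale 32 px ≈ 3.2 mm) is
composited onto a matching lichen-like background and onto a low-contrast
striated bark-like background, given a small chromatic offset, and scored
under a blue-tit-like receptor set at two viewing distances:

```r
library(camoquant)

recs  <- gen_receptor_set()                       # uv/sw/mw/lw + double cone
moth  <- texture_config("moth",   32, seed = 101)
lichen<- texture_config("lichen", 32, seed = 202)
bark  <- texture_config("bark",    8, seed = 303)
shift <- c(0.03, 0.01, 0, -0.02, 0.02)            # moth UV-bright, LW-dark

scene_l <- gen_scene(moth, lichen, moth_shift = shift)
scene_b <- gen_scene(moth, bark,   moth_shift = shift)

run_image_pipeline(list(
  list(image = scene_l$image, mask = scene_l$mask,
       specimen = "moth", background = "lichen"),
  list(image = scene_b$image, mask = scene_b$mask,
       specimen = "moth", background = "bark")), recs)
#>   specimen background distance_mm    dS    dL    ped n_scales
#> 1     moth     lichen         500 0.965 0.564 0.0504        7
#> 2     moth     lichen        1000 0.900 0.520 0.0183        6
#> 3     moth       bark         500 0.967 0.518 0.2718        7
#> 4     moth       bark        1000 0.902 0.464 0.0827        6
```

Colour and luminance barely differ between backgrounds (`dS` ≈ 0.97 on
both at 0.5 m), but the pattern metric separates them sharply: PED ≈ 0.05
on lichen versus ≈ 0.27 on bark, and both fall with viewing distance as
acuity loss removes pattern energy.

Survival of simulated model replicates (100 per treatment, exponential
hazards, checks at 24/48/72 h):

```r
ev <- gen_predation_dataset(predation_sim_config(
  c(bark = 0.0102, lichen = 0.0058, off_lichen = 0.0083), seed = 99))
surv <- run_survival_pipeline(ev)
surv$km_end
#>  treatment surv    se
#>       bark 0.45 0.050
#>     lichen 0.63 0.048
#> off_lichen 0.58 0.049
surv$cox
#> <cox_fit: reference = bark, ties = efron>
#>                  term    coef hazard_ratio     se      z        p
#> 1     treatmentlichen -0.5571       0.5729 0.2128 -2.618 0.008855
#> 2 treatmentoff_lichen -0.4482       0.6388 0.2051 -2.185 0.028876
#> Wald = 8.290 on 2 df, p = 0.0158
```

Being on lichen multiplies the attack hazard by 0.57 relative to bark —
models on the pattern-matched background survive best, mirroring the PED
result above.

## Acceptance script

`scripts/acceptance.R` rebuilds the predation experiment's event table
from its printed design (100 replicates per background; 52/45/35 attacked
on bark/off-lichen/lichen; censoring at 72 h), runs the survival pipeline,
and writes the recomputed Kaplan–Meier survival probabilities at 72 h to
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The `--seed` only controls how attacks are split across the 24/48/72 h
checks; the product-limit estimate at 72 h is invariant to that split.

## Layout

- `R/` — spectra & quantum catches, receptor sets, RNL JNDs, acuity
  control, granularity/PED, survival wrappers, synthetic generators,
  pipelines.
- `tests/testthat/` — unit, property and end-to-end suites (all fixtures
  generated in code).
- `vignettes/camouflage-quantification.Rmd` — methods and design notes.
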