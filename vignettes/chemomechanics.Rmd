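---
title: "Chemo-mechanical mapping of bone by Brillouin-Raman micro-spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemo-mechanical mapping of bone by Brillouin-Raman micro-spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brams)
```

## The measurement and the model

Correlative Brillouin-Raman micro-spectroscopy (BRmS) records, at every
pixel of a raster scan over a tissue section, two spectra of the same
scattering volume: a Brillouin spectrum (GHz frequency shifts of light
scattered by thermally excited acoustic waves) that reports mechanics, and a
Raman spectrum (cm^-1 vibrational shifts) that reports chemistry.

Bone tissue at the micro-scale is a two-phase composite. Brillouin spectra
of cortical and trabecular sections show two well-separated peaks in the
same scattering volume: a *soft* peak between 4 and 13 GHz, from the
disordered extracellular matrix, cells and marrow constituents, and a *hard*
peak between 13 and 32 GHz, from aggregates of mineralised collagen bundles.
This package implements the fit-free, moment-based decomposition of that
two-peak structure:

1. **Band spectral moments.** Each peak's shift is estimated by its first
   spectral moment over the band,
   $\bar\nu_B = \sum_i I_i \nu_i / \sum_i I_i$, with $i$ spanning the band's
   channels. A moment requires no lineshape model, which suits extremely
   heterogeneous pixels where a single-peak fit is ill-posed. The bands are
   contiguous at 13 GHz; the shared edge channel is assigned to the soft
   band ($[4, 13]$ closed, $(13, 32]$ half-open) so it is counted exactly
   once.

2. **Relative volume fractions.** Band intensities (trapezoidal integrals)
   are proportional to the amount of each elastic species in the scattering
   volume. Because the bone surface is rough, the illuminated volume's
   filling factor varies pixel to pixel; normalising the two
   efficiency-weighted band intensities to 100 % cancels it:
   $I_{soft} = 100\,(A_{soft}/r) / (A_{soft}/r + A_{hard})$, where $r$ is
   the soft-vs-hard scattering-efficiency ratio (`efficiencyRatio`, default
   1 — the study-specific coefficient is not published, so the package
   exposes it as a single configurable scalar).

3. **Longitudinal modulus.** In backscattering the modulus follows from the
   shift as $M = \nu_B^2 \lambda^2 \rho / (4 n^2)$. The density and
   refractive index enter only through $\kappa = \rho/n^2$, held constant
   across the tissue at 1.29 g/cm^3 (configurable; the conversion divides by
   $n^2$, so the constant is carried in exactly the form the equation
   consumes). `longitudinalModulus()` tracks every unit explicitly (GHz to
   s^-1, nm to m, g/cm^3 to kg/m^3) and returns GPa; it is exactly
   quadratic in the shift.

4. **Voigt average.** The pixel's composite stiffness is the
   fraction-weighted arithmetic mean
   $M_{avg} = (I_s M_s + I_h M_h)/(I_s + I_h)$ — the iso-strain (Voigt)
   upper bound — bounded by the two phase moduli and invariant under common
   rescaling of the fractions.

On the Raman side the pipeline is: iterative polynomial baseline removal
(fluorescence), normalisation to the CH2 wagging band at 1445 cm^-1, then
three markers — the mineral-to-matrix ratio $I(965)/I(860)$
(phosphate vs proline, collagen mineralisation degree), the first moment of
the CH2-CH3 band (2800--3100 cm^-1; lipids at 2872 cm^-1 pull it down,
proteins at 2935 cm^-1 up), and the first moment of the heme-amide band
(1500--1720 cm^-1; hemoglobin at 1580 cm^-1 pulls it below the amide I
position, flagging red-marrow regions).

```{r single-pixel}
cfg <- analysisConfig()
truth <- pixelTruth(nuSoft = 6.87, nuHard = 18.6, fracSoft = 34)
sb <- simulateBrillouinSpectrum(truth)
extractBrillouinFeatures(sb, cfg)
```

## Tunable parameters

All knobs live in one validated `AnalysisConfig` object (YAML round-trip via
`readConfig()`/`writeConfig()`):

| parameter | default | units | role |
|---|---|---|---|
| `softRange`, `hardRange` | (4, 13), (13, 32) | GHz | moment/intensity bands |
| `lambdaLaser` | 532 | nm | excitation wavelength in the modulus conversion |
| `kappa` | 1.29 | g/cm^3 | $\rho/n^2$, constant across the tissue |
| `efficiencyRatio` | 1 | — | soft-vs-hard scattering efficiency |
| `backgroundSubtract` | off | — | constant Brillouin background (median outside both bands) |
| `baselineOrder`, `baselineIters` | 5, 50 | — | fluorescence baseline polynomial |
| `refWavenumber`, `refWindow` | 1445, 10 | cm^-1 | normalisation reference window |
| `mineralPeak`, `prolinePeak`, `peakWindow` | 965, 860, 8 | cm^-1 | marker peaks; "intensity" is the window maximum |
| `fingerprintRange` | (800, 1780) | cm^-1 | PCA region |
| `chBand`, `hemeBand` | (2800, 3100), (1500, 1720) | cm^-1 | moment markers |
| `autoscale` | off | — | PCA pretreatment (centering always on) |
| `separationThreshold` | 2 | SD | when a component "divides" groups |

Choices worth spelling out:

* **Peak "intensity" is a window maximum**, not a fitted area: it matches
  intensity-ratio usage and tolerates small calibration shifts between
  instruments; the half-width (8 cm^-1) is below the closest
  marker-neighbour separation.
* **Baseline removal** is the iterative clipping polynomial: fit an
  order-5 polynomial, replace intensities above the fit by the fit, refit
  until the fit changes by less than 1e-6 (relative) or 50 iterations. The
  basis is orthogonal (`stats::poly`) so the fit stays conditioned on axes
  spanning thousands of cm^-1. The clip-refit map contracts slowly on
  peak-dense spectra, so every third step the implementation advances the
  fit by a geometric-series extrapolation of its increments (accepted only
  when the estimated contraction factor lies in (0, 1)); this reaches the
  same fixed point about an order of magnitude sooner and keeps the
  iteration cap from truncating convergence. Negative residuals are clipped
  at zero because they would otherwise enter moment weights.
* **PCA** is the column-mean-centred SVD (`stats::prcomp`), with optional
  unit-variance autoscaling off by default: mean centering alone is the
  pretreatment under which the normalised fingerprint spectra classify
  best. Loadings follow a deterministic sign convention (largest-magnitude
  weight positive) so results are reproducible across platforms. When a
  component's separating direction matters — e.g. "which channels
  characterise the group this component isolates" — orient the component
  toward that group's score mean first; the sign convention alone fixes
  only an arbitrary overall flip.
* **Missing features are `NA`, never zero.** An empty band, a failed
  normalisation or a zero proline peak flags the pixel's affected features;
  masked cells are excluded from every ROI statistic. ROI "±" values are
  reported as the standard error of the mean.

## What the synthetic phantoms emulate

No raw maps from the motivating study are publicly available, so the
package ships a first-class generator that every stage is tested against.

**Brillouin.** Each pixel's spectrum is two Lorentzian peaks on a 2--35 GHz
axis (0.05 GHz channels), with per-pixel positions, widths (default FWHM
0.2 GHz), fractions and an optional constant background. Two deliberate
idealisations:

* Each peak is rendered only within its own analysis band and normalised to
  unit in-band trapezoidal area, so the configured `fracSoft` is *exactly*
  the efficiency-weighted in-band area fraction the analysis estimates.
  Real Lorentzian tails leak between bands — a hard peak at 18.6 GHz with
  FWHM 1.5 GHz would put ~5 % of its area below 13 GHz — and the moment
  method absorbs that leakage as a bias it cannot distinguish from signal.
  The phantom instead emulates the two-phase separability the method
  assumes, which is the property a ground-truth recovery test needs.
* The default width keeps the one bias that remains — the moment of an
  asymmetrically truncated peak is pulled toward the far band edge — within
  ±0.04 GHz at the worst peak positions the phantoms use (the bias grows
  roughly linearly with FWHM: ~0.05 GHz at 0.25--0.3 GHz width). Widths are
  per-pixel configurable for users who want to study that bias.

**Raman.** Spectra are weighted sums of five component templates (mineral
965/1030/1068; collagen and other proteins 860/870/1003/1242/1445/1660/2935;
lipid 1298/1445/1745/2872; heme 1170/1580; carotenoid 1130/1155 cm^-1),
Lorentzian bands of 10--25 cm^-1 width on a 1 cm^-1 axis, plus a quadratic
fluorescence baseline scaled to the template maximum.
`templateRamanFeatures()` evaluates the markers directly on the noiseless,
baseline-free template — the ground truth the full pipeline is expected to
recover.

**Noise** is Poisson on the whole spectrum, parameterised by a target peak
signal-to-noise ratio: the expected counts at the strongest channel are
`snr^2` (photon-counting statistics), and `snr = 0` means noiseless.

**Phantoms.** The cortical phantom embeds two elliptical vessel channels
(soft-dominated, lipid-rich, mineral-poor) in a mineralised lamellar matrix;
the trabecular phantom alternates spicule bands (hard phase at lower shifts
than cortical matrix) with marrow bands randomly labeled yellow (lipid-rich)
or red (heme-rich, lowest soft shifts). The study fixture emits six
homogeneous ROIs whose per-pixel parameters jitter (SD 0.02 GHz on shifts,
1.5 points on fractions, 10 % on weights) around means taken from the
published ROI moduli: shifts inverted through the modulus conversion and
fractions from the Voigt relation
$I_s = (M_{hard} - M_{avg}) / (M_{hard} - M_{soft})$, giving 33.9 % / 10.2 %
(cortical frozen/fixed), 61.8 % / 24.7 % (trabecular), and 20.3 % / 67.3 %
in the epiphyseal cortical/trabecular ROIs. Fixation multiplies the soft
shift by $\sqrt{1.34}$ (cortical) and $\sqrt{1.37}$ (trabecular), depletes
the soft fraction by 70 % and 60 %, and strips lipid and heme from the
composition; the epiphyseal trabecular marrow is heme-enriched where the
diaphyseal one is lipid-dominant.

What passing the recovery tests does **not** show: the phantoms have no
inter-band tail leakage, no cosmic-ray spikes, no wavelength-calibration
drift, no anti-Stokes/quasi-elastic structure, no spatial correlation of
noise, and Lorentzian lineshapes throughout. Performance on real
instrument output will be correspondingly less clean, especially for the
soft-band moment when the hard peak is broad.

```{r phantom}
ph <- generatePhantom("cortical", shape = c(8, 8), seed = 11)
fm <- mapFeatures(ph$map)
vessel <- ph$truth$region == "vessel"
t(vapply(c("I_soft", "M_avg", "mineral_to_matrix"), function(f) {
  v <- featureMatrix(fm, f)[cbind(ph$truth$row, ph$truth$col) + 1L]
  c(matrix_mean = mean(v[!vessel]), vessel_mean = mean(v[vessel]))
}, numeric(2)))
```

## Numerical choices and degenerate inputs

* Moments include both band edges; for the contiguous 4/13/32 GHz split the
  hard band opens at 13 so the edge channel is never double-counted.
* `bandIntensity()` uses the trapezoidal rule; a single in-band channel has
  zero area by that rule, so fraction estimates need at least two channels
  per band (the default axes have 180 and 380).
* An all-zero band yields `NA` moments (distinct from 0); both-zero band
  areas yield `NA` fractions rather than an arbitrary 0/100 split.
* Text formats write 6 significant digits — below every stated tolerance —
  and read back as absent (`NA`) any pixel/modality that was absent, never
  as zero.
* Grid coordinates in files are 0-based pixel indices; stage positions in
  micrometres follow from `origin + index * step` (default step 3 µm).
* PCA rank is judged against the data's own magnitude, so a constant matrix
  reports zero explained variance for every component instead of amplifying
  rounding noise; requesting more components than the rank warns and
  truncates.

## Problem sizes used by the tests

The suite validates recovery on a 32 x 32 noiseless cortical phantom
(per-pixel: shifts ±0.05 GHz, fractions ±1 point, moduli ±2 %, CH moment
±2 cm^-1, mineral ratio ±5 % of template truth), fraction recovery at
Poisson SNR 50 (median error ≤ 2 points over 1024 pixels), moment oracles on
1000 random spectra, and the six-ROI study fixture at 8 x 8 pixels per ROI —
sizes at which the full suite completes in well under a minute while leaving
every tolerance meaningfully exercised.

## Known limitations

* The scattering-efficiency coefficient is a single scalar with default 1;
  the study-specific value is unpublished, so absolute fraction maps are
  only as good as that calibration.
* $\kappa = \rho/n^2$ constant across tissue is an approximation the method
  inherits; mineral-rich and marrow-rich pixels surely differ somewhat.
* The moment estimator is biased for peaks within ~3 FWHM of a band edge or
  for broad peaks with heavy cross-band tails; the package deliberately
  does not fit lineshapes (a non-goal of the moment-based design).
* ROI comparisons report percent changes and SEMs, not hypothesis tests.
* Hydroxyapatite crystallinity (`crystallinity()`, FWHM of the 965 cm^-1
  band) is provided as an optional marker but excluded from the default
  feature set.
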