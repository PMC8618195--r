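# brams — chemo-mechanical analysis of Brillouin–Raman micro-spectroscopy maps

Correlative Brillouin–Raman micro-spectroscopy (BRmS) scans a tissue section
on a micrometre grid and records, at every pixel, a Brillouin spectrum (GHz
shifts — mechanics) and a Raman spectrum (cm⁻¹ shifts — chemistry) of the
same scattering volume. In lamellar bone the Brillouin spectrum shows two
well-separated peaks: a *soft* band (4–13 GHz) from the disordered
extracellular matrix, cells and marrow, and a *hard* band (13–32 GHz) from
mineralised collagen bundles. `brams` implements the moment-based two-phase
analysis of such maps for spectroscopists and bone-tissue researchers who
want a tested, scriptable version of the workflow.

Per pixel, the package computes:

- band centres as first spectral moments, ν̄ = Σᵢ Iᵢνᵢ / Σᵢ Iᵢ (fit-free,
  robust on heterogeneous pixels);
- relative volume fractions `I_soft`/`I_hard` from efficiency-weighted band
  intensities normalised to 100 % (cancelling the rough-surface filling
  factor);
- longitudinal elastic moduli M = ν²λ²ρ/(4n²), with ρ/n² = 1.29 g/cm³ held
  constant across the tissue (configurable), returned in GPa;
- the Voigt-averaged composite modulus
  M_avg = (I_s·M_s + I_h·M_h)/(I_s + I_h);
- Raman markers after polynomial fluorescence-baseline removal and
  normalisation to the 1445 cm⁻¹ CH₂ band: the mineral-to-matrix ratio
  I(965)/I(860), the CH₂–CH₃ band moment (2800–3100 cm⁻¹,
  lipid-to-protein balance) and the heme–amide band moment
  (1500–1720 cm⁻¹, red-marrow marker).

Feature maps feed ROI statistics (mean/SD/SEM/quartiles/histograms),
percent-change comparisons between ROIs, and PCA of the 800–1780 cm⁻¹
fingerprint region for classification. A synthetic cortical/trabecular
tissue-phantom generator with per-pixel ground truth makes every stage
testable end to end; see the methods vignette
(`vignettes/chemomechanics.Rmd`) for the model, parameter defaults and the
phantom's idealisations.

## Worked example

Simulate a 16 × 16 cortical phantom (mineralised matrix with two embedded
vessel channels), extract all features, and compare a matrix region against
a vessel-containing region:

```r
library(brams)
cfg <- analysisConfig()

longitudinalModulus(10)      # 10 GHz shift -> 9.127524 GPa

ph <- generatePhantom("cortical", shape = c(16, 16), seed = 42)
fm <- mapFeatures(ph$map, cfg)

sa <- roiStatistics(fm, roi("matrix_top", 0, 4, 0, 16), cfg)
sb <- roiStatistics(fm, roi("vessels",    6, 11, 2, 8), cfg)
compareROIs(sa, sb, c("M_avg", "I_soft", "mineral_to_matrix", "ch_moment"))
```

```
            feature   mean_a   sem_a  mean_b  sem_b pct_change pct_change_rounded
1             M_avg   22.592 0.11902   16.68 1.2337    -26.182                -26
2            I_soft   33.762 0.43474   54.13 4.3136     60.322                 60
3 mineral_to_matrix    3.351 0.04488    2.22 0.2731    -33.741                -34
4         ch_moment 2932.066 0.13017 2917.08 3.1476     -0.511                 -1
```

Read: the vessel-containing ROI has a 26 % lower average modulus, a 60 %
higher soft-phase fraction, a third less mineral relative to collagen, and a
CH band shifted toward the 2872 cm⁻¹ lipid line — the chemo-mechanical
signature of Haversian channels against lamellar matrix. `mean ± sem` are
over unmasked ROI pixels; percent changes are signed, with the
integer-rounded convention in the last column.

The same pipeline runs from a shell via the thin CLI:

```sh
Rscript inst/cli/brams.R simulate --tissue cortical --rows 16 --cols 16 \
    --seed 42 --out simdir
Rscript inst/cli/brams.R extract --in simdir/map.tsv --out features.tsv
Rscript inst/cli/brams.R pca --in mapA.tsv,mapB.tsv --components 3 --out pca
```

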