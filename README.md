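# memphys

Quantitative analysis of plasma-membrane biophysics experiments that
compare control cells with glycosphingolipid-enriched (Gaucher-model)
cells, together with a ground-truth synthetic-data generator that makes
every analysis stage testable by parameter recovery.

Glycosphingolipid accumulation changes the physical state of the plasma
membrane: ordered (raft-like, high Laurdan GP) domains grow, lateral
mobility of non-raft components drops, the cell softens, membrane
nanotubes (tethers) form more readily, and membrane-linked processes such
as transferrin endocytosis and STAT1 signaling slow down. Measuring these
effects requires five quite different quantitative pipelines, all of which
this package implements:

| Measurement | Model / estimator | Functions |
|---|---|---|
| FRAP recovery | double normalization R(t) = [(I−bg)/(I₀−bg₀)]·[(T₀−bg₀)/(T−bg)]; fit of R(t) = R(0) − a + a(1−b)(1−e^(−t/τ)) with immobile fraction b | `doubleNormalize`, `averageCurves`, `fitRecovery` |
| Fluorometry | anisotropy r = (Ivv − G·Ivh)/(Ivv + 2G·Ivh); Laurdan GP = (I_blue − I_red)/(I_blue + I_red) | `anisotropy`, `generalizedPolarization` |
| GP imaging | per-pixel GP map; high/low-order segmentation at one shared (pooled-Otsu) threshold; high-GP area fraction | `gpMap`, `pooledGpThreshold`, `segmentGpDomains` |
| AFM | contact-point detection; pyramidal-tip Hertz fit F = E/(1−ν²)·tanα/√2·δ²; dual-algorithm tether step detection with consensus; tether force/count statistics; 25-bin modulus-height profile | `findContactPoint`, `fitHertz`, `detectSteps`, `tetherStatistics`, `modulusHeightProfile` |
| Cell images | marker-controlled watershed nuclei; nucleus-seeded watershed cells with inward-thickened membrane ring; per-cell endocytosed and nuclear intensity fractions | `detectNuclei`, `segmentCells`, `endocytosedFraction`, `nuclearFraction` |

The generator (`makePreset`, `simulateFrapRecord`, `simulateForceCurve`,
`simulateGpImage`, `simulateCellField`) emits each modality with known
ground truth; the built-in `"control"` and `"gaucher"` presets encode the
published condition values (tether force medians 30/27 pN, tether counts
4.8 ± 2.4 / 11.1 ± 4.3, modulus median 614/459 Pa, high-GP area 13%/48%,
transferrin endocytosis 60%/30%, a 3-fold immobile-fraction difference).

## Worked example

```r
library(memphys)

ctrl <- makePreset("control")
ctrl
#> MemPreset 'control' (ligand: transferrin)
#>   frap: a=0.60 b=0.15 tau=10.0s noise=0.020
#>   afm:  E median/mean 614/1031 Pa, tethers 4.8+/-2.4, force median 30 pN
#>   gp:   high-GP fraction 0.13 (levels -0.60 / -0.90)
#>   endo: f_endo 0.60, 100 cells

## FRAP: simulate 10 noisy records, normalize, average, fit
curves <- lapply(1:10, function(s)
  doubleNormalize(simulateFrapRecord(ctrl, seed = s)))
fitRecovery(averageCurves(curves))
#> FrapFit (R0 fixed to pre-bleach mean)
#>   R0 = 1.0003
#>   a   = 0.5980  [95% CI 0.5864, 0.6096]
#>   b   = 0.1475  [95% CI 0.1392, 0.1559]
#>   tau = 9.8024  [95% CI 9.4642, 10.1406]

## AFM: Hertz fit and tether steps on one simulated curve
fc <- simulateForceCurve(ctrl, seed = 1)
youngsModulus(fitHertz(fc))      # 440.4727 -- the curve's true E is 440.4727 Pa
detectSteps(fc)
#> StepEvents (consensus): 8 steps, heights 21.5-61.6 pN (median 27.6)  [algA: 8, algB: 12]
```

The FRAP fit recovers the preset's generating parameters (a = 0.6,
b = 0.15, τ = 10 s) within its confidence bounds; the Hertz fit returns
the modulus the curve was generated with; the step detector finds all 8
simulated tether ruptures.

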