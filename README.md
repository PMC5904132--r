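# rhenet

Single-trial EEG analysis of error versus correct responses at the cortical
level, for researchers studying error monitoring and for BCI work that needs
a per-trial error signal. The package implements, end to end:

1. **Preprocessing** — amplitude-criterion trial rejection (±75 µV),
   zero-phase 0.1–30 Hz band-pass, average or REST re-referencing, and
   decomposition into theta (4–8 Hz), alpha (8–13 Hz) and beta (13–30 Hz)
   bands.
2. **Weighted minimum-norm source estimation** — per trial and band,
   S(t) = W x(t) with W = R Aᵀ(A R Aᵀ + λ²C)⁻¹ and
   λ² = trace(A R Aᵀ)/(trace(C)·SNR²) at an assumed SNR of 5.
3. **Rhythm entropy** — per trial and dipole, the Shannon entropy (bits) of
   the normalized theta/alpha/beta band-power proportions,
   iEn = −Σᵢ Pᵢ log₂ Pᵢ ∈ [0, log₂ 3].
4. **Discriminative dipole selection** — per-dipole
   R² = (E X₊₁ − E X₋₁)²/(4σ²) with threshold at a fraction (default 0.6)
   of the maximum, a threshold sweep, and identity back-projection to the
   full dipole space.
5. **Classification** — class-balanced RBF-SVM under leave-one-out
   cross-validation, C from a 21-value grid 10⁻⁸…10⁸ (step 10⁰·⁸) by nested
   grid search; accuracy, sensitivity, specificity and AUC.
6. **Time-varying directed networks** — Kalman-fitted time-varying
   multivariate autoregressive models (order by SBC), the normalized
   adaptive directed transfer function
   ι²ᵢⱼ(f,t) = |Hᵢⱼ(f,t)|²/Σₖ|Hᵢₖ(f,t)|², integrated over 4–30 Hz, with
   phase-randomization surrogate significance (200 shuffles, per-edge 95th
   percentile).
7. **Association statistics** — Pearson correlations of reaction time with
   entropy and with degree-adjusted edge strength; paired t-tests of
   entropy between classes.

Since raw recordings of this kind are not publicly deposited, the package
ships a synthetic-EEG generator with known ground truth (active dipoles,
per-class band-power proportions, directed couplings, leadfield) used by
the test suite to validate the whole chain: chance-level behavior when the
classes are identical, high accuracy and correct dipole recovery when they
differ, calibrated surrogate false-positive rates, and exact agreement of
the closed-form operators with independent oracles.

## Worked example

```r
library(rhenet)

cfg <- runConfig(sim = simConfig(seed = 7), nSurrogates = 200)
res <- runPipeline(cfg, outDir = "run7")

res$eval
#> EvalResult (LOOCV RBF-SVM): CA = 1.000, SE = 1.000, SP = 1.000, AUC = 1.000
#>   confusion: TP=20 TN=20 FP=0 FN=0

res$r2map
#> R2Map: 64 dipoles, max R2 = 0.9888, threshold frac = 0.6, 3 selected
selectedDipoles(res$r2map)
#> [1] 10 32 54
selectedDipoles(res$truth)      # planted active dipoles
#> [1] 10 32 54

res$truth
#> GroundTruth: active dipoles {10, 32, 54}; class entropy error = 0.922, correct = 1.585 bits
tapply(rowMeans(featureValues(res$features)[, selectedDipoles(res$r2map)]),
       trialLabels(res$features), mean)
#>     error   correct
#> 0.9094227 1.5718979

res$networks$error
#> TVNetwork: 3 nodes x 175 time points, band 4-30 Hz
#>   surrogate thresholds present (95th percentile)
```

The generator plants a lower-entropy band mixture (0.8, 0.1, 0.1 → 0.922
bits) in the error trials' active dipoles and a uniform mixture (1.585
bits) in the correct trials'. The run above recovers exactly the three
planted dipoles, separates the classes perfectly under LOOCV on this
dataset, and reproduces the planted entropy ordering at the selected
dipoles (0.91 vs 1.57 bits against the analytic 0.92 vs 1.585). Stage
outputs (features, selection, metrics, network edge trajectories, stats,
manifest) are written to `run7/`.

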