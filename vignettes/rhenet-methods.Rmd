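---
title: "rhenet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rhenet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rhenet` implements a single-trial EEG analysis chain that separates
erroneous from correct responses at the cortical level and then asks how the
discriminative regions exchange information over time. This vignette is the
package's account of the science: the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not show.

## The analysis chain

**Preprocessing.** Epoched scalp EEG (trials x channels x samples, in
microvolts) is cleaned by an amplitude criterion (default +/-75 uV: any trial
whose absolute amplitude exceeds the threshold on any channel is dropped),
band-pass filtered to 0.1--30 Hz, and re-referenced. Both an average
reference and a REST-style reference (reconstruction toward a reference at
infinity through a leadfield) are available; REST first average-references
the data, estimates sources with the pseudoinverse of the average-referenced
leadfield, and rebuilds potentials against the infinity-referenced
leadfield.

All filters are zero-phase. They are implemented by applying the *squared
magnitude response* of a Butterworth design spectrally -- exactly the gain a
forward-backward (`filtfilt`) pass realizes, with literally zero phase error
and no edge transients, and vectorizable across channels. The broadband
filter cascades a 2nd-order high-pass at 0.1 Hz with a 4th-order low-pass at
30 Hz (a single band-pass design with a passband edge at 0.0008 of Nyquist
is numerically fragile). The rhythm decomposition uses 4th-order band-pass
designs for theta (4--8 Hz), alpha (8--13 Hz) and beta (13--30 Hz). A
wavelet decomposition would serve equally here: the downstream feature
depends only on band powers, and the Butterworth bands are deterministic and
analytically checkable, which is why they are the default and only
implementation.

**Source estimation (WMNE).** Cortical activity is estimated per trial and
band by the weighted minimum-norm inverse

$$ S(t) = W x(t), \qquad W = R A^\top (A R A^\top + \lambda^2 C)^{-1}, $$

with gain matrix $A$ (channels x dipoles), source covariance $R$ (identity
by default; optional depth weighting by inverse squared column norms), noise
covariance $C$ (identity by default) and

$$ \lambda^2 = \frac{\mathrm{trace}(A R A^\top)}{\mathrm{trace}(C)\,\mathrm{SNR}^2}, $$

at an assumed amplitude SNR of 5, the conventional value for evoked
responses. The operator is built with a symmetric solve rather than an
explicit inverse and is data independent under the identity-covariance
default, so it is computed once per dataset and reused across trials and
bands. How $C$ should be estimated per recording is left open by the method;
identity is the stand-in and both covariances are arguments.

**Rhythm entropy.** For each trial and dipole, the band power is the sum of
squared source amplitudes over the analysis window (no sub-windowing; the
window is the 700 ms epoch). The three band powers are normalized to
proportions $P_i$ and the feature is the Shannon entropy in bits,
$-\sum_i P_i \log_2 P_i$, with the continuity convention
$0 \log 0 = 0$. The feature ranges from 0 (all power in one rhythm) to
$\log_2 3 \approx 1.585$ (uniform spread), is invariant to amplitude
scaling, and is symmetric in the bands. Trials with all-zero band power at
some dipole are degenerate; they are excluded and logged, never imputed.

**Discriminative dipole selection.** Separability per dipole is scored by

$$ R^2 = \frac{(\mathbb{E}X_{+1} - \mathbb{E}X_{-1})^2}{4 \sigma_X^2}, $$

where $\sigma_X$ is the *population standard deviation of the pooled
two-class sample* -- with the factor 4 this makes $R^2$ the squared
point-biserial correlation between feature and class tag at equal class
sizes, matching its interpretation as a feature--label correlation (the
choice of sample for $\sigma_X$ was genuinely open). Dipoles at or above a
fraction of the maximum $R^2$ (default 0.6) are selected; the argmax always
qualifies, so selection is never empty. A sweep over fractions 0.1..1.0
reports LOOCV accuracy per fraction, breaking ties toward the smallest
fraction (fewest assumptions). Selected-space values are back-projected to
the full dipole space through an identity placement (zeros elsewhere).
Thresholding is per dataset; whether a single global threshold should be
shared across datasets is exposed as a choice for the user
(`perFoldSelection`, `thresholdFrac`).

**Classification.** A radial-basis SVM with the penalty grid
$C \in \{10^{-8}, 10^{-7.2}, \ldots, 10^{8}\}$ (21 values) is evaluated by
leave-one-out cross-validation on class-balanced data (the majority class is
randomly subsampled to the minority count, seeded). Design choices worth
stating:

* *Nested grid search.* The placement of the grid search relative to LOOCV
  is ambiguous in common practice; the default searches $C$ by an inner
  stratified 5-fold CV inside every training fold, avoiding selection
  leakage. A non-nested mode (one grid search on all data, then LOOCV) is
  available for comparison.
* *Grid-search ties* break toward the $C$ nearest 1 in log distance (the
  conventional default penalty). On null data all grid points tie
  frequently; breaking toward an extreme $C$ would produce a degenerate
  majority-vote classifier.
* *Per-fold balancing.* Leaving one trial out of a balanced design leaves
  the training fold imbalanced by one trial. This is not cosmetic: on
  label-free data, plain LOOCV measured a mean accuracy of 0.36 (the
  held-out trial's class is always the training minority) and
  inverse-frequency class weights overcorrected to 0.61. The default
  therefore drops one seeded random opposite-class trial from each training
  fold, which restores chance-level behavior (0.53 +/- 0.02 measured over 30
  null replicates). This extends the method's own random-subsampling class
  balancing to the fold level.
* *Per-fold selection.* Dipole selection is recomputed from the training
  fold inside every LOOCV fold by default (again avoiding leakage); a
  select-once mode exists.
* The RBF width defaults to $\gamma = 1/(p \cdot \overline{\mathrm{var}})$
  on standardized training features; features are standardized with
  training-fold statistics.

Performance is summarized by accuracy, sensitivity and specificity from the
pooled held-out confusion counts, and by the AUC computed from pooled signed
decision scores as the tie-corrected normalized Mann--Whitney statistic.

**Time-varying directed networks.** Node series are region-averaged cortical
waveforms of the discriminative dipoles, estimated from trial-averaged ERPs.
The time-varying VAR

$$ X(t) = \sum_{k=1}^{p} w(k, t) X(t-k) + \varepsilon(t) $$

is tracked by a Kalman filter (RLS form with a shared state covariance,
random-walk state noise scaled by the update coefficient `uc`, and an EWMA
estimate of the innovation variance). The order $p$ is selected by the
Schwarz Bayesian criterion from stationary least-squares fits on a common
sample. The spectral coefficient matrix uses the identity lag-0 convention,
$A(f,t) = I - \sum_k w_k(t) e^{-i 2\pi f k \Delta t}$, so the zero-coupling
case yields $H = A^{-1} = I$ (without the identity term $H$ would be
undefined for the trivial system). The normalized ADTF

$$ \iota^2_{ij}(f,t) = \frac{|H_{ij}(f,t)|^2}{\sum_k |H_{ik}(f,t)|^2} $$

sums to 1 over senders $j$ for each receiver $i$, frequency and time; the
band-integrated ADTF is its *mean* over the 1 Hz-spaced bins inside 4--30 Hz
(a literal sum divided by $f_2 - f_1$ with an inclusive grid would exceed
the mean by one bin's worth and can leave $[0,1]$, so the mean is used, and
bounds are asserted). The Kalman filter and the ADTF loops are implemented
in C++ (RcppArmadillo); a composed R path
(`transferFunction()` -> `adtfNormalize()` -> `integrateAdtf()`) exists and
the two are tested for exact agreement.

Numerical defaults: `uc = 1e-3` (stable results over `1e-4`..`1e-2` in the
sensitivity checks run during development -- coefficient recovery and edge
ranking do not change qualitatively across that range); frequency grid 1 Hz
from 1 to Nyquist; burn-in `max(50, 5p)` time points excluded from
summaries and significance.

**Surrogate significance.** The null of no directed coupling is built by
Fourier phase randomization applied independently per node: magnitudes are
kept exactly (Hermitian symmetry preserved, DC and Nyquist untouched), so
each node's autospectrum survives while cross-node phase relations are
destroyed. The full pipeline (Kalman fit, transfer function, normalized and
integrated ADTF) runs on each of 200 surrogates. Per directed edge, the
surrogate values are pooled across retained time points and the 95th
percentile is the threshold; a per-time-point mode is available. Under a
no-coupling null this calibrates to a ~5% edge-time false-positive rate.

**Association statistics.** Pearson correlations (reaction time vs entropy,
reaction time vs degree-adjusted edge strength) and paired t-tests (error vs
correct entropy) with Cohen's $d$ for the paired contrast. "Weighted degree"
is taken as a node's total incident strength (incoming plus outgoing,
diagonal excluded) at the time point; in-only and out-only variants are
options. Identical paired vectors have zero-variance differences and are
rejected as degenerate rather than reported as $t = 0$. No multiple-testing
correction is applied; reports state the number of tests. Group-level use
expects per-subject summaries (one pair per subject); at single-dataset
scale the pipeline reports per-trial correlations and labels them as such.

## The synthetic generator

There is no public accession for the kind of recordings this method was
designed for, so validation runs on a generator that emulates exactly the
statistical structure the pipeline claims to detect:

* a known leadfield: random mixing with spatially correlated rows (a
  Gaussian kernel over a 1-D channel axis plus an equal-weight independent
  component, keeping the matrix well conditioned), unit-norm columns, full
  row rank enforced;
* two trial classes whose *active dipoles* differ only in theta/alpha/beta
  power proportions -- by default (0.8, 0.1, 0.1) for error trials
  (analytic entropy 0.922 bits) vs uniform for correct trials (1.585 bits),
  matching the direction of the reported effect (lower entropy on errors);
* band components generated by ideal zero-phase spectral masks, so
  empirical band powers equal the configured proportions exactly and the
  generator is analytically checkable;
* inactive dipoles carrying broadband 4--30 Hz background at 10% of the
  active amplitude (selection stays nontrivial without swamping the
  signal);
* white sensor noise scaled so scalp signal power over noise power equals
  the configured SNR (default 10);
* reaction times from truncated normals (floor 100 ms), error
  650 +/- 120 ms vs correct 500 +/- 100 ms -- the direction (error slower)
  is what the literature reports; the magnitudes are plausible round
  numbers;
* optionally, coupled node series from a stable VAR with known directed
  edges for the connectivity stage.

Default geometry is 48 channels x 64 dipoles at 250 Hz with 0.7 s epochs
and 20 trials per class (the minimum error-trial count the method assumes).
This is a desk-scale montage chosen so that the inverse problem stays
underdetermined (more dipoles than channels) while inverse crosstalk stays
below the selection threshold: with too few channels the estimated activity
at *inactive* dipoles inherits enough class-structured crosstalk from the
active ones to pass the 0.6 R-squared cut, and selection then recovers a
superset of the planted dipoles. Crosstalk-driven discriminability is real
physics of linear inverses, and on sparser montages the selection should be
read as "discriminative", not "active".

What the generator does *not* emulate: realistic head geometry or BEM
physics, ERP waveform morphology (no N1/P3 shapes), ocular artifacts,
correlated sensor noise, inter-subject variability. Passing the end-to-end
checks therefore shows that the chain recovers planted band-structure
contrasts through volume conduction and noise -- not that it reproduces any
particular empirical dataset.

## Validation problem sizes

The test-suite checks run at sizes chosen to make their statistics
meaningful while staying desk-scale: chance control and separability each
use 20 replicate datasets of 20+20 trials (pooling 800 held-out
predictions); localization uses 50 single-dipole draws on fresh leadfields;
the chain-recovery benchmark uses 50 seeds of a 3-node VAR at 2000 samples;
surrogate calibration uses 20 null datasets of 1200 samples with 200
surrogates each; type-I calibration uses 2000 null replicates. The
acceptance script reruns the same computations at moderately smaller
replicate counts (its JSON records the `n` used for each number).

## Known limitations

* The inverse stage smears sources: entropy contrasts at active dipoles are
  compressed toward uniform relative to the analytic values, and selection
  occasionally includes crosstalk neighbors. This is inherent to linear
  distributed inverses, not a defect of the feature.
* LOOCV accuracy on 40 trials has high variance (SD across replicate
  datasets ~0.05--0.1); single-dataset accuracies should not be
  over-interpreted.
* The Kalman tracker assumes slowly varying coefficients; `uc` trades
  tracking speed against estimator variance, and abrupt coefficient jumps
  are smoothed.
* Surrogate thresholds pool over time by default; genuinely nonstationary
  null statistics would argue for the per-time-point mode at higher
  surrogate counts.
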