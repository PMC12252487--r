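---
title: "Detecting slow-paced-breathing relaxation from HRV with fuzzy recurrence plots"
author: "frphrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting slow-paced-breathing relaxation from HRV with fuzzy recurrence plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frphrv)
```

## The problem

Guided slow breathing (around 4-6 breaths per minute) engages the
parasympathetic nervous system and produces a large, breathing-synchronous
oscillation of the heart period: respiratory sinus arrhythmia (RSA). Because
the pacing frequency sits inside the low-frequency (LF, 0.04-0.15 Hz) band of
heart-rate-variability (HRV) analysis, a paced session leaves a distinctive
multi-domain signature in the RR-interval series: LF power and the LF/HF
ratio rise, normalized HF power falls, the Poincare major axis SD2 grows, and
the tachogram becomes more regular, lowering sample entropy.

`frphrv` implements a complete detector for this state. Its distinctive
ingredient is a *fuzzy recurrence plot* (FRP): the RR series is converted
into a greyscale image whose texture differs visibly between spontaneous and
paced breathing, and grey-level co-occurrence (GLCM) statistics of that image
join the classic HRV features in a classification pipeline.

## The FRP model

Each beat's RR value (optionally delay-embedded) is a state $x_i$. Fuzzy
C-means (FCM) clustering minimizes

$$J(U, Z) = \sum_{i=1}^{N}\sum_{j=1}^{c} \mu_{ij}^{m}\, d(x_i, z_j)^2,$$

alternating the membership update
$\mu_{ik} = 1 / \sum_j (d_{ik}/d_{ij})^{2/(m-1)}$ with the centre update
$z_j = \sum_i \mu_{ij}^m x_i / \sum_i \mu_{ij}^m$, from a seeded random
row-stochastic initialization, until the membership matrix changes by at most
$\epsilon = 10^{-5}$ in max-norm. The recurrence image then comes from fuzzy
relation composition:

$$\mathrm{FRP}(i, j) = \max_k \min(\mu_{ik}, \mu_{jk}), \qquad
  \mathrm{FRP}(i, i) = 1,$$

which is symmetric with values in $[0, 1]$. Two beats that inhabit the same
fuzzy clusters light up bright pixels; a periodic signal produces recurrence
diagonals at multiples of its period. For crisp (one-hot) memberships the
image degenerates to the block equivalence matrix of the cluster labels, a
useful closed-form limit that the tests exercise.

Design choices that the construction leaves open:

* **Number of clusters.** Default `c = 3`, exposed everywhere. On a 5-minute
  tachogram (~300-400 beats), small `c` keeps the texture stable; larger
  values over-segment the narrow RR range.
* **Embedding.** Default `dim = 1, tau = 1` (scalar states). Delay embedding
  is supported but off by default.
* **Diagonal.** Set to 1 explicitly (reflexivity) rather than derived from
  the composition, which would give $\max_k \mu_{ik} < 1$.
* **Transitivity.** The max-min composition is applied once, not iterated to
  a transitive closure: the single composition is what defines the pixels.
* **Initialization.** Per-row Dirichlet(1, ..., 1) draws under a mandatory
  seed; FCM is the one stochastic step of feature extraction.

## The 39-feature panel

* **Time domain (6):** mean RR, SDNN, RMSSD, pNN50, mean HR, SD HR.
* **Frequency domain (7):** VLF/LF/HF band powers (0.003-0.04 / 0.04-0.15 /
  0.15-0.40 Hz), total power, LF and HF in normalized units, LF/HF. The
  tachogram is resampled at 4 Hz with a natural cubic spline, and the power
  spectral density is a Welch estimate: Hann window, 256-sample (64 s)
  segments, 50% overlap, per-segment linear detrend. Normalized units are
  taken over LF + HF, so `lf_nu + hf_nu = 100` identically.
* **Poincare (2):** `sd1 = sqrt(var(diff(rr))/2)` and
  `sd2 = sqrt(2 var(rr) - var(diff(rr))/2)` with sample variances — the
  centred (ellipse-fit) convention, matching the SDs of the lagged point
  cloud rotated by 45 degrees. Under this convention `sd1 = SDSD/sqrt(2)`
  exactly, and `sd1 ≈ RMSSD/sqrt(2)` only approximately (exactly when the
  mean successive difference is 0).
* **Entropy (5):** approximate entropy (m = 2, r = 0.2 SD), sample entropy
  (m = 2, r = 0.2 SD, tau = 1), fuzzy entropy (m = 2, tau = 2, trapezoidal
  membership), amplitude-aware permutation entropy (m = 6, tau = 1,
  a = 0.5), bubble entropy (m = 10). The trapezoid corners are not fixed by
  the membership shape alone; this package uses a plateau edge of 0.1 SD and
  a zero edge of 0.3 SD, both configurable. Amplitude-aware permutation
  entropy is computed on the mean-centred series so that, like the other
  four measures, it is invariant to additive shifts. A sample entropy with
  no template matches is propagated as a flagged missing value rather than
  fabricated.
* **FRP texture (19):** the Haralick/Soh/Clausi set (autocorrelation,
  contrast, correlation, cluster prominence, cluster shade, dissimilarity,
  energy, entropy, homogeneity, maximum probability, sum-of-squares
  variance, sum average, sum variance, sum entropy, difference variance,
  difference entropy, two information measures of correlation, inverse
  difference) of the 8-level, distance-1, horizontal, symmetric, normalized
  GLCM of the FRP. Natural logarithms with $0 \log 0 = 0$ throughout. The
  membership matrix is quantized directly — uniform bins on $[0,1]$, top
  edge closed — never the rendered 8-bit file.

Cluster prominence,
$\sum_{k,l}(k + l - \mu_x - \mu_y)^4\, p(k,l)$, is the headline texture
feature: paced breathing spreads the co-occurrence distribution and inflates
this fourth moment severalfold.

## Statistics and selection

Each feature is compared between conditions with a paired Wilcoxon
signed-rank test (two-sided; zero differences dropped; mid-ranks for ties).
The p-value is exact — full enumeration of sign assignments — for up to 12
effective pairs, and otherwise uses a tie-corrected normal approximation
with continuity correction plus an Edgeworth fourth-cumulant term, which
keeps it within about 0.01 of the exact tail at the switch point. Effect
sizes are Kerby rank-biserial correlations (difference of favorable and
unfavorable rank-sum proportions, in $[-1, 1]$). A one-sample
Kolmogorov-Smirnov screen against a fitted normal is reported for context
only; the pipeline is unconditionally nonparametric, and no multiplicity
correction is applied (each feature's test is reported as-is).

Selection is a cascade, each stage a subset of the last:

1. **z-scoring** (columns to mean 0, SD 1; parameters stored for held-out
   reuse; constant columns dropped).
2. **Fisher discriminant ratio** $(\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$,
   ranked descending, survivors strictly above 0.95. FDR is invariant to
   affine transforms applied to both classes, so the ranking is unaffected
   by the z-scoring; and because `lf_nu = 100 - hf_nu`, those two features
   tie exactly on any dataset. Ties are broken by feature name.
3. **Correlation filter:** walk the survivors in FDR order, accepting a
   feature only if |Pearson r| with everything already accepted is at most
   0.9.
4. **Greedy stepwise wrapper:** forward additions maximizing 10-fold CV
   accuracy of the target classifier, backward removals that cost nothing,
   stopping when no addition strictly improves. Folds are seed-fixed and
   ties break by name, so the search is deterministic. The evaluation uses
   the same table the cascade was fitted on — a deliberately faithful but
   optimistic protocol; no outer resampling wraps the selection, and the
   documentation flags the leakage implication for real-data use.

## Classifiers and evaluation

Six standard learners (SVM with RBF kernel via `e1071`, LDA via `MASS`, kNN
with k = 3 via `class`, a CART decision tree with minimum bucket 2 via
`rpart`, a single-hidden-layer MLP trained up to 500 iterations via `nnet`,
and a 100-tree random forest via `randomForest`) are evaluated with
stratified 10-fold cross-validation: pooled confusion counts, sensitivity /
specificity / accuracy / F1, and AUC computed from the pooled decision
scores by the rank (Mann-Whitney) formula. The positive class is
`slow_paced`, so specificity measures how rarely a non-relaxed recording is
called relaxed. Learning curves hold out 90% down to 10% of the data
(stratified), averaging the test error over 20 repetitions per point.
Exact replication of any other toolkit's internals (e.g. learning-rate and
momentum settings of a particular MLP implementation) is a non-goal; the
configurations above are this package's documented mapping.

## The synthetic cohort

Real paired recordings are not redistributable, so the package ships a
generator that emulates the study conditions: beats are laid down
iteratively, $t_{k+1} = t_k + RR(t_k)/1000$, with

$$RR(t) = \text{baseline} + A_{rsa} \sin(2\pi f_{resp} t)
        + A_{mayer} \sin(2\pi \cdot 0.1\, t) + \varepsilon_t .$$

Defaults, fixed once as the package's study conditions: baseline 800 ms,
Mayer amplitude 15 ms, beat noise SD 15 ms, 300 s per recording; the
spontaneous arm breathes at 0.25 Hz with RSA amplitude 25 ms, the paced arm
at 1/15 Hz (the 6/2/6/1 s protocol: 15 s cycle, 4 breaths/min) with RSA
amplitude 100 ms — severalfold larger, reflecting the qualitative amplitude
difference slow pacing produces. Between-subject variability jitters the
baseline (truncated normal, SD 40 ms, +/-120 ms) and scales both arms' RSA
by a shared factor (truncated normal, SD 0.2, clipped to [0.5, 1.5]). A
guard (`rsa + mayer + 4 sd < baseline`, with clamping of >4 SD noise)
ensures every interval passes the 333-2000 ms artefact screen.

What the generator does *not* emulate: ectopic beats and detection
artefacts, non-stationary drift, individually varying Mayer-wave frequency,
skewed RR distributions, and the imperfect pacing compliance of real
subjects. The additive-sinusoid model is deliberately simple — analytically
checkable and sampled at beat times rather than through an
integral-pulse-frequency model. Consequently the synthetic arms separate
more cleanly than real recordings: rank-biserial correlations on the default
cohort are at or near +/-1 and the three-feature SVM reaches ~100% CV
accuracy. Passing the pipeline's checks on this cohort demonstrates that
every stage implements its contract and recovers the documented effect
directions (sample entropy down; cluster prominence, LF/HF and SD2 up; HFnu
down under pacing) — it does not certify real-data accuracy figures.

## Numerical choices and edge cases

* Outlier bounds 333-2000 ms are treated as a *closed* interval, so the
  printed bounds are themselves legal values; removed beats are deleted and
  beat times re-accumulated, not interpolated.
* Natural boundary conditions for the resampling spline; the 4 Hz grid runs
  from the first to the last beat time.
* HF power of exactly zero yields `lf_hf = Inf` (flag, not a crash); a
  negative SD2 radicand is clipped to zero with a warning.
* FCM handles a state coincident with a centre by assigning its full
  membership to the zero-distance centre(s); non-convergence at `max_iter`
  returns the model with a warning flag rather than failing.
* Zero-variance series short-circuit every entropy to 0 with a degenerate
  flag.
* Test-set splits too small to train a learner contribute `NA` to a
  learning-curve cell instead of aborting the grid.

## Problem sizes

The test-suite and reproduction scripts run the full pipeline on the
default 60-pair cohort (120 recordings of ~375 beats each, 39 features),
which completes in well under a minute per stage on a single CPU;
brute-force oracle comparisons use series of 30-80 samples, where the
$O(N^2)$ references are instant.
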