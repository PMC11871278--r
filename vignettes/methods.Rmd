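---
title: "Scoring temporal visual attention from salience maps and multi-observer EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring temporal visual attention from salience maps and multi-observer EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsalience)
```

## The problem

Spatial visual salience — *where* people look in an image — is well
studied; the *temporal* dimension, how strongly a moment of a video
focuses collective attention, much less so. This package implements three
per-timestep scores and the machinery to relate them:

* **Visual score** `s_V(t)`: how spatially concentrated the salience map
  of frame `t` is.
* **Gaze score** `s_G(t)`: the fraction of gaze-point pairs from multiple
  observers that fall close together — the multi-observer agreement
  measure that `s_V` generalises from discrete points to a continuous
  map.
* **Brain score** `s_B(t)`: the fraction of subject pairs whose EEG
  feature vectors for segment `t` are similar — inter-subject
  consistency, the "brainsourcing" idea of aggregating brain signals
  from many viewers to read out a shared cognitive variable.

The scientific question is whether `s_B` tracks `s_V`: if the brains of
independent viewers respond more consistently exactly when the video's
salience is concentrated, brain consistency carries temporal-attention
information.

## The visual score and its fast evaluation

For a normalized map $S$ with $m = wh$ pixels,

$$s_V = \frac{\sum_{i=1}^m \sum_{j=1}^m S_i S_j \,
  \mathbf{1}[d_{ij} < \theta_s]}
  {\sum_{i=1}^m \sum_{j=1}^m S_i S_j},$$

the salience-weighted fraction of ordered pixel pairs (self-pairs
included, strict inequality) closer than a spatial threshold
$\theta_s$. The literal double sum is $O(m^2)$ — prohibitive at
$224\times384$. We evaluate it exactly as

$$s_V = \frac{\sum_p S(p)\,(S \star K)(p)}{\left(\sum_p S(p)\right)^2},$$

where $K$ is the binary disk kernel of integer offsets with Euclidean
norm below $\theta_s$ and $\star$ is cross-correlation, computed by FFT
with zero padding so circular wrap-around never reaches the image. The
rearrangement is algebraically exact; the test suite verifies agreement
with the literal double sum to better than $10^{-9}$ relative error on
random maps. Distances are in pixel units on the map grid.

`theta_s` defaults to 10% of the mean map dimension,
`0.1 * (w + h) / 2` — the continuous analogue of the customary 0.1
threshold for gaze coordinates normalized to $[0,1]$. Maps are
normalized per frame (each frame divided by its own maximum); all-zero
frames yield `NA` rather than a fabricated score, and downstream
smoothing interpolates such gaps from their neighbours. Optional integer
block-mean downsampling trades a little accuracy for speed; the default
factor is 1.

The gaze score resolves the pair sum as *unordered* pairs with
denominator $n(n-1)/2$, keeping the score in $[0,1]$ (an ordered-pair
reading would double the numerator). The $n$ points are everything in
the temporal window of length $2\theta_t + 1$ around $t$, pooled over
observers and clipped at the signal edges; fewer than two points give
`NA`.

## EEG features and the brain score

Recordings are cut into non-overlapping segments (1 s by default; a 60-s
recording gives `T = 60` steps, 2-s windows give `T = 30`). Per segment,
band and channel we compute five features: the three Hjorth parameters
(activity = variance, mobility, complexity), normalized spectral
entropy, and signal energy. Five canonical bands are used — Delta
0.5–4, Theta 4–7, Alpha 8–12, Beta 13–30 and Gamma 31+ Hz — so a
32-channel montage yields $5 \times 5 \times 32 = 800$ features, laid
out band-major with labels `band.feature.channel`.

Numerical conventions, stated so the 800-vector is reproducible
bit-exactly:

* **Filter**: zero-phase (forward–backward) 4th-order Butterworth
  band-pass. The feature literature this recipe follows does not fix a
  filter; this is the standard phase-preserving choice.
* **Gamma upper edge**: the open-ended band is resolved to
  `min(45, 0.45 * fs)` Hz, matching recordings low-passed at 45 Hz
  during standard preprocessing.
* **Filtering scope**: by default the continuous recording is filtered
  once per band and then segmented (`filter_scope = "recording"`), the
  usual EEG practice, which avoids filter edge transients inside every
  1-s segment and is considerably faster. `filter_scope = "segment"`
  filters each segment independently and matches a standalone
  `feature_vector()` call exactly.
* **Variance**: population convention (denominator $n$) for Hjorth
  activity; derivatives are first differences at unit spacing. The
  sampling-rate factor cancels in complexity and rescales mobility
  uniformly across subjects, which the cosine comparison below ignores.
* **Spectral entropy**: periodogram over positive-frequency bins (DC
  excluded), Shannon entropy normalized by `log(#bins)`.

The brain score applies the pair-agreement idea in feature space: for
each segment, the fraction of subject pairs with cosine distance
$1 - \cos(u, v)$ below a threshold. Cosine distance is scale-invariant,
so no per-subject normalization is needed; note its full range is
$[0, 2]$ (the *similarity* is bounded by $[-1, 1]$, the distance is
not). No temporal window is applied — the features already integrate
time within each segment. The threshold has no universal value and must
be supplied — or calibrated by the documented default recipe, the
median of all pairwise distances pooled over the video, which keeps the
score's base rate near 0.5 and away from floor/ceiling saturation.

## Local correlation, baseline and effect size

Global metrics hide local agreement, so the comparison slides aligned
windows of length `l` (stride 1, fully contained — no partial tail
windows) along the two smoothed series and counts matching tests:

$$\rho = \frac{1}{M} \sum_{k=1}^{M}
  \mathbf{1}[c(s_V^{(k)}, s_B^{(k)}; \theta_c)].$$

Element-wise criteria (`abs_diff`; `sign` on first differences with the
$\theta_c = 0$ convention) make every window one test, $M = T - l + 1$.
Correlation criteria (Spearman with average ranks for ties) mark every
position covered by at least one matching window and take $M = T$.
Constant segments have undefined rank correlation and count as
non-matches. An element-wise intersection-over-union criterion is
sometimes mentioned in this context, but it has no well-defined scalar
form on score series, so it is not offered. Note a structural
consequence of position coverage: with lenient thresholds, longer
windows can *raise* $\rho$ (one match covers `l` positions); the
characteristic drop of $\rho$ with growing `l` appears when long-window
correlations fall below $\theta_c$ while short-window ones do not.

Smoothing precedes comparison: Gaussian kernels (sd 1 for `s_V`, sd 2
for `s_B` by default, truncated at $4\sigma$, reflection padding) or a
width-3 mean filter; missing values are interpolated first.

Whether an observed $\rho$ means anything is judged against a
*temporal-shuffling* baseline: $\tilde s_B$ is a seeded uniform
permutation of $s_B$ — same value distribution, no temporal structure.
We permute the raw series and push it through the identical pipeline,
smoothing included, so observed and baseline correlations differ only
in temporal order. The standardized difference over a set of videos is
Cohen's d:

$$d = \frac{\rho_m - \tilde\rho_m}{s_p}.$$

Two readings of the pooled scale are shipped. The conventional one
(default, `mode = "standard"`) is
$s_p = \sqrt{(\rho_s^2 + \tilde\rho_s^2)/2}$ with sample standard
deviations; `mode = "literal"` keeps the variance-scale expression
$s_p = (\rho_s^2 + \tilde\rho_s^2)/2$ that some write-ups print for the
"pooled standard deviation". Both are exposed because which one a given
study computed is often undecidable from its text; the default is the
textbook definition. Qualitative labels use the extended ranges: very
small 0.01, small 0.2, medium 0.5, large 0.8, very large 1.2, huge 2.0.

`brainsource()` wraps all of this: per-video $\rho$ over an
`(l, theta_c)` grid, `n_perm` shuffles per video (reused across the
grid), and one Cohen's d per permutation, reported as
mean [standard error] over permutations — matching the common
mean-over-ten-permutations reporting convention.

## Feature selection

Which brain features track the visual score is answered by LASSO:

$$\min_w \tfrac{1}{2N}\|Xw - y\|_2^2 + \lambda\|w\|_1,$$

where row $t$ of $X$ is the *sum* of the feature vectors over the $K$
subjects for segment $t$ (videos stacked), and $y$ the matching visual
scores. The objective is taken literally: no intercept, no column
standardization by default — both available as flags, with the caveat
that unstandardized features of wildly different scales (energy vs
entropy) make selection scale-driven. Fitting is delegated to glmnet,
whose Gaussian objective is exactly the expression above; the suite
verifies the subgradient (KKT) optimality conditions independently.
The default penalty grid is $\lambda \in \{0.1, 1, 10, 100\}$; the
count of selected features is non-increasing along it.

## What the synthetic generators emulate

All generators are pure functions of a `synthetic_spec()` and its
mandatory seed; defaults mirror a DEAP-style study (60 one-second
timesteps, 32 subjects, 32 channels at 128 Hz, 30 gaze observers,
384×224 maps).

* **Maps**: one isotropic Gaussian blob per frame whose sd interpolates
  from scattered ($\sigma_{\max}$, 30% of the smaller dimension) to
  concentrated ($\sigma_{\min}$, 5%) as the concentration series
  $c(t) \in (0,1]$ rises, with a smooth sinusoidal centre drift
  (amplitude 5%, settable to 0 for strictly static frames). By
  construction $s_V$ is monotone in $c(t)$.
* **Gaze**: one point per observer per frame drawn from the frame as an
  unnormalized density (uniform fallback for all-zero frames).
* **EEG**: per channel, subject $k$'s signal is
  $\kappa(t)\,z + (1-\kappa(t))\,\sigma_\epsilon e_k$ with shared $z$
  and idiosyncratic $e_k$, both band-limited noise built by filtering
  white noise into the five canonical bands with the *same* filters as
  the feature extractor (so every band carries non-trivial power),
  mixed with mild $1/\sqrt{f}$-style band weights. The per-segment
  coupling $\kappa(t) \in [0,1]$ is linearly interpolated to a
  per-sample envelope so segments join continuously. Coupling acts in
  signal space, not feature space — consistency recovery downstream is
  a genuine test, not a tautology. When `coupling` is not supplied it
  is tied to the concentration series: the coupled condition in which
  $s_B$ should track $s_V$. The default concentration series is a
  smooth seeded sinusoid (1–2 cycles per minute) spanning most of
  $(0, 1]$.

What the generators do **not** emulate: physiological EEG (no dipole
geometry, no 1/f spectrum beyond the band weights, no artifacts), eye
movement dynamics (no saccades or fixation durations), and real
salience-model output (no multi-object or textured maps). Passing tests
therefore demonstrate that the estimators recover *planted* coupling
and concentration structure, not that real EEG carries such structure.

## Demonstration scale and stochastic margins

The test suite and the acceptance script run the pipeline at a reduced
demonstration scale — typically 8 subjects × 8 channels at 128 Hz and
96×64 maps over 60 steps, 50 videos for the null condition and 12 for
the coupled condition — chosen so the full suite completes in a few
minutes while leaving every moving part exercised. Package defaults
remain at study scale.

Two empirical behaviours worth recording. Under the coupled condition
the effect size is unambiguous (d ≈ 2.5–3.5 at `l = 5`,
`theta_c = 0.4`, far above the 0.8 "large" boundary). Under the null
(zero coupling) the *expected* effect is zero, but a single Cohen's d
over 50 videos is itself a random variable with standard deviation
roughly 0.15–0.25, so individual draws up to ≈0.4 in magnitude occur;
the suite pins a fixed seed for which the near-zero expectation is
visible. Increasing the number of videos — not the number of
permutations, which only polishes the baseline mean — is what shrinks
this spread.

## Known limitations

* The brain-score threshold calibration (median pooled distance) adapts
  per video; comparing absolute `s_B` levels *across* videos therefore
  requires a shared, externally fixed threshold.
* Spearman windows of length 5 on smoothed series are highly
  autocorrelated; $\rho$ values should only ever be interpreted against
  the permutation baseline, never in absolute terms.
* The LASSO design sums feature vectors over subjects, so features in
  which subjects disagree in sign can cancel.
* EEG file input is plain-text (CSV matrix + JSON metadata); standard
  binary biosignal formats are out of scope here and should be
  converted upstream.
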