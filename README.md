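# eegsalience

Does a crowd of brains reveal when a video grips attention? `eegsalience`
quantifies **temporal visual attention** in dynamic stimuli and tests
whether **inter-subject EEG consistency** tracks it — the "brainsourcing"
idea: aggregate brain signals from many viewers to read out a shared
cognitive variable. It is aimed at researchers in cognitive
neuroinformatics, HCI and media analytics who have (or simulate) salience
maps, gaze logs and multi-subject EEG for the same videos.

## The scores and the statistic

* **Visual score** — for a normalized salience map *S* with *m = wh*
  pixels,

  `s_V = Σᵢⱼ Sᵢ Sⱼ 1[dᵢⱼ < θₛ] / Σᵢⱼ Sᵢ Sⱼ`,

  the salience-weighted fraction of pixel pairs closer than θₛ
  (default: 10% of the mean map dimension). High = concentrated
  attention focus. Evaluated exactly in *O(m log m)* via a disk-kernel
  FFT correlation, verified against the literal double sum.
* **Gaze score** — fraction of gaze-point pairs (observers pooled in a
  ±θₜ frame window) closer than θₛ: the discrete measure `s_V`
  generalises; used to validate it.
* **Brain score** — per 1-s EEG segment, the fraction of subject pairs
  whose feature vectors (Hjorth activity/mobility/complexity, spectral
  entropy, energy × 5 bands × channels; 800 features for 32 channels)
  are closer than a cosine-distance threshold.
* **Relevance** — the local matching ratio
  `ρ = (1/M) Σₖ 1[c(s_V⁽ᵏ⁾, s_B⁽ᵏ⁾; θ_c)]` over sliding length-*l*
  windows (Spearman, absolute-difference or sign criteria), compared
  with temporally shuffled baselines via Cohen's
  `d = (ρₘ − ρ̃ₘ)/sₚ`, and LASSO
  `min_w (1/2N)‖Xw − y‖² + λ‖w‖₁` to find the features that matter.

## Worked example

A fully synthetic study: maps whose concentration `c(t)` drifts over a
minute, and an 8-subject EEG cohort whose coupling is tied to `c(t)`.

```r
library(eegsalience)

videos <- lapply(1:4, function(v) {
  spec <- synthetic_spec(n_steps = 60, map_w = 96, map_h = 64,
                         n_subjects = 8, n_channels = 8, fs = 128,
                         seed = 100 + v)     # coupling = concentration
  maps   <- gen_salience_stack(spec)
  tensor <- eeg_feature_tensor(gen_eeg_cohort(spec), window_s = 1)
  list(s_v = visual_score_series(maps),      # theta_s auto = 8
       s_b = brain_score_series(tensor))     # median-calibrated threshold
})

fit <- brainsource(lapply(videos, `[[`, "s_v"),
                   lapply(videos, `[[`, "s_b"),
                   l = 5, theta_c = c(0.2, 0.4), n_perm = 10, seed = 9)
print(fit)
```

```
Brainsourcing fit: 4 video(s), 10 permutation baseline, criterion = spearman
 l theta_c           rho      baseline     d effect
 5     0.2 0.996 [0.004] 0.752 [0.021] 3.360   huge
 5     0.4 0.992 [0.008] 0.706 [0.021] 4.236   huge
```

Read: in ~99% of timesteps the visual and brain scores move together
inside some matching 5-step window (`rho`), against ~71–75% after the
brain score is temporally shuffled (`baseline`); the standardized gap
over videos is a *huge* effect (`d` ≈ 3.4–4.2, mean [stderr] over the
10 permutations). With `coupling = rep(0, 60)` in the spec, `d`
collapses to ≈ 0 — the method reports nothing where nothing was
planted.

`run_pipeline()` chains the same stages from a YAML/list config and
writes a results bundle (scores CSV, effect-size grid, JSON with config
hash and seed); `lasso_fit()`/`selected_features()` identify which
band × feature × channel combinations predict `s_V`.

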