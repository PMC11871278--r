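# Shared fixtures and independent oracles, built in code at test time.

# Literal double-sum evaluation of the visual concentration score over all
# ordered pixel pairs (the brute-force oracle the fast path is checked
# against). Independent of the package's FFT implementation.
brute_visual_score <- function(frame, theta_s) {
  h <- nrow(frame); w <- ncol(frame)
  coords <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h))
  s <- as.vector(frame)
  D <- as.matrix(stats::dist(coords))
  W <- outer(s, s)
  sum(W[D < theta_s]) / sum(W)
}

# A single normalized Gaussian-blob frame.
blob_frame <- function(h, w, sigma, cx = w / 2, cy = h / 2) {
  f <- outer(exp(-(seq_len(h) - cy)^2 / (2 * sigma^2)),
             exp(-(seq_len(w) - cx)^2 / (2 * sigma^2)))
  f / max(f)
}

# Small synthetic study used across tests (demonstration scale; defaults
# of synthetic_spec() are DEAP-scale).
small_spec <- function(seed, ...) {
  synthetic_spec(n_steps = 30L, map_w = 48L, map_h = 48L, n_observers = 20L,
                 n_subjects = 6L, n_channels = 4L, fs = 128, seed = seed, ...)
}

# Visual + brain score pair for one synthetic video.
score_pair <- function(spec) {
  maps <- gen_salience_stack(spec)
  tensor <- eeg_feature_tensor(gen_eeg_cohort(spec),
                               window_s = spec$window_s)
  list(s_v = visual_score_series(maps),
       s_b = brain_score_series(tensor),
       spec = spec)
}
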