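#' Specification of a synthetic study
#'
#' Parameters of the seeded generators that emulate the study conditions:
#' salience-map stacks whose spatial concentration `c(t)` varies over time,
#' gaze observers sampling those maps, and an EEG cohort sharing a common
#' band-limited component whose inter-subject coupling `kappa(t)` varies
#' over time. Defaults mirror a DEAP-style study: 60 one-second timesteps,
#' 32 subjects and 32 channels at 128 Hz, 30 gaze observers and
#' 384 x 224 maps.
#'
#' @param n_steps series length `T` (timesteps).
#' @param map_w,map_h salience map size in pixels.
#' @param n_observers gaze observers.
#' @param n_subjects EEG cohort size `K`.
#' @param n_channels EEG channels.
#' @param fs EEG sampling rate in Hz (must support the five canonical
#'   bands, so >= ~70 Hz).
#' @param window_s EEG segment length in seconds (one timestep).
#' @param concentration length-`T` series in (0, 1]: 1 = maximally
#'   concentrated salience. `NULL` draws a smooth seeded sinusoidal curve.
#' @param coupling length-`T` series in \[0, 1\]: inter-subject EEG
#'   coupling strength. `NULL` ties it to `concentration` (the coupled
#'   condition); pass `rep(0, n_steps)` for the null condition.
#' @param noise_sd standard deviation scale of the idiosyncratic EEG
#'   component.
#' @param seed mandatory integer seed; all generators are pure functions
#'   of (spec, seed).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_steps = 60L, map_w = 384L, map_h = 224L,
                           n_observers = 30L, n_subjects = 32L,
                           n_channels = 32L, fs = 128, window_s = 1,
                           concentration = NULL, coupling = NULL,
                           noise_sd = 1, seed) {
  if (missing(seed)) stop_invalid("`seed` is mandatory")
  n_steps <- as.integer(n_steps)
  if (is.null(concentration)) {
    concentration <- with_preserved_rng({
      set.seed(offset_seed(seed, 104729))
      cycles <- stats::runif(1, 1, 2)
      phase <- stats::runif(1, 0, 2 * pi)
      0.5 + 0.45 * sin(2 * pi * cycles * seq_len(n_steps) / n_steps + phase)
    })
  }
  coupling <- coupling %||% concentration
  stopifnot(length(concentration) == n_steps, length(coupling) == n_steps)
  if (any(concentration <= 0 | concentration > 1))
    stop_invalid("`concentration` must lie in (0, 1]")
  if (any(coupling < 0 | coupling > 1))
    stop_invalid("`coupling` must lie in [0, 1]")
  structure(list(n_steps = n_steps, map_w = as.integer(map_w),
                 map_h = as.integer(map_h),
                 n_observers = as.integer(n_observers),
                 n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels), fs = fs,
                 window_s = window_s, concentration = concentration,
                 coupling = coupling, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Synthetic salience-map stack
#'
#' One isotropic Gaussian blob per frame, with standard deviation
#' interpolating from `sigma_max` (scattered) to `sigma_min`
#' (concentrated) as the spec's concentration series `c(t)` goes from 0 to
#' 1: `sigma_t = sigma_max * (1 - c(t)) + sigma_min * c(t)`. The blob
#' centre can drift smoothly along a sinusoidal path; frames are
#' normalized to maximum 1.
#'
#' @param spec a [synthetic_spec()].
#' @param sigma_min,sigma_max blob standard deviations in pixels; defaults
#'   scale with the map (5% and 30% of the smaller dimension).
#' @param drift_amplitude centre drift amplitude in pixels (default 5% of
#'   the smaller dimension; 0 keeps the blob static).
#' @return A [salience_map_sequence()].
#' @export
gen_salience_stack <- function(spec, sigma_min = NULL, sigma_max = NULL,
                               drift_amplitude = NULL) {
  m <- min(spec$map_w, spec$map_h)
  sigma_min <- sigma_min %||% (0.05 * m)
  sigma_max <- sigma_max %||% (0.30 * m)
  drift_amplitude <- drift_amplitude %||% (0.05 * m)
  tt <- seq_len(spec$n_steps)
  phase <- with_preserved_rng({
    set.seed(offset_seed(spec$seed, 15485863))
    stats::runif(2, 0, 2 * pi)
  })
  cx <- spec$map_w / 2 + drift_amplitude * sin(2 * pi * tt / spec$n_steps + phase[1])
  cy <- spec$map_h / 2 + drift_amplitude * sin(4 * pi * tt / spec$n_steps + phase[2])
  sig <- sigma_max * (1 - spec$concentration) + sigma_min * spec$concentration
  xs <- seq_len(spec$map_w); ys <- seq_len(spec$map_h)
  frames <- lapply(tt, function(t) {
    gx <- exp(-(xs - cx[t])^2 / (2 * sig[t]^2))
    gy <- exp(-(ys - cy[t])^2 / (2 * sig[t]^2))
    outer(gy, gx)
  })
  salience_map_sequence(frames, frame_period = spec$window_s,
                        video_id = sprintf("synthetic-%d", spec$seed))
}

#' Synthetic gaze sampled from salience maps
#'
#' For every observer and frame, one gaze point is drawn from the frame
#' treated as an (unnormalized) spatial density; coordinates are reported
#' normalized to \[0, 1\] (pixel centres). Degenerate all-zero frames fall
#' back to uniform sampling.
#'
#' @param seq a [salience_map_sequence()].
#' @param n_observers number of observers.
#' @param seed integer seed.
#' @return A [gaze_table()].
#' @export
gen_gaze_from_maps <- function(seq, n_observers, seed) {
  h <- seq$h; w <- seq$w
  with_preserved_rng({
    set.seed(seed)
    recs <- lapply(seq_len(seq$n_frames), function(t) {
      f <- seq$frames[[t]]
      p <- as.vector(f)
      if (sum(p) == 0) p <- rep(1, length(p))
      idx <- sample.int(length(p), n_observers, replace = TRUE, prob = p)
      row <- ((idx - 1L) %% h) + 1L
      col <- ((idx - 1L) %/% h) + 1L
      data.frame(observer = seq_len(n_observers), t = t,
                 x = (col - 0.5) / w, y = (row - 0.5) / h)
    })
    df <- do.call(rbind, recs)
    gaze_table(df$observer, df$t, df$x, df$y, n_frames = seq$n_frames)
  })
}

# Band-limited noise: white noise filtered into the five canonical bands
# (same filters as the feature extractor) and summed with mild 1/f-style
# weights so every band carries non-trivial power.
band_limited_noise <- function(n, fs, bands) {
  w <- 1 / sqrt(seq_len(nrow(bands)))
  x <- numeric(n)
  for (b in seq_len(nrow(bands))) {
    x <- x + w[b] * bandpass_filter(stats::rnorm(n), bands$low_hz[b],
                                    bands$high_hz[b], fs)
  }
  x
}

#' Synthetic EEG cohort with time-varying inter-subject coupling
#'
#' Subject `k`'s channel signal is
#' `kappa(t) * shared + (1 - kappa(t)) * noise_sd * independent`, where
#' both components are band-limited noise and `kappa(t)` (the spec's
#' coupling series, one value per segment) is linearly interpolated to a
#' per-sample envelope so the mixture is continuous at segment joins.
#' Coupling acts in signal space, not feature space, so downstream
#' consistency recovery is a genuine test.
#'
#' @param spec a [synthetic_spec()].
#' @return List of `n_subjects` [eeg_recording()] objects.
#' @export
gen_eeg_cohort <- function(spec) {
  fs <- spec$fs
  n_per <- as.integer(round(fs * spec$window_s))
  n <- n_per * spec$n_steps
  bands <- resolve_bands(eeg_bands(), fs)
  # per-sample coupling envelope anchored at segment midpoints
  mid <- (seq_len(spec$n_steps) - 0.5) * n_per
  kappa <- stats::approx(mid, spec$coupling, xout = seq_len(n), rule = 2)$y
  with_preserved_rng({
    set.seed(spec$seed)
    shared <- t(vapply(seq_len(spec$n_channels), function(ch)
      band_limited_noise(n, fs, bands), numeric(n)))
    lapply(seq_len(spec$n_subjects), function(k) {
      own <- t(vapply(seq_len(spec$n_channels), function(ch)
        band_limited_noise(n, fs, bands), numeric(n)))
      x <- sweep(shared, 2L, kappa, "*") +
        sweep(own * spec$noise_sd, 2L, 1 - kappa, "*")
      eeg_recording(x, fs, paste0("ch", seq_len(spec$n_channels)),
                    subject_id = sprintf("s%02d", k),
                    video_id = sprintf("synthetic-%d", spec$seed))
    })
  })
}
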