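#' EEG recordings
#'
#' Minimal container for one subject's multichannel EEG while watching one
#' video: a channels-by-time numeric matrix plus sampling rate and channel
#' labels. Preprocessing (re-referencing, artifact removal) is assumed to
#' have happened upstream.
#'
#' @param samples `channels x time` numeric matrix, all values finite.
#' @param fs sampling rate in Hz.
#' @param channel_names character labels, one per row; defaults to
#'   `rownames(samples)` or `ch1..chC`.
#' @param subject_id,video_id labels carried through to outputs.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_names = NULL,
                          subject_id = "s1", video_id = "video") {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (any(!is.finite(samples))) stop_invalid("EEG samples must be finite")
  check_scalar_number(fs, "fs", positive = TRUE)
  channel_names <- channel_names %||% rownames(samples) %||%
    paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples))
    stop_invalid("one channel name per row required")
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, video_id = video_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s/%s: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              x$subject_id, x$video_id, nrow(x$samples), ncol(x$samples),
              x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' Delta (0.5-4), Theta (4-7), Alpha (8-12), Beta (13-30) and Gamma
#' (31+ Hz). The open-ended Gamma edge is resolved against the sampling
#' rate as `min(45, 0.45 * fs)` Hz, matching recordings low-passed at
#' 45 Hz during standard preprocessing.
#'
#' @return `data.frame` with columns `band`, `low_hz`, `high_hz`
#'   (`high_hz = Inf` for Gamma until resolved).
#' @export
eeg_bands <- function() {
  data.frame(band = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
             low_hz = c(0.5, 4, 8, 13, 31),
             high_hz = c(4, 7, 12, 30, Inf))
}

# Resolve open-ended band edges against fs and validate against Nyquist.
resolve_bands <- function(bands, fs) {
  bands$high_hz <- ifelse(is.finite(bands$high_hz), bands$high_hz,
                          min(45, 0.45 * fs))
  bad <- bands$low_hz >= fs / 2
  if (any(bad))
    stop_invalid("band(s) entirely above Nyquist: ",
                 paste(bands$band[bad], collapse = ", "))
  bands$high_hz <- pmin(bands$high_hz, 0.499 * fs)
  if (any(bands$low_hz >= bands$high_hz))
    stop_invalid("band edges collapsed below Nyquist; increase fs")
  bands
}

#' Split a recording into fixed-length segments
#'
#' Cuts the recording into `T = floor(duration / window_s)` consecutive
#' non-overlapping windows; a trailing remainder shorter than one window is
#' dropped. One-second windows on a 60-s recording give `T = 60` steps;
#' two-second windows give `T = 30`.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds; `window_s * fs` must be a
#'   positive integer.
#' @return List of `channels x (window_s * fs)` matrices.
#' @export
segment_recording <- function(rec, window_s = 1) {
  n_per <- rec$fs * window_s
  if (abs(n_per - round(n_per)) > 1e-8 || n_per < 1)
    stop_invalid("`window_s * fs` must be a positive integer")
  n_per <- as.integer(round(n_per))
  n <- ncol(rec$samples)
  n_seg <- n %/% n_per
  if (n_seg < 1L) stop_invalid("recording shorter than one window")
  lapply(seq_len(n_seg), function(t) {
    rec$samples[, ((t - 1L) * n_per + 1L):(t * n_per), drop = FALSE]
  })
}

# Cache of Butterworth designs keyed by (low, high, fs).
.filter_cache <- new.env(parent = emptyenv())

butter_band <- function(low, high, fs, order = 4L) {
  key <- paste(low, high, fs, order, sep = "|")
  f <- .filter_cache[[key]]
  if (is.null(f)) {
    f <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    .filter_cache[[key]] <- f
  }
  f
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass. Accepts a
#' single signal or a channels-by-time matrix (filtered row-wise); output
#' has the same length as the input.
#'
#' @param x numeric vector or `channels x time` matrix.
#' @param low_hz,high_hz band edges in Hz; `high_hz = Inf` is resolved to
#'   `min(45, 0.45 * fs)`.
#' @param fs sampling rate in Hz.
#' @return Filtered signal with the same shape as `x`.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, fs) {
  b <- resolve_bands(data.frame(band = "custom", low_hz = low_hz,
                                high_hz = high_hz), fs)
  flt <- butter_band(b$low_hz, b$high_hz, fs)
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, function(row) signal::filtfilt(flt, row)))
    dimnames(out) <- dimnames(x)
    out
  } else {
    signal::filtfilt(flt, x)
  }
}

#' Hjorth parameters
#'
#' Time-domain descriptors of a signal `x` with first difference `dx`:
#' activity `= var(x)`, mobility `= sqrt(var(dx)/var(x))`, and complexity
#' `= mobility(dx)/mobility(x)`. Variances use the population convention
#' (denominator `n`) so results are reproducible bit-exactly. A
#' zero-variance signal returns `(0, 0, 0)` with attribute
#' `degenerate = TRUE`.
#'
#' @param x numeric vector, length >= 3.
#' @return Named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth <- function(x) {
  if (length(x) < 3L) stop_invalid("Hjorth parameters need length >= 3")
  v0 <- pop_var(x)
  if (v0 == 0)
    return(structure(c(activity = 0, mobility = 0, complexity = 0),
                     degenerate = TRUE))
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- pop_var(d1); v2 <- pop_var(d2)
  mob <- sqrt(v1 / v0)
  cplx <- if (v1 == 0) 0 else sqrt(v2 / v1) / mob
  c(activity = v0, mobility = mob, complexity = cplx)
}

pop_var <- function(x) mean(x^2) - mean(x)^2

#' Normalized spectral entropy
#'
#' Shannon entropy of the power spectral density over positive-frequency
#' periodogram bins (DC excluded), normalized by `log(#bins)` so the value
#' lies in \[0, 1\]: 0 for a pure single-bin tone, 1 for a flat spectrum.
#'
#' @param x numeric vector, length >= 4.
#' @param fs sampling rate in Hz (bookkeeping; the entropy itself is
#'   scale-free).
#' @return A number in \[0, 1\]; zero signals give 0 with attribute
#'   `degenerate = TRUE`.
#' @export
spectral_entropy <- function(x, fs = 1) {
  n <- length(x)
  if (n < 4L) stop_invalid("spectral entropy needs length >= 4")
  p <- Mod(stats::fft(x))^2
  bins <- p[2:(n %/% 2 + 1L)]
  s <- sum(bins)
  if (s == 0) return(structure(0, degenerate = TRUE))
  q <- bins / s
  q <- q[q > 0]
  -sum(q * log(q)) / log(length(bins))
}

#' Signal energy
#'
#' Sum of squared samples.
#'
#' @param x numeric vector.
#' @return Nonnegative number.
#' @export
signal_energy <- function(x) sum(x^2)

#' The five per-band features, in canonical order
#'
#' @return `c("activity", "mobility", "complexity", "entropy", "energy")`.
#' @export
eeg_feature_names <- function() {
  c("activity", "mobility", "complexity", "entropy", "energy")
}

#' Feature labels in canonical order
#'
#' The feature vector is laid out band-major: for each band, for each
#' feature, for each channel. Labels are `band.feature.channel` strings and
#' map bijectively to vector positions.
#'
#' @param bands character vector of band names.
#' @param features character vector of feature names.
#' @param channels character vector of channel names.
#' @return Character vector of length
#'   `length(bands) * length(features) * length(channels)`.
#' @export
feature_labels <- function(bands, features, channels) {
  as.vector(vapply(bands, function(b)
    vapply(features, function(f)
      paste(b, f, channels, sep = "."), character(length(channels))),
    character(length(features) * length(channels))))
}

#' Parse feature labels back to (band, feature, channel)
#'
#' @param labels labels produced by [feature_labels()].
#' @return `data.frame` with columns `band`, `feature`, `channel`.
#' @export
parse_feature_labels <- function(labels) {
  parts <- strsplit(labels, ".", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop_invalid("labels must be 'band.feature.channel'")
  data.frame(band = vapply(parts, `[`, "", 1L),
             feature = vapply(parts, `[`, "", 2L),
             channel = vapply(parts, `[`, "", 3L))
}

# Per-column features of a samples x T matrix of one (band, channel)
# filtered signal. Returns a features x T matrix (rows in `features`
# order). Matches the scalar hjorth()/spectral_entropy()/signal_energy()
# definitions exactly.
features_of_columns <- function(X, features) {
  n <- nrow(X)
  col_pop_var <- function(M) colMeans(M^2) - colMeans(M)^2
  v0 <- col_pop_var(X)
  need_hj <- any(features %in% c("activity", "mobility", "complexity"))
  if (need_hj) {
    D1 <- X[-1L, , drop = FALSE] - X[-n, , drop = FALSE]
    D2 <- D1[-1L, , drop = FALSE] - D1[-(n - 1L), , drop = FALSE]
    v1 <- col_pop_var(D1); v2 <- col_pop_var(D2)
    mob <- ifelse(v0 == 0, 0, sqrt(v1 / v0))
    cplx <- ifelse(v0 == 0 | v1 == 0, 0, sqrt(v2 / v1) / mob)
  }
  out <- matrix(NA_real_, length(features), ncol(X),
                dimnames = list(features, NULL))
  for (f in features) {
    out[f, ] <- switch(f,
      activity = v0,
      mobility = mob,
      complexity = cplx,
      energy = colSums(X^2),
      entropy = {
        P <- Mod(stats::mvfft(X))^2
        B <- P[2:(n %/% 2 + 1L), , drop = FALSE]
        tot <- colSums(B)
        Q <- sweep(B, 2L, ifelse(tot == 0, 1, tot), "/")
        H <- -colSums(ifelse(Q > 0, Q * log(Q), 0)) / log(nrow(B))
        ifelse(tot == 0, 0, H)
      },
      stop_invalid("unknown feature: ", f))
  }
  out
}

#' Feature vector of one EEG segment
#'
#' For each requested frequency band the segment is band-pass filtered
#' ([bandpass_filter()]) and the requested features are computed per
#' channel on the filtered signal. With the default 5 bands and 5 features
#' a 32-channel segment yields an 800-dimensional labeled vector.
#'
#' @param segment `channels x samples` matrix (row names = channel labels).
#' @param fs sampling rate in Hz.
#' @param bands band table as in [eeg_bands()] (default) or a subset.
#' @param features subset of
#'   `c("activity","mobility","complexity","entropy","energy")`.
#' @param channels channel labels to use; `NULL` = all rows.
#' @return Named numeric vector in band-major (band, feature, channel)
#'   order.
#' @export
feature_vector <- function(segment, fs, bands = eeg_bands(),
                           features = eeg_feature_names(),
                           channels = NULL) {
  if (!is.matrix(segment)) segment <- as.matrix(segment)
  if (is.null(rownames(segment)))
    rownames(segment) <- paste0("ch", seq_len(nrow(segment)))
  channels <- channels %||% rownames(segment)
  if (length(channels) == 0L || length(features) == 0L || nrow(bands) == 0L)
    stop_invalid("bands, features and channels must be non-empty")
  missing_ch <- setdiff(channels, rownames(segment))
  if (length(missing_ch))
    stop_invalid("unknown channel(s): ", paste(missing_ch, collapse = ", "))
  if (!all(features %in% eeg_feature_names()))
    stop_invalid("unknown feature name(s)")
  bands <- resolve_bands(bands, fs)
  segment <- segment[channels, , drop = FALSE]
  out <- numeric(0)
  for (b in seq_len(nrow(bands))) {
    filt <- bandpass_filter(segment, bands$low_hz[b], bands$high_hz[b], fs)
    vals <- features_of_columns(t(filt), features)  # features x channels
    out <- c(out, as.vector(t(vals)))
  }
  names(out) <- feature_labels(bands$band, features, channels)
  out
}

#' Per-segment EEG feature tensor for a cohort
#'
#' Builds the `subjects x T x k` array of labeled feature vectors for all
#' subjects who watched the same video. By default each recording is
#' band-pass filtered once as a continuous signal and then segmented
#' (`filter_scope = "recording"`), the standard practice that avoids
#' per-segment filter edge artifacts; `filter_scope = "segment"` filters
#' every segment independently, matching [feature_vector()] exactly.
#'
#' @param recordings list of [eeg_recording()] objects with identical
#'   sampling rates and channel sets.
#' @param window_s segment length in seconds (see [segment_recording()]).
#' @param bands,features,channels as in [feature_vector()].
#' @param filter_scope `"recording"` (default) or `"segment"`.
#' @return Numeric array `subjects x T x k` with dimnames
#'   `(subject, NULL, label)`, attributes `window_s`, `fs` and
#'   `filter_scope`.
#' @export
eeg_feature_tensor <- function(recordings, window_s = 1, bands = eeg_bands(),
                               features = eeg_feature_names(),
                               channels = NULL,
                               filter_scope = c("recording", "segment")) {
  filter_scope <- match.arg(filter_scope)
  if (!length(recordings)) stop_invalid("no recordings")
  fs <- recordings[[1L]]$fs
  if (any(vapply(recordings, function(r) r$fs, 0) != fs))
    stop_invalid("all recordings must share one sampling rate")
  channels <- channels %||% recordings[[1L]]$channel_names
  bands <- resolve_bands(bands, fs)
  n_per <- as.integer(round(fs * window_s))
  n_seg <- min(vapply(recordings, function(r) ncol(r$samples), 0L)) %/% n_per
  if (n_seg < 1L) stop_invalid("recordings shorter than one window")
  labels <- feature_labels(bands$band, features, channels)
  k <- length(labels)
  subj <- vapply(recordings, function(r) r$subject_id, "")
  tensor <- array(NA_real_, c(length(recordings), n_seg, k),
                  dimnames = list(subj, NULL, labels))
  for (i in seq_along(recordings)) {
    x <- recordings[[i]]$samples[channels, seq_len(n_seg * n_per),
                                 drop = FALSE]
    for (b in seq_len(nrow(bands))) {
      for (ch in seq_along(channels)) {
        sig <- if (filter_scope == "recording") {
          bandpass_filter(x[ch, ], bands$low_hz[b], bands$high_hz[b], fs)
        } else NULL
        X <- if (is.null(sig)) {
          # per-segment filtering
          vapply(seq_len(n_seg), function(t) {
            seg <- x[ch, ((t - 1L) * n_per + 1L):(t * n_per)]
            bandpass_filter(seg, bands$low_hz[b], bands$high_hz[b], fs)
          }, numeric(n_per))
        } else {
          matrix(sig, nrow = n_per, ncol = n_seg)
        }
        vals <- features_of_columns(X, features)  # features x T
        for (f in seq_along(features)) {
          lab <- paste(bands$band[b], features[f], channels[ch], sep = ".")
          tensor[i, , lab] <- vals[features[f], ]
        }
      }
    }
  }
  structure(tensor, window_s = window_s, fs = fs, filter_scope = filter_scope)
}

#' Slice a feature tensor by band / feature / channel
#'
#' Subsetting the tensor at a set of labels is exactly equivalent to
#' computing it on that subset in the first place.
#'
#' @param tensor array from [eeg_feature_tensor()].
#' @param bands,features,channels optional character filters; `NULL` keeps
#'   everything.
#' @return The sliced `subjects x T x k'` array (labels preserved).
#' @export
select_features <- function(tensor, bands = NULL, features = NULL,
                            channels = NULL) {
  lab <- parse_feature_labels(dimnames(tensor)[[3L]])
  keep <- rep(TRUE, nrow(lab))
  if (!is.null(bands)) keep <- keep & lab$band %in% bands
  if (!is.null(features)) keep <- keep & lab$feature %in% features
  if (!is.null(channels)) keep <- keep & lab$channel %in% channels
  if (!any(keep)) stop_invalid("selection removes every feature")
  out <- tensor[, , keep, drop = FALSE]
  for (a in c("window_s", "fs", "filter_scope"))
    attr(out, a) <- attr(tensor, a)
  out
}
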