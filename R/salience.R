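#' Salience map sequences
#'
#' Container for a sequence of 2D salience maps, one per video frame. Maps
#' are nonnegative fields predicting where viewers look; this package
#' consumes them (from any upstream salience model) and summarises each
#' frame by how spatially concentrated its salient mass is.
#'
#' @param frames either a `T x h x w` numeric array or a list of `h x w`
#'   numeric matrices, all the same size, with nonnegative finite values.
#' @param frame_period seconds per frame (metadata only).
#' @param video_id label carried through to outputs.
#' @param normalize if `TRUE` (default) each frame is rescaled so its
#'   maximum is 1 (see [normalize_map()]); all-zero frames are kept and
#'   flagged degenerate.
#'
#' @return An object of class `salience_map_sequence`: a list with elements
#'   `frames` (list of `h x w` matrices), `h`, `w`, `n_frames`,
#'   `frame_period`, `video_id` and a logical `degenerate` vector marking
#'   all-zero frames.
#' @seealso [visual_score_series()], [read_salience_dir()]
#' @export
salience_map_sequence <- function(frames, frame_period = 1, video_id = "video",
                                  normalize = TRUE) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[1L]), function(t) frames[t, , ])
  }
  if (!is.list(frames) || length(frames) == 0L)
    stop_invalid("`frames` must be a non-empty list of matrices or a T x h x w array")
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) f <- as.matrix(f)
    storage.mode(f) <- "double"
    f
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_invalid("all frames must share the same dimensions")
  degenerate <- logical(length(frames))
  frames <- lapply(seq_along(frames), function(i) {
    f <- if (normalize) normalize_map(frames[[i]]) else frames[[i]]
    degenerate[i] <<- isTRUE(attr(f, "degenerate"))
    attr(f, "degenerate") <- NULL
    f
  })
  structure(
    list(frames = frames, h = dims[1, 1], w = dims[2, 1],
         n_frames = length(frames), frame_period = frame_period,
         video_id = video_id, degenerate = degenerate),
    class = "salience_map_sequence")
}

#' @export
print.salience_map_sequence <- function(x, ...) {
  cat(sprintf("<salience_map_sequence '%s': %d frames of %d x %d, %.4g s/frame>\n",
              x$video_id, x$n_frames, x$h, x$w, x$frame_period))
  if (any(x$degenerate))
    cat(sprintf("  %d degenerate (all-zero) frame(s)\n", sum(x$degenerate)))
  invisible(x)
}

#' Normalize a salience map to [0, 1]
#'
#' Divides a nonnegative frame by its maximum so the largest value is 1.
#' All-zero frames pass through unchanged with attribute
#' `degenerate = TRUE`, rather than silently fabricating values.
#'
#' @param raw_frame `h x w` matrix of nonnegative finite values.
#' @return The rescaled matrix; degenerate frames carry
#'   `attr(, "degenerate") == TRUE`.
#' @export
normalize_map <- function(raw_frame) {
  if (!is.numeric(raw_frame))
    stop_invalid("salience frame must be numeric")
  if (any(!is.finite(raw_frame)))
    stop_invalid("salience frame contains non-finite values")
  if (any(raw_frame < 0))
    stop_invalid("salience frame contains negative values")
  mx <- max(raw_frame)
  if (mx == 0) {
    attr(raw_frame, "degenerate") <- TRUE
    return(raw_frame)
  }
  raw_frame / mx
}

#' Default spatial threshold for the visual score
#'
#' The spatial sensitivity threshold is set heuristically to 10% of the
#' arithmetic mean of the map dimensions, mirroring the 0.1 threshold used
#' for gaze coordinates normalized to \[0, 1\].
#'
#' @param w,h map width and height in pixels.
#' @return Threshold in pixel units: `0.1 * (w + h) / 2`.
#' @export
default_spatial_threshold <- function(w, h) {
  check_scalar_number(w, "w", positive = TRUE)
  check_scalar_number(h, "h", positive = TRUE)
  0.1 * (w + h) / 2
}

# Integer offsets (dr, dc) with Euclidean norm strictly below theta,
# including (0, 0). Strict inequality matches the score's definition.
disk_offsets <- function(theta) {
  r <- ceiling(theta)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 < theta^2
  as.matrix(g[keep, , drop = FALSE])
}

# Cross-correlation of `frame` with the binary disk kernel of radius theta,
# evaluated by FFT with zero padding so that circular wrap-around never
# reaches the image. Because the disk is symmetric, correlation equals
# convolution and the result at pixel p is sum over q of S(q) for all q
# with ||q - p|| < theta, weighted by S.
disk_correlate <- function(frame, theta) {
  h <- nrow(frame); w <- ncol(frame)
  off <- disk_offsets(theta)
  r <- ceiling(theta)
  P <- stats::nextn(h + 2L * r, c(2, 3, 5))
  Q <- stats::nextn(w + 2L * r, c(2, 3, 5))
  K <- matrix(0, P, Q)
  K[cbind((off[, "dr"] %% P) + 1L, (off[, "dc"] %% Q) + 1L)] <- 1
  S <- matrix(0, P, Q)
  S[seq_len(h), seq_len(w)] <- frame
  C <- Re(stats::fft(stats::fft(S) * stats::fft(K), inverse = TRUE)) / (P * Q)
  C[seq_len(h), seq_len(w)]
}

#' Visual salience concentration score of one frame
#'
#' For a normalized salience map \eqn{S} with \eqn{m = wh} pixels, the score
#' is the salience-weighted fraction of ordered pixel pairs (including
#' self-pairs) whose Euclidean distance is strictly below the spatial
#' threshold:
#' \deqn{s_V = \frac{\sum_{i=1}^{m}\sum_{j=1}^{m} S_i S_j\,
#'   \mathbf{1}[d_{ij} < \theta_s]}{\sum_{i=1}^{m}\sum_{j=1}^{m} S_i S_j}.}
#' High values mean the salient mass is compact (tight focus of predicted
#' attention); low values mean it is scattered. It is the continuous,
#' probability-weighted counterpart of the gaze pair-agreement score
#' ([gaze_score()]).
#'
#' The double sum is evaluated in \eqn{O(m \log m)} as
#' \eqn{\sum_p S(p)\,(S \star K)(p) / (\sum_p S(p))^2}, where \eqn{K} is the
#' binary disk kernel of integer offsets with norm below `theta_s`. This
#' rearrangement is exact up to floating-point rounding and is verified
#' against the literal double sum in the test suite.
#'
#' @param frame normalized `h x w` salience map (max 1; see
#'   [normalize_map()]).
#' @param theta_s spatial threshold in pixel units; `NULL` uses
#'   [default_spatial_threshold()].
#' @return A number in (0, 1].
#' @examples
#' f <- matrix(0, 9, 9); f[5, 5] <- 1
#' visual_score_frame(f, 2)        # single salient pixel -> 1
#' @export
visual_score_frame <- function(frame, theta_s = NULL) {
  if (!is.matrix(frame)) frame <- as.matrix(frame)
  theta_s <- theta_s %||% default_spatial_threshold(ncol(frame), nrow(frame))
  check_scalar_number(theta_s, "theta_s", positive = TRUE)
  tot <- sum(frame)
  if (tot == 0)
    stop_invalid("degenerate all-zero frame: score undefined")
  num <- sum(frame * disk_correlate(frame, theta_s))
  val <- num / tot^2
  min(max(val, 0), 1)  # clamp float rounding at the boundaries
}

#' Visual salience score series of a map sequence
#'
#' Applies [visual_score_frame()] to every frame. No additional temporal
#' averaging is performed: salience maps produced from neighbouring video
#' frames already carry the temporal smoothing effect, so the per-frame
#' score is the temporal series.
#'
#' @param seq a [salience_map_sequence()].
#' @param theta_s spatial threshold in pixels, or `NULL`/`"auto"` for
#'   [default_spatial_threshold()] on the (possibly downsampled) grid.
#' @param downsample_factor positive integer block size; `> 1` reduces each
#'   frame by block averaging (then renormalizes) before scoring, with
#'   `theta_s` rescaled accordingly. Default 1 (no downsampling).
#' @return Numeric vector of length `n_frames`; degenerate frames give
#'   `NA`. Attributes `video_id` and `theta_s` record the provenance.
#' @export
visual_score_series <- function(seq, theta_s = NULL, downsample_factor = 1L) {
  if (!inherits(seq, "salience_map_sequence"))
    stop_invalid("`seq` must be a salience_map_sequence")
  if (seq$n_frames < 1L) stop_invalid("empty sequence")
  downsample_factor <- as.integer(downsample_factor)
  if (downsample_factor < 1L) stop_invalid("`downsample_factor` must be >= 1")
  if (identical(theta_s, "auto")) theta_s <- NULL
  theta_s <- theta_s %||% default_spatial_threshold(seq$w, seq$h)
  theta_eff <- theta_s / downsample_factor
  s <- vapply(seq_len(seq$n_frames), function(t) {
    if (seq$degenerate[t]) return(NA_real_)
    f <- seq$frames[[t]]
    if (downsample_factor > 1L) {
      f <- block_mean(f, downsample_factor)
      f <- f / max(f)
    }
    visual_score_frame(f, theta_eff)
  }, numeric(1))
  structure(s, video_id = seq$video_id, theta_s = theta_s)
}

# Block-mean downsampling by an integer factor; trailing rows/columns that
# do not fill a block are dropped.
block_mean <- function(f, k) {
  h <- (nrow(f) %/% k) * k
  w <- (ncol(f) %/% k) * k
  if (h < k || w < k) stop_invalid("frame too small for downsample factor")
  f <- f[seq_len(h), seq_len(w), drop = FALSE]
  # average over k x k blocks
  g <- rowsum(f, rep(seq_len(h %/% k), each = k))
  g <- t(rowsum(t(g), rep(seq_len(w %/% k), each = k)))
  g / k^2
}
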