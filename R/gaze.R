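#' Gaze tables
#'
#' Long-format table of normalized gaze coordinates: one row per
#' (observer, frame) with `x`, `y` in \[0, 1\]. This is the input of the
#' gaze-based temporal salience score that the visual score generalises.
#'
#' @param observer integer/character observer identifiers.
#' @param t 1-based frame indices.
#' @param x,y normalized gaze coordinates in \[0, 1\].
#' @param n_frames total series length `T`; defaults to `max(t)`.
#' @return A `data.frame` of class `gaze_table` with attributes
#'   `n_observers` and `n_frames`.
#' @export
gaze_table <- function(observer, t, x, y, n_frames = NULL) {
  t <- as.integer(t)
  if (any(t < 1L)) stop_invalid("frame indices must be >= 1")
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x < 0 | x > 1) || any(y < 0 | y > 1))
    stop_invalid("gaze coordinates must be finite and in [0, 1]")
  df <- data.frame(observer = observer, t = t, x = x, y = y)
  if (anyDuplicated(df[, c("observer", "t")]))
    stop_invalid("at most one gaze record per (observer, t)")
  attr(df, "n_observers") <- length(unique(observer))
  attr(df, "n_frames") <- as.integer(n_frames %||% max(t))
  class(df) <- c("gaze_table", "data.frame")
  df
}

#' Gaze points within a temporal window
#'
#' Collects all gaze records whose frame index falls in the window
#' `[t - theta_t, t + theta_t]` (clipped to `[1, T]`), pooling observers.
#' The window has nominal length `2 * theta_t + 1` frames.
#'
#' @param gaze a [gaze_table()].
#' @param t centre frame (1-based).
#' @param theta_t temporal half-window in frames (>= 0).
#' @return The subset of rows of `gaze` in the window (possibly empty).
#' @export
gather_window <- function(gaze, t, theta_t = 0L) {
  n_frames <- attr(gaze, "n_frames") %||% max(gaze$t)
  if (t < 1L || t > n_frames) stop_invalid("`t` outside [1, T]")
  if (theta_t < 0) stop_invalid("`theta_t` must be >= 0")
  lo <- max(1L, t - theta_t)
  hi <- min(n_frames, t + theta_t)
  gaze[gaze$t >= lo & gaze$t <= hi, , drop = FALSE]
}

#' Gaze pair-agreement score
#'
#' The fraction of unordered point pairs whose Euclidean distance (in
#' normalized coordinates) is strictly below `theta_s`:
#' \deqn{s_G = \frac{\#\{(i,j): i<j,\ d_{ij} < \theta_s\}}{n(n-1)/2}.}
#' With fewer than two points the score is undefined and `NA` is returned.
#'
#' @param points a two-column matrix / data.frame of `x`, `y` coordinates
#'   (a [gather_window()] result works directly).
#' @param theta_s spatial threshold in normalized units (> 0); 0.1 is the
#'   customary choice for coordinates normalized to \[0, 1\].
#' @return A number in \[0, 1\], or `NA` if fewer than two points.
#' @export
gaze_score <- function(points, theta_s = 0.1) {
  check_scalar_number(theta_s, "theta_s", positive = TRUE)
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  n <- nrow(points)
  if (is.null(n) || n < 2L) return(NA_real_)
  count_close_pairs(points, theta_s) / (n * (n - 1) / 2)
}

#' Gaze-based temporal salience score series
#'
#' For every frame `t` in `1..T`, pools the gaze points in the temporal
#' window and computes the pair-agreement score.
#'
#' @inheritParams gather_window
#' @inheritParams gaze_score
#' @return Numeric vector of length `T` (`NA` where fewer than two points
#'   fall in the window), with attributes `theta_t`, `theta_s`.
#' @export
gaze_score_series <- function(gaze, theta_t = 0L, theta_s = 0.1) {
  n_frames <- attr(gaze, "n_frames") %||% max(gaze$t)
  s <- vapply(seq_len(n_frames), function(t) {
    gaze_score(gather_window(gaze, t, theta_t), theta_s)
  }, numeric(1))
  structure(s, theta_t = theta_t, theta_s = theta_s)
}
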