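#' Cosine distance between feature vectors
#'
#' `1 - u.v / (||u|| ||v||)`, in \[0, 2\]: 0 for parallel, 1 for
#' orthogonal, 2 for anti-parallel vectors. Scale-invariant, which is why
#' no per-subject feature normalization is required before comparing EEG
#' feature vectors. (Note the full range is \[0, 2\], not \[-1, 1\]: the
#' similarity is bounded by \[-1, 1\], the distance is not.)
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return A number in \[0, 2\].
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_invalid("cosine distance undefined for zero-norm vectors")
  1 - sum(u * v) / (nu * nv)
}

# All unordered pairwise cosine distances among the rows of a matrix.
pairwise_cosine <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0))
    stop_invalid("cosine distance undefined for zero-norm vectors")
  Mn <- M / nrm
  D <- 1 - tcrossprod(Mn)
  D[upper.tri(D)]
}

#' Inter-subject consistency at one timestep
#'
#' Fraction of unordered subject pairs whose feature vectors are closer
#' than `theta_s_cos` in cosine distance — the brain-signal counterpart of
#' the gaze pair-agreement score, with feature-space proximity replacing
#' screen-space proximity.
#'
#' @param vectors `subjects x k` matrix, one feature vector per row.
#' @param theta_s_cos threshold on the cosine distance, in (0, 2).
#' @return A number in \[0, 1\], or `NA` with fewer than two subjects.
#' @export
consistency_at_t <- function(vectors, theta_s_cos) {
  check_scalar_number(theta_s_cos, "theta_s_cos", positive = TRUE)
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 2L) return(NA_real_)
  d <- pairwise_cosine(vectors)
  sum(d < theta_s_cos) / length(d)
}

#' Calibrate the consistency threshold from pooled distances
#'
#' The brain-score threshold has no universal value; the documented default
#' recipe sets it to a quantile (median by default) of all pairwise cosine
#' distances pooled over the video's timesteps, which keeps the score's
#' base rate away from 0/1 saturation.
#'
#' @param tensor `subjects x T x k` array from [eeg_feature_tensor()].
#' @param q quantile in (0, 1); 0.5 = median.
#' @return The calibrated threshold (scalar).
#' @export
calibrate_consistency_threshold <- function(tensor, q = 0.5) {
  d <- unlist(lapply(seq_len(dim(tensor)[2L]), function(t) {
    pairwise_cosine(tensor[, t, , drop = TRUE])
  }))
  as.numeric(stats::quantile(d, q, names = FALSE))
}

#' Brain-based temporal salience score series
#'
#' For each timestep, the fraction of subject pairs whose EEG feature
#' vectors agree (cosine distance below threshold). No temporal window is
#' applied: the features are computed from time windows of the signal, so
#' temporal smoothing is already implicit.
#'
#' @param tensor `subjects x T x k` array from [eeg_feature_tensor()].
#' @param theta_s_cos threshold on the cosine distance; `NULL` calibrates
#'   it via [calibrate_consistency_threshold()] with quantile `q`.
#' @param q calibration quantile used when `theta_s_cos` is `NULL`.
#' @return Numeric vector of length `T` in \[0, 1\] with attribute
#'   `theta_s_cos` recording the threshold actually used.
#' @export
brain_score_series <- function(tensor, theta_s_cos = NULL, q = 0.5) {
  if (length(dim(tensor)) != 3L)
    stop_invalid("`tensor` must be a subjects x T x k array")
  if (dim(tensor)[1L] < 2L)
    stop_invalid("at least two subjects required")
  theta_s_cos <- theta_s_cos %||% calibrate_consistency_threshold(tensor, q)
  s <- vapply(seq_len(dim(tensor)[2L]), function(t) {
    consistency_at_t(tensor[, t, , drop = TRUE], theta_s_cos)
  }, numeric(1))
  structure(s, theta_s_cos = theta_s_cos)
}
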