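#' Smoothing specifications
#'
#' Constructor for the smoothing applied to temporal score series before
#' comparison: `"gaussian"` (kernel standard deviation `sigma` in
#' timesteps, truncated at 4 sigma, reflection padding), `"mean"` (boxcar
#' of odd `width`), or `"none"`.
#'
#' @param kind `"gaussian"`, `"mean"` or `"none"`.
#' @param sigma Gaussian kernel standard deviation (timesteps).
#' @param width mean-filter window length (odd integer).
#' @return A list of class `smoother`.
#' @export
smoother <- function(kind = c("none", "gaussian", "mean"), sigma = 1,
                     width = 3L) {
  kind <- match.arg(kind)
  if (kind == "gaussian") check_scalar_number(sigma, "sigma", positive = TRUE)
  if (kind == "mean") {
    width <- as.integer(width)
    if (width < 1L || width %% 2L == 0L)
      stop_invalid("mean filter `width` must be a positive odd integer")
  }
  structure(list(kind = kind, sigma = sigma, width = width),
            class = "smoother")
}

as_smoother <- function(x) {
  if (inherits(x, "smoother")) return(x)
  if (is.null(x)) return(smoother("none"))
  if (is.character(x) && length(x) == 1L) return(smoother(x))
  stop_invalid("cannot interpret smoothing specification")
}

#' Smooth a temporal score series
#'
#' Missing values (degenerate frames) are first linearly interpolated from
#' their neighbours, then the kernel is applied with reflection padding so
#' the output has the same length and a constant series passes through
#' unchanged. `kind = "none"` is the identity (missing values preserved).
#'
#' @param series numeric score series (may contain `NA`).
#' @param spec a [smoother()] (or `"gaussian"`/`"mean"`/`"none"` shorthand).
#' @return Smoothed series, same length.
#' @export
smooth_score <- function(series, spec = smoother("none")) {
  spec <- as_smoother(spec)
  if (spec$kind == "none") return(as.numeric(series))
  x <- interp_na(as.numeric(series))
  kern <- switch(spec$kind,
    gaussian = {
      r <- max(1L, ceiling(4 * spec$sigma))
      k <- stats::dnorm(-r:r, sd = spec$sigma)
      k / sum(k)
    },
    mean = rep(1 / spec$width, spec$width))
  r <- (length(kern) - 1L) %/% 2L
  n <- length(x)
  if (n == 1L) return(x)
  # reflection padding (without repeating the edge sample)
  idx_pre <- pmin(pmax(seq(r + 1L, 2L, by = -1L), 1L), n)
  idx_post <- pmin(pmax(seq(n - 1L, n - r, by = -1L), 1L), n)
  xp <- c(x[idx_pre], x, x[idx_post])
  as.numeric(stats::filter(xp, kern, sides = 2L))[(r + 1L):(r + n)]
}

#' Does one aligned segment pair match?
#'
#' Decides whether two temporally aligned segments of the visual and brain
#' score series are "close enough" under the chosen criterion:
#' \describe{
#'   \item{`spearman`}{rank correlation of the two segments `> theta_c`
#'     (segments of length >= 2; a constant segment has undefined rank
#'     correlation and counts as a non-match, flagged degenerate).}
#'   \item{`abs_diff`}{`|v_i - b_i| < theta_c` for every element.}
#'   \item{`sign`}{the first differences have equal sign at every step
#'     (`theta_c = 0` convention: simultaneous increase/decrease).}
#' }
#'
#' @param seg_v,seg_b numeric segments of equal length.
#' @param criterion `"spearman"`, `"abs_diff"` or `"sign"`.
#' @param theta_c criterion threshold.
#' @return Logical; non-matches caused by a constant segment under
#'   `spearman` carry attribute `degenerate = TRUE`.
#' @export
segment_match <- function(seg_v, seg_b, criterion = "spearman",
                          theta_c = 0.4) {
  if (length(seg_v) != length(seg_b))
    stop_invalid("segments must have equal length")
  switch(criterion,
    spearman = {
      if (length(seg_v) < 2L)
        stop_invalid("spearman criterion needs segments of length >= 2")
      if (stats::sd(seg_v) == 0 || stats::sd(seg_b) == 0)
        return(structure(FALSE, degenerate = TRUE))
      stats::cor(seg_v, seg_b, method = "spearman") > theta_c
    },
    abs_diff = all(abs(seg_v - seg_b) < theta_c),
    sign = {
      if (length(seg_v) < 2L)
        stop_invalid("sign criterion needs segments of length >= 2")
      all(sign(diff(seg_v)) == sign(diff(seg_b)))
    },
    stop_invalid("unknown criterion: ", criterion))
}

#' Local matching ratio between two score series
#'
#' Slides aligned windows of length `l` (stride 1, fully contained) along
#' the smoothed visual and brain score series and counts matching tests:
#' \deqn{\rho = \frac{1}{M}\sum_{k=1}^{M} \mathbf{1}[c(s_V^{(k)},
#'   s_B^{(k)}; \theta_c)].}
#' For element-wise criteria (`abs_diff`, `sign`) every window is one test,
#' so `M = T - l + 1`. For correlation criteria (`spearman`) a matching
#' window marks all `l` positions it covers and `rho` is the fraction of
#' marked positions, so `M = T`.
#'
#' @param s_v,s_b numeric series of equal length `T` (NAs from degenerate
#'   frames are interpolated).
#' @param l window length in timesteps, `1 <= l <= T` (>= 2 for
#'   `spearman`/`sign`).
#' @param criterion,theta_c see [segment_match()].
#' @param smooth_v,smooth_b [smoother()] specs applied to each series
#'   before comparison (default: none).
#' @return Object of class `local_rho`: list with `rho`, `match_mask`
#'   (length `T`), `window_match` (length `T - l + 1`), `M`, and the
#'   parameters used.
#' @export
local_rho <- function(s_v, s_b, l = 5L, criterion = "spearman",
                      theta_c = 0.4, smooth_v = smoother("none"),
                      smooth_b = smoother("none")) {
  s_v <- as.numeric(s_v); s_b <- as.numeric(s_b)
  if (length(s_v) != length(s_b))
    stop_invalid("series must have equal length")
  n <- length(s_v)
  l <- as.integer(l)
  if (l < 1L || l > n) stop_invalid("`l` must be in [1, T]")
  v <- interp_na(smooth_score(s_v, smooth_v))
  b <- interp_na(smooth_score(s_b, smooth_b))
  n_win <- n - l + 1L
  win_match <- vapply(seq_len(n_win), function(t) {
    idx <- t:(t + l - 1L)
    isTRUE(segment_match(v[idx], b[idx], criterion, theta_c))
  }, logical(1))
  elementwise <- criterion %in% c("abs_diff", "sign")
  mask <- logical(n)
  for (t in which(win_match)) mask[t:(t + l - 1L)] <- TRUE
  if (elementwise) {
    M <- n_win
    rho <- sum(win_match) / M
  } else {
    M <- n
    rho <- sum(mask) / M
  }
  structure(list(rho = rho, match_mask = mask, window_match = win_match,
                 M = M, l = l, criterion = criterion, theta_c = theta_c,
                 n = n),
            class = "local_rho")
}

#' @export
print.local_rho <- function(x, ...) {
  cat(sprintf("<local_rho: rho = %.4f (%s, l = %d, theta_c = %g, M = %d)>\n",
              x$rho, x$criterion, x$l, x$theta_c, x$M))
  invisible(x)
}
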