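#' Temporal shuffling of a score series
#'
#' Uniformly random permutation of the series under a seeded generator:
#' the value distribution is preserved exactly while the temporal structure
#' is destroyed, giving the null reference for the local matching ratio.
#'
#' @param s_b numeric series.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return Permuted series of the same length.
#' @export
permute_series <- function(s_b, seed = NULL) {
  n <- length(s_b)
  if (n < 2L) return(s_b)
  if (is.null(seed)) return(s_b[sample.int(n)])
  with_preserved_rng({
    set.seed(seed)
    s_b[sample.int(n)]
  })
}

#' Permutation baseline of the matching ratio
#'
#' Recomputes [local_rho()] against temporally shuffled copies of the
#' brain score and returns the per-permutation values and their mean.
#' Shuffling is applied to the raw series; the comparison pipeline
#' (smoothing included) is then identical to the observed one.
#'
#' @inheritParams local_rho
#' @param n_perm number of random permutations (>= 1).
#' @param seed integer seed driving a per-permutation seed sequence.
#' @return List with `values` (length `n_perm`) and `mean`.
#' @export
baseline_rho <- function(s_v, s_b, l = 5L, criterion = "spearman",
                         theta_c = 0.4, smooth_v = smoother("none"),
                         smooth_b = smoother("none"), n_perm = 10L,
                         seed = NULL) {
  if (n_perm < 1L) stop_invalid("`n_perm` must be >= 1")
  seeds <- if (is.null(seed)) rep(list(NULL), n_perm)
           else as.list(derive_seeds(seed, n_perm))
  vals <- vapply(seq_len(n_perm), function(p) {
    local_rho(s_v, permute_series(s_b, seeds[[p]]), l, criterion, theta_c,
              smooth_v, smooth_b)$rho
  }, numeric(1))
  list(values = vals, mean = mean(vals))
}

effect_size_breaks <- c(0, 0.01, 0.2, 0.5, 0.8, 1.2, 2.0, Inf)
effect_size_names <- c("negligible", "very small", "small", "medium",
                       "large", "very large", "huge")

#' Qualitative label for an effect size
#'
#' Ranges extending Cohen's original small/medium/large convention:
#' very small (0.01), small (0.2), medium (0.5), large (0.8), very large
#' (1.2) and huge (2.0), applied to `|d|`.
#'
#' @param d effect size value(s).
#' @return Character vector of labels.
#' @export
effect_size_label <- function(d) {
  as.character(cut(abs(d), breaks = effect_size_breaks,
                   labels = effect_size_names, right = FALSE))
}

#' Cohen's d between observed and baseline matching ratios
#'
#' Standardized difference between the mean observed ratio and the mean
#' baseline ratio over a set of videos:
#' \deqn{d = \frac{\rho_m - \tilde\rho_m}{s_p}.}
#' In `mode = "standard"` the pooled scale is the conventional
#' \eqn{s_p = \sqrt{(\rho_s^2 + \tilde\rho_s^2)/2}} with sample standard
#' deviations (denominator `n - 1`); `mode = "literal"` uses
#' \eqn{s_p = (\rho_s^2 + \tilde\rho_s^2)/2} (the variance-scale
#' expression), kept for exact-replication studies.
#'
#' @param rhos per-video observed matching ratios.
#' @param rho_tildes per-video baseline ratios (same length).
#' @param mode `"standard"` (default) or `"literal"`.
#' @return Object of class `effect_size`: list with `d`, the group means
#'   and standard deviations, `s_p`, `n_videos`, `mode` and the
#'   qualitative `label`.
#' @export
cohens_d <- function(rhos, rho_tildes, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (length(rhos) < 2L || length(rho_tildes) < 2L)
    stop_invalid("Cohen's d needs at least two videos per group")
  m1 <- mean(rhos); m2 <- mean(rho_tildes)
  s1 <- stats::sd(rhos); s2 <- stats::sd(rho_tildes)
  s_p <- switch(mode,
    standard = sqrt((s1^2 + s2^2) / 2),
    literal = (s1^2 + s2^2) / 2)
  if (s_p == 0)
    stop_invalid("zero pooled scale: effect size undefined")
  d <- (m1 - m2) / s_p
  structure(list(d = d, rho_mean = m1, rho_tilde_mean = m2,
                 rho_sd = s1, rho_tilde_sd = s2, s_p = s_p,
                 n_videos = length(rhos), mode = mode,
                 label = effect_size_label(d)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s; mode = %s)\n", x$d, x$label, x$mode))
  cat(sprintf("  rho: %.4f (sd %.4f)   baseline: %.4f (sd %.4f)   n = %d\n",
              x$rho_mean, x$rho_sd, x$rho_tilde_mean, x$rho_tilde_sd,
              x$n_videos))
  invisible(x)
}
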