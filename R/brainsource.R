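#' Relate temporal visual salience to inter-subject brain consistency
#'
#' The package's central estimator. Given per-video visual salience score
#' series and brain consistency score series, it computes the local
#' matching ratio \eqn{\rho} ([local_rho()]) for every cell of an
#' `(l, theta_c)` grid, a temporal-permutation baseline \eqn{\tilde\rho}
#' ([baseline_rho()]), and the Cohen's d effect size of their difference
#' across videos ([cohens_d()]). A relevant visual-brain coupling shows as
#' \eqn{\rho} exceeding its shuffled baseline with a non-trivial effect
#' size.
#'
#' The same `n_perm` shuffles of each video's brain score are reused for
#' every grid cell. Effect sizes are computed once per permutation (each
#' permutation gives one baseline value per video) and reported as their
#' mean with the standard error over permutations.
#'
#' @param s_v visual score series: numeric vector (one video) or list of
#'   vectors (one per video).
#' @param s_b brain score series, same shape as `s_v`.
#' @param l vector of window lengths (timesteps).
#' @param theta_c vector of criterion thresholds.
#' @param criterion comparison criterion; see [segment_match()].
#' @param smooth_v,smooth_b [smoother()] specs applied before comparison.
#'   Defaults follow the 1-s segment protocol: Gaussian sd 1 for the
#'   visual series and sd 2 for the brain series.
#' @param n_perm number of permutations for the baseline.
#' @param seed integer seed for the permutations (strongly recommended).
#' @param d_mode `"standard"` or `"literal"`; see [cohens_d()].
#' @return Object of class `brainsource`: list with `grid` (one row per
#'   cell: `l`, `theta_c`, `rho_mean`, `rho_se`, `rho_tilde_mean`,
#'   `rho_tilde_se`, `d`, `d_se`, `label`), `rho` (videos x cells),
#'   `rho_tilde` (videos x perms x cells), and the parameters used.
#' @examples
#' set.seed(1)
#' s <- lapply(1:4, function(i) runif(30))
#' b <- lapply(s, function(x) pmin(pmax(x + rnorm(30, sd = 0.05), 0), 1))
#' fit <- brainsource(s, b, l = 5, theta_c = 0.4, n_perm = 5, seed = 7)
#' print(fit)
#' @export
brainsource <- function(s_v, s_b, l = 5L, theta_c = 0.4,
                        criterion = "spearman",
                        smooth_v = smoother("gaussian", sigma = 1),
                        smooth_b = smoother("gaussian", sigma = 2),
                        n_perm = 10L, seed = NULL,
                        d_mode = c("standard", "literal")) {
  d_mode <- match.arg(d_mode)
  if (is.numeric(s_v)) s_v <- list(s_v)
  if (is.numeric(s_b)) s_b <- list(s_b)
  if (length(s_v) != length(s_b))
    stop_invalid("`s_v` and `s_b` must cover the same videos")
  n_videos <- length(s_v)
  if (n_videos < 1L) stop_invalid("no videos")
  smooth_v <- as_smoother(smooth_v); smooth_b <- as_smoother(smooth_b)
  grid <- expand.grid(l = as.integer(l), theta_c = theta_c,
                      KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(grid)

  # one set of temporal shuffles per video, reused across the grid
  seeds <- if (is.null(seed)) NULL else derive_seeds(seed, n_videos * n_perm)
  perms <- lapply(seq_len(n_videos), function(v) {
    lapply(seq_len(n_perm), function(p) {
      s <- if (is.null(seeds)) NULL else seeds[(v - 1L) * n_perm + p]
      permute_series(as.numeric(s_b[[v]]), s)
    })
  })

  rho <- matrix(NA_real_, n_videos, n_cells)
  rho_tilde <- array(NA_real_, c(n_videos, n_perm, n_cells))
  for (cell in seq_len(n_cells)) {
    li <- grid$l[cell]; th <- grid$theta_c[cell]
    for (v in seq_len(n_videos)) {
      rho[v, cell] <- local_rho(s_v[[v]], s_b[[v]], li, criterion, th,
                                smooth_v, smooth_b)$rho
      for (p in seq_len(n_perm)) {
        rho_tilde[v, p, cell] <- local_rho(s_v[[v]], perms[[v]][[p]], li,
                                           criterion, th, smooth_v,
                                           smooth_b)$rho
      }
    }
  }

  se <- function(x) stats::sd(x) / sqrt(length(x))
  grid$rho_mean <- colMeans(rho)
  grid$rho_se <- apply(rho, 2L, se)
  tilde_by_video <- apply(rho_tilde, c(1L, 3L), mean)  # videos x cells
  grid$rho_tilde_mean <- colMeans(tilde_by_video)
  grid$rho_tilde_se <- apply(tilde_by_video, 2L, se)
  d_mat <- matrix(NA_real_, n_perm, n_cells)
  if (n_videos >= 2L) {
    for (cell in seq_len(n_cells)) {
      for (p in seq_len(n_perm)) {
        d_mat[p, cell] <- tryCatch(
          cohens_d(rho[, cell], rho_tilde[, p, cell], mode = d_mode)$d,
          error = function(e) NA_real_)
      }
    }
  }
  grid$d <- colMeans(d_mat)
  grid$d_se <- apply(d_mat, 2L, function(x)
    if (all(is.na(x))) NA_real_ else stats::sd(x, na.rm = TRUE) /
      sqrt(sum(!is.na(x))))
  grid$label <- ifelse(is.na(grid$d), NA_character_,
                       effect_size_label(grid$d))

  structure(list(grid = grid, rho = rho, rho_tilde = rho_tilde,
                 d_by_perm = d_mat, n_videos = n_videos, n_perm = n_perm,
                 criterion = criterion, smooth_v = smooth_v,
                 smooth_b = smooth_b, seed = seed, d_mode = d_mode,
                 call = match.call()),
            class = "brainsource")
}

#' @export
print.brainsource <- function(x, digits = 3, ...) {
  cat(sprintf("Brainsourcing fit: %d video(s), %d permutation baseline, criterion = %s\n",
              x$n_videos, x$n_perm, x$criterion))
  g <- x$grid
  tab <- data.frame(l = g$l, theta_c = g$theta_c,
                    rho = sprintf("%.*f [%.*f]", digits, g$rho_mean,
                                  digits, g$rho_se),
                    baseline = sprintf("%.*f [%.*f]", digits,
                                       g$rho_tilde_mean, digits,
                                       g$rho_tilde_se),
                    d = round(g$d, digits), effect = g$label)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.brainsource <- function(object, ...) {
  structure(list(grid = object$grid, n_videos = object$n_videos,
                 n_perm = object$n_perm, criterion = object$criterion,
                 d_mode = object$d_mode, seed = object$seed),
            class = "summary.brainsource")
}

#' @export
print.summary.brainsource <- function(x, ...) {
  cat("Local matching ratio vs temporal-permutation baseline\n")
  cat(sprintf("  videos: %d, permutations: %d, criterion: %s, d mode: %s\n",
              x$n_videos, x$n_perm, x$criterion, x$d_mode))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' @export
coef.brainsource <- function(object, ...) {
  g <- object$grid
  stats::setNames(g$d, sprintf("l=%d,theta_c=%g", g$l, g$theta_c))
}

#' Plot effect sizes across the comparison grid
#'
#' Cohen's d against the comparison threshold, one line per window length,
#' with the qualitative range boundaries (0.2, 0.5, 0.8, 1.2, 2) dashed.
#'
#' @param x a [brainsource()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.brainsource <- function(x, ...) {
  g <- x$grid
  ls <- sort(unique(g$l)); ths <- sort(unique(g$theta_c))
  D <- matrix(NA_real_, length(ths), length(ls))
  for (i in seq_along(ths)) for (j in seq_along(ls))
    D[i, j] <- g$d[g$l == ls[j] & g$theta_c == ths[i]][1L]
  graphics::matplot(ths, D, type = "b", pch = 19, lty = 1,
                    xlab = expression(theta[c]), ylab = "Cohen's d", ...)
  graphics::abline(h = c(0.2, 0.5, 0.8, 1.2, 2), lty = 3,
                   col = "grey60")
  graphics::legend("topleft", legend = paste("l =", ls), col = seq_along(ls),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}

# Shipped 10-20 lobe assignment. The occipital group is deliberately the
# three O* electrodes only (PO3/PO4 are counted as parietal).
default_channel_groups <- function() {
  list(
    prefrontal = c("Fp1", "Fp2", "Fpz", "AF3", "AF4", "AF7", "AF8", "AFz"),
    frontal = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
                "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
                "FT7", "FT8"),
    temporal = c("T7", "T8", "TP7", "TP8", "FT9", "FT10", "TP9", "TP10"),
    parietal = c("CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
                 "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
                 "PO3", "PO4", "PO7", "PO8", "POz"),
    occipital = c("O1", "Oz", "O2"))
}

#' Channel subsets by scalp region
#'
#' Resolves a named electrode group against a montage, using a standard
#' 10-20 lobe assignment (user-overridable). Available groups:
#' `"occipital"` (O1/Oz/O2 only — the PO* electrodes count as parietal),
#' `"parietal"`, `"temporal"`, `"frontal"`, `"prefrontal"`,
#' `"no occipital"` (complement of occipital) and `"all"`.
#'
#' @param montage_labels channel labels present in the recording.
#' @param group_name one of the group names above (case-insensitive;
#'   `"no_occipital"` also accepted).
#' @param groups optional named list of character vectors overriding the
#'   shipped assignment.
#' @return The subset of `montage_labels` in the group, montage order
#'   preserved.
#' @export
channel_group <- function(montage_labels, group_name,
                          groups = default_channel_groups()) {
  key <- tolower(gsub("[ _-]+", " ", group_name))
  if (key == "all") return(montage_labels)
  lower <- tolower(montage_labels)
  if (key == "no occipital") {
    occ <- tolower(groups$occipital)
    return(montage_labels[!(lower %in% occ)])
  }
  key <- gsub(" ", "", key)
  if (!key %in% names(groups))
    stop_invalid("unknown channel group: ", group_name)
  out <- montage_labels[lower %in% tolower(groups[[key]])]
  if (length(out) == 0L)
    stop_invalid("group '", group_name, "' matches no montage channel")
  out
}
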