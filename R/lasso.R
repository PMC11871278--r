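#' Build the sparse-regression design from feature tensors
#'
#' Stacks one row per temporal segment per video: row `t` of a video's
#' block is the sum of the feature vectors over its `K` subjects,
#' \eqn{\sum_k f_t^{(k)}}, and the response is the visual score
#' \eqn{s_V(t)} of the same segment. Videos are stacked in the order
#' given.
#'
#' @param tensors list of `subjects x T x k` arrays
#'   ([eeg_feature_tensor()]), one per video, sharing one label set.
#' @param s_v_series list of visual score series, `T` matching per video.
#' @return Object of class `lasso_problem`: list with `X` (`N x M`), `y`
#'   (length `N`), `feature_labels`, and `video` (row provenance).
#' @export
build_design <- function(tensors, s_v_series) {
  if (length(tensors) != length(s_v_series))
    stop_invalid("one score series per tensor required")
  labels <- dimnames(tensors[[1L]])[[3L]]
  blocks <- vector("list", length(tensors))
  ys <- vector("list", length(tensors))
  for (v in seq_along(tensors)) {
    tensor <- tensors[[v]]
    if (!identical(dimnames(tensor)[[3L]], labels))
      stop_invalid("tensors must share one feature label set")
    s_v <- as.numeric(s_v_series[[v]])
    if (dim(tensor)[2L] != length(s_v))
      stop_invalid("video ", v, ": tensor T and series length differ")
    # sum over subjects -> T x k
    blocks[[v]] <- apply(tensor, c(2L, 3L), sum)
    ys[[v]] <- s_v
  }
  X <- do.call(rbind, blocks)
  colnames(X) <- labels
  y <- unlist(ys, use.names = FALSE)
  if (anyNA(y)) {
    y <- interp_na(y)
  }
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop_invalid("design contains non-finite entries")
  structure(list(X = X, y = y, feature_labels = labels,
                 video = rep(seq_along(tensors),
                             vapply(ys, length, 0L))),
            class = "lasso_problem")
}

#' LASSO fit of brain features against the visual score
#'
#' Solves \deqn{\min_w \frac{1}{2N}\|Xw - y\|_2^2 + \lambda \|w\|_1}
#' (no intercept, no column standardization by default — the objective is
#' taken literally; both are available as flags, with the caveat that
#' unstandardized features of very different scales make selection
#' scale-driven). The L1 penalty drives inactive coefficients to exact
#' zero. Fitting is delegated to \pkg{glmnet}, whose Gaussian objective is
#' exactly the one above; `lambda = 0` falls back to ordinary least
#' squares.
#'
#' @param problem a [build_design()] result (or a list with `X`, `y`).
#' @param lambda penalty value(s) >= 0.
#' @param intercept fit an unpenalized intercept (default `FALSE`).
#' @param standardize standardize columns internally (default `FALSE`).
#' @return For one `lambda`, a named weight vector (attributes `lambda`
#'   and `intercept`); for several, an `M x length(lambda)` matrix.
#' @export
lasso_fit <- function(problem, lambda, intercept = FALSE,
                      standardize = FALSE) {
  X <- problem$X; y <- problem$y
  if (any(lambda < 0)) stop_invalid("`lambda` must be >= 0")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop_invalid("non-finite entries in the design")
  W <- matrix(0, ncol(X), length(lambda),
              dimnames = list(colnames(X), NULL))
  ic <- numeric(length(lambda))
  pos <- lambda > 0
  if (any(pos)) {
    # fit one warm-started path containing every requested penalty (plus a
    # few larger values that only help convergence), then read the
    # coefficients off the path at the exact positions
    lam_desc <- sort(unique(c(lambda[pos], max(lambda[pos]) * c(8, 4, 2))),
                     decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "gaussian",
                          lambda = lam_desc, intercept = intercept,
                          standardize = standardize, thresh = 1e-12,
                          maxit = 1e6)
    for (j in which(pos)) {
      idx <- which.min(abs(fit$lambda - lambda[j]))
      ic[j] <- fit$a0[idx]
      W[, j] <- as.numeric(fit$beta[, idx])
    }
  }
  if (any(!pos)) {
    # penalty-free limit: ordinary least squares
    for (j in which(!pos)) {
      if (intercept) {
        cf <- stats::lm.fit(cbind(1, X), y)$coefficients
        ic[j] <- cf[1L]; W[, j] <- cf[-1L]
      } else {
        W[, j] <- stats::lm.fit(X, y)$coefficients
      }
      W[is.na(W[, j]), j] <- 0
    }
  }
  if (length(lambda) == 1L) {
    w <- W[, 1L]
    attr(w, "lambda") <- lambda
    attr(w, "intercept") <- ic[1L]
    return(w)
  }
  colnames(W) <- paste0("lambda_", lambda)
  attr(W, "lambda") <- lambda
  attr(W, "intercept") <- ic
  W
}

#' Features selected by a LASSO fit
#'
#' @param w weight vector from [lasso_fit()] (names = feature labels).
#' @param labels feature labels; defaults to `names(w)`.
#' @return List with `labels` (selected), `weights`, `table`
#'   (band/feature/channel breakdown), `count` and `percent` of the full
#'   feature set.
#' @export
selected_features <- function(w, labels = names(w)) {
  if (length(w) != length(labels))
    stop_invalid("`w` and `labels` lengths differ")
  nz <- which(w != 0)
  tab <- if (length(nz)) parse_feature_labels(labels[nz])
         else parse_feature_labels(character(0))
  tab$weight <- as.numeric(w[nz])
  list(labels = labels[nz], weights = as.numeric(w[nz]), table = tab,
       count = length(nz), percent = 100 * length(nz) / length(w))
}

#' Selection grid across a penalty path
#'
#' Convenience wrapper fitting a penalty grid and reporting, per lambda,
#' how many and which features stay active — sparsity is non-increasing as
#' the penalty grows.
#'
#' @inheritParams lasso_fit
#' @param lambdas penalty grid (default `c(0.1, 1, 10, 100)`).
#' @return `data.frame` with one row per lambda: `lambda`, `count`,
#'   `percent`; attribute `weights` holds the full `M x length(lambdas)`
#'   weight matrix.
#' @export
lasso_selection_path <- function(problem, lambdas = c(0.1, 1, 10, 100),
                                 intercept = FALSE, standardize = FALSE) {
  W <- lasso_fit(problem, lambdas, intercept, standardize)
  if (is.null(dim(W))) W <- matrix(W, ncol = 1L,
                                   dimnames = list(problem$feature_labels))
  counts <- colSums(W != 0)
  out <- data.frame(lambda = lambdas, count = as.integer(counts),
                    percent = 100 * counts / nrow(W))
  attr(out, "weights") <- W
  out
}
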