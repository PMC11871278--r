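# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_invalid <- function(...) stop(..., call. = FALSE)

# Linear interpolation of NA entries from their nearest non-NA neighbours;
# leading/trailing NAs take the nearest observed value. All-NA input is
# returned unchanged.
interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(x)
  if (length(ok) == 1L) return(rep(x[ok], length(x)))
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

# Shift a seed by a fixed offset without integer overflow (stays a valid
# 32-bit seed for any input seed).
offset_seed <- function(seed, k) {
  as.integer((as.numeric(seed) - 1 + as.numeric(k)) %% 2147483646) + 1L
}

# Deterministic stream of child seeds derived from one parent seed, without
# disturbing the caller's RNG state. Values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_preserved_rng({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
  })
}

# Evaluate `expr` while protecting the global RNG state.
with_preserved_rng <- function(expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# Pairwise Euclidean distances below which two points count as "close":
# returns the count of unordered pairs with distance strictly below theta.
count_close_pairs <- function(coords, theta) {
  d <- stats::dist(coords)
  sum(d < theta)
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_invalid(sprintf("`%s` must be positive", name))
  invisible(x)
}
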