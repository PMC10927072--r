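# Internal helpers shared across modules.

# Deterministic sub-seed derivation (Lehmer-style), keeps results inside
# 32-bit integer range so set.seed() never overflows.
derive_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, open = TRUE) {
  ok <- length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) stop(sprintf("`%s` must be a fraction in %s", name,
                        if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(as.numeric(x))
}

# Symmetric, zero-diagonal, non-negative check for distance matrices.
# `finite` additionally requires every entry to be finite.
assert_distance_matrix <- function(d, finite = FALSE) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || !is.numeric(d))
    stop("distance matrix must be a square numeric matrix", call. = FALSE)
  if (max(abs(diag(d))) > 1e-12)
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  fin <- is.finite(d)
  if (!isTRUE(all.equal(d[fin], t(d)[t(fin)], tolerance = 1e-8)) ||
      !identical(fin, t(fin)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(d[fin] < 0))
    stop("distance matrix entries must be non-negative", call. = FALSE)
  if (finite && !all(fin))
    stop("distance matrix contains non-finite entries; apply finite_fill() first",
         call. = FALSE)
  invisible(d)
}

# Upper-triangle (i < j) entries of a square matrix as a vector.
upper_entries <- function(d) d[upper.tri(d)]

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
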