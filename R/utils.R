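#' @keywords internal
"_PACKAGE"

# shared small helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

# squared euclidean cross-distance between rows of X (n x m) and rows of Y (k x m)
cross_dist2 <- function(X, Y) {
  xs <- rowSums(X^2)
  ys <- rowSums(Y^2)
  d2 <- outer(xs, ys, "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

# deterministic RNG scope: runs expr with a local seed, restores global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
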