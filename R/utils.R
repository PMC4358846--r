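# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Sum of each s x s block of X (X has dimensions (Ms*s) x (Ns*s)).
# Returns an Ms x Ns matrix. rowsum() runs in C, so this is the workhorse
# behind the vectorized segment statistics.
block_sums <- function(X, s) {
  Ms <- nrow(X) %/% s
  Ns <- ncol(X) %/% s
  gr <- rep(seq_len(Ms), each = s)
  gc <- rep(seq_len(Ns), each = s)
  out <- rowsum(X, gr, reorder = FALSE)
  out <- rowsum(t(out), gc, reorder = FALSE)
  t(out)
}

# Derive a sub-seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483587L) + 1L
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}
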