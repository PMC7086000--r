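# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Auto-detect the delimiter of a text table (comma vs tab).
detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

# Near-zero standard deviation test, scaled to the data magnitude.
is_degenerate_sd <- function(x) {
  s <- stats::sd(x)
  !is.finite(s) || s <= .Machine$double.eps^0.75 * max(1, max(abs(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
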