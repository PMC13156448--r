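# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180

#' @noRd
stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-replicate substream seeds derived from a master seed.
derive_seeds <- function(master, n) {
  (as.numeric(master) * 48271 + 7919 * seq_len(n)) %% 2147483587
}

check_number <- function(x, name, lo = -Inf, hi = Inf, closed_lo = TRUE,
                         closed_hi = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  ok_lo <- if (closed_lo) x >= lo else x > lo
  ok_hi <- if (closed_hi) x <= hi else x < hi
  if (!ok_lo || !ok_hi)
    stop_invalid("'%s' = %g outside the admissible range %s%g, %g%s", name, x,
                 if (closed_lo) "[" else "(", lo, hi,
                 if (closed_hi) "]" else ")")
  invisible(x)
}
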