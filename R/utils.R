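# internal helpers shared across modules

# Derive a reproducible sub-seed from a root seed and a stage label, so each
# simulation/analysis stage draws from an independent, regenerable stream.
# Kept below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi), call. = FALSE)
  invisible(x)
}

# symmetric matrix check with tolerance
is_symmetric_tol <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}
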