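# Internal helpers shared across modules.

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so simulations never perturb the user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a per-stage seed from one global seed; keeps results reproducible
# stage-by-stage while staying inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 16807) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Lookup table: ASCII code of an uppercase base -> 1 if G/C, 0 if A/T, NA if N.
gc_indicator <- function(chars_int) {
  out <- rep(NA_real_, length(chars_int))
  out[chars_int == 71L | chars_int == 67L] <- 1 # G, C
  out[chars_int == 65L | chars_int == 84L] <- 0 # A, T
  out
}

chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
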