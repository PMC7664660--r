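# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a temporary RNG state seeded with `seed`; with
# seed = NULL the current RNG stream is used (so a caller such as
# run_experiment() can drive generation, injection and correction from a
# single per-repetition generator in a fixed order).
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

is_odd <- function(x) x %% 2 == 1

`%||%` <- function(a, b) if (is.null(a)) b else a
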