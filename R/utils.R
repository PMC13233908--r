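# internal helpers shared across modules

# run `code` under a fixed RNG seed, restoring RNG state afterwards
with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

# derive a child seed from a parent seed and a stream index; kept < 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if ((strict && x <= lower) || (!strict && x < lower))
    stopf("`%s` must be %s %s", name, if (strict) ">" else ">=", format(lower))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
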