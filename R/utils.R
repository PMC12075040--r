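# internal helpers shared across modules

# Derive a reproducible child seed from a master seed.  `stream` separates
# independent uses of the same master seed within one computation; results
# stay in [1, 2^31 - 2] so they are valid R integer seeds.
sub_seed <- function(seed, i, stream = 0L) {
  s <- (as.numeric(seed) %% 1000003) * 1009 + as.numeric(stream) * 333331 +
    as.numeric(i) * 101
  as.integer(s %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
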