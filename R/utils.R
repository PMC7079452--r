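# Run expr with a local, seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from (seed, k) staying within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
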