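# Internal helpers: deterministic seed substreams and scoped RNG use.
#
# A single master seed fans out into named substreams so that, e.g., changing
# the anchor-sampling seed never perturbs the reservoir matrices.  The stream
# derivation is a plain polynomial string hash reduced mod 2^31 - 1; it only
# needs to be deterministic and well-spread, not cryptographic.

# Deterministic 31-bit hash of character labels.
hashLabels <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                    character(1)), collapse = "/")
  h <- 5381
  for (code in utf8ToInt(s)) h <- (h * 33 + code) %% 2147483647
  as.integer(h)
}

# Derive a substream seed from a master seed and labels.
seedStream <- function(seed, ...) {
  h <- hashLabels(...)
  as.integer((as.double(seed) * 2654435 + h) %% 2147483647)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
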