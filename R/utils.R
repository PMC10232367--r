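# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so simulations never disturb user code.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "bsitools_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed derivation: one master seed, one label per
# signal type. Stays below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- fnv1a32(paste0("bsitools:", label))
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# Tiny deterministic polynomial hash used for sub-stream seeds and for
# fingerprinting feature configurations in serialized models.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(as.character(x), collapse = "\x1f"))
  h <- 216613626
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  h
}

fnv1a32_hex <- function(x) sprintf("%08x", as.integer(fnv1a32(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "bsitools_config_error")
  }
}

# Forward (right-aligned at t .. t+n-1) rolling mean; trailing positions use
# the shrinking tail window.
roll_mean_forward <- function(x, n) {
  n <- as.integer(n)
  if (n <= 1L) return(x)
  cs <- cumsum(c(0, x))
  len <- length(x)
  ends <- pmin(seq_len(len) + n - 1L, len)
  (cs[ends + 1L] - cs[seq_len(len)]) / (ends - seq_len(len) + 1L)
}
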