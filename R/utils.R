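# internal helpers: error constructors, hashing, seed derivation

stop_fibroct <- function(class, message, call. = FALSE, ...) {
  cond <- structure(
    class = c(class, "fibroct_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a over a character string; returned as 8-hex-digit string.
# Multiplication is split into 16-bit halves to stay inside double precision.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  prime_lo <- 403   # 16777619 = 256*65536 + 403
  prime_hi <- 256
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime_lo + ((lo * prime_hi + hi * prime_lo) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# xor for doubles in [0, 2^32)
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648; lo_b <- b %% 2147483648
  xor_lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  xor_hi <- (hi_a + hi_b) %% 2
  xor_hi * 2147483648 + as.double(xor_lo)
}

# deterministic per-subject seed derived from a cohort seed and a subject id;
# keeps the result in [1, 2^31 - 2] so it is a valid R integer seed
derive_seed <- function(seed, subject_id) {
  h <- fnv1a32(paste0(seed, "::", subject_id))
  (strtoi(substr(h, 1, 7), base = 16L) %% 2147483645L) + 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
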