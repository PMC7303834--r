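# Internal helpers shared across modules.

# FNV-1a 32-bit hash over a character string, returned as 8 hex digits.
# Used only to fingerprint a model specification so that payloads produced
# under different specs cannot be aggregated together; collisions are
# harmless beyond a missed mismatch diagnostic.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    # 32-bit modular multiply by the FNV prime 16777619, exact in doubles
    # via a 16-bit split (intermediate products stay below 2^53).
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # render as hex; h < 2^32 so split into two 16-bit halves for sprintf
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# bitwXor on doubles that may exceed .Machine$integer.max
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a - a %% 65536) / 65536, (b - b %% 65536) / 65536)
  hi * 65536 + lo
}

# Render a double so that it round-trips bit-exactly through text.
fmt_real <- function(x) {
  sprintf("%.17g", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dranet <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "dranet_error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 1
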