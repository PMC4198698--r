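# Pseudonymization.
#
# Samples are never exposed to other users under their local names; each gets
# an opaque system sample id at registration. Tokens are a keyed hash over
# (center id, per-center insertion counter) with a deployment-secret salt, so
# they are deterministic (stable across restarts), unique per (center,
# counter), and never embed the local name. This is obfuscation for display
# and backlinking, not cryptography: pseudonymized genome data remains
# personal data.

# 32-bit FNV-1a in pure R. Multiplication mod 2^32 is done in two 16-bit
# halves to stay inside exact double-precision integer range.
fv_hash32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  prime <- 16777619
  two16 <- 65536
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- ((h %/% two16 * prime %% two16) * two16 + (h %% two16) * prime) %% two32
  }
  # h < 2^32 exceeds R's integer range; format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor for doubles holding 32-bit values (bitwXor needs ints, which overflow
# at 2^31).
bitwXor_dbl <- function(a, b) {
  two31 <- 2147483648
  hi <- xor(a >= two31, b >= two31)
  lo <- bitwXor(as.integer(a %% two31), as.integer(b %% two31))
  (if (hi) two31 else 0) + lo
}

#' Generate a pseudonymous system sample id
#'
#' Deterministic keyed-hash token over the center id and that center's
#' insertion counter, rendered as `"SID-"` plus 8 hex characters. The same
#' (salt, center, counter) always yields the same token; different centers or
#' counters yield different tokens (collisions over realistic registry sizes
#' are checked in the test suite). The token carries no information about the
#' sample's local name.
#'
#' @param center_id center token.
#' @param counter positive integer, monotone per center (insertion order).
#' @param salt deployment secret; defaults to a fixed development salt.
#' @return character scalar, e.g. `"SID-3fa1b202"`.
#' @export
#' @examples
#' make_pseudonym("C1", 1)
make_pseudonym <- function(center_id, counter, salt = "fedvarq-dev-salt") {
  stopifnot(is_scalar_chr(center_id), counter >= 1)
  paste0("SID-", fv_hash32(paste(salt, center_id, format(counter, scientific = FALSE), sep = "\x1f")))
}
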