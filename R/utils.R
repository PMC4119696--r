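# Deterministic substream seeding: one user-facing seed expands to
# independent per-(subject, behavior, channel, ...) streams by stable string
# hashing, so generated data do not depend on generation order.

# 32-bit FNV-1a over the UTF-8 bytes of a string; multiplication is split
# into 16-bit halves to stay exact in double precision.
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- bitwXor_num(h %% 2^32, b %% 256)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 2^32
  }
  h %% 2^32
}

# xor of two nonnegative numerics < 2^32 without integer overflow
bitwXor_num <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

# stable seed in [0, 2^31 - 2] from a base seed plus arbitrary components
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")),
               collapse = "/")
  as.integer(fnv1a32(key) %% (2^31 - 1))
}

# short hexadecimal content hash used to stamp configs into output files
config_hash <- function(x) {
  key <- paste(deparse(x, control = "all"), collapse = "")
  h <- fnv1a32(key)
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
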