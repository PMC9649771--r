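# Internal helpers shared across modules.

# Classed error helper so callers can condition on failure modes.
ts_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("traitstack_", class), "traitstack_error"), ...)
}

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a named substream seed from a master seed, so that changing one
# pipeline stage's draws does not perturb the others. Plain 32-bit
# polynomial string hash; result always a valid positive integer seed.
substream_seed <- function(master_seed, name) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- 0
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((abs(master_seed) + 1000003 * h) %% 2147483647)
}

# Number of set bits for masks 0..1023 (decile combination bitmasks).
popcount10 <- function(mask) {
  bits <- 2L^(0:9)
  vapply(mask, function(m) sum(bitwAnd(m, bits) > 0L), integer(1))
}

# Tiny polynomial string hash (mod 2^31 - 1), hex-encoded; used to tie
# manifest entries to the configuration that produced them.
config_hash_hex <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) {
    h <- (h * 131 + code) %% 2147483647
  }
  sprintf("%08x", h)
}
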