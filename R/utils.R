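# small internal helpers shared across modules

# FNV-1a 32-bit hash of a character scalar; used for provenance headers so
# outputs embed a config fingerprint without external digest dependencies.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (the FNV input is bytewise)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by 16777619 = 2^24 + 403, kept exact in
    # doubles: h*403 < 2^41 and (h mod 2^8)*2^24 < 2^32
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

ribodyn_version <- function() {
  as.character(utils::packageVersion("ribodyn"))
}

# provenance header lines for writers: tool version + content hash.
# Deliberately timestamp-free so identical inputs give byte-identical files.
provenance_header <- function(payload) {
  c(sprintf("# ribodyn %s", ribodyn_version()),
    sprintf("# sha=%s", fnv1a32(paste(payload, collapse = "\n"))))
}

# consistent numeric formatting for writers (full precision, reproducible)
fmt_num <- function(x) formatC(x, format = "g", digits = 15)

`%||%` <- function(a, b) if (is.null(a)) b else a
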