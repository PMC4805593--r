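#' Deterministic child seeds for labelled random streams
#'
#' All stochastic operations in the package draw from labelled, indexed
#' streams derived from one master seed, so that no simulation depends on
#' global RNG state and any sub-computation can be reproduced in isolation.
#' The stream label is hashed (MurmurHash3, 32-bit, keyed by the master
#' seed) to a stream base, and the index is added to the base.  Because
#' indices within a stream are mapped to consecutive seeds while distinct
#' labels land in widely separated regions of the 31-bit seed space,
#' collisions between (label, index) pairs are only possible when two label
#' bases fall closer together than the largest index in use.
#'
#' @param master Master seed, a single integer.
#' @param stream_label Character scalar naming the stream (e.g. `"trial"`).
#' @param index Non-negative integer offset within the stream.
#' @return A single integer in `[0, 2^31 - 1)`, suitable for [set.seed()].
#' @examples
#' derive_seed(42L, "trial", 0)
#' derive_seed(42L, "trial", 1)
#' @export
derive_seed <- function(master, stream_label, index = 0L) {
  stopifnot(length(master) == 1L, is.finite(master),
            is.character(stream_label), length(stream_label) == 1L,
            length(index) == 1L, is.finite(index), index >= 0)
  key <- paste0(master, "\r", stream_label)
  base <- .seed_cache[[key]]
  if (is.null(base)) {
    base <- murmur3_32(utf8ToInt(stream_label),
                       seed = as.integer(master %% 2147483647))
    .seed_cache[[key]] <- base
  }
  as.integer((base + index) %% 2147483647)
}

.seed_cache <- new.env(parent = emptyenv())

# MurmurHash3 x86_32 over a vector of byte values (0..255); pure-R, uses
# base 32-bit bitwise ops.  Returns a double in [0, 2^32).
murmur3_32 <- function(bytes, seed = 0L) {
  c1 <- -862048943L    # 0xcc9e2d51
  c2 <- 461845907L     # 0x1b873593
  h <- as.integer(seed)
  n <- length(bytes)
  nblocks <- n %/% 4L
  if (nblocks > 0L) {
    for (b in seq_len(nblocks)) {
      j <- (b - 1L) * 4L
      k <- bytes[j + 1L] + bytes[j + 2L] * 256 + bytes[j + 3L] * 65536 +
        bytes[j + 4L] * 16777216
      k <- to_i32(k)
      k <- imul32(k, c1)
      k <- rotl32(k, 15L)
      k <- imul32(k, c2)
      h <- bitwXor(h, k)
      h <- rotl32(h, 13L)
      h <- to_i32(u32(imul32(h, 5L)) + 3864292196)  # 0xe6546b64
    }
  }
  tail_n <- n %% 4L
  if (tail_n > 0L) {
    j <- nblocks * 4L
    k <- 0
    if (tail_n >= 3L) k <- k + bytes[j + 3L] * 65536
    if (tail_n >= 2L) k <- k + bytes[j + 2L] * 256
    k <- k + bytes[j + 1L]
    k <- to_i32(k)
    k <- imul32(k, c1)
    k <- rotl32(k, 15L)
    k <- imul32(k, c2)
    h <- bitwXor(h, k)
  }
  h <- bitwXor(h, as.integer(n))
  h <- fmix32(h)
  u32(h)
}

# --- 32-bit helpers on R integers (two's complement semantics) ------------

u32 <- function(x) {
  x <- as.double(x)
  ifelse(x < 0, x + 4294967296, x)
}

to_i32 <- function(x) {
  x <- x %% 4294967296
  as.integer(ifelse(x >= 2147483648, x - 4294967296, x))
}

imul32 <- function(a, b) {
  # 32-bit multiply without double-precision overflow: split into 16-bit halves
  au <- u32(a); bu <- u32(b)
  ah <- au %/% 65536; al <- au %% 65536
  bh <- bu %/% 65536; bl <- bu %% 65536
  lo <- al * bl
  mid <- ((ah * bl + al * bh) %% 65536) * 65536
  to_i32((lo + mid) %% 4294967296)
}

rotl32 <- function(x, r) {
  bitwOr(bitwShiftL(x, r), bitwShiftR(x, 32L - r))
}

fmix32 <- function(h) {
  h <- bitwXor(h, bitwShiftR(h, 16L))
  h <- imul32(h, -2048144789L)  # 0x85ebca6b
  h <- bitwXor(h, bitwShiftR(h, 13L))
  h <- imul32(h, -1028477387L)  # 0xc2b2ae35
  bitwXor(h, bitwShiftR(h, 16L))
}

#' Fingerprint of a parameter bundle
#'
#' Short hexadecimal digest of an R object's deparsed content, recorded in
#' trajectories and trial-set metadata so outputs can be matched to the
#' exact parameters that generated them.
#'
#' @param ... Objects (typically parameter lists) to fingerprint.
#' @return Character scalar, 8 hex digits.
#' @export
params_fingerprint <- function(...) {
  txt <- paste(vapply(list(...), function(x)
    paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
          collapse = ""), character(1)), collapse = "|")
  h <- murmur3_32(utf8ToInt(txt), seed = 97L)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
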