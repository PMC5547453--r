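# Shared binary-layout helpers and typed error conditions.
#
# All multi-byte integers in on-disk layouts are little-endian. Values up to
# 2^48 are carried in R doubles, which represent them exactly; nothing in the
# package relies on integers above 2^53.

# ---- typed conditions --------------------------------------------------

vv_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "vcfvault_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @export
print.vcfvault_error <- function(x, ...) {
  cat("<", class(x)[1], "> ", conditionMessage(x), "\n", sep = "")
  invisible(x)
}

# ---- little-endian integer packing ------------------------------------

pack_uint <- function(x, width) {
  stopifnot(length(x) == 1, !is.na(x), x >= 0, x < 2^(8 * width))
  out <- raw(width)
  for (i in seq_len(width)) {
    out[i] <- as.raw(x %% 256)
    x <- (x - x %% 256) / 256
  }
  out
}

unpack_uint <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

pack_f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

unpack_f64 <- function(bytes) readBin(bytes, "double", n = 1, size = 8, endian = "little")

# float32 round trip (used so quantized FCH split fractions serialize exactly)
quantize_f32 <- function(x) readBin(writeBin(x, raw(), size = 4), "double", size = 4)

pack_f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")

unpack_f32 <- function(bytes) readBin(bytes, "double", n = 1, size = 4, endian = "little")

# ---- 8-byte key containers --------------------------------------------

KEY_SENTINEL_BYTES <- as.raw(rep(255L, 8))

# keys: numeric vector, each < 2^40 or NA (pad sentinel 0xFF..FF on disk).
keys_to_raw <- function(keys) {
  n <- length(keys)
  m <- matrix(as.raw(0L), nrow = 8, ncol = n)
  pad <- is.na(keys)
  v <- keys
  v[pad] <- 0
  for (i in 1:5) {  # valid keys fit in 5 bytes; bytes 6-8 stay zero
    b <- v %% 256
    m[i, ] <- as.raw(b)
    v <- (v - b) / 256
  }
  if (any(pad)) m[, pad] <- KEY_SENTINEL_BYTES
  as.vector(m)
}

raw_to_keys <- function(bytes) {
  stopifnot(length(bytes) %% 8 == 0)
  m <- matrix(as.numeric(bytes), nrow = 8)
  pad <- colSums(m == 255) == 8
  high <- colSums(m[6:8, , drop = FALSE]) > 0
  if (any(high & !pad)) {
    vv_abort("container holds a value with nonzero high bits that is not the pad sentinel",
             "vv_invalid_key_error")
  }
  keys <- colSums(m[1:5, , drop = FALSE] * 256^(0:4))
  keys[pad] <- NA_real_
  keys
}

# ---- bit packing for displacement arrays ------------------------------

# values: non-negative integers < 2^width, packed LSB-first into bytes.
pack_bits <- function(values, width) {
  stopifnot(width >= 1, width <= 32)
  nbits <- length(values) * width
  bits <- logical(nbits)
  at <- 0L
  for (v in values) {
    for (j in seq_len(width)) {
      bits[at + j] <- bitwAnd(v, bitwShiftL(1L, j - 1L)) != 0L
      }
    at <- at + width
  }
  nbytes <- ceiling(nbits / 8)
  length(bits) <- nbytes * 8
  bits[is.na(bits)] <- FALSE
  packBits(bits, type = "raw")
}

unpack_bits <- function(bytes, width, count) {
  bits <- as.logical(rawToBits(bytes))
  need <- count * width
  if (length(bits) < need) {
    vv_abort("bit-packed array shorter than declared", "vv_deserialize_error")
  }
  vapply(seq_len(count), function(i) {
    chunk <- bits[((i - 1) * width + 1):(i * width)]
    as.integer(sum(2^(which(chunk) - 1)))
  }, integer(1))
}

# ---- misc --------------------------------------------------------------

raw_to_hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

utf8_raw <- function(s) charToRaw(enc2utf8(s))

# Deterministic local RNG scope: evaluates expr with R's RNG seeded, then
# restores the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
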