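# Fox-Chen-Heath minimal perfect hashing over one block's encoded keys.
#
# The construction is randomized: a seeded mixer maps keys to skewed buckets
# (a p1 fraction of keys into a p2 fraction of buckets) plus a provisional
# slot; buckets are processed largest first and each receives a displacement
# that shifts all of its keys onto free slots. Bucket count is
# b = ceiling(c * n / (log2(n) + 1)); at the default c and the 500-key block
# size the serialized function fits the ~4.1 bits/key budget.

#' Default FCH construction parameters
#'
#' @param p1 fraction of keys directed to the heavy bucket region.
#' @param p2 fraction of buckets making up the heavy region.
#' @param c bucket-density constant: `b = ceiling(c * n / (log2(n) + 1))`.
#'   Larger c means easier construction but more bits per key.
#' @param probe_limit displacement probes attempted per bucket.
#' @param max_restarts seed redraws before the bucket count is escalated.
#' @param max_escalations times the bucket count may grow by 15% after the
#'   restart budget is exhausted (each escalation is reported via `message`).
#' @return list of parameters for [fch_build()].
#' @export
fch_params <- function(p1 = 0.6, p2 = 0.3, c = 3.95, probe_limit = 1000L,
                       max_restarts = 50L, max_escalations = 4L) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, c > 0)
  list(p1 = p1, p2 = p2, c = c, probe_limit = as.integer(probe_limit),
       max_restarts = as.integer(max_restarts),
       max_escalations = as.integer(max_escalations))
}

fch_bucket_count <- function(n, c) {
  max(1L, as.integer(ceiling(c * n / (log2(max(n, 2)) * as.numeric(n > 1) + 1))))
}

#' Build a minimal perfect hash over a set of keys
#'
#' Returns a function object mapping the n construction keys bijectively
#' onto 0..n-1. Construction retries with fresh seeds on failure; if the
#' restart budget is exhausted the bucket count is escalated (rare, logged),
#' trading a few bits of space for constructability.
#'
#' @param keys numeric vector of distinct encoded keys.
#' @param params see [fch_params()].
#' @param rng_seed integer seed making the construction (and its serialized
#'   bytes) fully deterministic.
#' @return an object of class `vcfvault_fch`.
#' @export
fch_build <- function(keys, params = fch_params(), rng_seed = 1) {
  n <- length(keys)
  if (n < 1) vv_abort("cannot build an FCH over zero keys", "vv_construction_error")
  if (anyDuplicated(keys)) {
    vv_abort("FCH construction requires distinct keys", "vv_construction_error")
  }
  if (any(is.na(keys)) || any(keys < 0) || any(keys >= 2^48)) {
    vv_abort("FCH keys must be integers below 2^48", "vv_construction_error")
  }
  p1 <- quantize_f32(params$p1)
  p2 <- quantize_f32(params$p2)
  b <- fch_bucket_count(n, params$c)
  total_attempts <- 0L
  for (esc in 0:params$max_escalations) {
    res <- .c_fch_build(as.numeric(keys), b, p1, p2,
                        as.numeric(rng_seed) + esc * 2^20,
                        params$max_restarts, params$probe_limit)
    total_attempts <- total_attempts + res$attempts
    if (isTRUE(res$success)) {
      f <- structure(list(n = n, b = b, p1 = p1, p2 = p2,
                          seed_map = res$seed_map, seed_probe = res$seed_probe,
                          g = res$g, attempts = total_attempts),
                     class = "vcfvault_fch")
      return(f)
    }
    b <- as.integer(ceiling(b * 1.15))
    message(sprintf("fch_build: restart budget exhausted at n=%d; escalating bucket count to %d", n, b))
  }
  vv_abort(sprintf("FCH construction failed after %d attempts (n=%d)", total_attempts, n),
           "vv_construction_error", attempts = total_attempts)
}

#' Evaluate a minimal perfect hash
#'
#' Total on any well-formed key: keys outside the construction set map to
#' some arbitrary slot in `[0, n)`. Membership therefore requires comparing
#' the stored key at the returned slot; the hash alone is never a
#' certificate.
#'
#' @param f a `vcfvault_fch` object.
#' @param keys numeric vector of keys.
#' @return integer slots in `[0, n)`.
#' @export
fch_evaluate <- function(f, keys) {
  stopifnot(inherits(f, "vcfvault_fch"))
  .c_fch_eval(as.numeric(keys), f$n, f$b, f$p1, f$p2, f$seed_map, f$g)
}

fch_disp_width <- function(n) max(1L, as.integer(ceiling(log2(n))))

#' Serialize / deserialize an FCH function
#'
#' Layout (little-endian): u32 n, u32 b, u64 mapping seed, u64 probe seed,
#' float32 p1, float32 p2, then the displacement array bit-packed at
#' `max(1, ceiling(log2 n))` bits per bucket. The round trip is lossless and
#' byte-identical.
#'
#' @param f a `vcfvault_fch` object.
#' @param bytes a raw vector from `fch_serialize`.
#' @return `fch_serialize`: raw vector; `fch_deserialize`: `vcfvault_fch`.
#' @export
fch_serialize <- function(f) {
  stopifnot(inherits(f, "vcfvault_fch"))
  c(pack_uint(f$n, 4), pack_uint(f$b, 4),
    pack_uint(f$seed_map, 8), pack_uint(f$seed_probe, 8),
    pack_f32(f$p1), pack_f32(f$p2),
    pack_bits(f$g, fch_disp_width(f$n)))
}

FCH_HEADER_BYTES <- 32L

#' @rdname fch_serialize
#' @export
fch_deserialize <- function(bytes) {
  if (length(bytes) < FCH_HEADER_BYTES) {
    vv_abort("truncated FCH blob: header incomplete", "vv_deserialize_error")
  }
  n <- as.integer(unpack_uint(bytes[1:4]))
  b <- as.integer(unpack_uint(bytes[5:8]))
  if (n < 1 || b < 1) vv_abort("corrupt FCH blob: bad counts", "vv_deserialize_error")
  seed_map <- unpack_uint(bytes[9:16])
  seed_probe <- unpack_uint(bytes[17:24])
  p1 <- unpack_f32(bytes[25:28])
  p2 <- unpack_f32(bytes[29:32])
  if (is.na(p1) || is.na(p2) || p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    vv_abort("corrupt FCH blob: split fractions out of range", "vv_deserialize_error")
  }
  width <- fch_disp_width(n)
  need <- FCH_HEADER_BYTES + ceiling(b * width / 8)
  if (length(bytes) < need) {
    vv_abort("truncated FCH blob: displacement array incomplete", "vv_deserialize_error")
  }
  g <- unpack_bits(bytes[(FCH_HEADER_BYTES + 1):length(bytes)], width, b)
  if (any(g >= n)) vv_abort("corrupt FCH blob: displacement out of range", "vv_deserialize_error")
  structure(list(n = n, b = b, p1 = p1, p2 = p2, seed_map = seed_map,
                 seed_probe = seed_probe, g = g, attempts = NA_integer_),
            class = "vcfvault_fch")
}

#' Storage cost of a serialized FCH function
#'
#' `8 * serialized length in bytes / n`, headers included.
#'
#' @param f a `vcfvault_fch` object.
#' @return bits per key (numeric).
#' @export
fch_bits_per_key <- function(f) {
  8 * length(fch_serialize(f)) / f$n
}

#' @export
print.vcfvault_fch <- function(x, ...) {
  cat(sprintf("<vcfvault_fch> n=%d keys, b=%d buckets, %.3f bits/key\n",
              x$n, x$b, fch_bits_per_key(x)))
  invisible(x)
}
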