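# Page-wise partitioning, sealing, the manifest, and the adversarial surface.

test_that("partitioning yields ceiling(n/500) blocks with page-sized payloads", {
  keys <- random_keys(10000, seed = 1)
  blocks <- partition_blocks(keys, rng_seed = 1)
  expect_length(blocks, 20)
  expect_true(all(vapply(blocks, function(b) b$real_count, integer(1)) == 500L))
  expect_true(all(vapply(blocks, function(b) length(keys_to_raw(b$keys)), numeric(1)) == 4000))
  expect_lte(4000, 4096)
  # directory maxima strictly increasing, equal to each block's top key
  maxima <- vapply(blocks, function(b) b$max_key, numeric(1))
  expect_identical(maxima, keys[seq(500, 10000, by = 500)])
  expect_false(is.unsorted(maxima, strictly = TRUE))
})

test_that("a 501-key set makes a tail block with one real key and 499 sentinels", {
  keys <- random_keys(501, seed = 2)
  blocks <- partition_blocks(keys, rng_seed = 2)
  expect_length(blocks, 2)
  expect_equal(blocks[[1]]$real_count, 500L)
  expect_equal(blocks[[2]]$real_count, 1L)
  expect_equal(sum(is.na(blocks[[2]]$keys)), 499)
  # on disk every pad slot is the all-ones sentinel, never a valid key
  bytes <- keys_to_raw(blocks[[2]]$keys)
  pads <- matrix(bytes, nrow = 8)[, is.na(blocks[[2]]$keys)]
  expect_true(all(pads == as.raw(255)))
  # exactly 500 keys -> one full block, no sentinels
  b1 <- partition_blocks(random_keys(500, seed = 3), rng_seed = 3)
  expect_length(b1, 1)
  expect_equal(sum(is.na(b1[[1]]$keys)), 0)
  expect_error(partition_blocks(numeric(0)), class = "vv_construction_error")
})

test_that("within each block the key at slot i hashes to i", {
  blocks <- partition_blocks(random_keys(1200, seed = 4), rng_seed = 4)
  for (b in blocks) {
    real_idx <- which(!is.na(b$keys))
    slots <- fch_evaluate(b$fch, b$keys[real_idx])
    expect_identical(slots, real_idx - 1L)
  }
})

test_that("seal/unseal round-trips bit-for-bit and resealing refreshes the IV", {
  fx <- sealed_fixture(750, seed = 5)
  b <- unseal_block(fx$sealed_blocks[[1]], fx$seal_key, fx$expected(0))
  orig <- partition_blocks(fx$keys, rng_seed = 5)[[1]]
  expect_identical(vcfvault:::block_payload(b), vcfvault:::block_payload(orig))
  # sealing the same block twice: different IV, different ciphertext
  ctx <- seal_context(fx$seal_key, epoch = 99)
  meta <- list(dataset_id = as.raw(1:16), owner_id = "alice", total_blocks = 2,
               dataset_version = 1, timestamp = 1700000000)
  s1 <- seal_block(orig, ctx, meta)
  s2 <- seal_block(orig, ctx, meta)
  p1 <- vcfvault:::parse_sealed(s1); p2 <- vcfvault:::parse_sealed(s2)
  expect_false(identical(p1$iv, p2$iv))
  expect_false(identical(p1$ciphertext, p2$ciphertext))
})

test_that("issuing a duplicate IV under one key is a hard failure", {
  ctx <- seal_context(as.raw(1:16))
  vcfvault:::next_iv(ctx)
  ctx$counter <- 0  # force the generator back onto an issued IV
  expect_error(vcfvault:::next_iv(ctx), class = "vv_iv_reuse_error")
})

test_that("sampled single-bit flips anywhere in a sealed block defeat unsealing", {
  fx <- sealed_fixture(500, seed = 6)
  sb <- fx$sealed_blocks[[1]]
  nbits <- length(sb) * 8
  set.seed(6)
  for (bit in unique(c(1:8, sample(nbits, 300), (nbits - 7):nbits))) {
    expect_error(unseal_block(flip_bit(sb, bit), fx$seal_key, fx$expected(0)),
                 class = "vcfvault_error")
  }
})

test_that("block swaps surface as reorder, stale versions as replay, foreign data as substitution", {
  fx <- sealed_fixture(4000, seed = 7)   # 8 blocks
  # swap stored positions of blocks 3 and 7 (0-based), unseal expecting 3
  expect_error(unseal_block(fx$sealed_blocks[[8]], fx$seal_key, fx$expected(3)),
               class = "vv_reorder_error")
  # a block sealed under version 1 presented after the manifest advanced
  fx2 <- sealed_fixture(4000, seed = 7, dataset_version = 2)
  exp2 <- fx2$expected(0)
  expect_error(unseal_block(fx$sealed_blocks[[1]], fx$seal_key, exp2),
               class = "vv_replay_error")
  # a block from a different dataset id
  other <- seal_dataset(fx$keys, fx$secret, owner_id = "alice",
                        dataset_id = as.raw(16:1), rng_seed = 7)
  expect_error(unseal_block(other$sealed_blocks[[1]], other$seal_key, fx$expected(0)),
               class = "vv_substitution_error")
  # honest round trip still fine
  expect_s3_class(unseal_block(fx$sealed_blocks[[4]], fx$seal_key, fx$expected(3)),
                  "vcfvault_block")
})

test_that("manifest verification detects tampering, deletion and version bumps", {
  fx <- sealed_fixture(1500, seed = 8)   # 3 blocks
  m <- verify_manifest(fx$manifest_bytes, fx$sealed_blocks, fx$seal_key)
  expect_equal(m$total_blocks, 3)
  # delete one sealed block: violation naming its index
  err <- expect_error(
    verify_manifest(fx$manifest_bytes, fx$sealed_blocks[-2], fx$seal_key),
    class = "vv_manifest_error")
  # substitute a block: digest mismatch at its index
  tampered <- fx$sealed_blocks
  tampered[[3]] <- flip_bit(tampered[[3]], 200)
  err <- expect_error(verify_manifest(fx$manifest_bytes, tampered, fx$seal_key),
                      class = "vv_manifest_error")
  expect_equal(err$block_index, 2L)
  # bump the version field without re-MACing
  mb <- fx$manifest_bytes
  at <- 24 + length(charToRaw("alice"))  # version field offset in the body
  mb[at + 5] <- as.raw(9)
  expect_error(verify_manifest(mb, fx$sealed_blocks, fx$seal_key),
               class = "vv_manifest_error")
})

test_that("route_key agrees with a linear scan of directory ranges", {
  fx <- sealed_fixture(5000, seed = 9)   # 10 blocks
  m <- parse_manifest(fx$manifest_bytes)
  # boundary: a key equal to block 5's directory maximum routes to 5
  expect_equal(route_key(m, m$directory[6]), 5)
  # below the global minimum routes to block 0
  expect_equal(route_key(m, 2^35 + 32), 0)
  probes <- c(fx$keys, random_keys(10000, seed = 10))
  linear <- vapply(probes, function(k) {
    hits <- which(m$directory >= k)
    if (length(hits) == 0) m$total_blocks - 1L else hits[1] - 1L
  }, numeric(1))
  expect_identical(as.numeric(route_key(m, probes)), linear)
})

test_that("container files round-trip and report storage accounting", {
  fx <- sealed_fixture(1000, seed = 11)
  path <- tempfile(fileext = ".vvlt")
  write_container(fx$sealed_blocks, fx$manifest_bytes, path)
  back <- read_container(path)
  expect_identical(back$sealed_blocks, fx$sealed_blocks)
  expect_identical(back$manifest_bytes, fx$manifest_bytes)
  st <- container_stats(path)
  expect_equal(st$total_blocks, 2)
  expect_gt(st$overhead_ratio, 1)
})

test_that("sealed payload bytes look uniformly random (no plaintext structure leaks)", {
  fx <- sealed_fixture(500, seed = 12)
  recs <- random_records(500, seed = 12)
  recs$pos[1] <- recs$pos[1] + 2  # differ in one record
  keys2 <- sort(encode_record(recs))
  other <- seal_dataset(keys2, fx$secret, owner_id = "alice",
                        dataset_id = as.raw(1:16), rng_seed = 12)
  ct1 <- vcfvault:::parse_sealed(fx$sealed_blocks[[1]])$ciphertext
  ct2 <- vcfvault:::parse_sealed(other$sealed_blocks[[1]])$ciphertext
  for (ct in list(ct1, ct2)) {
    counts <- tabulate(as.integer(ct) + 1L, nbins = 256)
    p <- stats::chisq.test(counts)$p.value
    expect_gt(p, 1e-9)
  }
  # the plaintext key bytes (low 5 bytes per slot) must not appear in order
  pt <- keys_to_raw(fx$blocks[[1]]$keys)[1:40]
  expect_false(any(vapply(seq_len(length(ct1) - 39), function(i) {
    identical(ct1[i:(i + 39)], pt)
  }, logical(1))))
})
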