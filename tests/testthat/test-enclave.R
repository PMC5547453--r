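# The simulated-enclave query engine.

test_that("candidate expansion is the sorted cross product of the four value sets", {
  q <- genetic_query(20, c(17330, 14370), c("T", "G"), "A")
  cand <- expand_candidates(q)
  expect_length(cand, 4)
  expect_false(is.unsorted(cand, strictly = TRUE))
  expect_length(expand_candidates(genetic_query(1, 1, "A", "C")), 1)
  # every candidate decodes to a tuple from the sets, flagged as SNV
  dec <- decode_record(cand)
  expect_true(all(dec$chrom == 20 & dec$pos %in% c(14370, 17330) &
                    dec$ref %in% c("T", "G") & dec$alt == "A" & dec$is_snp))
  # combinatorial oracle on random set sizes
  set.seed(1)
  for (i in 1:20) {
    sizes <- sample(3, 4, replace = TRUE)
    q <- genetic_query(sample(25, sizes[1]), sample(1e6, sizes[2]),
                       sample(c("A", "C", "G", "T"), sizes[3]),
                       sample(c("A", "C", "G", "T"), sizes[4]))
    expect_length(expand_candidates(q), prod(lengths(unclass(q))))
  }
})

test_that("invalid or oversized queries are rejected at expand time", {
  expect_error(genetic_query(integer(0), 1, "A", "C"), class = "vv_query_error")
  expect_error(genetic_query(26, 1, "A", "C"), class = "vv_query_error")
  expect_error(genetic_query(1, 2^30, "A", "C"), class = "vv_query_error")
  expect_error(genetic_query(1, 1, "AT", "C"), class = "vv_query_error")
  big <- genetic_query(1:25, 1:100, c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  expect_error(expand_candidates(big, cap = 10000), class = "vv_query_error")
})

test_that("the worked chromosome-20 example counts 2 through the full sealed pipeline", {
  vcf <- system.file("extdata", "sample_chr20.vcf", package = "vcfvault")
  norm <- normalize_variants(read_vcf(vcf))
  expect_equal(nrow(norm$records), 4)  # four biallelic SNVs survive
  keys <- sort(encode_dataset(norm$records)$keys)
  h <- provisioned_enclave(keys)
  res <- run_query(h, genetic_query(20, c(17330, 14370), c("T", "G"), "A"))
  expect_equal(res$matched_count, 2L)
  expect_equal(res$candidates_evaluated, 4L)
})

test_that("lookup finds every dataset key and rejects thousands of absent keys", {
  recs <- random_records(1234, seed = 31)
  keys <- sort(encode_record(recs))
  h <- provisioned_enclave(keys, rng_seed = 31)
  store <- h$enclave$datasets[[vcfvault:::raw_to_hex(h$dataset_id)]]
  cache <- new.env()
  hits <- vapply(sample(keys, 300), function(k) lookup_key(store, k, cache)$present,
                 logical(1))
  expect_true(all(hits))
  absent <- setdiff(random_keys(3000, seed = 32), keys)
  misses <- vapply(absent, function(k) lookup_key(store, k, cache)$present, logical(1))
  expect_false(any(misses))
  # a probe landing on a pad slot in the tail block compares against the
  # sentinel and misses
  tail_block <- store$manifest$total_blocks - 1L
  expect_true(any(is.na(unseal_block(store$sealed_blocks[[tail_block + 1]],
                                     store$seal_key,
                                     list(dataset_id = store$manifest$dataset_id,
                                          owner_id = store$manifest$owner_id,
                                          block_index = tail_block,
                                          dataset_version = 1,
                                          total_blocks = store$manifest$total_blocks))$keys)))
})

test_that("sealed-pipeline counts equal the plaintext brute-force filter", {
  set.seed(41)
  for (trial in 1:6) {
    recs <- random_records(sample(c(300, 700, 1500), 1), seed = 41 + trial,
                           chroms = 1:4, pos_max = 50000)
    keys <- sort(unique(encode_record(recs)))
    h <- provisioned_enclave(keys, rng_seed = trial)
    for (j in 1:5) {
      qr <- recs[sample(nrow(recs), 3), ]
      q <- genetic_query(unique(c(qr$chrom, sample(4, 1))),
                         unique(c(qr$pos, sample(50000, 2))),
                         unique(qr$ref), unique(qr$alt))
      res <- run_query(h, q)
      expect_identical(res$matched_count, brute_count(recs, q))
    }
  }
})

test_that("the page-access trace is a function of the candidate set, not of match outcomes", {
  # same geometry, 100% vs 0% matching: positions p (present) vs p+1 (absent)
  base_pos <- seq(10, by = 10, length.out = 2000)
  qpos <- base_pos[c(50:57, 550:557, 1050:1057, 1550:1557)]
  make_keys <- function(pos) {
    sort(encode_record(data.frame(chrom = 7L, pos = pos, ref = "A", alt = "G",
                                  is_snp = TRUE, stringsAsFactors = FALSE)))
  }
  all_match <- make_keys(base_pos)
  pos_none <- base_pos
  pos_none[match(qpos, base_pos)] <- qpos + 1
  no_match <- make_keys(pos_none)
  q <- genetic_query(7, qpos, "A", "G")
  h1 <- provisioned_enclave(all_match, rng_seed = 1)
  h2 <- provisioned_enclave(no_match, rng_seed = 1)
  r1 <- run_query(h1, q)
  r2 <- run_query(h2, q)
  expect_equal(r1$matched_count, 32L)
  expect_equal(r2$matched_count, 0L)
  expect_identical(h1$enclave$last_trace, h2$enclave$last_trace)
  # per-candidate cost: blocks touched bounded by distinct routed blocks
  expect_equal(r1$blocks_touched, length(unique(h1$enclave$last_trace)))
  expect_lte(r1$blocks_touched, r1$candidates_evaluated)
})

test_that("every byte leaving the enclave is an encrypted frame", {
  keys <- random_keys(600, seed = 51)
  h <- provisioned_enclave(keys, rng_seed = 51)
  run_query(h, genetic_query(1, 1:4, "A", "C"))
  expect_gt(length(h$enclave$egress), 0)
  for (frame in h$enclave$egress) {
    expect_true(is.raw(frame))
    # frames parse as version||role||counter||iv||len||ct||tag, and the body
    # is not recoverable without the session key
    expect_identical(frame[1], as.raw(1))
    expect_true(as.integer(frame[2]) %in% 1:3)
    fresh <- establish_session(vcfvault:::.c_ec_keygen()$private,
                               vcfvault:::.c_ec_keygen()$public,
                               charToRaw("x"), "user")
    expect_error(open_message(fresh, frame), class = "vcfvault_error")
  }
})

test_that("re-provisioning increments the dataset version by exactly one", {
  keys <- random_keys(700, seed = 61)
  h <- provisioned_enclave(keys, rng_seed = 61)
  expect_equal(h$ack$dataset_version, 1)
  frame <- owner_upload_frame(h$owner$client, random_keys(800, seed = 62),
                              dataset_id = h$dataset_id)
  ack2_frame <- provision_dataset(h$enclave, frame, h$owner$enclave)
  ack2 <- jsonlite::fromJSON(rawToChar(open_message(h$owner$client, ack2_frame)))
  expect_equal(ack2$dataset_version, 2)
  expect_equal(ack2$dataset_id, vcfvault:::raw_to_hex(h$dataset_id))
})

test_that("a truncated upload aborts provisioning with nothing persisted", {
  enclave <- enclave_new()
  s <- open_session(enclave, "owner")
  keys <- random_keys(100, seed = 71)
  body <- c(as.raw(0), vcfvault:::pack_uint(5, 2), charToRaw("alice"),
            vcfvault:::pack_uint(100, 4), keys_to_raw(keys)[1:400])  # half the keys
  frame <- seal_message(s$client, body)
  expect_error(provision_dataset(enclave, frame, s$enclave),
               class = "vv_provision_error")
  expect_length(ls(enclave$datasets), 0)
})

test_that("storage violations reach the user as typed encrypted errors, never partial counts", {
  keys <- random_keys(1100, seed = 81)
  h <- provisioned_enclave(keys, rng_seed = 81)
  st <- h$enclave$datasets[[vcfvault:::raw_to_hex(h$dataset_id)]]
  tmp <- st$sealed_blocks[[1]]
  st$sealed_blocks[[1]] <- st$sealed_blocks[[2]]
  st$sealed_blocks[[2]] <- tmp
  h$enclave$datasets[[vcfvault:::raw_to_hex(h$dataset_id)]] <- st
  q <- genetic_query(unique(decode_record(keys[1])$chrom),
                     unique(decode_record(keys[1:2])$pos), "A", "C")
  err <- expect_error(run_query(h, q), class = "vv_remote_error")
  expect_match(conditionMessage(err), "reorder|vv_reorder")
})
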