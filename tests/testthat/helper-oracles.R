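# Independent oracles and fixture builders shared across the suite.
# Oracles never call the code path they check.

# Bit-string assembly of the 40-bit key: each field rendered to a fixed-width
# binary string, concatenated, then evaluated as a base-2 number. Independent
# of the codec's arithmetic.
oracle_encode <- function(chrom, pos, ref, alt, flag) {
  to_bits <- function(x, width) {
    out <- integer(width)
    for (i in width:1) {
      out[i] <- x %% 2
      x <- x %/% 2
    }
    out
  }
  base_code <- c(A = 0, C = 1, G = 2, T = 3)
  bits <- c(to_bits(chrom, 5), to_bits(pos, 30),
            to_bits(base_code[[ref]], 2), to_bits(base_code[[alt]], 2),
            to_bits(as.integer(flag), 1))
  sum(bits * 2^(39:0))
}

# Random valid variant records with unique (chrom,pos,ref,alt) tuples.
random_records <- function(n, seed, chroms = 1:25, pos_max = 2^30 - 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- floor(runif(n, 1, pos_max + 1))
  ref <- sample(bases, n, replace = TRUE)
  alt <- sample(bases, n, replace = TRUE)
  tup <- paste(chrom, pos, ref, alt)
  while (anyDuplicated(tup)) {
    d <- duplicated(tup)
    pos[d] <- floor(runif(sum(d), 1, pos_max + 1))
    tup <- paste(chrom, pos, ref, alt)
  }
  data.frame(chrom = as.integer(chrom), pos = pos, ref = ref, alt = alt,
             is_snp = TRUE, stringsAsFactors = FALSE)
}

random_keys <- function(n, seed) {
  sort(encode_record(random_records(n, seed)))
}

# Plaintext SQL-style conjunctive membership count.
brute_count <- function(records, q) {
  sum(records$chrom %in% q$chrom & records$pos %in% q$pos &
        records$ref %in% q$ref & records$alt %in% q$alt)
}

flip_bit <- function(bytes, bit_index) {  # bit_index 1-based over the buffer
  byte <- (bit_index - 1) %/% 8 + 1
  bit <- (bit_index - 1) %% 8
  bytes[byte] <- xor(bytes[byte], as.raw(bitwShiftL(1L, bit)))
  bytes
}

hex_to_raw <- function(h) {
  as.raw(strtoi(substring(h, seq(1, nchar(h) - 1, 2), seq(2, nchar(h), 2)), 16L))
}

# Provision a key set into a fresh simulated enclave; returns handles for
# querying.
provisioned_enclave <- function(keys, rng_seed = 1) {
  enclave <- enclave_new(rng_seed = rng_seed)
  owner <- open_session(enclave, "owner")
  ack_frame <- provision_dataset(enclave, owner_upload_frame(owner$client, keys),
                                 owner$enclave)
  ack <- jsonlite::fromJSON(rawToChar(open_message(owner$client, ack_frame)))
  user <- open_session(enclave, "user")
  list(enclave = enclave, user = user, owner = owner,
       dataset_id = hex_to_raw(ack$dataset_id), ack = ack)
}

run_query <- function(h, q) {
  reply <- execute_query(h$enclave, query_frame(h$user$client, q, h$dataset_id),
                         h$user$enclave)
  parse_result(h$user$client, reply)
}

# A sealed single-block dataset plus everything needed to unseal it.
sealed_fixture <- function(n_keys = 500, seed = 42, dataset_version = 1) {
  keys <- random_keys(n_keys, seed)
  secret <- vcfvault:::.c_sha256(charToRaw("fixture-secret"))
  sealed <- seal_dataset(keys, secret, owner_id = "alice",
                         dataset_id = as.raw(1:16), dataset_version = dataset_version,
                         rng_seed = seed)
  sealed$keys <- keys
  sealed$secret <- secret
  sealed$expected <- function(i) list(dataset_id = as.raw(1:16), owner_id = "alice",
                                      block_index = i, dataset_version = dataset_version,
                                      total_blocks = length(sealed$sealed_blocks))
  sealed
}
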