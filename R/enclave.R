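# The simulated-enclave query engine.
#
# The enclave holds its identity (signing key, sealing secret, measurement)
# and a registry of provisioned datasets. A query arrives encrypted on an
# attested session, is expanded into candidate keys, and each candidate
# costs exactly one sealed-page access (cached within the query): the
# page-access trace is computed from the candidate set alone, before any
# match outcome exists, so it cannot leak which candidates matched.

#' Create a simulated enclave
#'
#' @param identity an [enclave_identity()]; fresh by default.
#' @param rng_seed base seed for per-block hash construction.
#' @param candidate_cap maximum candidate-set size a query may expand to.
#' @param strict when `TRUE`, results carry only the matched count (no
#'   observability fields).
#' @return environment of class `vcfvault_enclave`.
#' @export
enclave_new <- function(identity = enclave_identity(), rng_seed = 1,
                        candidate_cap = 10000L, strict = FALSE) {
  e <- new.env(parent = emptyenv())
  e$identity <- identity
  e$datasets <- new.env(parent = emptyenv())
  e$rng_seed <- rng_seed
  e$candidate_cap <- as.integer(candidate_cap)
  e$strict <- isTRUE(strict)
  e$last_trace <- integer(0)
  e$egress <- list()
  class(e) <- "vcfvault_enclave"
  e
}

egress <- function(enclave, frame) {
  enclave$egress[[length(enclave$egress) + 1]] <- frame
  frame
}

#' Run the attestation + session handshake against an enclave
#'
#' In-process simulation of the wire exchange: the client issues a
#' challenge nonce and an ephemeral ECDH key; the enclave answers with a
#' signed attestation report carrying its own ephemeral ECDH key; the
#' client verifies the report against the pinned key and expected
#' measurement, and both sides derive the session key over the transcript.
#'
#' @param enclave a `vcfvault_enclave`.
#' @param role `"owner"` or `"user"`.
#' @param trusted_key pinned verification key (defaults to the enclave's
#'   true key, the honest case).
#' @param expected_measurement digest the client trusts.
#' @param registry client's [nonce_registry()].
#' @return list with `client` and `enclave` session contexts and the
#'   `report`.
#' @export
open_session <- function(enclave, role = c("user", "owner"),
                         trusted_key = enclave$identity$sign_public,
                         expected_measurement = enclave$identity$measurement,
                         registry = nonce_registry()) {
  role <- match.arg(role)
  nonce <- .c_rand_bytes(16L)
  client_kp <- .c_ec_keygen()
  enclave_kp <- .c_ec_keygen()
  report <- attest(enclave$identity, nonce, enclave_kp$public)
  verify_attestation(report, trusted_key, expected_measurement, nonce, registry)
  transcript <- c(report$measurement, nonce, enclave_kp$public, client_kp$public,
                  utf8_raw(report$curve), as.raw(ROLE_BYTES[[role]]))
  list(
    client = establish_session(client_kp$private, enclave_kp$public, transcript, role),
    enclave = establish_session(enclave_kp$private, client_kp$public, transcript, "enclave"),
    report = report
  )
}

# ---- queries -----------------------------------------------------------

#' Construct a genetic count query
#'
#' Four value sets with conjunctive-membership semantics: a record matches
#' when its CHROM, POS, REF and ALT each belong to the corresponding set
#' (the SQL `CHROM IN (...) AND POS IN (...) AND REF IN (...) AND ALT IN
#' (...)` count query). All sets must be non-empty.
#'
#' @param chrom chromosome codes (1..25) or names (`"X"`, `"Y"`, `"MT"`,
#'   optionally `chr`-prefixed).
#' @param pos 1-based positions.
#' @param ref,alt single bases among A, C, G, T.
#' @return list of class `vcfvault_query`.
#' @export
genetic_query <- function(chrom, pos, ref, alt) {
  if (length(chrom) == 0 || length(pos) == 0 || length(ref) == 0 || length(alt) == 0) {
    vv_abort("invalid query: every value set must be non-empty", "vv_query_error")
  }
  ch <- if (is.numeric(chrom)) as.integer(chrom) else chrom_to_code(as.character(chrom))
  if (any(is.na(ch)) || any(ch < 1L) || any(ch > CHROM_MAX)) {
    vv_abort("invalid query: unmappable chromosome", "vv_query_error")
  }
  if (any(is.na(pos)) || any(pos < 1) || any(pos > POS_MAX) || any(pos != floor(pos))) {
    vv_abort("invalid query: position outside the encodable range", "vv_query_error")
  }
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!all(ref %in% names(BASE_CODES)) || !all(alt %in% names(BASE_CODES))) {
    vv_abort("invalid query: alleles must be single bases A/C/G/T", "vv_query_error")
  }
  structure(list(chrom = sort(unique(ch)), pos = sort(unique(as.numeric(pos))),
                 ref = sort(unique(ref)), alt = sort(unique(alt))),
            class = "vcfvault_query")
}

#' Expand a query into its candidate keys
#'
#' The cross product of the four value sets, each tuple encoded with the
#' SNV flag set (the codec retains only SNVs, all flagged), in ascending
#' key order. Exact-match hashing forces enumeration: a conjunctive
#' membership query over k values is k candidate lookups.
#'
#' @param q a [genetic_query()].
#' @param cap refuse queries whose candidate count exceeds this.
#' @return numeric vector of encoded candidate keys, sorted.
#' @export
expand_candidates <- function(q, cap = 10000L) {
  stopifnot(inherits(q, "vcfvault_query"))
  n_cand <- length(q$chrom) * length(q$pos) * length(q$ref) * length(q$alt)
  if (n_cand > cap) {
    vv_abort(sprintf("query expands to %d candidates, above the cap of %d", n_cand, cap),
             "vv_query_error")
  }
  grid <- expand.grid(chrom = q$chrom, pos = q$pos, ref = q$ref, alt = q$alt,
                      stringsAsFactors = FALSE)
  rec <- data.frame(chrom = grid$chrom, pos = grid$pos, ref = grid$ref,
                    alt = grid$alt, is_snp = TRUE, stringsAsFactors = FALSE)
  sort(encode_record(rec))
}

# ---- dataset state and lookups ----------------------------------------

dataset_state <- function(enclave, dataset_id) {
  h <- raw_to_hex(dataset_id)
  st <- enclave$datasets[[h]]
  if (is.null(st)) {
    vv_abort("unknown dataset", "vv_query_error")
  }
  st
}

#' Membership lookup for one candidate key
#'
#' Routes the key through the manifest directory, unseals the single block
#' that could hold it (header checked against the expected index and
#' version), evaluates the block's minimal perfect hash, and compares the
#' stored 8-byte key at that slot for exact equality. The comparison is
#' mandatory — the hash maps alien keys to arbitrary slots, so equality is
#' the sole membership certificate. One sealed-page access per call, hit or
#' miss, unless the block is already in `cache`.
#'
#' @param store dataset state: list with `sealed_blocks`, `manifest`
#'   (parsed, verified), `seal_key`, `block_size`.
#' @param key one encoded candidate key.
#' @param cache optional environment caching unsealed blocks by index.
#' @return list with `present` (logical) and `block_index` (0-based).
#' @export
lookup_key <- function(store, key, cache = NULL) {
  bi <- route_key(store$manifest, key)
  ck <- as.character(bi)
  block <- if (!is.null(cache)) cache[[ck]] else NULL
  if (is.null(block)) {
    block <- unseal_block(
      store$sealed_blocks[[bi + 1]], store$seal_key,
      expected = list(dataset_id = store$manifest$dataset_id,
                      owner_id = store$manifest$owner_id,
                      block_index = bi,
                      dataset_version = store$manifest$dataset_version,
                      total_blocks = store$manifest$total_blocks),
      block_size = store$block_size)
    if (!is.null(cache)) cache[[ck]] <- block
  }
  slot <- fch_evaluate(block$fch, key)
  stored <- block$keys[slot + 1]
  list(present = !is.na(stored) && stored == key, block_index = bi)
}

# ---- wire payload formats (binary upload, JSON control) ---------------

#' Build the owner's provisioning frame
#'
#' Serializes the sorted distinct key set plus owner and dataset identity
#' and seals it to the owner session. Layout: u8 has_dataset_id,
#' dataset_id(16 when present), u16 owner_len, owner, u32 n_keys, keys.
#'
#' @param session owner-side session context.
#' @param keys sorted distinct encoded keys.
#' @param owner_id owner identity string.
#' @param dataset_id raw 16 bytes to update an existing dataset, or `NULL`
#'   for a fresh one.
#' @return raw wire frame.
#' @export
owner_upload_frame <- function(session, keys, owner_id = "owner", dataset_id = NULL) {
  owner <- utf8_raw(owner_id)
  body <- c(as.raw(!is.null(dataset_id)),
            if (!is.null(dataset_id)) dataset_id else raw(0),
            pack_uint(length(owner), 2), owner,
            pack_uint(length(keys), 4), keys_to_raw(keys))
  seal_message(session, body)
}

#' Provision a dataset into the enclave
#'
#' Decrypts the owner's upload, range-partitions the keys into 500-record
#' blocks with per-block minimal perfect hashes, seals every block under
#' the enclave's dataset sealing key, and installs the MAC-protected
#' manifest. Updates to an existing dataset increment its version counter
#' by exactly one; nothing is persisted if any step fails.
#'
#' @param enclave a `vcfvault_enclave`.
#' @param frame the owner's sealed upload frame.
#' @param session the enclave-side session context.
#' @return raw frame: encrypted acknowledgment (JSON: dataset id hex,
#'   version, total blocks).
#' @export
provision_dataset <- function(enclave, frame, session) {
  body <- open_message(session, frame)
  parse_upload <- function(b) {
    if (length(b) < 7) vv_abort("truncated upload", "vv_provision_error")
    has_id <- as.integer(b[1]) == 1L
    at <- 1
    dataset_id <- NULL
    if (has_id) { dataset_id <- b[2:17]; at <- 17 }
    owner_len <- unpack_uint(b[(at + 1):(at + 2)])
    owner <- rawToChar(b[at + 2 + seq_len(owner_len)])
    at <- at + 2 + owner_len
    n_keys <- unpack_uint(b[(at + 1):(at + 4)])
    at <- at + 4
    if (length(b) != at + 8 * n_keys) vv_abort("truncated upload", "vv_provision_error")
    keys <- raw_to_keys(b[(at + 1):(at + 8 * n_keys)])
    list(dataset_id = dataset_id, owner_id = owner, keys = keys)
  }
  up <- parse_upload(body)
  keys <- sort(unique(up$keys))
  if (length(keys) == 0) vv_abort("empty upload: nothing to provision", "vv_provision_error")
  dataset_id <- up$dataset_id
  prev <- NULL
  if (!is.null(dataset_id)) {
    prev <- enclave$datasets[[raw_to_hex(dataset_id)]]
  } else {
    dataset_id <- .c_rand_bytes(16L)
  }
  version <- if (is.null(prev)) 1 else prev$manifest$dataset_version + 1
  sealed <- seal_dataset(keys, enclave$identity$seal_secret,
                         owner_id = up$owner_id, dataset_id = dataset_id,
                         dataset_version = version, rng_seed = enclave$rng_seed)
  manifest <- verify_manifest(sealed$manifest_bytes, sealed$sealed_blocks, sealed$seal_key)
  enclave$datasets[[raw_to_hex(dataset_id)]] <- list(
    sealed_blocks = sealed$sealed_blocks,
    manifest_bytes = sealed$manifest_bytes,
    manifest = manifest,
    seal_key = sealed$seal_key,
    block_size = BLOCK_RECORDS)
  ack <- jsonlite::toJSON(list(dataset_id = raw_to_hex(dataset_id),
                               dataset_version = version,
                               total_blocks = manifest$total_blocks),
                          auto_unbox = TRUE)
  egress(enclave, seal_message(session, utf8_raw(ack)))
}

#' Build the user's query frame
#'
#' @param session user-side session context.
#' @param q a [genetic_query()].
#' @param dataset_id raw 16-byte dataset identifier.
#' @return raw wire frame (encrypted JSON query document).
#' @export
query_frame <- function(session, q, dataset_id) {
  doc <- jsonlite::toJSON(list(dataset_id = raw_to_hex(dataset_id),
                               chrom = q$chrom, pos = q$pos,
                               ref = q$ref, alt = q$alt))
  seal_message(session, utf8_raw(doc))
}

#' Execute an encrypted count query
#'
#' Decrypts the query, expands its candidate set, precomputes the
#' page-access trace from the candidates alone (one routed block per
#' candidate, independent of any match outcome), then unseals each routed
#' block once (per-query cache) and counts exact-match candidates. The
#' result — or, on any storage violation, an error indicator naming the
#' violation class but never a partial count — is sealed to the session.
#'
#' @param enclave a `vcfvault_enclave`.
#' @param frame the user's sealed query frame.
#' @param session the enclave-side session context.
#' @return raw frame: encrypted JSON result.
#' @export
execute_query <- function(enclave, frame, session) {
  reply <- function(x) egress(enclave, seal_message(session, utf8_raw(
    jsonlite::toJSON(x, auto_unbox = TRUE))))
  out <- tryCatch({
    doc <- jsonlite::fromJSON(rawToChar(open_message(session, frame)))
    q <- genetic_query(doc$chrom, doc$pos, doc$ref, doc$alt)
    store <- dataset_state(enclave, as.raw(strtoi(
      substring(doc$dataset_id, seq(1, 31, 2), seq(2, 32, 2)), 16L)))
    cand <- expand_candidates(q, enclave$candidate_cap)
    # access trace: a pure function of the candidate set
    trace <- route_key(store$manifest, cand)
    enclave$last_trace <- trace
    cache <- new.env(parent = emptyenv())
    matched <- 0L
    for (k in cand) {
      if (lookup_key(store, k, cache)$present) matched <- matched + 1L
    }
    res <- list(matched_count = matched)
    if (!enclave$strict) {
      res$candidates_evaluated <- length(cand)
      res$blocks_touched <- length(unique(trace))
    }
    res
  }, vcfvault_error = function(e) {
    list(error = class(e)[1], message = conditionMessage(e))
  })
  reply(out)
}

#' Decrypt and interpret a query result frame
#'
#' @param session user-side session context.
#' @param frame the enclave's sealed reply.
#' @return list with `matched_count` (and observability fields unless the
#'   enclave runs strict); a typed error is re-raised if the enclave
#'   reported one.
#' @export
parse_result <- function(session, frame) {
  res <- jsonlite::fromJSON(rawToChar(open_message(session, frame)))
  if (!is.null(res$error)) {
    vv_abort(sprintf("enclave reported %s: %s", res$error, res$message),
             c(res$error, "vv_remote_error"))
  }
  res
}
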