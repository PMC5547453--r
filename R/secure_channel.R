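# Simulated remote attestation and the authenticated session channel.
#
# The trust root is a locally pinned ECDSA (P-256) verification key standing
# in for the quoting infrastructure; the enclave "measurement" is a SHA-256
# digest over the enclave module's code bundle, recomputable by any
# verifier. Session keys come from ECDH (P-256) + HKDF over the handshake
# transcript; every message is AES-128-GCM with a strictly increasing
# sequence counter bound as associated data.

CHANNEL_VERSION <- as.raw(1L)
ROLE_BYTES <- c(owner = 1L, user = 2L, enclave = 3L)
CURVE_LABEL <- "P-256"

#' Digest a code bundle into an enclave measurement
#'
#' @param bundle raw bytes of the code to be measured.
#' @return raw 32-byte SHA-256 digest.
#' @export
measure_bundle <- function(bundle) {
  stopifnot(is.raw(bundle))
  .c_sha256(bundle)
}

#' The enclave module's own code bundle
#'
#' Deterministic byte serialization (deparsed source) of the query-engine
#' functions that constitute the simulated enclave; its digest plays the
#' role of a hardware code measurement. Any edit to these functions changes
#' the measurement.
#'
#' @return raw vector.
#' @export
enclave_code_bundle <- function() {
  fns <- c("expand_candidates", "lookup_key", "execute_query",
           "provision_dataset", "unseal_block", "route_key", "fch_evaluate")
  ns <- asNamespace("vcfvault")
  txt <- vapply(fns, function(f) {
    paste(deparse(get(f, envir = ns), control = "exact"), collapse = "\n")
  }, character(1))
  utf8_raw(paste(txt, collapse = "\n"))
}

#' Create an enclave identity
#'
#' An ECDSA signing keypair, a sealing secret, and the measurement of the
#' enclave code bundle. The public verification key is what relying parties
#' pin out-of-band.
#'
#' @param bundle code bundle to measure; defaults to the package's enclave
#'   module.
#' @return list of class `vcfvault_identity` with `sign_private`,
#'   `sign_public`, `seal_secret`, `measurement`.
#' @export
enclave_identity <- function(bundle = enclave_code_bundle()) {
  kp <- .c_ec_keygen()
  structure(list(sign_private = kp$private, sign_public = kp$public,
                 seal_secret = .c_rand_bytes(32L),
                 measurement = measure_bundle(bundle)),
            class = "vcfvault_identity")
}

#' Produce an attestation report
#'
#' Signs (measurement, challenge nonce, ephemeral ECDH public key, curve
#' label) under the enclave's identity key. The nonce binds the report to
#' one challenge; the embedded ECDH key bootstraps the session.
#'
#' @param identity a [enclave_identity()].
#' @param nonce raw challenge from the verifier.
#' @param ecdh_public raw DER public key offered for key agreement.
#' @return list: the report.
#' @export
attest <- function(identity, nonce, ecdh_public) {
  stopifnot(inherits(identity, "vcfvault_identity"), is.raw(nonce))
  body <- c(identity$measurement, nonce,
            pack_uint(length(ecdh_public), 4), ecdh_public,
            utf8_raw(CURVE_LABEL))
  list(measurement = identity$measurement, nonce = nonce,
       ecdh_public = ecdh_public, curve = CURVE_LABEL,
       signature = .c_ecdsa_sign(identity$sign_private, body))
}

#' Registry of consumed attestation nonces
#' @return an environment tracking nonces already accepted.
#' @export
nonce_registry <- function() new.env(parent = emptyenv())

#' Verify an attestation report
#'
#' Checks the ECDSA signature under the pinned key, that the nonce is the
#' one this verifier issued and has not been consumed before (a replayed
#' report fails), and that the measurement equals the expected one.
#'
#' @param report output of [attest()].
#' @param trusted_key pinned raw DER verification key.
#' @param expected_measurement raw 32-byte digest the verifier trusts.
#' @param challenge the nonce this verifier issued for this handshake.
#' @param registry a [nonce_registry()]; pass the same one across
#'   handshakes to defeat report replay.
#' @return `TRUE` invisibly; typed errors otherwise
#'   (`vv_attestation_replay_error`, `vv_untrusted_enclave_error`,
#'   `vv_attestation_error`).
#' @export
verify_attestation <- function(report, trusted_key, expected_measurement,
                               challenge, registry = nonce_registry()) {
  if (!identical(report$nonce, challenge)) {
    vv_abort("attestation nonce does not match the issued challenge",
             "vv_attestation_replay_error")
  }
  h <- raw_to_hex(report$nonce)
  if (!is.null(registry[[h]])) {
    vv_abort("attestation report replayed: nonce already consumed",
             "vv_attestation_replay_error")
  }
  body <- c(report$measurement, report$nonce,
            pack_uint(length(report$ecdh_public), 4), report$ecdh_public,
            utf8_raw(report$curve))
  if (!.c_ecdsa_verify(trusted_key, body, report$signature)) {
    vv_abort("attestation signature invalid", "vv_attestation_error")
  }
  if (!identical(report$measurement, expected_measurement)) {
    vv_abort("enclave measurement mismatch: untrusted code",
             "vv_untrusted_enclave_error")
  }
  registry[[h]] <- TRUE
  invisible(TRUE)
}

#' Establish a session from an ECDH exchange
#'
#' Both sides derive the same 128-bit AES key:
#' `HKDF-SHA256(ECDH shared secret, salt = SHA-256(transcript))`. The
#' transcript should cover the attestation handshake so that differing
#' views yield differing keys. Counters start at zero.
#'
#' @param own_private own raw DER ECDH private key.
#' @param peer_public peer's raw DER ECDH public key (authenticated via
#'   attestation before calling this).
#' @param transcript raw handshake transcript.
#' @param role one of `"owner"`, `"user"`, `"enclave"`.
#' @return an environment of class `vcfvault_session`.
#' @export
establish_session <- function(own_private, peer_public, transcript, role) {
  role <- match.arg(role, names(ROLE_BYTES))
  secret <- tryCatch(.c_ecdh_derive(own_private, peer_public),
                     error = function(e) {
                       vv_abort(paste0("handshake abort: ", conditionMessage(e)),
                                "vv_handshake_error")
                     })
  key <- .c_hkdf_sha256(secret, .c_sha256(transcript),
                        utf8_raw("vcfvault-session-v1"), 16L)
  ctx <- new.env(parent = emptyenv())
  ctx$key <- key
  ctx$send <- 0
  ctx$recv <- 0
  ctx$role <- role
  class(ctx) <- "vcfvault_session"
  ctx
}

# frame: version(1) role(1) counter(8) iv(12) ct_len(4) ciphertext tag(16)
message_aad <- function(role_byte, counter) {
  c(CHANNEL_VERSION, as.raw(role_byte), pack_uint(counter, 8))
}

#' Seal / open a channel message
#'
#' Authenticated encryption under the session key with the sender role and
#' a strictly increasing sequence counter in the associated data.
#' `open_message` rejects tampered frames (`vv_channel_integrity_error`)
#' and any frame whose counter does not exceed the last accepted one
#' (`vv_channel_replay_error`), which covers replays and reorders.
#'
#' @param ctx a `vcfvault_session`.
#' @param plaintext raw message body.
#' @param frame raw wire frame from `seal_message`.
#' @return `seal_message`: raw frame; `open_message`: raw plaintext.
#' @export
seal_message <- function(ctx, plaintext) {
  stopifnot(inherits(ctx, "vcfvault_session"), is.raw(plaintext))
  ctr <- ctx$send + 1
  iv <- .c_rand_bytes(12L)
  role_byte <- ROLE_BYTES[[ctx$role]]
  enc <- .c_aes_gcm_encrypt(ctx$key, iv, message_aad(role_byte, ctr), plaintext)
  ctx$send <- ctr
  c(CHANNEL_VERSION, as.raw(role_byte), pack_uint(ctr, 8), iv,
    pack_uint(length(enc$ciphertext), 4), enc$ciphertext, enc$tag)
}

#' @rdname seal_message
#' @export
open_message <- function(ctx, frame) {
  stopifnot(inherits(ctx, "vcfvault_session"))
  if (length(frame) < 26) {
    vv_abort("channel frame truncated", "vv_channel_integrity_error")
  }
  role_byte <- as.integer(frame[2])
  ctr <- unpack_uint(frame[3:10])
  iv <- frame[11:22]
  ct_len <- unpack_uint(frame[23:26])
  if (length(frame) != 26 + ct_len + 16) {
    vv_abort("channel frame truncated", "vv_channel_integrity_error")
  }
  if (ctr <= ctx$recv) {
    vv_abort(sprintf("channel counter violation: got %d after %d (replay/reorder)",
                     ctr, ctx$recv),
             c("vv_channel_replay_error", "vv_channel_error"))
  }
  ct <- frame[26 + seq_len(ct_len)]
  tag <- frame[(26 + ct_len + 1):length(frame)]
  pt <- .c_aes_gcm_decrypt(ctx$key, iv, message_aad(role_byte, ctr), ct, tag)
  if (is.null(pt)) {
    vv_abort("channel message failed authentication",
             c("vv_channel_integrity_error", "vv_channel_error"))
  }
  ctx$recv <- ctr
  pt
}
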