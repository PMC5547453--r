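Package: vcfvault
Title: Sealed Outsourcing of VCF Variant Data with Minimal Perfect Hashing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale framework for privacy-preserving outsourcing of
    genetic-testing queries against Variant Call Format (VCF) data. Variant
    records are normalized to biallelic SNVs and bit-packed into 40-bit keys
    held in 8-byte containers; keys are range-partitioned into 500-record
    blocks sized to a 4 KB page, indexed per block with a Fox-Chen-Heath
    (FCH) minimal perfect hash, and sealed with AES-128-GCM authenticated
    encryption under a manifest that defeats tampering, reordering and
    replay. A simulated trusted-execution enclave answers conjunctive
    exact-match count queries over an attested, encrypted channel (ECDSA
    attestation, ECDH session keys), touching exactly one sealed page per
    candidate key so that the page-access trace is independent of match
    outcomes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
SystemRequirements: OpenSSL >= 1.1.1 (libcrypto)
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
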