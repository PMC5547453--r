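---
title: "Sealed genomic count queries: design and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sealed genomic count queries: design and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfvault)
```

`vcfvault` lets a data owner outsource a VCF-derived variant set to an
untrusted host such that an authorized user can obtain exact-match counts
— and nothing else — while the host learns neither data, queries, nor
results, and cannot undetectably tamper with, reorder, or roll back the
stored data. This vignette explains the model behind each layer, the
parameters that matter, what the synthetic fixtures do and do not emulate,
and where the design was genuinely open.

## Threat model and scope

The host is malicious: it controls the OS and storage and may modify,
reorder, duplicate, or replay anything kept outside the enclave boundary.
The enclave itself — here a simulated software boundary holding its own
keys — is trusted, as is the correctness of the cryptographic primitives
(consumed from OpenSSL's libcrypto). Side channels are addressed only at
page granularity: the sequence of 4 KB sealed pages touched by a query is
made independent of the data contents and match outcomes. Finer channels
(cache timing, within-page offsets, query timing) are out of scope, as are
range queries, genotype awareness, and record retrieval — the result is a
count, by design.

## The 40-bit record code

A biallelic SNV needs 5 bits of chromosome (25 values: 22 autosomes, X, Y,
MT), 30 bits of position (human chromosome 1 is ~2.5·10^8 bp, well under
2^30 − 1), 2 bits per single-base allele, and one flag bit: 40 bits, held
in the low half of an 8-byte integer so a record loads in one aligned read
and sorts numerically by (chromosome, position). The field order
(chromosome most significant) is what makes the sorted range partition
meaningful; the alphabetical base code and the chromosome table are fixed
conventions of this package. Anything a 2-bit allele cannot express —
indels, symbolic alleles, missing ALT — is dropped and counted rather than
encoded: the retained domain is exactly the queryable domain, and the flag
bit is therefore 1 on every retained record. Query-side candidates are
encoded with the same flag, keeping the two sides consistent. Multi-allelic
sites expand to one key per alternate, matching the tuple semantics of the
query language; exact duplicate keys are removed before hashing because a
minimal perfect hash is undefined on multisets. Decoding is the exact
inverse on the full valid domain, and the round trip is property-tested
over random records.

## The FCH minimal perfect hash

Each 500-record block carries its own Fox–Chen–Heath function: with n keys
and b buckets, a seeded 64-bit mixing hash assigns each key a bucket — a
p1 = 0.6 fraction of keys lands in the first p2 = 0.3 fraction of buckets —
and a provisional slot in [0, n). Buckets are placed largest-first (ties by
index, for determinism); each receives a displacement d such that
(slot + d) mod n is free for all of its keys. Storage is the 32-byte header
(n, b, two seeds, the two split fractions as float32) plus one
⌈log2 n⌉-bit displacement per bucket.

Parameter choices, fixed from the serialization arithmetic:

* **b = ⌈c·n / (log2 n + 1)⌉ with c = 3.95.** At n = 500 this gives
  b = 199 and a serialized size of 32 + ⌈199·9/8⌉ = 256 bytes = 4.096
  bits/key — the largest bucket count (hence the easiest construction)
  that stays within the ~4.1 bits/key budget the format targets.
* **Probe order.** The displacement search walks all n values from a
  random start with a stride coprime to n, both derived per bucket from
  the probe seed: deterministic, seeded, and guaranteed to cover every
  displacement. Two keys of one bucket sharing a provisional slot can
  never be separated by a common shift, so that case aborts the attempt
  immediately rather than wasting the probe budget.
* **Retry policy.** Up to 1000 probes per bucket and 50 seed redraws;
  with these defaults a 500-key construction typically succeeds within a
  handful of redraws. If the budget is ever exhausted the bucket count is
  escalated by 15% (reported via `message`), trading a few bits of space
  for constructability; the compactness tests tolerate this because it is
  rare at the default geometry.

Evaluation is total: any well-formed key produces *some* slot, so
membership always requires comparing the stored key at that slot. The
lookup path treats the hash as a routing device and the 8-byte comparison
as the only certificate — the oracle-equivalence tests (hash + compare
versus a linear scan) pin this down.

One global function over the whole dataset would also satisfy the
minimal-perfect-hash contract, but per-block functions keep each
construction small (the regime where FCH is most compact), keep the
serialized function inside the page it serves, and let the sorted range
partition route a candidate with directory metadata only. The global
alternative was considered and not implemented.

## Sealing and the anti-replay manifest

Blocks of 500 keys (8 B each, 4000 B — sized to a 4 KB page; tail slots
hold the all-ones sentinel, which no valid key can equal) are encrypted
with AES-128-GCM. The IV is 32 bits of dataset epoch plus a 64-bit
monotone counter; the sealing context refuses to issue the same IV twice
under one key. Everything a verifier needs to localize an attack rides in
the authenticated header: dataset id, owner, block index, total blocks,
seal timestamp, dataset version. Tag failure, wrong dataset/owner, stale
version and wrong index are distinct condition classes
(`vv_integrity_error`, `vv_substitution_error`, `vv_replay_error`,
`vv_reorder_error`), because the right response differs.

Freshness is enforced by the dataset version counter bound into headers
and manifest, not by wall-clock comparison — clocks are unreliable in this
threat model, so the timestamp is informational. The manifest (HMAC-SHA256
under the sealing key) lists the strictly increasing per-block key maxima
used for routing and a SHA-256 digest of every sealed block; deletion,
substitution and un-MACed edits each fail verification with the offending
index named. The sealing key itself is derived per dataset from the
enclave's sealing secret via HKDF with the dataset id as context — a
software stand-in for a hardware-bound sealing key. The version authority
lives with the manifest held by the enclave and the owner; the host
storing sealed bytes holds no authority at all.

The sealing overhead of this container reflects this package's header and
manifest sizes, not any hardware sealing format; it is reported by the
`stats` CLI verb rather than asserted against a constant.

## The attested channel

The enclave's measurement is a SHA-256 digest over the deparsed source of
its runtime functions, recomputed from the installed namespace — an
honest-but-checkable stand-in for a hardware code measurement: any edit to
the query engine changes it. Attestation is an ECDSA (P-256) signature
over (measurement, challenge nonce, ephemeral ECDH key, curve label)
verified against a locally pinned key; nonces are single-use, so a
replayed report fails. Sessions derive a 128-bit key via HKDF from the
ECDH shared secret salted with the handshake transcript — diverging
transcripts diverge keys — and every frame is AES-GCM with the sender role
and a strictly increasing counter as associated data, which subsumes
replay and reorder detection. P-256 is a configuration constant recorded
in the transcript; nothing in the design depends on the particular curve.

## Query execution and obliviousness

`expand_candidates` produces the sorted cross product of the four value
sets (capped at 10,000 candidates by default — conjunctive biomarker
queries are small products; the cap bounds adversarial blowup, and
out-of-range values are rejected loudly rather than silently counting
zero). The access trace — one routed block index per candidate — is
computed from the candidate set and directory alone, before any unsealing,
and is therefore identical whether all or none of the candidates match;
the test suite asserts this on two datasets constructed with identical
block geometry, one containing every candidate and one containing none.
Within a query each routed block is unsealed once and cached; across
queries nothing is cached, keeping the per-query page count equal to the
number of distinct routed blocks. On any storage violation the user
receives an encrypted error indicator naming the violation class — never a
partial count. Result frames optionally carry `candidates_evaluated` and
`blocks_touched` for observability; a strict mode returns the count alone.

## What the synthetic fixtures emulate

The generator produces biallelic SNVs with unique (CHROM, POS) pairs over
chromosomes 1–25, positions uniform on a configurable range, salted with
5% multi-allelic sites and 5% non-SNV rows by default — enough to exercise
expansion and drop accounting, with a ground-truth sidecar derived from
the generation plan rather than from the codec. Real VCFs differ in ways
that do not matter to this pipeline (clustered positions, transition/
transversion bias, INFO/genotype columns are ignored) and one way that
does: real files can contain structural variants and complex alleles in
forms the drop rules were not tuned against, so passing tests show the
exact-match pipeline is correct on its declared domain, not that the
normalization policy matches any particular caller's output. Test problem
sizes — datasets to 20,000 records, 200 random dataset/query pairs,
100,000-record encoding checks — were chosen as the package's own test
geometry; the same code paths run unchanged at larger sizes.

## Numerical and degenerate-input choices

Keys live in R doubles: every value below 2^53 is exact, and valid keys
are below 2^40, so no 64-bit integer type is needed R-side; the C++ layer
uses `uint64_t`. The FCH split fractions are quantized to float32 before
use so that serialize → deserialize → evaluate is bit-identical to the
original. `n = 1` degenerates cleanly (one bucket region, slot 0,
displacement width forced to 1 bit). Empty datasets refuse to seal;
empty query sets refuse to expand; a header whose corrupted length fields
break the frame arithmetic is reported as an integrity failure rather
than parsed on faith.

## Known limitations

Counts only — no retrieval, ranges, or allele-frequency aggregation. The
24 unused container bits per record are not compressed away. The enclave
is a simulation: it demonstrates the protocol logic and storage formats,
not hardware isolation, and its "measurement" covers the R functions, not
the process image. Page-granular obliviousness does not defend timing or
cache channels. Manifest updates re-seal the whole dataset (no
incremental/Merkle update path). Construction of the per-block hash is
single-threaded; at hundreds of thousands of records the owner-side
preprocessing dominates, which is acceptable for a one-time cost but is
the first thing to parallelize.
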