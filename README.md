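# vcfvault

Privacy-preserving outsourcing of genetic-testing queries against VCF data,
at desk scale. A data owner holds variants in Variant Call Format; a cloud
host is untrusted; a data user wants the answer to one narrow question —
*how many records match this set of biomarkers?* — without the host ever
seeing the data, the query, or the answer. `vcfvault` implements the whole
pipeline as an R package around a simulated trusted-execution enclave: the
storage and query formats are real, the hardware isolation is a software
boundary with its own keys.

## The method

**Encoding.** Each biallelic SNV record *r* = (CHROM, POS, REF, ALT) is
packed into a 40-bit key held in the low bits of an 8-byte container:

    a = CHROM·2^35 + POS·2^5 + code(REF)·2^3 + code(ALT)·2 + flag

with 5 bits for the chromosome (1–22, X=23, Y=24, MT=25), 30 bits for the
1-based position, 2 bits per allele (A=0, C=1, G=2, T=3) and 1 SNV-flag
bit. The chromosome occupies the most significant bits, so numeric key
order is (CHROM, POS) order. Indels, symbolic and multi-base alleles cannot
be represented in 2 bits and are dropped with a count; multi-allelic sites
expand to one key per alternate.

**Indexing.** Sorted keys are range-partitioned into blocks of 500 records
— 500 × 8 B = 4000 B, sized to one 4 KB page. Each block gets a
Fox–Chen–Heath (FCH) minimal perfect hash *f* mapping its *n* keys
bijectively onto {0,…,n−1}: a seeded hash throws keys into skewed buckets
(60% of keys into 30% of buckets), buckets are processed largest-first, and
each bucket receives one displacement that shifts all of its keys onto free
slots. The serialized function (seeds, split fractions, one bit-packed
displacement per bucket) costs ≈ 4.1 bits per key, and evaluation is O(1):
two hashes, one table read.

**Sealing.** Each block (keys in hash order, its FCH, the real-record
count) is encrypted with AES-128-GCM under a dataset key derived from the
enclave's sealing secret via HKDF. The header — dataset id, owner,
block index, total blocks, timestamp, dataset version, and a never-reused
96-bit IV (32-bit epoch ‖ 64-bit counter) — is bound as authenticated
associated data. A manifest under HMAC-SHA256 carries the version counter,
the per-block directory maxima and a digest of every sealed block, so
tampering, block reordering, block substitution and stale-version replay
are each detected and reported as distinct error types.

**Querying.** A query is four value sets (CHROM, POS, REF, ALT) with
conjunctive membership semantics — the SQL count query
`CHROM IN (…) AND POS IN (…) AND REF IN (…) AND ALT IN (…)`. The enclave
expands the cross product into candidate keys, routes each through the
manifest directory, unseals exactly one page per candidate (cached within a
query), evaluates the block's FCH and compares the stored 8-byte key for
exact equality. The page-access trace is computed from the candidate set
alone, before any outcome exists, so which pages are touched reveals
nothing about which candidates matched. Queries and the returned count
travel over an attested channel: ECDSA-signed enclave measurement, ECDH
(P-256) session keys, AES-GCM frames with strictly increasing counters.

## Worked example

The canonical five-row chromosome-20 sample (two plain SNVs, one
multi-allelic site, one missing ALT, one microsatellite) normalizes to four
biallelic SNV records; the query {CHROM=20, POS∈{17330,14370}, REF∈{T,G},
ALT∈{A}} matches two of them — (20,14370,G→A) and (20,17330,T→A):

```r
library(vcfvault)
vcf <- system.file("extdata", "sample_chr20.vcf", package = "vcfvault")
keys <- sort(encode_dataset(normalize_variants(read_vcf(vcf))$records)$keys)

enclave <- enclave_new(rng_seed = 1)
owner   <- open_session(enclave, "owner")
ack     <- provision_dataset(enclave, owner_upload_frame(owner$client, keys),
                             owner$enclave)
id_hex  <- jsonlite::fromJSON(rawToChar(open_message(owner$client, ack)))$dataset_id
did     <- as.raw(strtoi(substring(id_hex, seq(1,31,2), seq(2,32,2)), 16L))

user  <- open_session(enclave, "user")
q     <- genetic_query(20, c(17330, 14370), c("T", "G"), "A")
reply <- execute_query(enclave, query_frame(user$client, q, did), user$enclave)
str(parse_result(user$client, reply))
#> List of 3
#>  $ matched_count       : int 2
#>  $ candidates_evaluated: int 4
#>  $ blocks_touched      : int 1
```

The same flow is available from a shell via the installed launcher
(`inst/cli/vcfvault`): `gen-fixture`, `encode`, `build-index`, `seal`,
`provision`, `query`, `verify`, `stats`, `demo`. `verify` exits 0 on a
clean container and with distinct codes for integrity (2), reorder (3),
replay (4) and manifest (5) violations.

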