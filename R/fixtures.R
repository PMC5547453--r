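# Synthetic VCF fixtures and the end-to-end demo.
#
# The generator emulates the shape of the VCF inputs the pipeline is built
# for: biallelic SNVs with unique (CHROM, POS) pairs across chromosomes
# 1-22/X/Y/MT, salted with a configurable fraction of multi-allelic sites
# and of non-SNV rows (indels) to exercise the codec's drop logic. A
# ground-truth sidecar lists every record that survives normalization, so
# oracle tests never re-derive truth through the code under test.

#' Specify a synthetic VCF fixture
#'
#' @param n_records number of VCF data rows to generate.
#' @param chromosomes chromosome codes to draw from (1..25).
#' @param pos_min,pos_max per-chromosome position range sampled uniformly;
#'   `n_records` must not exceed the total (chromosome, position) capacity.
#' @param seed RNG seed; generation is byte-deterministic given one
#'   specification object.
#' @param frac_multi fraction of rows given two alternate alleles.
#' @param frac_non_snv fraction of rows made non-SNV (multi-base REF) to
#'   exercise drop accounting.
#' @return list of class `vcfvault_fixture_spec`.
#' @export
fixture_spec <- function(n_records, chromosomes = 1:25, pos_min = 1,
                         pos_max = 10000000, seed = 1,
                         frac_multi = 0.05, frac_non_snv = 0.05) {
  stopifnot(n_records >= 1, all(chromosomes >= 1), all(chromosomes <= 25),
            pos_min >= 1, pos_max <= POS_MAX, pos_min <= pos_max,
            frac_multi >= 0, frac_non_snv >= 0, frac_multi + frac_non_snv <= 1)
  capacity <- length(chromosomes) * (pos_max - pos_min + 1)
  if (n_records > capacity) {
    vv_abort(sprintf("fixture spec unsatisfiable: %d records exceed the %g unique-site capacity",
                     n_records, capacity), "vv_fixture_error")
  }
  structure(list(n_records = as.integer(n_records),
                 chromosomes = as.integer(sort(unique(chromosomes))),
                 pos_min = pos_min, pos_max = pos_max, seed = seed,
                 frac_multi = frac_multi, frac_non_snv = frac_non_snv),
            class = "vcfvault_fixture_spec")
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic VCF and its ground-truth sidecar
#'
#' Writes a well-formed VCF 4.2 file (rows sorted by chromosome and
#' position) and a sidecar TSV listing every normalized record the codec
#' should retain, plus the expected drop count. Deterministic under a fixed
#' spec: the same spec yields byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param path output VCF path.
#' @param sidecar_path output sidecar path (default `<path>.truth.tsv`).
#' @return list with `path`, `sidecar_path`, `retained` (data.frame of
#'   normalized records), `dropped` (expected drop count), invisibly.
#' @export
generate_vcf <- function(spec, path, sidecar_path = paste0(path, ".truth.tsv")) {
  stopifnot(inherits(spec, "vcfvault_fixture_spec"))
  n <- spec$n_records
  with_seed(spec$seed, {
    # unique (chrom, pos) pairs by rejection
    chrom <- sample(spec$chromosomes, n, replace = TRUE)
    pos <- floor(stats::runif(n, spec$pos_min, spec$pos_max + 1))
    key <- chrom * 2^30 + pos
    while (anyDuplicated(key)) {
      dup <- duplicated(key)
      chrom[dup] <- sample(spec$chromosomes, sum(dup), replace = TRUE)
      pos[dup] <- floor(stats::runif(sum(dup), spec$pos_min, spec$pos_max + 1))
      key <- chrom * 2^30 + pos
    }
    o <- order(key)
    chrom <- chrom[o]; pos <- pos[o]
    kind <- sample(c("snv", "multi", "indel"), n, replace = TRUE,
                   prob = c(1 - spec$frac_multi - spec$frac_non_snv,
                            spec$frac_multi, spec$frac_non_snv))
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(seq_len(n), function(i) {
      others <- setdiff(BASES, ref[i])
      switch(kind[i],
             snv = sample(others, 1),
             multi = paste(sample(others, 2), collapse = ","),
             indel = sample(others, 1))
    }, character(1))
    # non-SNV rows: multi-base REF (deletion-style), dropped by the codec
    ref[kind == "indel"] <- vapply(which(kind == "indel"), function(i) {
      paste(c(ref[i], sample(BASES, 1 + sample.int(3, 1), replace = TRUE)), collapse = "")
    }, character(1))
  })
  rows <- paste(code_to_chrom(chrom), format(pos, scientific = FALSE, trim = TRUE),
                ".", ref, alt, ".", "PASS", ".", sep = "\t")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=vcfvault synthetic fixture generator",
               paste0("##fixture_seed=", spec$seed),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  # ground truth, derived from the generation plan (not from the codec)
  n_alt <- ifelse(kind == "multi", 2L, 1L)
  idx <- rep.int(seq_len(n), n_alt)
  alts <- unlist(strsplit(alt, ",", fixed = TRUE))
  keep <- rep.int(kind != "indel", n_alt)
  retained <- data.frame(chrom = chrom[idx][keep], pos = pos[idx][keep],
                         ref = ref[idx][keep], alt = alts[keep],
                         is_snp = TRUE, stringsAsFactors = FALSE)
  dropped <- sum(kind == "indel")
  writeLines(c(sprintf("#retained=%d\tdropped=%d", nrow(retained), dropped),
               "chrom\tpos\tref\talt",
               paste(retained$chrom,
                     format(retained$pos, scientific = FALSE, trim = TRUE),
                     retained$ref, retained$alt, sep = "\t")),
             sidecar_path)
  invisible(list(path = path, sidecar_path = sidecar_path,
                 retained = retained, dropped = dropped))
}

#' Read a fixture sidecar
#' @param sidecar_path path written by [generate_vcf()].
#' @return list with `retained` data.frame and `dropped` count.
#' @export
read_sidecar <- function(sidecar_path) {
  first <- readLines(sidecar_path, n = 1)
  counts <- as.integer(regmatches(first, gregexpr("[0-9]+", first))[[1]])
  tab <- utils::read.delim(sidecar_path, skip = 1, stringsAsFactors = FALSE)
  tab$is_snp <- TRUE
  list(retained = tab, dropped = counts[2])
}

#' The worked five-row chromosome-20 sample
#'
#' The canonical example data rows from the VCF format description: two
#' plain SNVs, one multi-allelic SNV site, one row with a missing ALT and
#' one microsatellite, of which exactly four biallelic SNV records survive
#' normalization.
#'
#' @param path where to write the VCF.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "20\t14370\trs6054257\tG\tA\t29\tPASS\t.",
    "20\t17330\t.\tT\tA\t3\tq10\t.",
    "20\t1110696\trs6040355\tA\tG,T\t67\tPASS\t.",
    "20\t1230237\t.\tT\t.\t47\tPASS\t.",
    "20\t1234567\tmicrosat1\tGTC\tG,GTCT\t50\tPASS\t."
  ), path)
  invisible(path)
}

#' End-to-end demonstration of the full pipeline
#'
#' Runs the three phases against one synthetic fixture: owner-side encode +
#' per-block hashing; attested provisioning into a simulated enclave (seal,
#' manifest); then an attested user query with the decrypted count. An
#' optional adversary hook corrupts the sealed store between provisioning
#' and querying to show the violation surfacing to the user.
#'
#' @param n_records fixture size.
#' @param seed fixture and construction seed.
#' @param query a [genetic_query()]; by default one is built from fixture
#'   records so the expected count is known from the sidecar.
#' @param adversary `"none"`, or `"swap_blocks"` to swap two sealed blocks
#'   before the query.
#' @param quiet suppress the printed transcript.
#' @return transcript: a list with one entry per phase (sizes, counts, the
#'   block-access trace, and the decrypted result or surfaced violation).
#' @export
run_demo <- function(n_records = 2000, seed = 7, query = NULL,
                     adversary = c("none", "swap_blocks"), quiet = FALSE) {
  adversary <- match.arg(adversary)
  say <- function(...) if (!quiet) cat(sprintf(...), "\n", sep = "")
  transcript <- list()
  dir <- tempfile("vvdemo")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)

  vcf <- file.path(dir, "fixture.vcf")
  fx <- generate_vcf(fixture_spec(n_records, seed = seed), vcf)
  say("[fixture] %d VCF rows -> %s (%d bytes)", n_records, vcf, file.size(vcf))

  norm <- normalize_variants(read_vcf(vcf))
  enc <- encode_dataset(norm$records)
  keys <- sort(enc$keys)
  transcript$encode <- list(records = nrow(norm$records), dropped = norm$dropped,
                            duplicates = enc$duplicates, keys = length(keys))
  say("[encode] %d records retained (%d dropped, %d duplicate keys), 8 bytes/key",
      nrow(norm$records), norm$dropped, enc$duplicates)

  enclave <- enclave_new(rng_seed = seed)
  owner <- open_session(enclave, "owner")
  ack_frame <- provision_dataset(enclave, owner_upload_frame(owner$client, keys), owner$enclave)
  ack <- jsonlite::fromJSON(rawToChar(open_message(owner$client, ack_frame)))
  transcript$provision <- ack
  say("[provision] dataset %s v%d sealed into %d blocks of %d records",
      substr(ack$dataset_id, 1, 8), ack$dataset_version, ack$total_blocks, BLOCK_RECORDS)

  if (adversary == "swap_blocks") {
    st <- enclave$datasets[[ack$dataset_id]]
    if (st$manifest$total_blocks >= 2) {
      tmp <- st$sealed_blocks[[1]]
      st$sealed_blocks[[1]] <- st$sealed_blocks[[2]]
      st$sealed_blocks[[2]] <- tmp
      enclave$datasets[[ack$dataset_id]] <- st
      say("[adversary] swapped sealed blocks 0 and 1 in the store")
    }
  }

  if (is.null(query)) {
    r <- fx$retained[1:min(2, nrow(fx$retained)), ]
    query <- genetic_query(unique(r$chrom), unique(r$pos), unique(r$ref), unique(r$alt))
  }
  user <- open_session(enclave, "user")
  did <- as.raw(strtoi(substring(ack$dataset_id, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  reply <- execute_query(enclave, query_frame(user$client, query, did), user$enclave)
  res <- tryCatch(parse_result(user$client, reply), vcfvault_error = function(e) e)
  transcript$query <- list(query = unclass(query), trace = enclave$last_trace,
                           result = if (inherits(res, "error")) {
                             list(violation = class(res)[1], message = conditionMessage(res))
                           } else res)
  if (inherits(res, "error")) {
    say("[query] violation surfaced to user: %s", conditionMessage(res))
  } else {
    say("[query] matched_count=%d over %d candidates touching %d block(s)",
        res$matched_count, res$candidates_evaluated, res$blocks_touched)
  }
  invisible(transcript)
}
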