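# VCF parsing, SNV normalization, and the 40-bit record codec.

CHROM_MAX <- 25L
POS_MAX <- 2^30 - 1
BASE_CODES <- c(A = 0, C = 1, G = 2, T = 3)

#' Construct a normalized variant record
#'
#' A `variant_record` is one biallelic single-nucleotide variant: a
#' chromosome code (1-22 autosomes, 23 = X, 24 = Y, 25 = MT), a 1-based
#' position of at most \eqn{2^{30}-1}, single-base REF and ALT alleles, and
#' an SNV flag. These are exactly the fields the 40-bit codec can represent.
#'
#' @param chrom integer chromosome code in 1..25.
#' @param pos 1-based genomic position, at most 1,073,741,823.
#' @param ref,alt single bases, each one of A, C, G, T.
#' @param is_snp logical flag stored in the key's low bit.
#' @return a data.frame with one row per record (columns `chrom`, `pos`,
#'   `ref`, `alt`, `is_snp`); vector arguments are recycled by `data.frame`.
#' @export
variant_record <- function(chrom, pos, ref, alt, is_snp = TRUE) {
  rec <- data.frame(chrom = as.integer(chrom), pos = as.numeric(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    is_snp = as.logical(is_snp), stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

validate_records <- function(rec) {
  bad_field <- function(field) {
    vv_abort(sprintf("field '%s' out of range for the 40-bit encoding", field),
             "vv_encoding_error", field = field)
  }
  if (any(is.na(rec$chrom)) || any(rec$chrom < 1L) || any(rec$chrom > CHROM_MAX)) bad_field("chrom")
  if (any(is.na(rec$pos)) || any(rec$pos < 1) || any(rec$pos > POS_MAX) ||
      any(rec$pos != floor(rec$pos))) bad_field("pos")
  if (!all(rec$ref %in% names(BASE_CODES))) bad_field("ref")
  if (!all(rec$alt %in% names(BASE_CODES))) bad_field("alt")
  if (any(is.na(rec$is_snp))) bad_field("is_snp")
  invisible(rec)
}

#' Read raw variant rows from a VCF file
#'
#' Reads a VCF 4.x text file (plain or gzip-compressed), skips header lines
#' beginning with `#`, and returns the first five columns of each data line
#' unmodified. INFO/FORMAT/sample columns are ignored.
#'
#' @param path path to a VCF file.
#' @return data.frame with character columns `chrom`, `id`, `ref`, `alt` and
#'   numeric `pos`, one row per data line, in file order.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    vv_abort(sprintf("VCF file not found: %s", path), "vv_parse_error")
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_data <- !startsWith(lines, "#") & nzchar(lines)
  rows <- which(is_data)
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), pos = numeric(), id = character(),
                      ref = character(), alt = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5)) {
    bad <- rows[which(nf < 5)[1]]
    vv_abort(sprintf("malformed VCF data line %d: fewer than 5 tab-separated columns", bad),
             "vv_parse_error", line = bad)
  }
  data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    pos = as.numeric(vapply(parts, `[[`, character(1), 2L)),
    id = vapply(parts, `[[`, character(1), 3L),
    ref = vapply(parts, `[[`, character(1), 4L),
    alt = vapply(parts, `[[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
}

chrom_to_code <- function(chrom) {
  s <- toupper(sub("^chr", "", chrom, ignore.case = TRUE))
  code <- suppressWarnings(as.integer(s))
  code[s == "X"] <- 23L
  code[s == "Y"] <- 24L
  code[s %in% c("MT", "M")] <- 25L
  code[!is.na(code) & (code < 1L | code > 25L)] <- NA_integer_
  code
}

code_to_chrom <- function(code) {
  out <- as.character(code)
  out[code == 23L] <- "X"
  out[code == 24L] <- "Y"
  out[code == 25L] <- "MT"
  out
}

#' Normalize raw VCF rows to encodable SNV records
#'
#' Maps chromosome names to codes (a `chr` prefix is tolerated; X, Y and
#' MT/M map to 23, 24 and 25), splits multi-allelic ALT fields into one
#' record per alternate allele, and drops anything the 2-bit allele fields
#' cannot carry: indels, symbolic or missing alleles, unmappable
#' chromosomes, and positions beyond \eqn{2^{30}-1}. Drops are counted, not
#' fatal; every retained record has `is_snp = TRUE`.
#'
#' @param raw data.frame as returned by [read_vcf()].
#' @return list with `records` (a normalized record data.frame) and
#'   `dropped` (count of row/alternate combinations discarded).
#' @export
normalize_variants <- function(raw) {
  if (nrow(raw) == 0) {
    return(list(records = variant_record(integer(), numeric(), character(), character(), logical()),
                dropped = 0L))
  }
  alts <- strsplit(raw$alt, ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(raw)), nalt)
  cand <- data.frame(
    chrom = chrom_to_code(raw$chrom[idx]),
    pos = raw$pos[idx],
    ref = toupper(raw$ref[idx]),
    alt = toupper(unlist(alts)),
    stringsAsFactors = FALSE
  )
  keep <- !is.na(cand$chrom) &
    !is.na(cand$pos) & cand$pos >= 1 & cand$pos <= POS_MAX & cand$pos == floor(cand$pos) &
    cand$ref %in% names(BASE_CODES) &
    cand$alt %in% names(BASE_CODES)
  records <- cand[keep, , drop = FALSE]
  rownames(records) <- NULL
  records$is_snp <- TRUE
  list(records = records, dropped = sum(!keep))
}

#' Pack variant records into 40-bit keys
#'
#' Encodes each record into the low 40 bits of an 8-byte container:
#' \preformatted{ value = chrom * 2^35 + pos * 2^5 + code(ref) * 2^3 + code(alt) * 2 + flag }
#' with 5 bits for the chromosome, 30 for the position, 2 each for REF and
#' ALT (A=0, C=1, G=2, T=3) and 1 for the SNV flag. The chromosome occupies
#' the most significant bits, so keys sort by (chrom, pos). The high 24 bits
#' of the container are always zero.
#'
#' @param records data.frame of valid variant records.
#' @return numeric vector of keys, each an exact integer below \eqn{2^{40}}.
#' @export
encode_record <- function(records) {
  validate_records(records)
  unname(records$chrom * 2^35 + records$pos * 2^5 +
           BASE_CODES[records$ref] * 2^3 + BASE_CODES[records$alt] * 2 +
           as.numeric(records$is_snp))
}

#' Unpack 40-bit keys back into variant records
#'
#' Exact inverse of [encode_record()]. Keys at or above \eqn{2^{40}}, or
#' whose decoded chromosome falls outside 1..25, are rejected.
#'
#' @param keys numeric vector of encoded keys.
#' @return data.frame of variant records.
#' @export
decode_record <- function(keys) {
  if (any(is.na(keys)) || any(keys < 0) || any(keys >= 2^40) || any(keys != floor(keys))) {
    vv_abort("invalid key: value outside [0, 2^40)", "vv_invalid_key_error")
  }
  v <- keys
  flag <- v %% 2; v <- (v - flag) / 2
  alt <- v %% 4; v <- (v - alt) / 4
  ref <- v %% 4; v <- (v - ref) / 4
  pos <- v %% 2^30; v <- (v - pos) / 2^30
  chrom <- v
  if (any(chrom < 1) || any(chrom > CHROM_MAX)) {
    vv_abort("invalid key: decoded chromosome outside 1..25", "vv_invalid_key_error")
  }
  bases <- names(BASE_CODES)
  data.frame(chrom = as.integer(chrom), pos = pos,
             ref = bases[ref + 1], alt = bases[alt + 1],
             is_snp = flag == 1, stringsAsFactors = FALSE)
}

#' Encode a record set into distinct keys
#'
#' Encodes every record and removes exact duplicate keys (a minimal perfect
#' hash is undefined on multisets), reporting how many were removed.
#' Input order of first occurrences is preserved.
#'
#' @param records data.frame of valid variant records.
#' @return list with `keys` (distinct encoded keys) and `duplicates`
#'   (number of keys removed).
#' @export
encode_dataset <- function(records) {
  if (nrow(records) == 0) {
    return(list(keys = numeric(0), duplicates = 0L))
  }
  keys <- encode_record(records)
  dup <- duplicated(keys)
  list(keys = keys[!dup], duplicates = sum(dup))
}

#' Write / read an encoded key array
#'
#' On-disk layout is 8 bytes per key, little-endian, no header. `NA` keys
#' (pad slots) are written as the sentinel `0xFFFFFFFFFFFFFFFF`, which no
#' valid 40-bit key can collide with.
#'
#' @param keys numeric vector of keys (or `NA` pads).
#' @param path destination file.
#' @return `read_keys` returns the numeric key vector.
#' @export
write_keys <- function(keys, path) {
  writeBin(keys_to_raw(keys), path)
  invisible(path)
}

#' @rdname write_keys
#' @export
read_keys <- function(path) {
  raw_to_keys(readBin(path, "raw", n = file.size(path)))
}
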