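# The 40-bit record codec and VCF normalization.

test_that("read_vcf returns raw rows matching an independent text-splitting oracle", {
  path <- tempfile(fileext = ".vcf")
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             "20\t14370\trs6054257\tG\tA\t29\tPASS\t.",
             "20\t1110696\t.\tA\tG,T\t67\tPASS\t.")
  writeLines(lines, path)
  rows <- read_vcf(path)
  oracle <- lapply(strsplit(lines[3:4], "\t"), `[`, 1:5)
  expect_equal(nrow(rows), 2)
  expect_equal(unname(unlist(rows[1, ])),
               c(oracle[[1]][1], oracle[[1]][2], oracle[[1]][3:5]))
  expect_equal(rows$alt[2], "G,T")
  expect_equal(rows$pos, as.numeric(c(oracle[[1]][2], oracle[[2]][2])))
})

test_that("header-only VCF yields an empty sequence; short lines fail with line number", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT"), path)
  expect_equal(nrow(read_vcf(path)), 0)
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT", "20\t14370\tonly-three"), path)
  err <- expect_error(read_vcf(path), class = "vv_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("normalization expands multi-allelic rows, maps chromosome names, drops non-SNVs", {
  raw <- data.frame(chrom = c("20", "20", "chrX", "MT", "7", "weird"),
                    pos = c(1110696, 1234567, 100, 5, 2^30, 9),
                    id = ".", ref = c("A", "GTC", "T", "C", "A", "A"),
                    alt = c("G,T", "G,GTCT", "C", "G", "C", "C"),
                    stringsAsFactors = FALSE)
  out <- normalize_variants(raw)
  # row1 -> two records; row2 -> dropped (2 alternates); row3 X=23; row4 MT=25;
  # row5 pos above 2^30-1 dropped; row6 unmappable chrom dropped
  expect_equal(out$records$chrom, c(20L, 20L, 23L, 25L))
  expect_equal(out$records$alt, c("G", "T", "C", "G"))
  expect_true(all(out$records$is_snp))
  expect_equal(out$dropped, 4L)
})

test_that("encoding matches the independent bit-assembly oracle on spec examples and random records", {
  expect_identical(encode_record(variant_record(20, 14370, "G", "A", TRUE)),
                   687195227217)
  expect_identical(encode_record(variant_record(1, 1, "A", "A", FALSE)),
                   34359738400)
  recs <- random_records(200, seed = 11)
  keys <- encode_record(recs)
  oracle <- vapply(seq_len(200), function(i) {
    oracle_encode(recs$chrom[i], recs$pos[i], recs$ref[i], recs$alt[i], recs$is_snp[i])
  }, numeric(1))
  expect_identical(keys, oracle)
  expect_true(all(keys %/% 2^40 == 0))  # high 24 container bits zero
})

test_that("decode is the exact inverse of encode over the full valid domain", {
  expect_equal(decode_record(687195227217),
               data.frame(chrom = 20L, pos = 14370, ref = "G", alt = "A",
                          is_snp = TRUE, stringsAsFactors = FALSE))
  recs <- random_records(10000, seed = 5)
  expect_equal(decode_record(encode_record(recs)), recs, ignore_attr = TRUE)
  expect_error(decode_record(2^40), class = "vv_invalid_key_error")
  expect_error(decode_record(0), class = "vv_invalid_key_error")  # chrom 0
})

test_that("changing one field changes only that field's bit slice", {
  base <- variant_record(7, 123456, "C", "G", TRUE)
  k0 <- encode_record(base)
  variants <- list(
    list(field = "chrom", rec = variant_record(8, 123456, "C", "G", TRUE),
         mask_lo = 2^35),
    list(field = "pos", rec = variant_record(7, 123457, "C", "G", TRUE),
         mask_lo = 2^5),
    list(field = "ref", rec = variant_record(7, 123456, "T", "G", TRUE),
         mask_lo = 2^3),
    list(field = "alt", rec = variant_record(7, 123456, "C", "A", TRUE),
         mask_lo = 2^1),
    list(field = "flag", rec = variant_record(7, 123456, "C", "G", FALSE),
         mask_lo = 1))
  widths <- c(chrom = 5, pos = 30, ref = 2, alt = 2, flag = 1)
  expect_equal(sum(widths), 40)
  for (v in variants) {
    k1 <- encode_record(v$rec)
    diffbits <- abs(k1 - k0)
    # the difference is confined to the field's slice
    expect_true(diffbits %% v$mask_lo == 0, label = v$field)
    expect_lt(diffbits, v$mask_lo * 2^widths[[v$field]])
  }
})

test_that("keys serialize as exactly 8 bytes little-endian with zero high bytes", {
  keys <- random_keys(64, seed = 3)
  path <- tempfile()
  write_keys(keys, path)
  expect_equal(file.size(path), 64 * 8)
  bytes <- readBin(path, "raw", n = file.size(path))
  m <- matrix(as.integer(bytes), nrow = 8)
  expect_true(all(m[6:8, ] == 0))
  # little-endian: first byte is the least significant
  expect_equal(m[1, ], as.integer(keys %% 256))
  expect_identical(read_keys(path), keys)
})

test_that("encode_dataset deduplicates exact duplicate keys and reports the count", {
  empty <- encode_dataset(random_records(1, 1)[0, ])
  expect_equal(length(empty$keys), 0)
  expect_equal(empty$duplicates, 0L)
  rec <- variant_record(20, 14370, "G", "A", TRUE)
  two <- encode_dataset(rbind(rec, rec))
  expect_equal(length(two$keys), 1)
  expect_equal(two$duplicates, 1L)
  recs <- random_records(500, seed = 9)
  out <- encode_dataset(recs)
  expect_equal(length(out$keys), length(unique(out$keys)))
  expect_equal(length(out$keys), 500)
  expect_equal(out$duplicates, 0L)
})

test_that("out-of-range fields are rejected with the field named", {
  err <- expect_error(variant_record(26, 1, "A", "C"), class = "vv_encoding_error")
  expect_match(conditionMessage(err), "chrom")
  err <- expect_error(variant_record(1, 2^30, "A", "C"), class = "vv_encoding_error")
  expect_match(conditionMessage(err), "pos")
  expect_error(variant_record(1, 1, "N", "C"), class = "vv_encoding_error")
})
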