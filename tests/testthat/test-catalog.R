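catalog <- mybpc_catalog()

test_that("packaged catalog carries the full published variant complement", {
  expect_equal(nrow(catalog), 16)
  expect_equal(sum(catalog$species == "human"), 14)
  expect_equal(sum(catalog$species == "mouse"), 2)
  expect_false(any(catalog$partial))
  expect_false(anyDuplicated(catalog$id) > 0)
  expect_true(all(catalog$printed_mw_kda >= 115 & catalog$printed_mw_kda <= 132))

  # the variant lacking all four Pro/Ala cassettes
  v9 <- variant_pattern(catalog, "h-v9")
  expect_false(any(unlist(v9[c("exon2", "exon3", "exon4", "exon5")])))
  expect_true(v9$exon10 && v9$exon31 && v9$exon32)

  # the internally initiated variant starts in exon 7
  expect_equal(variant_pattern(catalog, "h-v012")$tss_truncation, 7L)
})

test_that("catalog i/o round-trips field-for-field and rejects bad input", {
  src <- system.file("extdata", "mybpc1_catalog.tsv", package = "smybpc")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(load_catalog(src), tmp)
  expect_identical(readLines(tmp), readLines(src))
  expect_identical(load_catalog(tmp), catalog)

  # header-only file loads as an empty catalog
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(readLines(src)[1], empty)
  expect_equal(nrow(load_catalog(empty)), 0)

  # malformed flag is reported with its row and column
  lines <- readLines(src)
  broken <- sub("\\+", "x", lines[3]) # first flag of the second record
  writeLines(c(lines[1:2], broken, lines[4:length(lines)]), empty)
  expect_error(load_catalog(empty), "row 2.*exon2")

  # duplicate id
  writeLines(c(lines, lines[2]), empty)
  expect_error(load_catalog(empty), "duplicate")

  expect_error(load_catalog(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("splice grammar validation accepts the catalog, rejects violations", {
  report <- validate_pattern(catalog)
  expect_true(all(report$ok))

  # exon 33 must carry coding sequence exactly when exon 32 is spliced out
  bad <- make_variant(exon32 = FALSE)
  bad$exon33_coding <- "utr_only"
  rep_bad <- validate_pattern(bad)
  expect_false(rep_bad$ok[rep_bad$check == "exon33_stop_rule"])

  # internal start with an upstream cassette still flagged present
  bad2 <- make_variant(exon2 = TRUE, tss_truncation = 7)
  rep2 <- validate_pattern(bad2)
  expect_false(rep2$ok[rep2$check == "tss_truncation"])

  # h-v012 itself is legal
  rep3 <- validate_pattern(variant_pattern(catalog, "h-v012"))
  expect_true(all(rep3$ok))
})

test_that("tail resolution is total with an image of exactly four states", {
  tails <- resolve_tail(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tails$aa_after_C10, c(26L, 35L, 3L, 33L))
  expect_equal(tails$stop_exon, c(32L, 33L, 32L, 33L))
  expect_equal(length(unique(tails$aa_after_C10)), 4)
  # exon 33 codes iff exon 32 is out
  expect_equal(tails$exon33_coding == "coding", !tails$exon32)
  # catalog tails agree with the published exon 31/32 partition
  cat_tails <- resolve_tail(catalog$exon31, catalog$exon32)
  both <- catalog$id[cat_tails$aa_after_C10 == 26]
  expect_setequal(both, c("h-v1", "h-v6", "h-v7", "h-v8", "h-v9", "h-v002",
                          "h-v202", "m-v002"))
  expect_equal(catalog$id[cat_tails$aa_after_C10 == 35], "h-v5")
  expect_equal(catalog$id[cat_tails$aa_after_C10 == 33], "h-v10")
})

test_that("NH2-terminal combinations and alternatively spliced exons", {
  expect_equal(nrow(nterm_combination_set(catalog)), 7)

  # identical NH2-termini collapse to one tuple
  v12 <- dplyr::filter(catalog, id %in% c("h-v1", "h-v2"))
  expect_equal(nrow(nterm_combination_set(v12)), 1)
  v9_only <- dplyr::filter(catalog, id == "h-v9")
  n9 <- nterm_combination_set(v9_only)
  expect_equal(nrow(n9), 1)
  expect_false(any(unlist(n9[, c("exon2", "exon3", "exon4", "exon5")])))

  expect_equal(alternative_exons(catalog), c(2L, 3L, 4L, 5L, 10L, 23L, 31L, 32L, 33L))
  expect_equal(alternative_exons(dplyr::filter(catalog, id %in% c("h-v3", "h-v4"))),
               23L)
  expect_equal(alternative_exons(dplyr::filter(catalog, id == "h-v1")), integer(0))
})

test_that("exon architecture preserves reading frame for every cassette", {
  ex <- mybpc_exons()
  expect_equal(nrow(ex), 33)
  expect_false(anyDuplicated(ex$index) > 0)
  cass <- dplyr::filter(ex, splice_class == "cassette")
  expect_equal(cass$index, c(2L, 3L, 4L, 5L, 10L, 23L))
  expect_equal(cass$nt_length, 3L * cass$aa_length)
  expect_equal(cass$nt_length[1:4], c(33L, 39L, 36L, 33L))
  expect_equal(cass$aa_length[1:4], c(11L, 13L, 12L, 11L))
})
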