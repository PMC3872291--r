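.catalog_cols <- function() {
  c("id", "species", .splice_cols, "exon33_coding",
    "tss_truncation", "printed_mw_kda", "accession", "partial")
}

#' Load a variant catalog from a TSV file
#'
#' Reads a tab-delimited catalog (UTF-8, header row) with one record per
#' splice variant: `id`, `species` (`human`/`mouse`), the eight
#' alternatively spliced exon flags encoded `+`/`-`, `exon33_coding`
#' (`coding`/`utr_only`), `tss_truncation` (exon index of an internal
#' translation start, or `NA`), `printed_mw_kda`, `accession` and `partial`.
#' Flags are converted to logical, duplicate ids are rejected, and every
#' pattern is validated against the splice grammar (see
#' [validate_pattern()]); grammar violations abort with the offending record
#' named.
#'
#' @param path Path to the catalog TSV.
#' @return A tibble with one row per variant, classed for convenience
#'   printing.
#' @seealso [mybpc_catalog()] for the packaged catalog, [write_catalog()]
#'   for the inverse.
#' @examples
#' cat <- load_catalog(system.file("extdata", "mybpc1_catalog.tsv",
#'                                 package = "smybpc"))
#' nrow(cat)
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "NA", progress = FALSE
  )
  missing <- setdiff(.catalog_cols(), names(raw))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) return(raw[, .catalog_cols()])

  for (col in .splice_cols) {
    ok <- raw[[col]] %in% c("+", "-", "−")
    if (any(!ok)) {
      abort(paste0("malformed catalog row ", which(!ok)[1], ", column '", col,
                   "': expected '+' or '-', got '", raw[[col]][which(!ok)[1]], "'"))
    }
    raw[[col]] <- raw[[col]] == "+"
  }
  bad33 <- !raw$exon33_coding %in% c("coding", "utr_only")
  if (any(bad33)) {
    abort(paste0("malformed catalog row ", which(bad33)[1],
                 ", column 'exon33_coding': expected 'coding' or 'utr_only'"))
  }
  raw$tss_truncation <- as.integer(raw$tss_truncation)
  raw$printed_mw_kda <- as.numeric(raw$printed_mw_kda)
  raw$partial <- as.logical(raw$partial)

  if (anyDuplicated(raw$id)) {
    abort(paste0("duplicate variant id in catalog: ",
                 raw$id[duplicated(raw$id)][1]))
  }
  report <- validate_pattern(raw)
  if (any(!report$ok)) {
    bad <- report[!report$ok, ]
    abort(paste0("catalog pattern fails the splice grammar: ",
                 bad$id[1], " (", bad$check[1], ")"))
  }
  raw[, .catalog_cols()]
}

#' Write a variant catalog to a TSV file
#'
#' Inverse of [load_catalog()]: logical exon flags are encoded back to
#' `+`/`-` so that a load/write round trip reproduces the file
#' field-for-field.
#'
#' @param catalog A catalog tibble as returned by [load_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  out <- tibble::as_tibble(catalog)[, .catalog_cols()]
  for (col in .splice_cols) out[[col]] <- ifelse(out[[col]], "+", "-")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' The packaged sMyBP-C variant catalog
#'
#' The 16 full-length sMyBP-C splice variants (14 human, 2 mouse) with their
#' exon-inclusion patterns across the alternatively spliced elements
#' (Pro/Ala exons 2-5, M-motif exon 10, domain-C7 exon 23, terminal exons
#' 31-33), the reported molecular weight of each variant, and its database
#' accession. h-v012 is the internally initiated variant: translation starts
#' in the middle of exon 7, so it lacks the Pro/Ala region and the first
#' half of Ig domain C1 (`tss_truncation = 7`).
#'
#' @return A validated catalog tibble (see [load_catalog()] for columns).
#' @examples
#' mybpc_catalog()
#' @export
mybpc_catalog <- function() {
  load_catalog(system.file("extdata", "mybpc1_catalog.tsv", package = "smybpc",
                           mustWork = TRUE))
}

#' Extract one variant's inclusion pattern
#'
#' @param catalog A catalog tibble.
#' @param id Variant id, e.g. `"h-v9"`.
#' @return A one-row tibble holding that variant's splice flags.
#' @examples
#' variant_pattern(mybpc_catalog(), "h-v013")
#' @export
variant_pattern <- function(catalog, id) {
  row <- catalog[catalog$id == id, ]
  if (nrow(row) != 1) abort(paste0("variant not found in catalog: ", id))
  row
}
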