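#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Cassette elements of the MYBPC1 transcript and their coding lengths.
# Exons 2-5 (Pro/Ala region), 10 (M-motif) and 23 (domain C7) are true
# cassettes; 31 appears here because its 19 residues enter the tail
# arithmetic of resolve_tail().
.cassette_nt <- c(`2` = 33L, `3` = 39L, `4` = 36L, `5` = 33L,
                  `10` = 54L, `23` = 57L, `31` = 57L)
.cassette_aa <- c(`2` = 11L, `3` = 13L, `4` = 12L, `5` = 11L,
                  `10` = 18L, `23` = 19L, `31` = 19L)

# Alternatively spliced exon columns of a catalog/pattern tibble.
.splice_cols <- c("exon2", "exon3", "exon4", "exon5", "exon10",
                  "exon23", "exon31", "exon32")

#' Exon architecture of the MYBPC1 transcript
#'
#' One row per exon (1-33, transcript numbering), with the nucleotide and
#' residue lengths of the alternatively spliced elements, the protein region
#' each exon contributes to, and its splice class. Domain boundaries of the
#' constitutive exons are approximate (the catalog models no genomic
#' coordinates); the placements that carry analysis weight are exact:
#' exons 2-5 in the Pro/Ala rich region, exon 10 in the M-motif, exon 23 in
#' FnIII domain C7, and exons 31-33 in the COOH-terminal tail.
#'
#' @return A tibble with columns `index`, `nt_length`, `aa_length`
#'   (`NA` for constitutive exons, whose lengths the catalog does not model),
#'   `region` and `splice_class`.
#' @examples
#' mybpc_exons()
#' @export
mybpc_exons <- function() {
  region <- c(
    "UTR5",                       # 1
    rep("ProAla", 4),             # 2-5
    "C1", "C1",                   # 6-7 (an internal start in exon 7 removes
                                  #      the Pro/Ala region and half of C1)
    "M-motif", "M-motif", "M-motif", # 8-10
    "C2", "C2",                   # 11-12
    "C3", "C3",                   # 13-14
    "C4", "C4",                   # 15-16
    "C5", "C5",                   # 17-18
    "C6", "C6",                   # 19-20
    "C7", "C7", "C7",             # 21-23
    "C8", "C8",                   # 24-25
    "C9", "C9", "C9",             # 26-28
    "C10", "C10",                 # 29-30
    "tail", "tail", "tail"        # 31-33 (33 doubles as 3'UTR)
  )
  splice_class <- rep("constitutive", 33)
  splice_class[c(2:5, 10, 23)] <- "cassette"
  splice_class[31:33] <- "alternate_terminal"
  idx <- as.character(1:33)
  tibble::tibble(
    index = 1:33,
    nt_length = unname(.cassette_nt[idx]),
    aa_length = unname(.cassette_aa[idx]),
    region = region,
    splice_class = splice_class
  )
}

# Normalize a pattern-like object (one-row data frame or named list with
# logical exon flags) to a one-row tibble. "+"/"-" strings are accepted.
as_pattern <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("a pattern must be a single row")
    p <- tibble::as_tibble(x)
  } else if (is.list(x)) {
    p <- tibble::as_tibble(x[!vapply(x, is.null, logical(1))])
  } else {
    abort("a pattern must be a one-row data frame or a named list")
  }
  missing <- setdiff(.splice_cols, names(p))
  if (length(missing) > 0) {
    abort(paste0("pattern is missing flags: ", paste(missing, collapse = ", ")))
  }
  for (col in .splice_cols) p[[col]] <- parse_flag(p[[col]], col)
  if (is.null(p$exon33_coding)) {
    # Table-2 default: exon 33 carries coding sequence only when exon 32 is out
    p$exon33_coding <- ifelse(p$exon32, "utr_only", "coding")
  }
  if (is.null(p$tss_truncation)) p$tss_truncation <- NA_integer_
  p$tss_truncation <- as.integer(p$tss_truncation)
  p
}

parse_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.character(x)) {
    x <- trimws(x)
    bad <- !x %in% c("+", "-", "−") # tolerate typeset minus
    if (any(bad)) {
      abort(paste0("column '", col, "': flags must be '+' or '-', got '",
                   x[which(bad)[1]], "' (row ", which(bad)[1], ")"))
    }
    return(x == "+")
  }
  abort(paste0("column '", col, "' must be logical or '+'/'-'"))
}

#' Resolve the COOH-terminal tail from the exon 31/32 splice state
#'
#' The residues following Ig domain C10 are determined entirely by which of
#' exons 31 and 32 survive splicing. The four legal states are: both retained
#' (19 residues from exon 31 plus 7 from exon 32, stop codon in exon 32);
#' only 31 (its 19 residues plus 16 read into exon 33, stop in exon 33);
#' only 32 (3 residues, stop in exon 32); neither (exon 33 alone encodes
#' 33 residues and the stop). Exon 33 therefore carries coding sequence
#' exactly when exon 32 is spliced out.
#'
#' @param exon31,exon32 Logical vectors (recycled to common length): is the
#'   exon retained?
#' @return A tibble with one row per input state: `exon31`, `exon32`,
#'   `aa_after_C10` (residues past C10), `stop_exon` (31/32/33),
#'   `contributing_exons` (comma-joined coding exon indices) and
#'   `exon33_coding`.
#' @examples
#' resolve_tail(exon31 = FALSE, exon32 = FALSE) # the h-v10 tail: 33 residues
#' resolve_tail(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
resolve_tail <- function(exon31, exon32) {
  n <- max(length(exon31), length(exon32))
  exon31 <- rep_len(as.logical(exon31), n)
  exon32 <- rep_len(as.logical(exon32), n)
  state <- 2L * exon31 + exon32 + 1L # 1:(-,-) 2:(-,+) 3:(+,-) 4:(+,+)
  tibble::tibble(
    exon31 = exon31,
    exon32 = exon32,
    aa_after_C10 = c(33L, 3L, 35L, 26L)[state],
    stop_exon = c(33L, 32L, 33L, 32L)[state],
    contributing_exons = c("33", "32", "31,33", "31,32")[state],
    exon33_coding = c("coding", "utr_only", "coding", "utr_only")[state]
  )
}

#' Validate inclusion patterns against the splice grammar
#'
#' Checks each record of a catalog-shaped tibble against the rules the
#' transcript architecture imposes: every cassette exon's nucleotide length
#' is three times its residue length (reading frame preserved), exon 33
#' carries coding sequence if and only if exon 32 is spliced out, and an
#' internal translation start (`tss_truncation`), when present, names a
#' legal exon and has all upstream cassette flags absent. Content failures
#' are reported, never raised.
#'
#' @param catalog A tibble with the alternatively spliced exon flags
#'   (logical), `exon33_coding`, `tss_truncation`, and optionally `id`.
#' @return A tibble with columns `id`, `check`, `ok`, `detail`; one row per
#'   record per check.
#' @examples
#' validate_pattern(mybpc_catalog())
#' @export
validate_pattern <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  if (!"id" %in% names(catalog)) {
    catalog$id <- paste0("pattern", seq_len(nrow(catalog)))
  }
  if (!"exon33_coding" %in% names(catalog)) catalog$exon33_coding <- NA_character_
  if (!"tss_truncation" %in% names(catalog)) catalog$tss_truncation <- NA_integer_

  frame_ok <- all(.cassette_nt == 3L * .cassette_aa)
  purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    tss <- row$tss_truncation
    stop33 <- identical(row$exon33_coding, "coding") == !isTRUE(row$exon32)
    tss_legal <- is.na(tss) || (tss >= 2 && tss <= 33)
    upstream <- intersect(as.integer(sub("exon", "", .splice_cols)),
                          if (is.na(tss)) integer(0) else seq_len(tss - 1L))
    tss_masked <- is.na(tss) ||
      !any(vapply(paste0("exon", upstream), function(c) isTRUE(row[[c]]),
                  logical(1)))
    tibble::tibble(
      id = rep(row$id, 3),
      check = c("cassette_frame", "exon33_stop_rule", "tss_truncation"),
      ok = c(frame_ok, stop33, tss_legal && tss_masked),
      detail = c(
        "nt_length = 3 x aa_length for every cassette exon",
        "exon 33 codes iff exon 32 is spliced out",
        if (is.na(tss)) "no internal start" else
          paste0("internal start in exon ", tss,
                 "; upstream cassettes must be absent")
      )
    )
  })
}

#' Distinct NH2-terminal exon 2-5 combinations
#'
#' Counts the distinct (exon2, exon3, exon4, exon5) inclusion tuples across
#' the human full-length variants that possess a Pro/Ala region. Records
#' with an internal translation start (which removes the Pro/Ala region
#' altogether), mouse records and partial records are excluded. The packaged
#' catalog yields 7 combinations.
#'
#' @param catalog A variant catalog tibble (see [mybpc_catalog()]).
#' @return A tibble of distinct tuples with columns `exon2`-`exon5` and
#'   `variants` (comma-joined member ids).
#' @examples
#' nterm_combination_set(mybpc_catalog())
#' @export
nterm_combination_set <- function(catalog) {
  catalog %>%
    dplyr::filter(.data$species == "human", !.data$partial,
                  is.na(.data$tss_truncation)) %>%
    dplyr::group_by(.data$exon2, .data$exon3, .data$exon4, .data$exon5) %>%
    dplyr::summarise(variants = paste(.data$id, collapse = ","),
                     .groups = "drop")
}

#' Alternatively spliced exons observed in a catalog
#'
#' Scans the human full-length records column-wise and returns the exon
#' indices whose coding status varies: the cassette exons 2-5, 10 and 23,
#' the terminal exons 31 and 32, and exon 33 (whose coding/UTR-only toggle
#' counts as variation). Exons masked by an internal translation start are
#' not counted as spliced for that record, so h-v012 does not inflate the
#' set. The packaged catalog yields nine exons.
#'
#' @param catalog A variant catalog tibble.
#' @return Sorted integer vector of exon indices.
#' @examples
#' alternative_exons(mybpc_catalog())
#' @export
alternative_exons <- function(catalog) {
  hum <- catalog %>%
    dplyr::filter(.data$species == "human", !.data$partial)
  if (nrow(hum) < 2) return(integer(0))
  out <- integer(0)
  for (col in .splice_cols) {
    ex <- as.integer(sub("exon", "", col))
    vals <- hum[[col]]
    # a record whose translation starts downstream of this exon says nothing
    # about its splicing
    keep <- is.na(hum$tss_truncation) | hum$tss_truncation <= ex
    if (dplyr::n_distinct(vals[keep]) > 1) out <- c(out, ex)
  }
  if (dplyr::n_distinct(hum$exon33_coding) > 1) out <- c(out, 33L)
  sort(out)
}
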