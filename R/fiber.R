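#' Tally variant-group expression patterns across fibers
#'
#' One tally per distinct group combination (pattern key, e.g. `"1,6"`),
#' with the fiber count and the percentage of the muscle's fibers (rounded
#' half-away-from-zero to integers, matching how the published frequencies
#' are reported). Counts always sum to the number of fibers tallied.
#'
#' @param fibers A fiber tibble with columns `fiber_id`, `muscle`, `groups`
#'   (pattern key).
#' @param muscle Optional muscle to restrict to; if `NULL`, all fibers must
#'   come from a single muscle.
#' @return A tibble with columns `groups`, `n_groups`, `count`, `percent`,
#'   ordered by count (descending) then pattern key.
#' @examples
#' fx <- generate_fixture(frequency_preset("fdb"))
#' tally_patterns(fx$fibers)
#' @export
tally_patterns <- function(fibers, muscle = NULL) {
  fibers <- tibble::as_tibble(fibers)
  if (!is.null(muscle)) {
    fibers <- dplyr::filter(fibers, .data$muscle == !!muscle)
  } else if (dplyr::n_distinct(fibers$muscle) > 1) {
    abort("fibers span multiple muscles; pass `muscle` to select one")
  }
  if (nrow(fibers) == 0) {
    return(tibble::tibble(groups = character(0), n_groups = integer(0),
                          count = integer(0), percent = numeric(0)))
  }
  n <- nrow(fibers)
  fibers %>%
    dplyr::count(.data$groups, name = "count") %>%
    dplyr::mutate(
      n_groups = key_size(.data$groups),
      percent = round_half_away(100 * .data$count / n)
    ) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$groups) %>%
    dplyr::select("groups", "n_groups", "count", "percent")
}

#' Distribution of group multiplicity per fiber
#'
#' Percentage of fibers expressing variants from one, two or three
#' molecular-weight groups. Integer percentages are reconciled to sum to
#' exactly 100 by the largest-remainder method (the raw shares rarely round
#' to a clean 100).
#'
#' @param fibers A fiber tibble (single muscle).
#' @return A tibble with columns `n_groups` (1, 2, 3), `count`, `percent`
#'   and `raw_percent` (unrounded).
#' @examples
#' fx <- generate_fixture(frequency_preset("soleus"))
#' multiplicity_distribution(fx$fibers)
#' @export
multiplicity_distribution <- function(fibers) {
  fibers <- tibble::as_tibble(fibers)
  n <- nrow(fibers)
  k <- key_size(fibers$groups)
  counts <- vapply(1:3, function(i) sum(k == i), integer(1))
  raw <- 100 * counts / n
  tibble::tibble(
    n_groups = 1:3,
    count = counts,
    percent = largest_remainder(counts, 100L),
    raw_percent = raw
  )
}

#' Per-group occurrence across fibers
#'
#' For each molecular-weight group, the percentage of fibers whose pattern
#' contains that group. Because fibers co-express groups, the column can sum
#' to more than 100.
#'
#' @param fibers A fiber tibble (single muscle).
#' @param groups Integer vector of group indices to report (default 1-6).
#' @return A tibble with columns `group`, `count`, `percent` (unrounded).
#' @examples
#' fx <- generate_fixture(frequency_preset("fdb"))
#' group_occurrence(fx$fibers)
#' @export
group_occurrence <- function(fibers, groups = 1:6) {
  fibers <- tibble::as_tibble(fibers)
  n <- nrow(fibers)
  sets <- key_groups(fibers$groups)
  counts <- vapply(groups, function(g) {
    sum(vapply(sets, function(s) g %in% s, logical(1)))
  }, integer(1))
  tibble::tibble(group = groups, count = counts,
                 percent = if (n > 0) 100 * counts / n else rep(0, length(groups)))
}

#' Reference myosin-isoform complements per expression pattern
#'
#' Transcription of the published correlation table between sMyBP-C
#' expression patterns and myosin heavy-chain complements in soleus and FDB
#' fibers. Patterns not observed in a muscle are absent (the published table
#' marks them NA).
#'
#' @return A tibble with columns `muscle`, `groups` (pattern key), `myosin`
#'   (comma-joined isoforms).
#' @examples
#' myosin_reference()
#' @export
myosin_reference <- function() {
  tibble::tribble(
    ~muscle,  ~groups,  ~myosin,
    "soleus", "1",      "I",
    "soleus", "2",      "I",
    "soleus", "3",      "I",
    "soleus", "4",      "I",
    "soleus", "1,5",    "I",
    "soleus", "1,6",    "I,IIa",
    "soleus", "2,6",    "I,IIa",
    "soleus", "3,6",    "I,IIa",
    "soleus", "4,6",    "I,IIa",
    "soleus", "5,6",    "I,IIa",
    "soleus", "4,5",    "I",
    "soleus", "1,2,6",  "I",
    "soleus", "1,3,6",  "I",
    "fdb",    "1",      "I,IIx",
    "fdb",    "2",      "I,IIa",
    "fdb",    "3",      "I,IIx",
    "fdb",    "4",      "I,IIa,IIx",
    "fdb",    "5",      "IIa"
  )
}

#' Associate expression patterns with observed myosin complements
#'
#' Tallies, for each expression pattern, the myosin-isoform complements
#' observed across fibers, and checks each (pattern, myosin) pair against
#' the published reference table ([myosin_reference()]). Fibers without
#' myosin labels (unstained lanes) are excluded and their number reported
#' in the `n_unlabeled` attribute.
#'
#' @param fibers A fiber tibble with a `myosin` column (comma-joined
#'   isoform labels, `""` or `NA` when unstained).
#' @param reference Reference table; rows are matched on `muscle`, pattern
#'   and myosin complement.
#' @return A tibble with columns `muscle`, `groups`, `myosin`, `count`,
#'   `expected_myosin` (from the reference, `NA` if the pattern has no
#'   reference row for this muscle) and `match`.
#' @examples
#' fx <- generate_fixture(frequency_preset("fdb"))
#' myosin_association(fx$fibers)
#' @export
myosin_association <- function(fibers, reference = myosin_reference()) {
  fibers <- tibble::as_tibble(fibers)
  labeled <- fibers %>%
    dplyr::filter(!is.na(.data$myosin), .data$myosin != "")
  n_unlabeled <- nrow(fibers) - nrow(labeled)
  out <- labeled %>%
    dplyr::count(.data$muscle, .data$groups, .data$myosin, name = "count") %>%
    dplyr::left_join(
      dplyr::rename(reference, expected_myosin = "myosin"),
      by = c("muscle", "groups")
    ) %>%
    dplyr::mutate(match = !is.na(.data$expected_myosin) &
                    .data$myosin == .data$expected_myosin)
  attr(out, "n_unlabeled") <- n_unlabeled
  out
}
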