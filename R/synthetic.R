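# Default simulated gel geometry: 6 markers at 250/150/125/100/75/50 kDa
# bracketing the 115-132 kDa analysis window, placed log-linearly with the
# 250 kDa marker at the well (rf 0) and the 50 kDa marker at the dye front
# (rf 1). This is the flattest legal gel for that ladder: log10(250/50)
# decades spread over the full unit rf range.
.default_intercept <- log10(250)
.default_slope <- -log10(5)

rf_for_mass <- function(mass_kda) {
  (log10(mass_kda) - .default_intercept) / .default_slope
}

#' Default simulated marker ladder
#'
#' @return A ladder tibble (`mass_kda`, `rf`) of six markers at 250, 150,
#'   125, 100, 75 and 50 kDa on the default log-linear gel.
#' @examples
#' default_ladder()
#' @export
default_ladder <- function() {
  m <- c(250, 150, 125, 100, 75, 50)
  tibble::tibble(mass_kda = m, rf = rf_for_mass(m))
}

#' Published single-fiber frequency presets
#'
#' The two single-fiber datasets reconstructed from their published pattern
#' frequencies. `"soleus"`: 48 fibers over 13 patterns - singles of groups
#' 1-4 (4/10/4/2%), group-5 pairs 1+5, 4+5 (2/2%), group-6 pairs 1+6, 2+6,
#' 3+6, 4+6, 5+6 (40/12/6/4/6%) and triples 1+2+6, 1+3+6 (2/4%). `"fdb"`:
#' 41 fibers, all single-group, groups 1-5 at 39/32/17/7/5%. Each pattern
#' carries the myosin complement reported for it; for the two soleus
#' single-group patterns where the published table and the published
#' percentages disagree ({2} and {3}), the preset follows the percentages
#' (myosin I+IIa), and [myosin_association()] flags the table rows as
#' mismatches.
#'
#' @param muscle `"soleus"` or `"fdb"`.
#' @return A `frequency_preset`: list with `muscle`, `n_fibers` and a
#'   `patterns` tibble (`groups`, `percent`, `myosin`).
#' @examples
#' frequency_preset("fdb")
#' @export
frequency_preset <- function(muscle = c("soleus", "fdb")) {
  muscle <- match.arg(muscle)
  patterns <- if (muscle == "soleus") {
    tibble::tribble(
      ~groups,  ~percent, ~myosin,
      "1",      4,        "I",
      "2",      10,       "I,IIa",
      "3",      4,        "I,IIa",
      "4",      2,        "I",
      "1,5",    2,        "I",
      "4,5",    2,        "I",
      "1,6",    40,       "I,IIa",
      "2,6",    12,       "I,IIa",
      "3,6",    6,        "I,IIa",
      "4,6",    4,        "I,IIa",
      "5,6",    6,        "I,IIa",
      "1,2,6",  2,        "I",
      "1,3,6",  4,        "I"
    )
  } else {
    tibble::tribble(
      ~groups, ~percent, ~myosin,
      "1",     39,       "I,IIx",
      "2",     32,       "I,IIa",
      "3",     17,       "I,IIx",
      "4",     7,        "I,IIa,IIx",
      "5",     5,        "IIa"
    )
  }
  structure(
    list(muscle = muscle,
         n_fibers = if (muscle == "soleus") 48L else 41L,
         patterns = patterns),
    class = "frequency_preset"
  )
}

#' @export
print.frequency_preset <- function(x, ...) {
  cat("<frequency_preset>", x$muscle, "-", x$n_fibers, "fibers,",
      nrow(x$patterns), "patterns\n")
  print(x$patterns)
  invisible(x)
}

#' Optimal integer fiber counts for a frequency preset
#'
#' The published pattern frequencies are rounded "~" percentages; this
#' solver finds the integer count vector summing exactly to `n_fibers` that
#' minimizes the maximum absolute deviation between the realized percentages
#' (`100 * count / n`) and the printed ones, breaking ties by minimum total
#' (L1) deviation and then by lexicographically smallest count vector in
#' pattern order. Solved exactly by dynamic programming over
#' (pattern, remaining fibers); with at most ~50 fibers the state space is
#' tiny, so the optimum is certified, not heuristic.
#'
#' @param preset A [frequency_preset()].
#' @return The preset's `patterns` tibble with `count` and
#'   `achieved_percent` columns appended; attribute `max_deviation` holds
#'   the optimal deviation in percentage points.
#' @examples
#' solve_integer_counts(frequency_preset("fdb")) # counts 16, 13, 7, 3, 2
#' @export
solve_integer_counts <- function(preset) {
  pat <- preset$patterns
  n <- preset$n_fibers
  k <- nrow(pat)
  if (k == 0) {
    if (n > 0) abort(paste0("infeasible preset: ", n,
                            " fibers but no patterns to receive them"))
    return(dplyr::mutate(pat, count = integer(0), achieved_percent = numeric(0)))
  }
  p <- pat$percent
  dev <- function(i, c) abs(100 * c / n - p[i])

  # f_max[i, r+1], f_l1[i, r+1]: best (max deviation, L1 deviation) over
  # counts for patterns i..k summing exactly to r
  f_max <- matrix(Inf, nrow = k + 1, ncol = n + 1)
  f_l1 <- matrix(Inf, nrow = k + 1, ncol = n + 1)
  f_max[k + 1, 1] <- 0
  f_l1[k + 1, 1] <- 0
  for (i in k:1) {
    d_i <- dev(i, 0:n)
    for (r in 0:n) {
      cs <- 0:r
      cand_max <- pmax(d_i[cs + 1], f_max[i + 1, r - cs + 1])
      cand_l1 <- d_i[cs + 1] + f_l1[i + 1, r - cs + 1]
      best <- min(cand_max)
      ok <- cand_max == best
      f_max[i, r + 1] <- best
      f_l1[i, r + 1] <- min(cand_l1[ok])
    }
  }
  # forward reconstruction, preferring the smallest count at each pattern
  counts <- integer(k)
  r <- n
  for (i in seq_len(k)) {
    d_i <- dev(i, 0:r)
    cand_max <- pmax(d_i, f_max[i + 1, r - (0:r) + 1])
    cand_l1 <- d_i + f_l1[i + 1, r - (0:r) + 1]
    ok <- which(cand_max <= f_max[i, r + 1] + 1e-9 &
                  cand_l1 <= f_l1[i, r + 1] + 1e-9)
    counts[i] <- ok[1] - 1L
    r <- r - counts[i]
  }
  out <- pat %>%
    dplyr::mutate(count = counts, achieved_percent = 100 * counts / n)
  attr(out, "max_deviation") <- max(abs(out$achieved_percent - out$percent))
  out
}

#' Deterministic reconstruction of a published single-fiber dataset
#'
#' Builds, with no randomness, the fiber table, per-lane band table and
#' ladder a gel of the preset would produce: one lane per fiber, counts
#' from [solve_integer_counts()], one noiseless band per expressed group at
#' exactly the rf corresponding to the group's center mass on the default
#' curve, and the preset's myosin complement per fiber. Running the band
#' table back through [fit_standard_curve()]/[assign_bands()] recovers the
#' generating patterns exactly.
#'
#' @param preset A [frequency_preset()].
#' @param groups Group table supplying center masses.
#' @return A list of class `gel_dataset`: `fibers` (fiber_id, muscle,
#'   groups, myosin), `bands` (lane_id, band_index, rf), `ladder`, `truth`
#'   (fiber_id, groups, myosin, masses).
#' @examples
#' fx <- generate_fixture(frequency_preset("fdb"))
#' nrow(fx$fibers)
#' @export
generate_fixture <- function(preset, groups = mw_groups()) {
  counts <- solve_integer_counts(preset)
  attr(counts, "max_deviation") <- NULL
  fibers <- counts %>%
    dplyr::mutate(.pat = dplyr::row_number()) %>%
    tidyr::uncount(.data$count) %>%
    dplyr::mutate(
      fiber_id = sprintf("%s_%02d", preset$muscle, dplyr::row_number()),
      muscle = preset$muscle,
      n_groups = key_size(.data$groups)
    ) %>%
    dplyr::select("fiber_id", "muscle", "groups", "n_groups", "myosin")

  centers <- stats::setNames(groups$center, groups$group)
  bands <- fibers %>%
    dplyr::mutate(group = key_groups(.data$groups)) %>%
    dplyr::select(lane_id = "fiber_id", "group") %>%
    tidyr::unnest("group") %>%
    dplyr::mutate(mass_kda = unname(centers[as.character(.data$group)]),
                  rf = rf_for_mass(.data$mass_kda)) %>%
    dplyr::arrange(.data$lane_id, .data$rf) %>%
    dplyr::group_by(.data$lane_id) %>%
    dplyr::mutate(band_index = dplyr::row_number()) %>%
    dplyr::ungroup()

  structure(
    list(
      fibers = fibers,
      bands = dplyr::select(bands, "lane_id", "band_index", "rf"),
      ladder = default_ladder(),
      truth = dplyr::select(bands, fiber_id = "lane_id", "group",
                            true_mass_kda = "mass_kda")
    ),
    class = "gel_dataset"
  )
}

#' Simulate a noisy single-fiber gel with ground truth
#'
#' Samples `n_fibers` fibers from the preset's count-normalized pattern
#' frequencies, then migrates one band per expressed group at the rf of the
#' group's center mass plus Gaussian rf noise. Marker lanes are emitted at
#' their exact rf. A fixed seed makes the output fully reproducible.
#'
#' @param preset A [frequency_preset()].
#' @param n_fibers Number of fibers to simulate (default: the preset's).
#' @param rf_noise_sd Standard deviation of the Gaussian rf migration noise
#'   (default 0.002; on the default gel this corresponds to ~0.4 kDa of
#'   sizing noise at 128 kDa).
#' @param seed Integer seed; same seed, same output.
#' @param groups Group table supplying center masses.
#' @return A `gel_dataset` (see [generate_fixture()]).
#' @examples
#' sim <- simulate_gel(frequency_preset("soleus"), n_fibers = 100, seed = 1)
#' head(sim$bands)
#' @export
simulate_gel <- function(preset, n_fibers = preset$n_fibers,
                         rf_noise_sd = 0.002, seed = 1,
                         groups = mw_groups()) {
  if (rf_noise_sd < 0) abort("rf_noise_sd must be non-negative")
  counts <- solve_integer_counts(preset)
  set.seed(seed)
  draw <- sample.int(nrow(counts), n_fibers, replace = TRUE,
                     prob = counts$count / sum(counts$count))
  fibers <- counts[draw, c("groups", "myosin")] %>%
    dplyr::mutate(
      fiber_id = sprintf("%s_sim_%04d", preset$muscle, dplyr::row_number()),
      muscle = preset$muscle,
      n_groups = key_size(.data$groups)
    ) %>%
    dplyr::select("fiber_id", "muscle", "groups", "n_groups", "myosin")

  centers <- stats::setNames(groups$center, groups$group)
  bands <- fibers %>%
    dplyr::mutate(group = key_groups(.data$groups)) %>%
    dplyr::select(lane_id = "fiber_id", "group") %>%
    tidyr::unnest("group") %>%
    dplyr::mutate(
      true_mass_kda = unname(centers[as.character(.data$group)]),
      rf = rf_for_mass(.data$true_mass_kda) +
        stats::rnorm(dplyr::n(), 0, rf_noise_sd)
    ) %>%
    dplyr::arrange(.data$lane_id, .data$rf) %>%
    dplyr::group_by(.data$lane_id) %>%
    dplyr::mutate(band_index = dplyr::row_number()) %>%
    dplyr::ungroup()

  structure(
    list(
      fibers = fibers,
      bands = dplyr::select(bands, "lane_id", "band_index", "rf"),
      ladder = default_ladder(),
      truth = dplyr::select(bands, fiber_id = "lane_id", "group",
                            "true_mass_kda", "rf")
    ),
    class = "gel_dataset"
  )
}

#' @export
print.gel_dataset <- function(x, ...) {
  cat("<gel_dataset>", nrow(x$fibers), "fibers,", nrow(x$bands), "bands,",
      nrow(x$ladder), "ladder markers\n")
  invisible(x)
}

#' Run the full gel pipeline on a dataset
#'
#' Fits the standard curve on the dataset's ladder, sizes and assigns every
#' band, and collapses lanes to per-fiber group sets, carrying each fiber's
#' myosin labels over from the dataset. This is the one-call version of the
#' published workflow: blot -> band table -> sized bands -> group patterns.
#'
#' @param dataset A `gel_dataset` from [generate_fixture()] or
#'   [simulate_gel()], or a list with `bands`, `ladder` and optionally
#'   `fibers`.
#' @param groups Group table from [mw_groups()].
#' @param ... Passed to [assign_bands()].
#' @return A fiber tibble (`fiber_id`, `muscle`, `groups`, `n_groups`,
#'   `myosin`) as recovered from the bands alone.
#' @examples
#' fx <- generate_fixture(frequency_preset("fdb"))
#' recovered <- profile_gel(fx)
#' tally_patterns(recovered)
#' @export
profile_gel <- function(dataset, groups = mw_groups(), ...) {
  curve <- fit_standard_curve(dataset$ladder)
  asg <- assign_bands(dataset$bands, curve, groups = groups, ...)
  muscle <- if (!is.null(dataset$fibers)) dataset$fibers$muscle[1] else
    NA_character_
  out <- lanes_to_fibers(asg, muscle = muscle)
  if (!is.null(dataset$fibers) && "myosin" %in% names(dataset$fibers)) {
    out <- dplyr::left_join(
      out, dplyr::select(dataset$fibers, "fiber_id", "myosin"),
      by = "fiber_id"
    )
  }
  out
}
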