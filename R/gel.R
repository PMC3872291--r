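#' Fit a semilog standard curve to a marker ladder
#'
#' Ordinary least squares of `log10(mass) ~ rf` over the ladder markers,
#' the standard sizing model for SDS-PAGE: over the narrow 115-132 kDa
#' window the bands of interest occupy, migration is log-linear. Rf is the
#' migration distance normalized to the dye front (0 at the well, 1 at the
#' front), so the fitted slope must be negative.
#'
#' @param ladder A tibble with columns `mass_kda` and `rf`, at least three
#'   markers, strictly monotone (rf increases as mass decreases).
#' @return A `standard_curve` object: slope, intercept, `r2`, the
#'   calibrated rf range, and a per-marker residual table (see
#'   [generics::tidy()]).
#' @examples
#' fit_standard_curve(default_ladder())
#' @export
fit_standard_curve <- function(ladder) {
  ladder <- tibble::as_tibble(ladder)
  if (!all(c("mass_kda", "rf") %in% names(ladder))) {
    abort("ladder needs columns 'mass_kda' and 'rf'")
  }
  if (nrow(ladder) < 3) {
    abort("insufficient calibration: a ladder needs at least 3 markers")
  }
  ord <- order(ladder$rf)
  if (any(diff(ladder$rf[ord]) <= 0) || any(diff(ladder$mass_kda[ord]) >= 0)) {
    abort("ladder is not monotone: mass must strictly decrease as rf increases")
  }
  fit <- stats::lm(log10(mass_kda) ~ rf, data = ladder)
  markers <- ladder %>%
    dplyr::mutate(
      fitted_mass_kda = unname(10^stats::fitted(fit)),
      residual_log10 = unname(stats::residuals(fit))
    )
  y <- log10(ladder$mass_kda)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = r2,
      rf_range = range(ladder$rf),
      markers = markers
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> log10(kDa) =", signif(x$intercept, 5), "+",
      signif(x$slope, 5), "x rf  (R2 =", signif(x$r2, 5), ",",
      nrow(x$markers), "markers)\n")
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) x$markers

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, fit_r2 = x$r2,
                 n_markers = nrow(x$markers))
}

#' Estimate band mass from relative migration
#'
#' Inverts the standard curve: `10^(intercept + slope * rf)`. Strictly
#' decreasing in rf. Rf values outside the calibrated marker range by more
#' than `extrapolation_margin` trigger a warning (the estimate is still
#' returned).
#'
#' @param curve A fitted [fit_standard_curve()] object.
#' @param rf Numeric vector of relative migrations in `[0, 1]`.
#' @param extrapolation_margin Allowed rf excursion beyond the marker range
#'   before a warning is raised.
#' @return Numeric vector of masses in kDa.
#' @examples
#' curve <- fit_standard_curve(default_ladder())
#' estimate_mass(curve, 0.43)
#' @export
estimate_mass <- function(curve, rf, extrapolation_margin = 0.05) {
  outside <- rf < curve$rf_range[1] - extrapolation_margin |
    rf > curve$rf_range[2] + extrapolation_margin
  if (any(outside)) {
    warn(paste0(sum(outside), " rf value(s) fall outside the calibrated range [",
                signif(curve$rf_range[1], 3), ", ", signif(curve$rf_range[2], 3),
                "] + margin; extrapolated sizes are unreliable"))
  }
  10^(curve$intercept + curve$slope * rf)
}

#' Size immunoreactive bands and assign them to molecular-weight groups
#'
#' The per-lane pipeline used on single-fiber blots: each band's rf is
#' converted to a mass on the standard curve; bands within a lane that size
#' to within `merge_within` of each other are merged (below the resolving
#' power of the gel; the merged band takes the mean rf); each surviving band
#' is assigned to the nearest molecular-weight group via [assign_group()];
#' results are ordered by estimated mass (descending) within lane and
#' duplicate group hits in a lane are collapsed to one row. Lanes are
#' processed independently - no cross-lane normalization.
#'
#' @param bands A tibble with columns `lane_id` and `rf` (a `band_index`
#'   column is accepted and ignored).
#' @param curve A fitted [fit_standard_curve()] object.
#' @param groups Group table from [mw_groups()].
#' @param tolerance,margin Passed to [assign_group()].
#' @param merge_within Mass resolution floor in kDa (default 0.25, half the
#'   0.5 kDa precision of the reported variant masses).
#' @return A tibble with columns `lane_id`, `rf`, `estimated_mass_kda`,
#'   `group`, `ambiguous`, `candidates`.
#' @examples
#' curve <- fit_standard_curve(default_ladder())
#' bands <- tibble::tibble(lane_id = "f1", rf = c(0.401, 0.480))
#' assign_bands(bands, curve)
#' @export
assign_bands <- function(bands, curve, groups = mw_groups(), tolerance = 1.5,
                         margin = 0.5, merge_within = 0.25) {
  bands <- tibble::as_tibble(bands)
  if (nrow(bands) == 0) {
    return(tibble::tibble(lane_id = character(0), rf = numeric(0),
                          estimated_mass_kda = numeric(0), group = integer(0),
                          ambiguous = logical(0), candidates = character(0)))
  }
  sized <- bands %>%
    dplyr::mutate(estimated_mass_kda = estimate_mass(curve, .data$rf)) %>%
    dplyr::arrange(.data$lane_id, dplyr::desc(.data$estimated_mass_kda)) %>%
    dplyr::group_by(.data$lane_id) %>%
    # successive bands closer than the resolution floor collapse into one
    dplyr::mutate(
      cluster = cumsum(c(1, diff(-.data$estimated_mass_kda) >= merge_within))
    ) %>%
    dplyr::group_by(.data$lane_id, .data$cluster) %>%
    dplyr::summarise(rf = mean(.data$rf), .groups = "drop") %>%
    dplyr::mutate(estimated_mass_kda = estimate_mass(curve, .data$rf))

  asg <- assign_group(sized$estimated_mass_kda, groups = groups,
                      tolerance = tolerance, margin = margin)
  sized %>%
    dplyr::mutate(group = asg$group, ambiguous = asg$ambiguous,
                  candidates = asg$candidates) %>%
    dplyr::arrange(.data$lane_id, dplyr::desc(.data$estimated_mass_kda)) %>%
    dplyr::distinct(.data$lane_id, .data$group, .keep_all = TRUE) %>%
    dplyr::select("lane_id", "rf", "estimated_mass_kda", "group",
                  "ambiguous", "candidates")
}

#' Collapse band assignments into per-fiber group sets
#'
#' Turns the output of [assign_bands()] into one record per fiber (lane):
#' the sorted set of assigned groups as a pattern key such as `"1,6"`.
#' Unassigned bands (`NA` group) are dropped; lanes with no assigned band
#' are dropped from the result (fibers without signal are excluded from all
#' denominators).
#'
#' @param assignments Output of [assign_bands()].
#' @param muscle Muscle label to attach (`"soleus"` or `"FDB"`), or `NA`.
#' @return A fiber tibble with columns `fiber_id`, `muscle`, `groups`
#'   (pattern key) and `n_groups`.
#' @examples
#' curve <- fit_standard_curve(default_ladder())
#' bands <- tibble::tibble(lane_id = "f1", rf = c(0.401, 0.480))
#' lanes_to_fibers(assign_bands(bands, curve), muscle = "soleus")
#' @export
lanes_to_fibers <- function(assignments, muscle = NA_character_) {
  assignments %>%
    dplyr::filter(!is.na(.data$group)) %>%
    dplyr::group_by(fiber_id = .data$lane_id) %>%
    dplyr::summarise(groups = pattern_key(list(.data$group)),
                     .groups = "drop") %>%
    dplyr::mutate(muscle = muscle, n_groups = key_size(.data$groups)) %>%
    dplyr::select("fiber_id", "muscle", "groups", "n_groups")
}
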