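#' Construct a delta-mass model
#'
#' Variant molecular weights are predicted relative to an anchor variant:
#' `predicted = anchor_mass + delta_aa(pattern, anchor) * mean_residue_mass`,
#' rounded half-away-from-zero to `rounding_step`. The default anchor is
#' h-v9 (126 kDa), the variant lacking all four NH2-terminal cassettes,
#' which keeps the residue deltas to the other variants free of uncertain
#' terms; 0.110 kDa is the textbook average residue mass and 0.5 kDa matches
#' the precision at which the catalog masses are reported.
#'
#' @param anchor_id Variant id of the anchor (must exist in the catalog used
#'   for prediction).
#' @param anchor_mass Anchor mass in kDa.
#' @param mean_residue_mass kDa per residue, constrained to [0.100, 0.120].
#' @param rounding_step Positive rounding increment in kDa.
#' @return An object of class `mass_model`.
#' @examples
#' mass_model()
#' @export
mass_model <- function(anchor_id = "h-v9", anchor_mass = 126,
                       mean_residue_mass = 0.110, rounding_step = 0.5) {
  if (mean_residue_mass < 0.100 || mean_residue_mass > 0.120) {
    abort("mean_residue_mass must lie in [0.100, 0.120] kDa")
  }
  if (rounding_step <= 0) abort("rounding_step must be positive")
  structure(
    list(anchor_id = anchor_id, anchor_mass = anchor_mass,
         mean_residue_mass = mean_residue_mass, rounding_step = rounding_step),
    class = "mass_model"
  )
}

#' @export
print.mass_model <- function(x, ...) {
  cat("<mass_model> anchor", x$anchor_id, "@", x$anchor_mass, "kDa,",
      format(x$mean_residue_mass, nsmall = 3), "kDa/residue, rounding",
      x$rounding_step, "kDa\n")
  invisible(x)
}

#' Signed residue difference between two inclusion patterns
#'
#' Sums the residue contributions of the cassette exons (2-5: 11/13/12/11
#' residues; 10: 18; 23: 19) over the flag differences of the two patterns,
#' plus the difference in COOH-terminal tail length from [resolve_tail()].
#' Antisymmetric by construction. Patterns with an internal translation
#' start are refused: the residue count of the truncation is not modeled.
#'
#' @param pattern_a,pattern_b One-row pattern tibbles (catalog rows or named
#'   lists of flags; see [variant_pattern()]).
#' @return A signed integer residue count (positive when `pattern_a` is the
#'   longer protein).
#' @examples
#' cat <- mybpc_catalog()
#' delta_aa(variant_pattern(cat, "h-v1"), variant_pattern(cat, "h-v9")) # +47
#' delta_aa(variant_pattern(cat, "h-v3"), variant_pattern(cat, "h-v4")) # +19
#' @export
delta_aa <- function(pattern_a, pattern_b) {
  a <- as_pattern(pattern_a)
  b <- as_pattern(pattern_b)
  for (p in list(a, b)) {
    if (!is.na(p$tss_truncation)) {
      abort(paste0(
        "delta_aa is undefined for internally initiated patterns",
        if (!is.null(p$id)) paste0(" (", p$id, ")") else "",
        ": the truncated segment has no modeled residue count"
      ))
    }
  }
  cassette <- c("2", "3", "4", "5", "10", "23")
  body <- sum(.cassette_aa[cassette] *
                (vapply(paste0("exon", cassette), function(c) a[[c]], logical(1)) -
                 vapply(paste0("exon", cassette), function(c) b[[c]], logical(1))))
  tail_d <- resolve_tail(a$exon31, a$exon32)$aa_after_C10 -
    resolve_tail(b$exon31, b$exon32)$aa_after_C10
  as.integer(body + tail_d)
}

#' Predict variant molecular weights from exon composition
#'
#' Applies the delta-mass model to each record: residue delta to the anchor
#' pattern times the mean residue mass, added to the anchor mass and rounded
#' to the model's step. Internally initiated records (h-v012) cannot be
#' predicted - their printed mass is carried as data only - and are returned
#' with `NA`.
#'
#' @param variants One or more catalog rows.
#' @param model A [mass_model()].
#' @param catalog Catalog supplying the anchor pattern (defaults to the
#'   packaged catalog).
#' @return A tibble with columns `id`, `delta_aa`, `predicted_mw_kda`.
#' @examples
#' predict_mw(mybpc_catalog())
#' @export
predict_mw <- function(variants, model = mass_model(),
                       catalog = mybpc_catalog()) {
  variants <- tibble::as_tibble(variants)
  anchor <- variant_pattern(catalog, model$anchor_id)
  deltas <- purrr::map_int(seq_len(nrow(variants)), function(i) {
    row <- variants[i, ]
    if (!is.na(row$tss_truncation)) return(NA_integer_)
    delta_aa(row, anchor)
  })
  ids <- if ("id" %in% names(variants)) variants$id else
    paste0("pattern", seq_len(nrow(variants)))
  tibble::tibble(
    id = ids,
    delta_aa = deltas,
    predicted_mw_kda = round_half_away(
      model$anchor_mass + deltas * model$mean_residue_mass,
      model$rounding_step
    )
  )
}

#' Calibrate the mean residue mass against reported molecular weights
#'
#' Least-squares fit of the per-residue mass: with residue deltas to the
#' anchor as the design, minimizes the sum of squared differences between
#' `anchor_mass + m * delta` and the reported masses over the human
#' full-length, non-truncated records. Closed form:
#' `m = sum(delta * (mw - anchor_mass)) / sum(delta^2)`.
#'
#' @param catalog Catalog with `printed_mw_kda` filled in.
#' @param model Starting [mass_model()]; anchor and rounding are kept.
#' @return A `mass_model_fit` (also a valid `mass_model`) with the fitted
#'   `mean_residue_mass` and a `$fit` tibble of per-variant residuals.
#'   Use [generics::tidy()] / [generics::glance()] on it.
#' @examples
#' fit <- calibrate(mybpc_catalog())
#' glance(fit)
#' @export
calibrate <- function(catalog, model = mass_model()) {
  use <- catalog %>%
    dplyr::filter(.data$species == "human", !.data$partial,
                  is.na(.data$tss_truncation), !is.na(.data$printed_mw_kda))
  if (nrow(use) < 2) abort("calibration needs at least 2 variants with masses")
  d <- predict_mw(use, model = model, catalog = catalog)$delta_aa
  y <- use$printed_mw_kda - model$anchor_mass
  if (all(d == 0)) abort("degenerate design: all residue deltas are zero")
  m <- sum(d * y) / sum(d^2)
  if (m < 0.100 || m > 0.120) {
    warn(paste0("fitted mean residue mass ", signif(m, 4),
                " kDa falls outside the physical range [0.100, 0.120]"))
  }
  fitted <- model$anchor_mass + m * d
  out <- model
  out$mean_residue_mass <- m
  out$fit <- tibble::tibble(
    id = use$id, delta_aa = d, printed_mw_kda = use$printed_mw_kda,
    fitted_mw_kda = fitted, residual_kda = use$printed_mw_kda - fitted
  )
  class(out) <- c("mass_model_fit", "mass_model")
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname calibrate
#' @param x A `mass_model_fit`.
#' @param ... Unused.
#' @export
tidy.mass_model_fit <- function(x, ...) x$fit

#' @rdname calibrate
#' @export
glance.mass_model_fit <- function(x, ...) {
  tibble::tibble(
    anchor_id = x$anchor_id,
    anchor_mass = x$anchor_mass,
    mean_residue_mass = x$mean_residue_mass,
    n = nrow(x$fit),
    rmse_kda = sqrt(mean(x$fit$residual_kda^2)),
    max_abs_residual_kda = max(abs(x$fit$residual_kda))
  )
}

#' The six molecular-weight groups of sMyBP-C variants
#'
#' Because several variants run at nearly identical sizes, immunoreactive
#' bands can only be resolved to groups of candidate variants. The six
#' groups (and their gel colors) are: 1 red, v1/v5/v202 at 131-131.5 kDa;
#' 2 orange, v2/v6/v013 at 129-129.5; 3 yellow, v3/v7/v10 at 128; 4 green,
#' v8/v002 at 127-127.5; 5 blue, v4/v9 at 126-126.5; 6 purple, v012 at
#' 115.5. Group centers are the arithmetic means of the members' reported
#' masses, computed from the catalog.
#'
#' @param catalog Catalog supplying the reported masses.
#' @return A tibble with columns `group`, `color`, `members` (comma-joined
#'   human variant ids), `mass_lo`, `mass_hi`, `center` (kDa).
#' @examples
#' mw_groups()
#' @export
mw_groups <- function(catalog = mybpc_catalog()) {
  members <- list(
    c("h-v1", "h-v5", "h-v202"),
    c("h-v2", "h-v6", "h-v013"),
    c("h-v3", "h-v7", "h-v10"),
    c("h-v8", "h-v002"),
    c("h-v4", "h-v9"),
    "h-v012"
  )
  mw <- stats::setNames(catalog$printed_mw_kda, catalog$id)
  tibble::tibble(
    group = 1:6,
    color = c("red", "orange", "yellow", "green", "blue", "purple"),
    mass_lo = vapply(members, function(m) min(mw[m]), numeric(1)),
    mass_hi = vapply(members, function(m) max(mw[m]), numeric(1)),
    center = vapply(members, function(m) mean(mw[m]), numeric(1)),
    members = vapply(members, paste, character(1), collapse = ",")
  )[, c("group", "color", "members", "mass_lo", "mass_hi", "center")]
}

#' Assign estimated masses to molecular-weight groups
#'
#' Each mass is assigned to the group with the nearest center. A result is
#' flagged `ambiguous` when the two best center distances differ by less
#' than `margin` (the band cannot confidently discriminate the neighboring
#' groups), and left unassigned (`NA`) when even the best distance exceeds
#' `tolerance`. Defaults reflect the geometry of the groups: neighboring
#' centers sit ~1 kDa apart, so a 1.5 kDa tolerance accepts any plausible
#' band while a 0.5 kDa margin flags boundary cases.
#'
#' @param mass Numeric vector of estimated masses (kDa).
#' @param groups Group table from [mw_groups()].
#' @param tolerance Maximum center distance (kDa) for any assignment.
#' @param margin Ambiguity margin (kDa) between the two best distances.
#' @return A tibble with columns `mass`, `group` (integer or `NA`),
#'   `ambiguous`, `runner_up`, `candidates` (members of the assigned group,
#'   `""` if none).
#' @examples
#' assign_group(c(131, 129, 90))
#' @export
assign_group <- function(mass, groups = mw_groups(), tolerance = 1.5,
                         margin = 0.5) {
  if (nrow(groups) == 0) abort("groups must be nonempty")
  if (length(mass) == 0) {
    return(tibble::tibble(mass = numeric(0), group = integer(0),
                          ambiguous = logical(0), runner_up = integer(0),
                          candidates = character(0)))
  }
  dist <- abs(outer(mass, groups$center, "-")) # bands x groups
  best <- apply(dist, 1, which.min)
  best_d <- dist[cbind(seq_along(mass), best)]
  second_d <- apply(dist, 1, function(d) if (length(d) < 2) Inf else sort(d)[2])
  second <- apply(dist, 1, function(d) if (length(d) < 2) NA_integer_ else order(d)[2])
  none <- best_d > tolerance
  amb <- !none & (second_d - best_d) < margin
  tibble::tibble(
    mass = mass,
    group = ifelse(none, NA_integer_, groups$group[best]),
    ambiguous = amb,
    runner_up = ifelse(amb, groups$group[second], NA_integer_),
    candidates = ifelse(none, "", groups$members[best])
  )
}
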