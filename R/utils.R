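# Internal numeric helpers shared across modules.

#' Round half away from zero
#'
#' Rounds `x` to the nearest multiple of `step`, with exact halves rounded
#' away from zero (the convention used for all printed molecular weights and
#' percentages in this package; base `round()` rounds halves to even).
#'
#' @param x Numeric vector.
#' @param step Positive rounding increment (e.g. 0.5 for kDa, 1 for percents).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_away(129.52, 0.5)
#' round_half_away(2.5, 1) # 3, not 2
#' @export
round_half_away <- function(x, step = 1) {
  stopifnot(is.numeric(step), length(step) == 1, step > 0)
  sign(x) * floor(abs(x) / step + 0.5) * step
}

#' Largest-remainder integer apportionment
#'
#' Scales `shares` so the returned integer vector sums exactly to `total`:
#' each entry gets its floored share, and the leftover units go to the
#' entries with the largest fractional remainders (ties to the earliest
#' entry). Used to reconcile rounded percentage distributions to 100.
#'
#' @param shares Non-negative numeric vector of raw (unrounded) shares.
#' @param total Integer the result must sum to (default 100).
#' @return Integer vector, `sum(result) == total`.
#' @examples
#' largest_remainder(c(20.83, 72.92, 6.25)) # sums to 100
#' @export
largest_remainder <- function(shares, total = 100L) {
  stopifnot(all(shares >= 0), sum(shares) > 0)
  scaled <- shares / sum(shares) * total
  base <- floor(scaled)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    take <- order(scaled - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# "1,6"-style pattern keys <-> integer group vectors -------------------------

pattern_key <- function(groups) {
  vapply(groups, function(g) paste(sort(unique(as.integer(g))), collapse = ","),
         character(1))
}

key_groups <- function(key) {
  lapply(strsplit(key, ","), as.integer)
}

key_size <- function(key) {
  lengths(key_groups(key))
}
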