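# Independent arithmetic used to cross-check the implementation. Constants
# are written out here on purpose: these helpers must not share code with
# the package functions they verify.

# Residues contributed by each spliced element when retained.
.oracle_aa <- c(exon2 = 11, exon3 = 13, exon4 = 12, exon5 = 11,
                exon10 = 18, exon23 = 19)

# Tail residues past C10 for the four (exon31, exon32) states.
.oracle_tail <- function(e31, e32) {
  if (e31 && e32) 26 else if (e31 && !e32) 35 else if (!e31 && e32) 3 else 33
}

# Total variable residues of a pattern (cassette body + tail).
oracle_total_aa <- function(row) {
  sum(.oracle_aa * unlist(row[names(.oracle_aa)])) +
    .oracle_tail(row$exon31, row$exon32)
}

# Exhaustive integer-apportionment oracle: enumerates every composition of
# n into k parts and returns the optimal (max deviation, L1) pair. Only
# usable for small k and n.
oracle_best_apportionment <- function(percents, n) {
  k <- length(percents)
  grid <- do.call(expand.grid, rep(list(0:n), k))
  grid <- grid[rowSums(grid) == n, , drop = FALSE]
  dev <- abs(100 * t(t(grid)) / n - matrix(percents, nrow(grid), k, byrow = TRUE))
  maxd <- apply(dev, 1, max)
  l1 <- rowSums(dev)
  best_max <- min(maxd)
  list(max_dev = best_max, l1 = min(l1[maxd <= best_max + 1e-9]))
}

# A minimal single-pattern record for constructing edge cases.
make_variant <- function(id = "x-v1", species = "human",
                         exon2 = TRUE, exon3 = TRUE, exon4 = FALSE,
                         exon5 = FALSE, exon10 = TRUE, exon23 = FALSE,
                         exon31 = TRUE, exon32 = TRUE,
                         tss_truncation = NA_integer_,
                         printed_mw_kda = NA_real_, partial = FALSE) {
  tibble::tibble(
    id = id, species = species,
    exon2 = exon2, exon3 = exon3, exon4 = exon4, exon5 = exon5,
    exon10 = exon10, exon23 = exon23, exon31 = exon31, exon32 = exon32,
    exon33_coding = ifelse(exon32, "utr_only", "coding"),
    tss_truncation = as.integer(tss_truncation),
    printed_mw_kda = printed_mw_kda,
    accession = "TEST", partial = partial
  )
}
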