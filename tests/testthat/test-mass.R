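catalog <- mybpc_catalog()
human_full <- dplyr::filter(catalog, species == "human",
                            is.na(tss_truncation))

test_that("residue deltas match independent arithmetic and are antisymmetric", {
  v1 <- variant_pattern(catalog, "h-v1")
  v9 <- variant_pattern(catalog, "h-v9")
  v3 <- variant_pattern(catalog, "h-v3")
  v4 <- variant_pattern(catalog, "h-v4")

  expect_equal(delta_aa(v1, v9), 47L)  # 11 + 13 + 12 + 11, identical tails
  expect_equal(delta_aa(v3, v4), 19L)  # exon 23 alone
  expect_equal(delta_aa(v9, v9), 0L)

  # oracle cross-check + antisymmetry over every pair of full-length humans
  for (i in seq_len(nrow(human_full))) {
    for (j in seq_len(nrow(human_full))) {
      a <- human_full[i, ]
      b <- human_full[j, ]
      expect_equal(delta_aa(a, b), oracle_total_aa(a) - oracle_total_aa(b))
      expect_equal(delta_aa(a, b), -delta_aa(b, a))
    }
  }

  expect_error(delta_aa(variant_pattern(catalog, "h-v012"), v9),
               "internally initiated")
})

test_that("default delta-mass model reproduces reported masses to 0.5 kDa", {
  pred <- predict_mw(catalog)
  joined <- dplyr::left_join(pred, catalog[, c("id", "printed_mw_kda")], by = "id")
  full <- dplyr::filter(joined, !id %in% "h-v012")
  expect_equal(nrow(full), 15) # 13 human + 2 mouse
  expect_true(all(abs(full$predicted_mw_kda - full$printed_mw_kda) <= 0.5))

  # spot predictions
  p <- function(vid) pred$predicted_mw_kda[pred$id == vid]
  expect_equal(p("h-v013"), 129.5) # 126 + 32 x 0.110 = 129.52 -> 129.5
  expect_equal(p("h-v9"), 126)     # anchor maps to itself
  expect_equal(p("h-v3"), 128)     # 126 + 20 x 0.110 = 128.2 -> 128.0
  # the truncated variant is never predicted
  expect_true(is.na(p("h-v012")))
})

test_that("predictions are anchor-independent to within one rounding step", {
  m9 <- mass_model()
  m1 <- mass_model(anchor_id = "h-v1", anchor_mass = 131.5)
  p9 <- predict_mw(human_full, model = m9)$predicted_mw_kda
  p1 <- predict_mw(human_full, model = m1)$predicted_mw_kda
  expect_true(all(abs(p9 - p1) <= m9$rounding_step))
})

test_that("calibration recovers the closed-form least-squares residue mass", {
  # two-point catalog: exact slope (131.5 - 126) / 47
  two <- dplyr::filter(catalog, id %in% c("h-v9", "h-v1"))
  fit2 <- calibrate(two)
  expect_equal(fit2$mean_residue_mass, (131.5 - 126) / 47)

  # full human catalog: closed form computed here from oracle residue totals
  d <- vapply(seq_len(nrow(human_full)), function(i) {
    oracle_total_aa(human_full[i, ]) -
      oracle_total_aa(variant_pattern(catalog, "h-v9"))
  }, numeric(1))
  y <- human_full$printed_mw_kda - 126
  expect_gt(sum(d^2), 0)
  m_hat <- sum(d * y) / sum(d^2)
  fit <- calibrate(catalog)
  expect_equal(fit$mean_residue_mass, m_hat, tolerance = 1e-12)
  expect_true(fit$mean_residue_mass >= 0.100 && fit$mean_residue_mass <= 0.120)
  expect_equal(nrow(tidy(fit)), 13)
  expect_lt(glance(fit)$max_abs_residual_kda, 0.6)

  # degenerate designs fail loudly
  expect_error(calibrate(dplyr::filter(catalog, id == "h-v1")), "at least 2")
  twin <- dplyr::bind_rows(
    variant_pattern(catalog, "h-v9"),
    dplyr::mutate(variant_pattern(catalog, "h-v9"), id = "h-v9b")
  )
  expect_error(calibrate(twin), "degenerate")
})

test_that("the six molecular-weight groups partition the human variants", {
  groups <- mw_groups()
  expect_equal(nrow(groups), 6)
  members <- strsplit(groups$members, ",")
  all_human <- dplyr::filter(catalog, species == "human")$id
  expect_setequal(unlist(members), all_human)
  expect_equal(sum(lengths(members)), 14)
  expect_false(anyDuplicated(unlist(members)) > 0)
  expect_equal(groups$center, c(mean(c(131.5, 131.5, 131)),
                                mean(c(129, 129, 129.5)),
                                128,
                                mean(c(127, 127.5)),
                                mean(c(126, 126.5)),
                                115.5))
  # ranges strictly descending and disjoint
  expect_true(all(diff(groups$center) < 0))
  expect_true(all(groups$mass_lo[-1] < groups$mass_hi[-6]))
})

test_that("mass-to-group assignment handles clear, ambiguous and distant bands", {
  a <- assign_group(c(131, 129, 90))
  expect_equal(a$group, c(1L, 2L, NA))
  expect_true(grepl("h-v1", a$candidates[1]) && grepl("h-v202", a$candidates[1]))
  expect_true(grepl("h-v013", a$candidates[2]))
  expect_equal(a$candidates[3], "")

  # midway between groups 3 (128.0) and 4 (127.25): flagged ambiguous
  amb <- assign_group(127.6)
  expect_equal(amb$group, 4L)
  expect_true(amb$ambiguous)
  expect_equal(amb$runner_up, 3L)

  # far band with a wide tolerance still assigns unambiguously
  far <- assign_group(115.5)
  expect_equal(far$group, 6L)
  expect_false(far$ambiguous)

  expect_equal(nrow(assign_group(numeric(0))), 0)
})

test_that("model construction enforces its physical bounds", {
  expect_error(mass_model(mean_residue_mass = 0.2), "0.100")
  expect_error(mass_model(rounding_step = 0), "positive")
})
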