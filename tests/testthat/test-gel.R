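perfect_ladder <- default_ladder()

test_that("a noiseless log-linear ladder is fitted exactly", {
  curve <- fit_standard_curve(perfect_ladder)
  expect_lt(abs(curve$r2 - 1), 1e-12)
  expect_lt(curve$slope, 0)
  expect_equal(tidy(curve)$fitted_mass_kda, perfect_ladder$mass_kda,
               tolerance = 1e-9)
  expect_equal(estimate_mass(curve, perfect_ladder$rf), perfect_ladder$mass_kda,
               tolerance = 1e-9)
})

test_that("a perturbed marker degrades the fit and is flagged by its residual", {
  lad <- perfect_ladder
  lad$rf[3] <- lad$rf[3] + 0.01 # the 125 kDa marker migrates slightly far

  # closed-form OLS oracle on the perturbed points
  x <- lad$rf
  y <- log10(lad$mass_kda)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_o <- mean(y) - slope_o * mean(x)
  resid_o <- y - (int_o + slope_o * x)
  r2_o <- 1 - sum(resid_o^2) / sum((y - mean(y))^2)

  curve <- fit_standard_curve(lad)
  expect_equal(curve$slope, slope_o, tolerance = 1e-12)
  expect_equal(curve$intercept, int_o, tolerance = 1e-12)
  expect_equal(curve$r2, r2_o, tolerance = 1e-12)
  expect_lt(curve$r2, 1)
  expect_equal(which.max(abs(tidy(curve)$residual_log10)), 3L)
})

test_that("degenerate ladders are rejected", {
  expect_error(fit_standard_curve(perfect_ladder[1:2, ]), "at least 3")
  bad <- perfect_ladder
  bad$mass_kda[2] <- 300 # mass rises while rf rises
  expect_error(fit_standard_curve(bad), "monotone")
  expect_error(fit_standard_curve(tibble::tibble(mass = 1, x = 2)), "columns")
})

test_that("mass estimation inverts the curve and is strictly decreasing", {
  curve <- fit_standard_curve(perfect_ladder)
  # intercept definition: rf = 0 maps to 10^intercept (= 250 on this gel)
  expect_equal(suppressWarnings(estimate_mass(curve, 0)), 250, tolerance = 1e-9)

  # midpoint between two markers sizes to their geometric mean
  lad2 <- tibble::tibble(mass_kda = c(180, 135, 125, 95, 60),
                         rf = (log10(250) - log10(mass_kda)) / log10(5))
  c2 <- fit_standard_curve(lad2)
  mid <- mean(lad2$rf[2:3])
  expect_equal(estimate_mass(c2, mid), sqrt(135 * 125), tolerance = 1e-9)

  # strict monotonicity on a randomly generated monotone ladder
  set.seed(101)
  for (rep in 1:5) {
    masses <- sort(exp(runif(5, log(40), log(260))), decreasing = TRUE)
    rfs <- sort(runif(5, 0.05, 0.95))
    cc <- fit_standard_curve(tibble::tibble(mass_kda = masses, rf = rfs))
    grid <- seq(0.05, 0.95, by = 0.01)
    expect_true(all(diff(suppressWarnings(estimate_mass(cc, grid))) < 0))
  }

  expect_warning(estimate_mass(curve, 1.2), "outside the calibrated range")
})

test_that("noiseless bands round-trip through sizing and group assignment", {
  for (muscle in c("soleus", "fdb")) {
    fx <- generate_fixture(frequency_preset(muscle))
    curve <- fit_standard_curve(fx$ladder)
    asg <- assign_bands(fx$bands, curve)
    truth <- dplyr::arrange(fx$truth, fiber_id, dplyr::desc(true_mass_kda))
    asg_s <- dplyr::arrange(asg, lane_id, dplyr::desc(estimated_mass_kda))
    expect_equal(nrow(asg_s), nrow(truth))
    expect_true(all(abs(asg_s$estimated_mass_kda - truth$true_mass_kda) < 0.01))
    expect_equal(asg_s$group, truth$group) # 100% correct recovery
  }
})

test_that("band lists are merged, ordered and deduplicated per lane", {
  curve <- fit_standard_curve(perfect_ladder)
  rf_for <- function(m) (log10(250) - log10(m)) / log10(5)

  # two bands 0.1 kDa apart collapse to one; distinct groups survive
  bands <- tibble::tibble(
    lane_id = c("f1", "f1", "f1", "f2"),
    rf = c(rf_for(131.4), rf_for(131.3), rf_for(115.5), rf_for(129.2))
  )
  asg <- assign_bands(bands, curve)
  f1 <- dplyr::filter(asg, lane_id == "f1")
  expect_equal(nrow(f1), 2)
  expect_equal(f1$group, c(1L, 6L)) # mass-descending order
  expect_true(all(diff(f1$estimated_mass_kda) < 0))
  expect_equal(dplyr::filter(asg, lane_id == "f2")$group, 2L)

  # duplicate group hits in a lane collapse even when bands are resolvable
  dup <- tibble::tibble(lane_id = "f3", rf = c(rf_for(131.5), rf_for(131.0)))
  expect_equal(nrow(assign_bands(dup, curve, merge_within = 0.25)), 1)

  expect_equal(nrow(assign_bands(bands[0, ], curve)), 0)
})

test_that("lane collapse yields per-fiber group sets and drops empty lanes", {
  curve <- fit_standard_curve(perfect_ladder)
  rf_for <- function(m) (log10(250) - log10(m)) / log10(5)
  bands <- tibble::tibble(
    lane_id = c("a", "a", "b", "c"),
    rf = c(rf_for(131.3), rf_for(115.5), rf_for(126.25), rf_for(60))
  )
  fibers <- lanes_to_fibers(assign_bands(bands, curve), muscle = "soleus")
  expect_equal(fibers$fiber_id, c("a", "b")) # lane c had no assignable band
  expect_equal(fibers$groups, c("1,6", "5"))
  expect_equal(fibers$n_groups, c(2L, 1L))
})
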