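test_that("tensile and specific crushing strength follow the diametral formulas", {
  expect_within(tensile_strength(12.07, 10.5, 3.34), 0.219, 1e-3)
  expect_within(specific_crushing_strength(12.07, 10.5, 3.34), 0.344, 1e-3)
  expect_within(tensile_strength(5.3, 10.5, 3.61), 0.089, 1e-3)
  expect_within(specific_crushing_strength(5.3, 10.5, 3.61), 0.140, 1e-3)
  # limit case: vanishing force
  expect_equal(tensile_strength(1e-9, 10.5, 3.34), 0, tolerance = 1e-9)
  expect_error(tensile_strength(0, 10.5, 3.34),
               class = "sedem_invalid_measurement")
  expect_error(specific_crushing_strength(5, -1, 3),
               class = "sedem_invalid_measurement")
})

test_that("Ts / tau = 2 / pi identically, including all fixture trials", {
  set.seed(41)
  for (i in 1:20) {
    F <- runif(1, 2, 15); D <- runif(1, 6, 13); H <- runif(1, 2, 5)
    expect_equal(tensile_strength(F, D, H) / specific_crushing_strength(F, D, H),
                 2 / pi, tolerance = 1e-12)
  }
  tab8 <- load_paper_fixtures()$tablets
  expect_equal(tab8$tensile_strength / tab8$specific_crushing_strength,
               rep(2 / pi, nrow(tab8)), tolerance = 0.02) # printed rounding
})

test_that("friability, weight variation and drug content apply the USP rules", {
  f <- friability(6.50, 6.47)
  expect_equal(f$percent_loss, 0.4615, tolerance = 1e-4)
  expect_true(f$pass)
  expect_equal(friability(6.50, 6.50)$percent_loss, 0)
  bad <- friability(6.50, 6.40)
  expect_equal(bad$percent_loss, 1.538, tolerance = 1e-3)
  expect_false(bad$pass)
  expect_error(friability(6.4, 6.5), class = "sedem_invalid_measurement")

  wv <- weight_variation(c(250, 255, 245))
  expect_equal(wv$mean_mg, 250)
  expect_equal(wv$max_deviation_pct, 2)
  expect_equal(weight_variation(rep(251, 10))$max_deviation_pct, 0)
  expect_error(weight_variation(numeric(0)), class = "sedem_insufficient_data")
  expect_error(weight_variation(250), class = "sedem_insufficient_data")

  expect_equal(drug_content(980, 1000)$percent, 98)
  expect_true(drug_content(980, 1000)$pass)
  expect_equal(drug_content(1000, 1000)$percent, 100)
  expect_false(drug_content(950, 1000)$pass)
  expect_error(drug_content(980, 0), class = "sedem_invalid_measurement")
})

test_that("dissolution profile applies the withdrawal correction", {
  # single non-trivial sample: Q = 100 * C * V / claim
  one <- dissolution_profile(15, 0.0883, 900, 10, 100)
  expect_equal(one$Q, 79.47)
  expect_equal(attr(one, "Q15"), 79.47)

  zero <- dissolution_profile(c(0, 5, 15), c(0, 0, 0))
  expect_equal(zero$Q, c(0, 0, 0))

  # hand evaluation of the two-point corrected profile:
  # Q1 = 100 * 0.05 * 900 / 100 = 45
  # Q2 = 100 * (0.0883 * 900 + 0.05 * 10) / 100 = 79.47 + 0.5
  two <- dissolution_profile(c(5, 15), c(0.05, 0.0883), 900, 10, 100)
  expect_equal(two$Q, c(45, 79.97))
  naive <- dissolution_profile(c(5, 15), c(0.05, 0.0883), 900, 10, 100,
                               correct_withdrawal = FALSE)
  expect_equal(naive$Q, c(45, 79.47))

  expect_error(dissolution_profile(c(5, 5), c(1, 1)),
               class = "sedem_validation")
  expect_error(dissolution_profile(c(5, 15), c(0.1, -0.1)),
               class = "sedem_invalid_measurement")

  # Q non-decreasing whenever concentrations are non-decreasing
  set.seed(42)
  for (i in 1:20) {
    conc <- cumsum(runif(5, 0, 0.02))
    q <- dissolution_profile(c(0, 5, 15, 30, 60), conc)$Q
    expect_true(all(diff(q) >= 0))
  }
})

test_that("tablet_report aggregates a batch with mean hardness and thickness", {
  tb <- tablet_batch(
    trial_id = "T", crushing_strengths = c(11.9, 12.24), diameter = 10.5,
    thicknesses = c(3.3, 3.38), individual_weights = c(250, 252, 248, 254),
    friability_mass_before = 6.5, friability_mass_after = 6.48,
    wetting_times = c(240, 250, 257), disintegration_times = rep(12.5, 6),
    peak_area_sample = 992, peak_area_standard = 1000,
    dissolution_times = c(0, 5, 15), dissolution_concentrations = c(0, 0.01, 0.0237))
  rep <- tablet_report(tb)
  expect_equal(rep$crushing_strength_kg, 12.07)
  expect_equal(rep$thickness_mm, 3.34)
  expect_equal(rep$tensile_strength, tensile_strength(12.07, 10.5, 3.34))
  expect_equal(rep$specific_crushing_strength,
               specific_crushing_strength(12.07, 10.5, 3.34))
  expect_true(rep$friability_pass)
  expect_true(rep$drug_content_pass)
  expect_equal(rep$Q15, 100 * (0.0237 * 900 + 0.01 * 10) / 100)
})
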