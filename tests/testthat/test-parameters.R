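test_that("density, porosity, Carr index and Hausner ratio follow their formulas", {
  expect_equal(density_from_mass_volume(100, 250), 0.4)
  expect_equal(density_from_mass_volume(50, 50), 1)
  expect_error(density_from_mass_volume(100, 0),
               class = "sedem_invalid_measurement")
  expect_error(density_from_mass_volume(-1, 10),
               class = "sedem_invalid_measurement")

  expect_equal(interparticle_porosity(0.4, 0.5), 0.5)
  expect_equal(interparticle_porosity(0.5, 0.5), 0)
  expect_equal(interparticle_porosity(0.4, 0.6), 0.8333, tolerance = 1e-4)
  expect_error(interparticle_porosity(0.6, 0.4),
               class = "sedem_invalid_measurement")

  expect_equal(carr_index(0.4, 0.5), 20)
  expect_equal(carr_index(0.5, 0.5), 0)
  expect_equal(carr_index(0.25, 0.5), 50)

  expect_equal(hausner_ratio(0.4, 0.5), 1.25)
  expect_equal(hausner_ratio(0.5, 0.5), 1)
  expect_equal(hausner_ratio(0.2, 0.6), 3)
  expect_error(hausner_ratio(0, 0.5), class = "sedem_invalid_measurement")
})

test_that("density-derived descriptors are mutually consistent", {
  set.seed(11)
  for (i in 1:50) {
    Da <- runif(1, 0.2, 0.9)
    Dc <- Da * runif(1, 1, 1.6)
    Ic <- carr_index(Da, Dc)
    IH <- hausner_ratio(Da, Dc)
    Ie <- interparticle_porosity(Da, Dc)
    expect_equal(Ic, 100 * (1 - 1 / IH), tolerance = 1e-12)
    expect_gte(Ic, 0); expect_gte(IH, 1); expect_gte(Ie, 0)
    # equality in all three exactly when Da == Dc
    expect_identical(Ic == 0, Da == Dc)
    expect_identical(IH == 1, Da == Dc)
    expect_identical(Ie == 0, Da == Dc)
  }
})

test_that("angle of repose is the arctangent of height over radius", {
  expect_equal(angle_of_repose(0, 40), 0)
  expect_equal(angle_of_repose(40, 40), 45)
  expect_equal(angle_of_repose(20, 40), 26.565, tolerance = 1e-3)
  expect_error(angle_of_repose(20, 0), class = "sedem_invalid_measurement")
})

test_that("cohesion index averages compact strengths", {
  expect_equal(cohesion_index(c(100, 100, 100)), 100)
  expect_equal(cohesion_index(c(80, 120)), 100)
  expect_error(cohesion_index(numeric(0)), class = "sedem_insufficient_data")
  expect_equal(kgf_to_newton(1), 9.80665)
})

test_that("homogeneity index matches the weighted-diameter formula", {
  stack <- c(850, 600, 425, 300, 250, 50)
  # degenerate: all mass in the 425-600 um fraction
  one <- sieve_fractions(stack, c(0, 0, 100, 0, 0, 0), 0)
  expect_equal(homogeneity_index(one), 1)
  # hand evaluation: Fm = 60 % at 512.5 um, 40 % at 362.5 um
  two <- sieve_fractions(stack, c(0, 0, 60, 40, 0, 0), 0)
  expect_equal(homogeneity_index(two), 60 / (100 + 150 * 40))
  expect_equal(homogeneity_index(two), 0.009836, tolerance = 1e-4)
  # invariant breach: percentages summing to 90
  expect_error(sieve_fractions(stack, c(0, 0, 60, 30, 0, 0), 0),
               class = "sedem_validation")
  # empty distribution
  expect_error(homogeneity_index(structure(
    list(percent_retained = c(0, 0), pan_percent = 0,
         mean_diameter = c(850, 425)), class = "sieve_fractions")),
    class = "sedem_insufficient_data")
  # majority tie broken toward the coarser fraction
  tie <- sieve_fractions(stack, c(0, 50, 50, 0, 0, 0), 0)
  expect_message(v_tie <- homogeneity_index(tie), "tie")
  expect_equal(v_tie, 50 / (100 + abs(512.5 - 725) * 50))
})

test_that("homogeneity index is invariant to proportional rescaling", {
  stack <- c(850, 600, 425, 300, 250, 50)
  base <- sieve_fractions(stack, c(2, 10, 62, 16, 6, 3), 1)
  # 100.4 total, still within the +/- 0.5 tolerance; renormalised internally
  scaled <- sieve_fractions(stack, 1.004 * c(2, 10, 62, 16, 6, 3), 1.004)
  expect_equal(homogeneity_index(scaled), homogeneity_index(base),
               tolerance = 1e-12)
})

test_that("assemble_basic_parameters composes the single-purpose operations", {
  stack <- c(850, 600, 425, 300, 250, 50)
  m <- raw_measurements(
    "batch-A", granule_mass = 100, bulk_volume = 250, tapped_volume = 200,
    cone_height = 20, cone_radius = 40, flow_time = 6,
    loss_on_drying_pct = 2.5, hygroscopicity_pct = 10.69,
    compact_strengths = rep(c(80, 120), 5),
    sieve = sieve_fractions(stack, c(2, 10, 62, 16, 6, 3), 1),
    percent_fines = 4.2, effervescence_times = rep(3, 6),
    disint_disk_times = rep(2, 6), disint_nodisk_times = c(2, 3, 2, 3, 2, 3))
  p <- assemble_basic_parameters(m)
  expect_s3_class(p, "basic_parameters")
  expect_equal(p$Da, 0.4); expect_equal(p$Dc, 0.5)
  expect_equal(p$Ic, 20);  expect_equal(p$IH, 1.25); expect_equal(p$Ie, 0.5)
  expect_equal(p$H, 10.69)            # pass-through percent weight gain
  expect_equal(p$Icd, 100)            # mean of the compact strengths
  expect_equal(p$DCD, 2); expect_equal(p$DSD, 2.5)
  expect_equal(p$alpha, angle_of_repose(20, 40))
  expect_equal(p$Itheta, homogeneity_index(m$sieve))
  # determinism
  expect_identical(assemble_basic_parameters(m), p)
})

test_that("missing raw fields are reported with the affected parameters", {
  m <- raw_measurements("b", granule_mass = 100, bulk_volume = 250)
  err <- tryCatch(assemble_basic_parameters(m), error = identity)
  expect_s3_class(err, "sedem_missing_field")
  expect_match(conditionMessage(err), "tapped_volume")
  expect_match(conditionMessage(err), "Dc")
  expect_match(conditionMessage(err), "Icd")
})

test_that("raw measurement invariants are enforced at construction", {
  expect_error(raw_measurements("b", bulk_volume = 200, tapped_volume = 250),
               class = "sedem_invalid_measurement")
  expect_error(raw_measurements("b", granule_mass = -5),
               class = "sedem_invalid_measurement")
  expect_error(raw_measurements(""), class = "sedem_validation")
})
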