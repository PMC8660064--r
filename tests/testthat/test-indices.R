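fx <- load_paper_fixtures()

test_that("parametric index counts raw radii at or above 5", {
  at_odt <- radius_profile_from_radii("Atenolol", fx$table4$Atenolol, "odt")
  at_cls <- radius_profile_from_radii("Atenolol", fx$table4$Atenolol, "classic")
  expect_equal(parametric_index(at_odt), 3 / 15)
  expect_equal(parametric_index(at_cls), 1 / 12)
  expect_equal(parametric_index(constant_profile(10)), 1)
  # negative raw radii can never count
  expect_equal(parametric_index(constant_profile(-2)), 0)
})

test_that("profile index is the mean clamped radius", {
  t5 <- radius_profile_from_radii("Trial-5", fx$table5[["Trial-5"]], "odt")
  expect_equal(round_half_up(parameter_profile_index(t5), 2), 5.45)
  t5c <- radius_profile_from_radii("Trial-5", fx$table5[["Trial-5"]], "classic")
  expect_equal(parameter_profile_index(t5c), 6.819, tolerance = 1e-3)
  for (c0 in c(0, 3.2, 10)) {
    expect_equal(parameter_profile_index(constant_profile(c0)), c0)
  }
})

test_that("reliability factor lookup and polygon fallback", {
  expect_equal(reliability_factor(15), 0.971)
  expect_equal(reliability_factor(12), 0.952)
  expect_equal(reliability_factor(8), 0.900)
  expect_equal(reliability_factor(Inf), 1)
  # closed form (0.97101) agrees with the n = 15 lookup to 3 dp; lookup wins
  expect_equal(oracle_polygon_fraction(15), 0.971, tolerance = 5e-4)
  expect_equal(round(oracle_polygon_fraction(15), 3), reliability_factor(15))
  expect_equal(reliability_factor(20), oracle_polygon_fraction(20))
  expect_error(reliability_factor(2), class = "sedem_domain")
})

test_that("igcb is the IPP x f product with validated domains", {
  expect_equal(round_half_up(igcb(5.455, 0.971), 2), 5.30)
  expect_equal(igcb(6.819, 0.952), 6.491, tolerance = 1e-3)
  expect_equal(igcb(4.2, 1), 4.2)
  expect_error(igcb(11, 0.9), class = "sedem_validation")
  expect_error(igcb(5, 0), class = "sedem_validation")
})

test_that("incidence factors are clamped group means", {
  t5 <- radius_profile_from_radii("Trial-5", fx$table5[["Trial-5"]], "odt")
  inc <- incidence_factors(t5)
  expect_equal(unname(inc[["Dimension"]]), 7.66)
  expect_equal(unname(inc[["Lubricity/Dosage"]]), 8.204)
  expect_equal(unname(inc[["Disgregability"]]), 0) # negatives clamp to zero
  blend <- radius_profile_from_radii("Powder Blend", fx$table4[["Powder Blend"]],
                                     "odt")
  expect_equal(unname(incidence_factors(blend)[["Disgregability"]]), 0.713,
               tolerance = 0.01)
})

test_that("weighted incidence means equal IPP and IGCB <= IPP", {
  set.seed(21)
  reg <- parameter_registry()
  for (i in 1:25) {
    r <- setNames(runif(15, -4, 12), reg$id)
    prof <- radius_profile_from_radii("p", r, "odt")
    rep <- full_report(prof)
    inc <- rep$incidence
    sizes <- table(factor(reg$group, levels = names(inc)))
    expect_equal(sum(inc * as.numeric(sizes)) / 15, rep$IPP, tolerance = 1e-12)
    expect_lte(rep$IGCB, rep$IPP)
    expect_true(all(inc >= 0 & inc <= 10))
    expect_gte(rep$IP, 0); expect_lte(rep$IP, 1)
  }
})

test_that("full_report reproduces the printed index rows", {
  t5 <- full_report(radius_profile_from_radii("Trial-5",
                                              fx$table5[["Trial-5"]], "odt"))
  expect_equal(t5$IP, 0.667, tolerance = 1e-3)
  expect_equal(t5$IPP, 5.45, tolerance = 0.01)
  expect_equal(t5$IGCB, 5.29, tolerance = 0.01)
  expect_equal(t5$verdict, "suitable")

  at <- full_report(radius_profile_from_radii("Atenolol", fx$table4$Atenolol,
                                              "odt"))
  expect_equal(at$IGCB, 3.47, tolerance = 0.01)
  expect_equal(at$verdict, "not-suitable")

  expect_error(full_report(structure(list(system = "odt",
                                          radii = data.frame()),
                                     class = "radius_profile")),
               class = "sedem_validation")
})

test_that("dropping Disgregability reproduces the classic columns", {
  for (tr in names(fx$table5)) {
    odt <- radius_profile_from_radii(tr, fx$table5[[tr]], "odt")
    cls <- full_report(sedemodt:::as_classic_profile(odt))
    expect_equal(cls$n_params, 12)
    expect_equal(cls$f, 0.952)
    row <- fx$indices[fx$indices$trial_id == tr, ]
    expect_equal(cls$IPP, row$classic_IPP, tolerance = 0.01, info = tr)
    expect_equal(cls$IGCB, row$classic_IGC, tolerance = 0.01, info = tr)
    expect_equal(cls$IP, row$classic_IP, tolerance = 1e-3, info = tr)
  }
})
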