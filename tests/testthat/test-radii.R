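test_that("the registry carries the canonical 15-parameter table", {
  reg <- parameter_registry()
  expect_equal(nrow(reg), 15)
  expect_equal(sum(reg$classic), 12)
  expect_equal(as.integer(table(factor(reg$group, levels = unique(reg$group)))),
               c(2L, 3L, 3L, 2L, 2L, 3L))
  expect_error(parameter_registry(list(bogus = list(slope = 1))),
               class = "sedem_registry")
  expect_error(parameter_registry(list(Da = list(color = "red"))),
               class = "sedem_registry")
  # overrides are applied
  reg2 <- parameter_registry(list(Icd = list(v_high = 300)))
  expect_equal(reg2$v_high[reg2$id == "Icd"], 300)
})

test_that("radius_value applies the printed factors", {
  expect_equal(radius_value("H", 10.69), 4.655)
  expect_equal(radius_value("Ic", 50), 10)
  expect_equal(radius_value("IH", 3), 0)
  expect_equal(radius_value("DCD", 0), 9.99)
  expect_equal(radius_value("Itheta", 0.02), 10)
  expect_error(radius_value("nope", 1), class = "sedem_registry")
  expect_error(radius_value("Da", Inf), class = "sedem_invalid_measurement")
})

test_that("every factor hits its ceiling at the favourable limit", {
  reg <- parameter_registry()
  for (i in seq_len(nrow(reg))) {
    top <- radius_value(reg$id[i], reg$favourable[i], reg)
    if (reg$id[i] %in% c("DCD", "DSD")) {
      expect_equal(top, 9.99, info = reg$id[i])  # printed constant 3.33
    } else {
      expect_equal(top, 10, tolerance = 1e-12, info = reg$id[i])
    }
  }
})

test_that("radii are monotone in V with the documented direction", {
  reg <- parameter_registry()
  increasing <- c("Da", "Dc", "Ie", "Ic", "Icd", "Itheta")
  set.seed(5)
  for (i in seq_len(nrow(reg))) {
    id <- reg$id[i]
    v <- sort(runif(8, reg$v_low[i], reg$v_high[i]))
    r <- radius_value(id, v, reg)
    if (id %in% increasing) {
      expect_true(all(diff(r) >= 0), info = id)
    } else {
      expect_true(all(diff(r) <= 0), info = id)
    }
  }
})

test_that("factor transforms round-trip through their inverse", {
  reg <- parameter_registry()
  set.seed(6)
  for (id in reg$id) {
    r <- runif(5, 0, 10)
    expect_equal(radius_value(id, sedemodt:::radius_inverse(id, r), reg), r,
                 tolerance = 1e-9, info = id)
  }
})

test_that("clamp_radius truncates onto [0, 10]", {
  expect_equal(clamp_radius(-7.299), 0)
  expect_equal(clamp_radius(4.655), 4.655)
  expect_equal(clamp_radius(12.3), 10)
  expect_equal(clamp_radius(c(-1, 0, 5, 10, 11)), c(0, 0, 5, 10, 10))
  expect_error(clamp_radius(NaN), class = "sedem_invalid_measurement")
})

test_that("build_profile produces raw and clamped radii for the system", {
  p <- demo_parameters()
  prof <- build_profile(p, "odt")
  expect_equal(nrow(prof$radii), 15)
  expect_equal(prof$radii$clamped_r, clamp_radius(prof$radii$raw_r))
  expect_true(all(prof$radii$clamped_r >= 0 & prof$radii$clamped_r <= 10))
  # hygroscopicity entry matches the single-purpose transform
  expect_equal(prof$radii$raw_r[prof$radii$id == "H"], radius_value("H", 3.9))

  classic <- build_profile(p, "classic")
  expect_equal(nrow(classic$radii), 12)
  expect_false(any(classic$radii$group == "Disgregability"))

  # all parameters at their favourable limits
  reg <- parameter_registry()
  best <- do.call(basic_parameters,
                  c(list("best"), as.list(setNames(reg$favourable, reg$id))))
  bp <- build_profile(best, "odt")
  expect_equal(bp$radii$clamped_r[bp$radii$id %in% c("DCD", "DSD")],
               c(9.99, 9.99))
  expect_equal(bp$radii$clamped_r[!bp$radii$id %in% c("DCD", "DSD")],
               rep(10, 13))
})

test_that("out-of-limit values are transformed with a warning, not dropped", {
  p <- demo_parameters()
  p$DE <- 9  # above the 5 min admissible limit
  expect_warning(prof <- build_profile(p, "odt"), "DE")
  expect_equal(prof$radii$raw_r[prof$radii$id == "DE"], (5 - 9) * 2)
  expect_equal(prof$radii$clamped_r[prof$radii$id == "DE"], 0)
})

test_that("profiles from literature radii reproduce the printed values", {
  fx <- load_paper_fixtures()
  at <- radius_profile_from_radii("Atenolol", fx$table4$Atenolol, "odt")
  expect_equal(at$radii$raw_r[at$radii$id == "H"], 4.66)
  # where V is recoverable, the forward transform returns the printed radius
  for (id in at$radii$id) {
    v <- at$radii$V[at$radii$id == id]
    expect_equal(radius_value(id, v), at$radii$raw_r[at$radii$id == id],
                 tolerance = 1e-9, info = id)
  }
  expect_error(radius_profile_from_radii("x", c(Da = 5), "odt"),
               class = "sedem_missing_field")
})

test_that("missing parameters for a system raise a named error", {
  p <- basic_parameters("partial", Da = 0.5, Dc = 0.6)
  err <- tryCatch(build_profile(p, "classic"), error = identity)
  expect_s3_class(err, "sedem_missing_field")
  expect_match(conditionMessage(err), "Icd")
})
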