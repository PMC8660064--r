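# Independent oracles, deliberately naive: used to freeze expected values and
# to cross-check the implementation without sharing its code path.

# absolute-tolerance comparison (testthat's tolerance= is relative)
expect_within <- function(object, expected, tol, info = NULL) {
  testthat::expect_true(
    abs(object - expected) <= tol + 1e-12,
    label = sprintf("|%.6g - %.6g| = %.2g <= %g", object, expected,
                    abs(object - expected), tol),
    info = info)
}

# average-rank assignment by direct counting
oracle_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Spearman rho as Pearson correlation of oracle ranks
oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# area ratio of a regular n-gon inscribed in the unit circle
oracle_polygon_fraction <- function(n) n * sin(2 * pi / n) / (2 * pi)

# a complete, in-limits basic-parameter set used by many tests
demo_parameters <- function(batch_id = "demo") {
  basic_parameters(batch_id,
    Da = 0.65, Dc = 0.71, Ie = interparticle_porosity(0.65, 0.71),
    Ic = carr_index(0.65, 0.71), Icd = 150, IH = hausner_ratio(0.65, 0.71),
    alpha = 24, t_flow = 4, HR = 2.9, H = 3.9, Pf = 4.4, Itheta = 0.014,
    DE = 4, DCD = 2, DSD = 2.5)
}

# profile with every parameter at the same raw radius
constant_profile <- function(r, system = "odt") {
  ids <- parameter_registry()$id
  if (system == "classic") {
    ids <- ids[parameter_registry()$classic]
  }
  radius_profile_from_radii("const", setNames(rep(r, length(ids)), ids),
                            system)
}

# tablet_report stand-ins carrying the printed QC metrics of the fixture
# table (enough structure for trend analysis; no raw tablet data exist)
fixture_tablet_reports <- function() {
  tab8 <- load_paper_fixtures()$tablets
  lapply(seq_len(nrow(tab8)), function(i) {
    structure(
      list(trial_id = tab8$trial_id[i],
           crushing_strength_kg = tab8$crushing_strength_kg[i],
           wetting_time_s = tab8$wetting_time_s[i],
           disintegration_time_min = tab8$disintegration_min[i],
           friability_pct = tab8$friability_pct[i],
           Q15 = tab8$Q15[i]),
      class = "tablet_report")
  })
}

fixture_profiles <- function(system = "odt") {
  tab5 <- load_paper_fixtures()$table5
  lapply(names(tab5), function(tr) {
    radius_profile_from_radii(tr, tab5[[tr]], system)
  })
}
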