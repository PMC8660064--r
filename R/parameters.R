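#' Bulk or tapped density from mass and volume
#'
#' @param mass sample mass in grams.
#' @param volume occupied volume in millilitres (bulk volume for Da, tapped
#'   volume for Dc).
#' @return Density in g/mL.
#' @export
#' @examples
#' density_from_mass_volume(100, 250) # 0.4 g/mL
density_from_mass_volume <- function(mass, volume) {
  stopifnot_number(mass, "mass")
  stopifnot_number(volume, "volume")
  if (mass <= 0 || volume <= 0) {
    abort_invalid_measurement("mass and volume must be strictly positive")
  }
  mass / volume
}

#' Inter-particle porosity
#'
#' `Ie = (Dc - Da) / (Dc * Da)`: the pore volume between particles per unit
#' solid-phase volume, from bulk density `Da` and tapped density `Dc`.
#'
#' @param Da bulk density, g/mL.
#' @param Dc tapped density, g/mL (must satisfy `Dc >= Da > 0`).
#' @return Dimensionless porosity, 0 when the densities coincide.
#' @export
interparticle_porosity <- function(Da, Dc) {
  check_density_pair(Da, Dc)
  (Dc - Da) / (Dc * Da)
}

#' Carr's compressibility index
#'
#' `Ic = 100 * (Dc - Da) / Dc`, the percent volume reduction on tapping.
#'
#' @inheritParams interparticle_porosity
#' @return Percent in `[0, 100)`.
#' @export
carr_index <- function(Da, Dc) {
  check_density_pair(Da, Dc)
  100 * (Dc - Da) / Dc
}

#' Hausner ratio
#'
#' `IH = Dc / Da`, a flowability descriptor (1 = free flowing).
#'
#' @inheritParams interparticle_porosity
#' @return Dimensionless ratio `>= 1`.
#' @export
hausner_ratio <- function(Da, Dc) {
  check_density_pair(Da, Dc)
  Dc / Da
}

check_density_pair <- function(Da, Dc) {
  stopifnot_number(Da, "Da")
  stopifnot_number(Dc, "Dc")
  if (Da <= 0) abort_invalid_measurement("bulk density must be positive")
  if (Da > Dc) {
    abort_invalid_measurement("tapped density must be >= bulk density")
  }
  invisible(NULL)
}

#' Angle of repose from the poured cone
#'
#' `alpha = atan(h / r)` in degrees, from the cone height and base radius
#' measured in the same length unit.
#'
#' @param height cone height (mm).
#' @param radius cone base radius (mm), strictly positive.
#' @return Angle in degrees, in `[0, 90)`.
#' @export
#' @examples
#' angle_of_repose(20, 40) # atan(0.5) = 26.57 deg
angle_of_repose <- function(height, radius) {
  stopifnot_number(height, "height")
  stopifnot_number(radius, "radius")
  if (radius <= 0) abort_invalid_measurement("cone radius must be positive")
  if (height < 0) abort_invalid_measurement("cone height must be non-negative")
  atan(height / radius) * 180 / pi
}

#' Cohesion index
#'
#' Mean crushing strength (newtons) of compacts prepared at maximal pressure
#' without capping or lamination; nominally the mean of n = 10 compacts.
#'
#' @param compact_strengths numeric vector of crushing strengths, newtons.
#' @return Mean strength, newtons.
#' @export
cohesion_index <- function(compact_strengths) {
  if (length(compact_strengths) == 0) {
    abort_insufficient_data("cohesion index needs at least one compact strength")
  }
  if (any(!is.finite(compact_strengths)) || any(compact_strengths < 0)) {
    abort_invalid_measurement("compact strengths must be finite and non-negative")
  }
  mean(compact_strengths)
}

#' Convert kilogram-force to newtons
#'
#' Hardness testers commonly report kg-force; the cohesion index is defined in
#' newtons (standard gravity conversion, 9.80665 N/kgf).
#'
#' @param kgf numeric vector in kilogram-force.
#' @return The same forces in newtons.
#' @export
kgf_to_newton <- function(kgf) kgf * 9.80665

#' Granulometric homogeneity index
#'
#' `Itheta = Fm / (100 + sum(dd_mn * Fn))` where `Fm` is the percent mass in
#' the majority sieve fraction, `Fn` the percent mass in each other fraction
#' and `dd_mn` the absolute difference (micrometres) between the mean diameter
#' of the majority fraction and that of fraction n.  A perfectly homogeneous
#' granulate (all mass in one fraction) gives `Fm / 100`; broad distributions
#' give values well below the 0.02 scoring ceiling.
#'
#' @param fractions a [sieve_fractions()] object.
#' @return Dimensionless homogeneity index, > 0.
#' @export
#' @examples
#' sf <- sieve_fractions(c(850, 600, 425, 300, 250, 50),
#'                       c(0, 0, 60, 40, 0, 0), 0)
#' homogeneity_index(sf) # 60 / (100 + 150 * 40)
homogeneity_index <- function(fractions) {
  if (!inherits(fractions, "sieve_fractions")) {
    abort_validation("fractions must be a sieve_fractions object")
  }
  pct <- c(fractions$percent_retained, fractions$pan_percent)
  dia <- fractions$mean_diameter
  if (all(pct == 0)) abort_insufficient_data("all sieve fractions are empty")
  top <- which(pct == max(pct))
  if (length(top) > 1L) {
    # tie broken toward the coarser fraction (diameters are ordered decreasing)
    top <- top[which.max(dia[top])]
    message("homogeneity_index: majority-fraction tie broken toward ",
            sprintf("%.1f um", dia[top]))
  }
  others <- setdiff(seq_along(pct), top)
  pct[top] / (100 + sum(abs(dia[others] - dia[top]) * pct[others]))
}

#' Assemble the 15 basic parameters of a batch
#'
#' Applies every single-purpose parameter operation to one batch's raw
#' measurements and returns the complete experimental-value vector V.
#' Replicate lists (compact strengths, effervescence and disintegration
#' times) are aggregated by arithmetic mean.
#'
#' @param m a [raw_measurements()] object.
#' @return An object of class `basic_parameters`: a named list with
#'   `batch_id` and the 15 values `Da`, `Dc`, `Ie`, `Ic`, `Icd`, `IH`,
#'   `alpha`, `t_flow`, `HR`, `H`, `Pf`, `Itheta`, `DE`, `DCD`, `DSD`
#'   (units per [parameter_registry()]).
#' @export
assemble_basic_parameters <- function(m) {
  if (!inherits(m, "raw_measurements")) {
    abort_validation("m must be a raw_measurements object")
  }
  # which raw fields feed which parameters, for precise error reporting
  needs <- list(
    granule_mass = c("Da", "Dc", "Ie", "Ic", "IH"),
    bulk_volume = c("Da", "Ie", "Ic", "IH"),
    tapped_volume = c("Dc", "Ie", "Ic", "IH"),
    cone_height = "alpha", cone_radius = "alpha",
    flow_time = "t_flow",
    loss_on_drying_pct = "HR",
    hygroscopicity_pct = "H",
    compact_strengths = "Icd",
    sieve = "Itheta",
    percent_fines = "Pf",
    effervescence_times = "DE",
    disint_disk_times = "DCD",
    disint_nodisk_times = "DSD"
  )
  missing <- names(needs)[vapply(names(needs), function(f) is.null(m[[f]]),
                                 logical(1))]
  if (length(missing)) {
    affected <- sort(unique(unlist(needs[missing])))
    abort_missing_field(sprintf(
      "missing raw field(s) %s; cannot compute parameter(s) %s",
      paste(missing, collapse = ", "), paste(affected, collapse = ", ")))
  }
  Da <- density_from_mass_volume(m$granule_mass, m$bulk_volume)
  Dc <- density_from_mass_volume(m$granule_mass, m$tapped_volume)
  structure(
    list(batch_id = m$batch_id,
         Da = Da, Dc = Dc,
         Ie = interparticle_porosity(Da, Dc),
         Ic = carr_index(Da, Dc),
         Icd = cohesion_index(m$compact_strengths),
         IH = hausner_ratio(Da, Dc),
         alpha = angle_of_repose(m$cone_height, m$cone_radius),
         t_flow = m$flow_time,
         HR = m$loss_on_drying_pct,
         H = m$hygroscopicity_pct,
         Pf = m$percent_fines,
         Itheta = homogeneity_index(m$sieve),
         DE = mean(m$effervescence_times),
         DCD = mean(m$disint_disk_times),
         DSD = mean(m$disint_nodisk_times)),
    class = "basic_parameters"
  )
}

#' Construct a basic-parameter set directly
#'
#' For workflows that start from already-computed experimental values (for
#' example literature tables) rather than raw bench measurements.
#'
#' @param batch_id batch label.
#' @param ... the 15 named values `Da` ... `DSD`; any subset is accepted, but
#'   profile building will require the parameters of the chosen system.
#' @return A `basic_parameters` object.
#' @export
basic_parameters <- function(batch_id, ...) {
  vals <- list(...)
  ids <- parameter_registry()$id
  bad <- setdiff(names(vals), ids)
  if (length(bad)) {
    abort_registry(sprintf("unknown parameter id(s): %s",
                           paste(bad, collapse = ", ")))
  }
  out <- c(list(batch_id = batch_id),
           stats::setNames(vals[intersect(ids, names(vals))],
                           intersect(ids, names(vals))))
  structure(out, class = "basic_parameters")
}

#' @export
print.basic_parameters <- function(x, ...) {
  ids <- setdiff(names(x), "batch_id")
  cat("<basic_parameters> batch", x$batch_id, "\n")
  vals <- unlist(x[ids])
  print(round(vals, 4))
  invisible(x)
}
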