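#' Sieve analysis of a granulate
#'
#' Holds the percent of mass retained on each test sieve (descending aperture)
#' plus the pan fraction passing the finest sieve.  The standard stack for the
#' homogeneity determination is 850, 600, 425, 300, 250 and 50 micrometres.
#'
#' Each retained fraction is assigned a mean particle diameter: the midpoint of
#' its bounding apertures for interior fractions, the top aperture itself for
#' material retained on the coarsest sieve (no upper bound is observed), and
#' half the finest aperture for the pan (25 um for a 50 um bottom sieve).
#'
#' @param apertures numeric vector of sieve apertures in micrometres, strictly
#'   decreasing.
#' @param percent_retained percent of mass retained on each sieve, same length
#'   as `apertures`, non-negative.
#' @param pan_percent percent of mass passing the finest sieve.
#' @return An object of class `sieve_fractions`: a list with the validated
#'   inputs (renormalised to total exactly 100) and the per-fraction
#'   `mean_diameter` vector (pan last).
#' @export
#' @examples
#' sf <- sieve_fractions(c(850, 600, 425, 300, 250, 50),
#'                       c(2, 10, 62, 16, 6, 3), pan_percent = 1)
#' sf$mean_diameter
sieve_fractions <- function(apertures, percent_retained, pan_percent = 0) {
  if (length(apertures) == 0 || length(apertures) != length(percent_retained)) {
    abort_validation("apertures and percent_retained must have equal, positive length")
  }
  if (any(diff(apertures) >= 0)) {
    abort_validation("sieve apertures must be strictly decreasing")
  }
  pct <- c(percent_retained, pan_percent)
  if (any(!is.finite(pct)) || any(pct < 0)) {
    abort_validation("sieve percentages must be finite and non-negative")
  }
  total <- sum(pct)
  if (abs(total - 100) > 0.5) {
    abort_validation(sprintf(
      "sieve percentages must total 100 +/- 0.5 (got %.3f)", total))
  }
  # first entry is the top fraction, interior midpoints follow, pan last
  mean_diameter <- c(apertures[1],
                     (utils::head(apertures, -1) + apertures[-1]) / 2,
                     apertures[length(apertures)] / 2)
  structure(
    list(apertures = apertures,
         percent_retained = 100 * percent_retained / total,
         pan_percent = 100 * pan_percent / total,
         mean_diameter = mean_diameter),
    class = "sieve_fractions"
  )
}

#' Raw bench measurements for one batch
#'
#' The entry point of the granule pipeline: one batch's raw laboratory
#' observations, from which the 15 basic parameters are derived.  Fields that
#' were not measured may be left `NULL`; downstream assembly reports exactly
#' which parameters become uncomputable.
#'
#' @param batch_id character label for the batch.
#' @param granule_mass mass of the density test sample, grams.
#' @param bulk_volume poured (bulk) volume of that mass, millilitres.
#' @param tapped_volume volume after tapping to constancy, millilitres
#'   (must not exceed `bulk_volume`).
#' @param cone_height,cone_radius height and base radius of the poured cone
#'   for angle of repose, both millimetres.
#' @param flow_time seconds for 100 g to discharge through the funnel.
#' @param loss_on_drying_pct percent weight loss on drying.
#' @param hygroscopicity_pct percent weight gain after 24 h at high humidity.
#' @param compact_strengths crushing strengths of compacts, newtons
#'   (nominally n = 10).
#' @param sieve a [sieve_fractions()] object.
#' @param percent_fines percent of particles below 50 micrometres.
#' @param effervescence_times compact disintegration times in a quiescent
#'   beaker, minutes (nominally n = 6).
#' @param disint_disk_times,disint_nodisk_times compact disintegration times
#'   with and without disk, minutes (nominally n = 6).
#' @return An object of class `raw_measurements`.
#' @export
raw_measurements <- function(batch_id,
                             granule_mass = NULL,
                             bulk_volume = NULL,
                             tapped_volume = NULL,
                             cone_height = NULL,
                             cone_radius = NULL,
                             flow_time = NULL,
                             loss_on_drying_pct = NULL,
                             hygroscopicity_pct = NULL,
                             compact_strengths = NULL,
                             sieve = NULL,
                             percent_fines = NULL,
                             effervescence_times = NULL,
                             disint_disk_times = NULL,
                             disint_nodisk_times = NULL) {
  if (!is.character(batch_id) || length(batch_id) != 1L || !nzchar(batch_id)) {
    abort_validation("batch_id must be a non-empty string")
  }
  check_pos <- function(x, what, strict = TRUE) {
    if (is.null(x)) return(invisible(NULL))
    if (any(!is.finite(x)) || (strict && any(x <= 0)) || (!strict && any(x < 0))) {
      abort_invalid_measurement(sprintf(
        "%s must be finite and %s", what, if (strict) "strictly positive" else "non-negative"))
    }
  }
  check_pos(granule_mass, "granule_mass")
  check_pos(bulk_volume, "bulk_volume")
  check_pos(tapped_volume, "tapped_volume")
  check_pos(cone_height, "cone_height", strict = FALSE)
  check_pos(cone_radius, "cone_radius")
  check_pos(flow_time, "flow_time")
  check_pos(loss_on_drying_pct, "loss_on_drying_pct", strict = FALSE)
  check_pos(hygroscopicity_pct, "hygroscopicity_pct", strict = FALSE)
  check_pos(compact_strengths, "compact_strengths", strict = FALSE)
  check_pos(percent_fines, "percent_fines", strict = FALSE)
  check_pos(effervescence_times, "effervescence_times", strict = FALSE)
  check_pos(disint_disk_times, "disint_disk_times", strict = FALSE)
  check_pos(disint_nodisk_times, "disint_nodisk_times", strict = FALSE)
  if (!is.null(bulk_volume) && !is.null(tapped_volume) &&
      tapped_volume > bulk_volume) {
    abort_invalid_measurement("tapped_volume must not exceed bulk_volume")
  }
  if (!is.null(sieve) && !inherits(sieve, "sieve_fractions")) {
    abort_validation("sieve must be a sieve_fractions object")
  }
  structure(
    list(batch_id = batch_id,
         granule_mass = granule_mass,
         bulk_volume = bulk_volume,
         tapped_volume = tapped_volume,
         cone_height = cone_height,
         cone_radius = cone_radius,
         flow_time = flow_time,
         loss_on_drying_pct = loss_on_drying_pct,
         hygroscopicity_pct = hygroscopicity_pct,
         compact_strengths = compact_strengths,
         sieve = sieve,
         percent_fines = percent_fines,
         effervescence_times = effervescence_times,
         disint_disk_times = disint_disk_times,
         disint_nodisk_times = disint_nodisk_times),
    class = "raw_measurements"
  )
}

#' @export
print.raw_measurements <- function(x, ...) {
  measured <- names(x)[!vapply(x, is.null, logical(1))]
  cat("<raw_measurements> batch", x$batch_id, "-",
      length(measured) - 1L, "field(s) present\n")
  invisible(x)
}
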