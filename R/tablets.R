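#' Diametral tensile strength of a flat-faced tablet
#'
#' `Ts = 2F / (pi * D * H)` for crushing force F (kg), tablet diameter D (mm)
#' and thickness H (mm).
#'
#' @param F crushing strength, kg-force.
#' @param D tablet diameter, mm.
#' @param H tablet thickness, mm.
#' @return Tensile strength, kg/mm^2.
#' @export
#' @examples
#' tensile_strength(12.07, 10.5, 3.34) # 0.219 kg/mm^2
tensile_strength <- function(F, D, H) {
  check_tablet_dims(F, D, H)
  2 * F / (pi * D * H)
}

#' Specific crushing strength
#'
#' `tau = F / (H * D)`: crushing force normalised by the diametral section.
#' For any tablet `Ts / tau = 2 / pi`.
#'
#' @inheritParams tensile_strength
#' @return Specific crushing strength, kg/mm^2.
#' @export
specific_crushing_strength <- function(F, D, H) {
  check_tablet_dims(F, D, H)
  F / (H * D)
}

check_tablet_dims <- function(F, D, H) {
  for (v in list(F = F, D = D, H = H)) {
    if (!is_number(v) || v <= 0) {
      abort_invalid_measurement("F, D and H must be single positive numbers")
    }
  }
  invisible(NULL)
}

#' Friability
#'
#' Percent weight loss of a de-dusted tablet sample after tumbling:
#' `100 * (before - after) / before`.  The compendial acceptance limit is
#' a loss below 1 %.
#'
#' @param mass_before,mass_after sample mass (g) before and after tumbling.
#' @return A list with `percent_loss` and logical `pass` (loss < 1 %).
#' @export
friability <- function(mass_before, mass_after) {
  stopifnot_number(mass_before, "mass_before")
  stopifnot_number(mass_after, "mass_after")
  if (mass_before <= 0 || mass_after <= 0 || mass_after > mass_before) {
    abort_invalid_measurement(
      "need 0 < mass_after <= mass_before for a friability test")
  }
  loss <- 100 * (mass_before - mass_after) / mass_before
  list(percent_loss = loss, pass = loss < 1)
}

#' Weight variation
#'
#' Mean tablet weight and the largest percent deviation of any individual
#' tablet from that mean.
#'
#' @param weights individual tablet weights, mg (at least 2).
#' @return A list with `mean_mg` and `max_deviation_pct`.
#' @export
weight_variation <- function(weights) {
  if (length(weights) < 2) {
    abort_insufficient_data("weight variation needs at least 2 tablets")
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort_invalid_measurement("weights must be finite and positive")
  }
  m <- mean(weights)
  list(mean_mg = m, max_deviation_pct = max(abs(weights - m)) / m * 100)
}

#' Drug content by external-standard peak-area ratio
#'
#' `100 * area_sample / area_standard`, with the compendial pass window of
#' 98-101 % of the label claim applied as a flag.
#'
#' @param peak_area_sample,peak_area_standard chromatographic peak areas of
#'   equally concentrated sample and standard injections.
#' @return A list with `percent` and logical `pass` (98-101 %).
#' @export
drug_content <- function(peak_area_sample, peak_area_standard) {
  stopifnot_number(peak_area_sample, "peak_area_sample")
  stopifnot_number(peak_area_standard, "peak_area_standard")
  if (peak_area_standard <= 0 || peak_area_sample < 0) {
    abort_invalid_measurement("peak areas must be positive (standard > 0)")
  }
  pct <- 100 * peak_area_sample / peak_area_standard
  list(percent = pct, pass = pct >= 98 && pct <= 101)
}

#' Cumulative dissolution profile with sampling-volume correction
#'
#' Converts sampled concentrations into cumulative percent released.  Each
#' withdrawal removes drug from the vessel (the same volume of fresh medium is
#' returned), so the cumulative amount at time t is
#' `C_t * V_media + sum_(i<t) C_i * V_sample`, expressed as percent of the
#' label claim.  Set `correct_withdrawal = FALSE` to report the naive
#' `C_t * V_media` percentage.
#'
#' @param times sampling times, minutes, strictly increasing.
#' @param concentrations measured concentrations at `times`, mg/mL.
#' @param media_volume vessel volume, mL (compendial default 900).
#' @param sample_volume withdrawn aliquot, mL.
#' @param label_claim drug per tablet, mg.
#' @param correct_withdrawal apply the withdrawn-mass correction (default).
#' @return A data.frame with columns `time` and `Q` (cumulative percent
#'   released), with attribute `Q15` (the value at t = 15 min, or `NA` if not
#'   sampled).
#' @export
#' @examples
#' dissolution_profile(c(0, 5, 15), c(0, 0.05, 0.0883),
#'                     media_volume = 900, sample_volume = 10,
#'                     label_claim = 100)
dissolution_profile <- function(times, concentrations, media_volume = 900,
                                sample_volume = 10, label_claim = 100,
                                correct_withdrawal = TRUE) {
  if (length(times) != length(concentrations) || length(times) == 0) {
    abort_validation("times and concentrations must have equal positive length")
  }
  if (any(diff(times) <= 0)) {
    abort_validation("sampling times must be strictly increasing")
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    abort_invalid_measurement("concentrations must be finite and non-negative")
  }
  for (v in list(media_volume, sample_volume, label_claim)) {
    if (!is_number(v) || v <= 0) {
      abort_invalid_measurement("volumes and label claim must be positive")
    }
  }
  withdrawn <- if (correct_withdrawal) {
    c(0, cumsum(concentrations * sample_volume)[-length(concentrations)])
  } else {
    rep(0, length(concentrations))
  }
  Q <- 100 * (concentrations * media_volume + withdrawn) / label_claim
  out <- data.frame(time = times, Q = Q)
  attr(out, "Q15") <- if (any(times == 15)) Q[times == 15] else NA_real_
  out
}

#' Tablet QC record for one trial
#'
#' Container for the per-trial tablet measurements consumed by
#' [tablet_report()].
#'
#' @param trial_id trial label.
#' @param crushing_strengths individual crushing strengths, kg-force.
#' @param diameter punch/tablet diameter, mm (a per-trial constant).
#' @param thicknesses individual tablet thicknesses, mm.
#' @param individual_weights individual tablet weights, mg.
#' @param friability_mass_before,friability_mass_after friability sample mass
#'   (g) before and after tumbling.
#' @param wetting_times wetting times, seconds.
#' @param disintegration_times tablet disintegration times, minutes.
#' @param peak_area_sample,peak_area_standard HPLC peak areas for assay.
#' @param dissolution_times,dissolution_concentrations sampled dissolution
#'   time points (min) and concentrations (mg/mL).
#' @param media_volume,sample_volume dissolution vessel and aliquot volumes, mL.
#' @param label_claim mg of drug per tablet.
#' @return An object of class `tablet_batch`.
#' @export
tablet_batch <- function(trial_id, crushing_strengths, diameter, thicknesses,
                         individual_weights, friability_mass_before,
                         friability_mass_after, wetting_times,
                         disintegration_times, peak_area_sample,
                         peak_area_standard, dissolution_times,
                         dissolution_concentrations, media_volume = 900,
                         sample_volume = 10, label_claim = 100) {
  if (!is.character(trial_id) || length(trial_id) != 1L) {
    abort_validation("trial_id must be a string")
  }
  structure(as.list(environment()), class = "tablet_batch")
}

#' Full tablet QC report
#'
#' Derives every tablet metric from a [tablet_batch()]: tensile and specific
#' crushing strength (from mean hardness and mean thickness at the trial's
#' punch diameter), friability, weight variation, drug content, wetting and
#' disintegration summaries and the dissolution profile with Q15.
#'
#' @param batch a `tablet_batch`.
#' @param correct_withdrawal passed to [dissolution_profile()].
#' @return An object of class `tablet_report` (a named list of metrics and
#'   pass/fail flags).
#' @export
tablet_report <- function(batch, correct_withdrawal = TRUE) {
  if (!inherits(batch, "tablet_batch")) {
    abort_validation("batch must be a tablet_batch object")
  }
  F_mean <- mean(batch$crushing_strengths)
  H_mean <- mean(batch$thicknesses)
  fri <- friability(batch$friability_mass_before, batch$friability_mass_after)
  wv <- weight_variation(batch$individual_weights)
  dc <- drug_content(batch$peak_area_sample, batch$peak_area_standard)
  diss <- dissolution_profile(batch$dissolution_times,
                              batch$dissolution_concentrations,
                              batch$media_volume, batch$sample_volume,
                              batch$label_claim, correct_withdrawal)
  structure(
    list(trial_id = batch$trial_id,
         crushing_strength_kg = F_mean,
         thickness_mm = H_mean,
         diameter_mm = batch$diameter,
         tensile_strength = tensile_strength(F_mean, batch$diameter, H_mean),
         specific_crushing_strength =
           specific_crushing_strength(F_mean, batch$diameter, H_mean),
         friability_pct = fri$percent_loss,
         friability_pass = fri$pass,
         weight_mean_mg = wv$mean_mg,
         weight_max_deviation_pct = wv$max_deviation_pct,
         drug_content_pct = dc$percent,
         drug_content_pass = dc$pass,
         wetting_time_s = mean(batch$wetting_times),
         disintegration_time_min = mean(batch$disintegration_times),
         dissolution = diss,
         Q15 = attr(diss, "Q15")),
    class = "tablet_report"
  )
}

#' @export
print.tablet_report <- function(x, ...) {
  cat(sprintf("<tablet_report> %s\n", x$trial_id))
  cat(sprintf("  crushing %.2f kg | Ts %.3f | tau %.3f kg/mm^2\n",
              x$crushing_strength_kg, x$tensile_strength,
              x$specific_crushing_strength))
  cat(sprintf("  friability %.2f%% (%s) | content %.2f%% (%s)\n",
              x$friability_pct, if (x$friability_pass) "pass" else "FAIL",
              x$drug_content_pct, if (x$drug_content_pass) "pass" else "FAIL"))
  cat(sprintf("  disintegration %.2f min | Q15 %.2f%%\n",
              x$disintegration_time_min, x$Q15))
  invisible(x)
}
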