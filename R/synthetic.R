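#' Two-factor wet-granulation trial design
#'
#' The default layout is the studied 13-run design: granulation time and
#' binder concentration each at three levels, five centre-point replicates
#' (Trials 1, 3, 4, 6, 7) and one run at each of the eight remaining level
#' combinations.
#'
#' @param time_levels actual granulation times (s) for coded -1/0/+1;
#'   exactly 3 values for the default layout.
#' @param binder_levels actual binder concentrations (%w/w) for coded
#'   -1/0/+1; exactly 3 values.
#' @param layout `"default"` (the 13 printed runs) or `"full_factorial"`
#'   (one run per level combination, any number of levels).
#' @return data.frame with `trial_id`, `time_coded`, `time_s`,
#'   `binder_coded`, `binder_pct`.
#' @export
#' @examples
#' build_design()          # 13 runs
#' build_design(layout = "full_factorial") # 9 runs
build_design <- function(time_levels = c(30, 45, 60),
                         binder_levels = c(5, 10, 15),
                         layout = c("default", "full_factorial")) {
  layout <- match.arg(layout)
  if (layout == "default") {
    if (length(time_levels) != 3 || length(binder_levels) != 3) {
      abort_validation("the default 13-run layout requires 3 levels per factor")
    }
    tc <- c(0, 1, 0, 0, 1, 0, 0, -1, -1, 0, 1, -1, 0)
    bc <- c(0, -1, 0, 0, 1, 0, 0, -1, 1, -1, 0, 0, 1)
    data.frame(trial_id = paste0("Trial-", seq_along(tc)),
               time_coded = tc, time_s = time_levels[tc + 2],
               binder_coded = bc, binder_pct = binder_levels[bc + 2],
               stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(time_i = seq_along(time_levels),
                        binder_i = seq_along(binder_levels))
    code <- function(i, k) if (k > 1) 2 * (i - 1) / (k - 1) - 1 else 0
    data.frame(trial_id = paste0("Run-", seq_len(nrow(grid))),
               time_coded = code(grid$time_i, length(time_levels)),
               time_s = time_levels[grid$time_i],
               binder_coded = code(grid$binder_i, length(binder_levels)),
               binder_pct = binder_levels[grid$binder_i],
               stringsAsFactors = FALSE)
  }
}

#' Default response effects for the synthetic study
#'
#' One row per latent response: baseline at the centre point, linear slopes
#' per coded unit of binder concentration and granulation time, the
#' between-trial noise SD, and physical truncation bounds.  Signs encode the
#' stated process behaviour: more binder and longer granulation increase
#' densification, cohesion, wetting and disintegration times and decrease
#' flow time, fines and the 15-minute release.  Magnitudes are set so the
#' simulated granule scores span roughly the observed 4.4-5.5 ODT-IPP band.
#'
#' @return data.frame with columns `response`, `base`, `b_binder`, `b_time`,
#'   `sd`, `lo`, `hi`.
#' @export
default_effects <- function() {
  df <- utils::read.csv(text = "
response,base,b_binder,b_time,sd,lo,hi
bulk_density,0.63,0.045,0.025,0.012,0.2,1
hausner,1.07,-0.012,-0.006,0.008,1.0005,1.6
cohesion_N,128,28,14,5,5,200
flow_time_s,4.2,-0.6,-0.35,0.3,0.5,20
angle_deg,25,-1.2,-0.6,0.8,5,50
lod_pct,2.8,0.08,0.04,0.12,0.2,10
hygro_pct,3.9,0.1,0.05,0.15,0.2,20
fines_pct,5.5,-0.9,-0.5,0.4,0.2,50
majority_pct,72,3,2,1.5,40,95
DE_min,7.8,1.5,1.0,0.5,0.5,30
DCD_min,3.4,0.9,0.55,0.35,0.2,30
DSD_min,5.5,1.5,1.0,0.45,0.3,40
tablet_crush_kg,8.7,2.2,1.1,0.45,1,25
thickness_mm,3.5,-0.1,-0.05,0.04,2.5,4.5
friability_pct,0.55,-0.18,-0.09,0.07,0.03,3
wetting_s,185,32,16,8,30,600
tablet_disint_min,9.0,1.6,0.9,0.5,1,30
Q15_pct,58,-16,-7,2,5,91
content_pct,99.4,0,0,0.5,97,102
", stringsAsFactors = FALSE)
  df$response <- trimws(df$response)
  df
}

#' Configuration of the synthetic study generator
#'
#' @param effects effects table in the [default_effects()] layout.
#' @param noise_scale multiplier applied to every SD (between-trial and
#'   within-trial); 0 gives a fully deterministic, exactly linear study.
#' @param slope_scale multiplier applied to every slope; -1 inverts all
#'   effect directions.
#' @return An `effect_config` list.
#' @export
effect_config <- function(effects = default_effects(), noise_scale = 1,
                          slope_scale = 1) {
  need <- c("response", "base", "b_binder", "b_time", "sd", "lo", "hi")
  if (!all(need %in% names(effects))) {
    abort_validation("effects must have the default_effects() columns")
  }
  if (!is_number(noise_scale) || noise_scale < 0) {
    abort_validation("noise_scale must be a non-negative number")
  }
  effects$sd <- effects$sd * noise_scale
  effects$b_binder <- effects$b_binder * slope_scale
  effects$b_time <- effects$b_time * slope_scale
  structure(list(effects = effects, noise_scale = noise_scale),
            class = "effect_config")
}

# deterministic per-trial sub-seed: adding trials never perturbs earlier ones
trial_seed <- function(seed, index) {
  (as.integer(seed) %% 100000L) * 20011L + index
}

#' Simulate one granulation trial
#'
#' Draws the latent trial-level responses as baseline + slope x coded level +
#' Gaussian noise (truncated to the configured physical bounds), then
#' synthesises a full raw-measurement record and tablet QC record around
#' them, with replicate-level noise scaled by the same `noise_scale`.
#'
#' @param design_row one row of [build_design()].
#' @param cfg an [effect_config()].
#' @param seed integer seed for this trial (see [simulate_study()] for the
#'   master-seed scheme).
#' @return List with elements `measurements` ([raw_measurements()]) and
#'   `tablets` ([tablet_batch()]).
#' @export
simulate_trial <- function(design_row, cfg = effect_config(), seed = 1L) {
  set.seed(seed)
  ef <- cfg$effects
  mu <- ef$base + ef$b_binder * design_row$binder_coded +
    ef$b_time * design_row$time_coded
  lat <- pmin(ef$hi, pmax(ef$lo, stats::rnorm(nrow(ef), mu, ef$sd)))
  names(lat) <- ef$response
  ns <- cfg$noise_scale
  reps <- function(n, mean, sd, lo = 0) {
    pmax(lo, mean + stats::rnorm(n, 0, sd * ns))
  }

  bulk_volume <- 100 / lat[["bulk_density"]]
  tapped_volume <- bulk_volume / lat[["hausner"]]
  cone_radius <- 40
  cone_height <- cone_radius * tan(lat[["angle_deg"]] * pi / 180)

  # remainder of the sieve mass split over the non-majority fractions
  rem_w <- c(0.03, 0.12, 0.55, 0.20, 0.07, 0.03)
  Fm <- lat[["majority_pct"]]
  rem <- (100 - Fm) * rem_w / sum(rem_w)
  sieve <- sieve_fractions(
    apertures = c(850, 600, 425, 300, 250, 50),
    percent_retained = c(rem[1], rem[2], Fm, rem[3], rem[4], rem[5]),
    pan_percent = rem[6])

  m <- raw_measurements(
    batch_id = design_row$trial_id,
    granule_mass = 100,
    bulk_volume = bulk_volume,
    tapped_volume = tapped_volume,
    cone_height = cone_height,
    cone_radius = cone_radius,
    flow_time = lat[["flow_time_s"]],
    loss_on_drying_pct = lat[["lod_pct"]],
    hygroscopicity_pct = lat[["hygro_pct"]],
    compact_strengths = reps(10, lat[["cohesion_N"]], 4),
    sieve = sieve,
    percent_fines = lat[["fines_pct"]],
    effervescence_times = reps(6, lat[["DE_min"]], 0.3, lo = 0.1),
    disint_disk_times = reps(6, lat[["DCD_min"]], 0.2, lo = 0.1),
    disint_nodisk_times = reps(6, lat[["DSD_min"]], 0.3, lo = 0.1))

  # dissolution: first-order release anchored on the latent Q15, sampled at
  # the compendial points and converted back to vessel concentrations
  times <- c(0, 5, 15, 30, 60)
  claim <- 100; v_media <- 900; v_sample <- 10
  q_inf <- 92
  k <- -log(1 - lat[["Q15_pct"]] / q_inf) / 15
  Q <- q_inf * (1 - exp(-k * times))
  conc <- numeric(length(times))
  for (i in seq_along(times)) {
    withdrawn <- if (i > 1) sum(conc[seq_len(i - 1)] * v_sample) else 0
    conc[i] <- (claim * Q[i] / 100 - withdrawn) / v_media
  }
  conc <- pmax(conc, 0)

  fri_before <- 6.5
  tb <- tablet_batch(
    trial_id = design_row$trial_id,
    crushing_strengths = reps(10, lat[["tablet_crush_kg"]], 0.5, lo = 0.2),
    diameter = 10.5,
    thicknesses = reps(10, lat[["thickness_mm"]], 0.05, lo = 2),
    individual_weights = reps(20, 254, 2.5, lo = 200),
    friability_mass_before = fri_before,
    friability_mass_after = fri_before * (1 - lat[["friability_pct"]] / 100),
    wetting_times = reps(3, lat[["wetting_s"]], 8, lo = 5),
    disintegration_times = reps(6, lat[["tablet_disint_min"]], 0.5, lo = 0.5),
    peak_area_sample = 10 * lat[["content_pct"]],
    peak_area_standard = 1000,
    dissolution_times = times,
    dissolution_concentrations = conc,
    media_volume = v_media,
    sample_volume = v_sample,
    label_claim = claim)

  list(measurements = m, tablets = tb)
}

#' Simulate a full granulation study
#'
#' Runs [simulate_trial()] for every design row.  Each trial gets the
#' deterministic sub-seed `(seed mod 1e5) * 20011 + trial index`, so a fixed
#' master seed reproduces the study exactly and appending trials never
#' changes earlier ones.
#'
#' @param design a [build_design()] frame.
#' @param cfg an [effect_config()].
#' @param seed master integer seed.
#' @return List with `design`, `measurements` (list) and `tablets` (list).
#' @export
simulate_study <- function(design = build_design(), cfg = effect_config(),
                           seed = 1L) {
  sims <- lapply(seq_len(nrow(design)), function(i) {
    simulate_trial(design[i, ], cfg, trial_seed(seed, i))
  })
  list(design = design,
       measurements = lapply(sims, `[[`, "measurements"),
       tablets = lapply(sims, `[[`, "tablets"))
}

#' Effect-sign recovery check
#'
#' Runs the full pipeline (parameters -> radii -> indices -> tablet QC) on a
#' simulated study and verifies that each stated process effect is recovered
#' as the sign of the Spearman correlation between the coded factor level and
#' the measured response across trials: binder and time increase the cohesion
#' index and tablet disintegration time and decrease Q15.
#'
#' @param study output of [simulate_study()] (at least 9 trials).
#' @param expected data.frame with `factor`, `response`, `sign` overriding
#'   the default six-check matrix.
#' @return data.frame of checks with observed `rho` and logical `recovered`;
#'   attribute `"pass"` is TRUE when every sign is recovered.
#' @export
recovery_check <- function(study, expected = NULL) {
  if (length(study$measurements) < 9) {
    abort_validation("recovery check needs at least 9 trials")
  }
  if (is.null(expected)) {
    expected <- data.frame(
      factor = rep(c("binder_coded", "time_coded"), each = 3),
      response = rep(c("cohesion", "disintegration", "Q15"), 2),
      sign = rep(c(1, 1, -1), 2),
      stringsAsFactors = FALSE)
  }
  params <- lapply(study$measurements, assemble_basic_parameters)
  treports <- lapply(study$tablets, tablet_report)
  obs <- list(
    cohesion = vapply(params, function(p) p$Icd, numeric(1)),
    disintegration = vapply(treports, function(t) t$disintegration_time_min,
                            numeric(1)),
    Q15 = vapply(treports, function(t) t$Q15, numeric(1)))
  expected$rho <- NA_real_
  for (i in seq_len(nrow(expected))) {
    expected$rho[i] <- rank_correlation(study$design[[expected$factor[i]]],
                                        obs[[expected$response[i]]])
  }
  expected$recovered <- sign(expected$rho) == expected$sign
  attr(expected, "pass") <- all(expected$recovered)
  expected
}
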