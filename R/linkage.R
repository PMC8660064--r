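#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties — the package's standard
#' measure for granule-to-tablet monotone trends (the underlying claims are
#' ordinal, so rank correlation is preferred over Pearson).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in `[-1, 1]`.
#' @export
#' @examples
#' rank_correlation(1:5, c(2, 4, 5, 8, 9)) # 1
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    abort_validation("x and y must have equal length")
  }
  if (length(x) < 3) {
    abort_validation("rank correlation needs at least 3 observations")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_validation("x and y must be finite")
  }
  stats::cor(x, y, method = "spearman")
}

# Expected-sign matrix for the granule -> tablet trend analysis.  Cohesive
# granules press into harder tablets that wet, disintegrate and dissolve
# more slowly; suitability (IGCB) tracks low friability.
trend_matrix <- function() {
  data.frame(
    granule_metric = c("Icd", "Icd", "Icd", "Icd", "IGCB"),
    tablet_metric = c("crushing_strength_kg", "wetting_time_s",
                      "disintegration_time_min", "Q15", "friability_pct"),
    expected_sign = c(1, 1, 1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Granule-to-tablet trend report
#'
#' Computes the rank correlation between granule scores and tablet outcomes
#' for each pair in the expected-sign matrix: cohesion-index radius against
#' crushing strength, wetting time and disintegration time (positive),
#' against Q15 (negative), and IGCB against friability (negative).  A pair
#' agrees when the sign of the observed correlation matches expectation.
#'
#' @param profiles list of `radius_profile` objects (ODT system), one per
#'   trial.
#' @param tablet_reports list of `tablet_report` objects with matching
#'   `trial_id`s.
#' @return An object of class `linkage_report`: data.frame `pairs` with
#'   `granule_metric`, `tablet_metric`, `rho`, `expected_sign`, `agreement`,
#'   plus the per-trial `predictions` (see [predict_attributes()]).
#' @export
trend_report <- function(profiles, tablet_reports) {
  if (length(profiles) < 3) {
    abort_validation("trend analysis needs at least 3 matched trials")
  }
  g_ids <- vapply(profiles, function(p) p$batch_id, character(1))
  t_ids <- vapply(tablet_reports, function(t) t$trial_id, character(1))
  if (!setequal(g_ids, t_ids) || anyDuplicated(g_ids) || anyDuplicated(t_ids)) {
    abort_validation("granule profiles and tablet reports must match 1:1 on trial id")
  }
  tablet_reports <- tablet_reports[match(g_ids, t_ids)]

  icd_r <- vapply(profiles, function(p) {
    p$radii$raw_r[p$radii$id == "Icd"]
  }, numeric(1))
  reports <- lapply(profiles, full_report)
  igcb_v <- vapply(reports, function(r) r$IGCB, numeric(1))
  granule <- list(Icd = icd_r, IGCB = igcb_v)

  pairs <- trend_matrix()
  pairs$rho <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    y <- vapply(tablet_reports, function(t) t[[pairs$tablet_metric[i]]],
                numeric(1))
    pairs$rho[i] <- rank_correlation(granule[[pairs$granule_metric[i]]], y)
  }
  pairs$agreement <- sign(pairs$rho) == pairs$expected_sign
  structure(
    list(pairs = pairs[, c("granule_metric", "tablet_metric", "rho",
                           "expected_sign", "agreement")],
         predictions = lapply(reports, predict_attributes)),
    class = "linkage_report"
  )
}

#' Qualitative predictions from a granule index report
#'
#' Rule-based reading of an index report: the material is predicted suitable
#' for compression when the classic-system good compressibility index reaches
#' 5, and a slow-disintegration warning is raised when the Disgregability
#' incidence falls below 5 (the tablets will need extra disintegrant to meet
#' compendial limits).
#'
#' @param report an `index_report`.  For ODT reports the classic IGC is
#'   recomputed from the non-Disgregability parameters; classic reports are
#'   used as-is (no disintegration call is possible).
#' @param profile optional `radius_profile` backing `report`; required to
#'   derive the classic subset from an ODT report built without one.
#' @return A list with `batch_id`, `igc`, `suitable_for_compression`,
#'   `slow_disintegration_warning` (NA when undeterminable).
#' @export
predict_attributes <- function(report, profile = NULL) {
  if (!inherits(report, "index_report")) {
    abort_validation("report must be an index_report")
  }
  if (report$system == "odt") {
    disg <- unname(report$incidence[["Disgregability"]])
    # classic IGC from the same radii: mean of the 12 clamped radii times f_12
    odt_sum <- report$IPP * report$n_params
    disg_sum <- disg * 3
    igc <- (odt_sum - disg_sum) / 12 * reliability_factor(12)
    warn <- disg < 5
  } else {
    igc <- report$IGCB
    warn <- NA
  }
  list(batch_id = report$batch_id,
       igc = igc,
       suitable_for_compression = igc >= 5,
       slow_disintegration_warning = warn)
}

#' @export
print.linkage_report <- function(x, ...) {
  cat("<linkage_report>\n")
  df <- x$pairs
  df$rho <- round_half_up(df$rho, 3)
  print(df, row.names = FALSE)
  n_warn <- sum(vapply(x$predictions, function(p)
    isTRUE(p$slow_disintegration_warning), logical(1)))
  cat(sprintf("  %d/%d trials predicted suitable for compression, %d with slow-disintegration warning\n",
              sum(vapply(x$predictions, function(p) p$suitable_for_compression,
                         logical(1))),
              length(x$predictions), n_warn))
  invisible(x)
}
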