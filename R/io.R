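# CSV dialect: UTF-8, comma separated, dot decimal, header row required.
# List-valued cells (replicate measurements) are semicolon-separated numbers.

split_numlist <- function(cell, where) {
  parts <- strsplit(as.character(cell), ";", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(vals) == 0 || any(is.na(vals))) {
    abort_validation(sprintf("non-numeric list cell at %s: '%s'", where, cell))
  }
  vals
}

join_numlist <- function(x) paste(format(x, digits = 15, trim = TRUE,
                                         scientific = FALSE), collapse = ";")

measurement_columns <- function() {
  c("batch_id", "granule_mass", "bulk_volume", "tapped_volume",
    "cone_height", "cone_radius", "flow_time", "loss_on_drying_pct",
    "hygroscopicity_pct", "compact_strengths",
    "sieve_850", "sieve_600", "sieve_425", "sieve_300", "sieve_250",
    "sieve_50", "pan_50", "percent_fines", "effervescence_times",
    "disint_disk_times", "disint_nodisk_times")
}

#' Read raw measurements from CSV
#'
#' One row per batch; scalar columns are numeric, replicate columns
#' (`compact_strengths`, `effervescence_times`, `disint_disk_times`,
#' `disint_nodisk_times`) are semicolon-separated lists, and the sieve
#' analysis occupies the columns `sieve_850 ... sieve_250, pan_50`
#' (percent retained per aperture plus the pan).  Malformed cells are
#' reported with their row number and column name.
#'
#' @param path CSV file path.
#' @return List of [raw_measurements()] objects.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(measurement_columns(), names(df))
  if (length(missing)) {
    abort_validation(sprintf("missing column(s) in %s: %s", path,
                             paste(missing, collapse = ", ")))
  }
  num <- function(i, col) {
    v <- suppressWarnings(as.numeric(df[[col]][i]))
    if (is.na(v)) {
      abort_validation(sprintf("non-numeric cell at row %d, column '%s'",
                               i, col))
    }
    v
  }
  lapply(seq_len(nrow(df)), function(i) {
    sieve <- tryCatch(
      sieve_fractions(
        apertures = c(850, 600, 425, 300, 250, 50),
        percent_retained = unname(vapply(
          c("sieve_850", "sieve_600", "sieve_425", "sieve_300", "sieve_250",
            "sieve_50"),
          function(cl) num(i, cl), numeric(1))),
        pan_percent = num(i, "pan_50")),
      sedem_validation = function(e) {
        abort_validation(sprintf("row %d: %s", i, conditionMessage(e)))
      })
    raw_measurements(
      batch_id = df$batch_id[i],
      granule_mass = num(i, "granule_mass"),
      bulk_volume = num(i, "bulk_volume"),
      tapped_volume = num(i, "tapped_volume"),
      cone_height = num(i, "cone_height"),
      cone_radius = num(i, "cone_radius"),
      flow_time = num(i, "flow_time"),
      loss_on_drying_pct = num(i, "loss_on_drying_pct"),
      hygroscopicity_pct = num(i, "hygroscopicity_pct"),
      compact_strengths = split_numlist(
        df$compact_strengths[i], sprintf("row %d, column 'compact_strengths'", i)),
      sieve = sieve,
      percent_fines = num(i, "percent_fines"),
      effervescence_times = split_numlist(
        df$effervescence_times[i], sprintf("row %d, column 'effervescence_times'", i)),
      disint_disk_times = split_numlist(
        df$disint_disk_times[i], sprintf("row %d, column 'disint_disk_times'", i)),
      disint_nodisk_times = split_numlist(
        df$disint_nodisk_times[i], sprintf("row %d, column 'disint_nodisk_times'", i))
    )
  })
}

#' Write raw measurements to CSV
#'
#' Inverse of [read_measurements()]; the written file reads back to
#' identical records.
#'
#' @param batches list of [raw_measurements()] objects (all fields present).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(batches, path) {
  rows <- lapply(batches, function(m) {
    data.frame(
      batch_id = m$batch_id,
      granule_mass = m$granule_mass,
      bulk_volume = m$bulk_volume,
      tapped_volume = m$tapped_volume,
      cone_height = m$cone_height,
      cone_radius = m$cone_radius,
      flow_time = m$flow_time,
      loss_on_drying_pct = m$loss_on_drying_pct,
      hygroscopicity_pct = m$hygroscopicity_pct,
      compact_strengths = join_numlist(m$compact_strengths),
      sieve_850 = m$sieve$percent_retained[1],
      sieve_600 = m$sieve$percent_retained[2],
      sieve_425 = m$sieve$percent_retained[3],
      sieve_300 = m$sieve$percent_retained[4],
      sieve_250 = m$sieve$percent_retained[5],
      sieve_50 = m$sieve$percent_retained[6],
      pan_50 = m$sieve$pan_percent,
      percent_fines = m$percent_fines,
      effervescence_times = join_numlist(m$effervescence_times),
      disint_disk_times = join_numlist(m$disint_disk_times),
      disint_nodisk_times = join_numlist(m$disint_nodisk_times),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Write tablet QC records to CSV
#'
#' @param batches list of [tablet_batch()] objects.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tablets <- function(batches, path) {
  rows <- lapply(batches, function(b) {
    data.frame(
      trial_id = b$trial_id,
      crushing_strengths = join_numlist(b$crushing_strengths),
      diameter = b$diameter,
      thicknesses = join_numlist(b$thicknesses),
      individual_weights = join_numlist(b$individual_weights),
      friability_mass_before = b$friability_mass_before,
      friability_mass_after = b$friability_mass_after,
      wetting_times = join_numlist(b$wetting_times),
      disintegration_times = join_numlist(b$disintegration_times),
      peak_area_sample = b$peak_area_sample,
      peak_area_standard = b$peak_area_standard,
      dissolution_times = join_numlist(b$dissolution_times),
      dissolution_concentrations = join_numlist(b$dissolution_concentrations),
      media_volume = b$media_volume,
      sample_volume = b$sample_volume,
      label_claim = b$label_claim,
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read tablet QC records from CSV
#'
#' @param path CSV file written in the [write_tablets()] layout.
#' @return List of [tablet_batch()] objects.
#' @export
read_tablets <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("trial_id", "crushing_strengths", "diameter", "thicknesses",
            "individual_weights", "friability_mass_before",
            "friability_mass_after", "wetting_times", "disintegration_times",
            "peak_area_sample", "peak_area_standard", "dissolution_times",
            "dissolution_concentrations", "media_volume", "sample_volume",
            "label_claim")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_validation(sprintf("missing column(s) in %s: %s", path,
                             paste(missing, collapse = ", ")))
  }
  num <- function(i, col) {
    v <- suppressWarnings(as.numeric(df[[col]][i]))
    if (is.na(v)) {
      abort_validation(sprintf("non-numeric cell at row %d, column '%s'", i, col))
    }
    v
  }
  lst <- function(i, col) split_numlist(df[[col]][i],
                                        sprintf("row %d, column '%s'", i, col))
  lapply(seq_len(nrow(df)), function(i) {
    tablet_batch(
      trial_id = df$trial_id[i],
      crushing_strengths = lst(i, "crushing_strengths"),
      diameter = num(i, "diameter"),
      thicknesses = lst(i, "thicknesses"),
      individual_weights = lst(i, "individual_weights"),
      friability_mass_before = num(i, "friability_mass_before"),
      friability_mass_after = num(i, "friability_mass_after"),
      wetting_times = lst(i, "wetting_times"),
      disintegration_times = lst(i, "disintegration_times"),
      peak_area_sample = num(i, "peak_area_sample"),
      peak_area_standard = num(i, "peak_area_standard"),
      dissolution_times = lst(i, "dissolution_times"),
      dissolution_concentrations = lst(i, "dissolution_concentrations"),
      media_volume = num(i, "media_volume"),
      sample_volume = num(i, "sample_volume"),
      label_claim = num(i, "label_claim"))
  })
}

#' Write radius profiles to CSV
#'
#' One row per batch, one column per parameter id.
#'
#' @param profiles list of `radius_profile` objects sharing a system.
#' @param path output CSV path.
#' @param clamped write clamped instead of raw radii.
#' @return Invisibly, `path`.
#' @export
write_radii_csv <- function(profiles, path, clamped = FALSE) {
  col <- if (clamped) "clamped_r" else "raw_r"
  rows <- lapply(profiles, function(p) {
    vals <- as.list(stats::setNames(p$radii[[col]], p$radii$id))
    cbind(data.frame(batch_id = p$batch_id, stringsAsFactors = FALSE),
          as.data.frame(vals, check.names = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# index_report -> plain list for JSON
report_to_list <- function(report) {
  list(batch_id = report$batch_id,
       system = report$system,
       n_params = report$n_params,
       n_pass = report$n_pass,
       IP = report$IP,
       IPP = report$IPP,
       f = report$f,
       IGCB = report$IGCB,
       incidence = as.list(report$incidence),
       verdict = report$verdict)
}

#' Write index reports to JSON
#'
#' @param reports list of `index_report` objects.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(reports, path) {
  jsonlite::write_json(lapply(reports, report_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read index reports back from JSON
#'
#' Round-trips the output of [write_report_json()] into `index_report`
#' objects.
#'
#' @param path JSON path.
#' @return List of `index_report` objects.
#' @export
read_report_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    structure(
      list(batch_id = x$batch_id, system = x$system,
           n_params = as.integer(x$n_params), n_pass = as.integer(x$n_pass),
           IP = as.numeric(x$IP), IPP = as.numeric(x$IPP),
           f = as.numeric(x$f), IGCB = as.numeric(x$IGCB),
           incidence = vapply(x$incidence, as.numeric, numeric(1)),
           verdict = x$verdict),
      class = "index_report")
  })
}
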