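#' Transform an experimental value into its radius
#'
#' Applies a parameter's fixed linear factor to the experimental value V,
#' giving the raw (unclamped) radius.  Values outside the admissible limits
#' are transformed all the same — they simply fall outside 0-10 and are
#' clamped later for diagrams and indices.
#'
#' @param parameter_id one of the 15 registry ids (see [parameter_registry()]).
#' @param V experimental value in the parameter's unit.
#' @param registry parameter registry, defaulting to the standard table.
#' @return The raw radius (may be negative or exceed 10).
#' @export
#' @examples
#' radius_value("H", 10.69)  # hygroscopicity 10.69 % -> 4.655
#' radius_value("Ic", 50)    # Carr index at its limit -> 10
radius_value <- function(parameter_id, V, registry = parameter_registry()) {
  row <- registry[registry$id == parameter_id, ]
  if (nrow(row) != 1L) {
    abort_registry(sprintf("unknown parameter id '%s'", parameter_id))
  }
  if (any(!is.finite(V))) {
    abort_invalid_measurement("V must be finite")
  }
  row$intercept + row$slope * V
}

# Experimental value that would produce a given raw radius (factors are
# linear, hence invertible); used by tests and by fixture reconstruction.
radius_inverse <- function(parameter_id, r, registry = parameter_registry()) {
  row <- registry[registry$id == parameter_id, ]
  if (nrow(row) != 1L) {
    abort_registry(sprintf("unknown parameter id '%s'", parameter_id))
  }
  (r - row$intercept) / row$slope
}

#' Clamp a raw radius onto the 0-10 diagram scale
#'
#' Radii below 0 (out-of-limit experimental values) contribute 0 to diagrams,
#' profile means and incidence factors; radii above 10 are capped at 10.
#'
#' @param raw_r numeric vector of raw radii.
#' @return `pmin(10, pmax(0, raw_r))`.
#' @export
clamp_radius <- function(raw_r) {
  if (any(!is.finite(raw_r))) abort_invalid_measurement("raw_r must be finite")
  pmin(10, pmax(0, raw_r))
}

#' Build a radius profile for a batch
#'
#' Transforms every basic parameter required by the chosen system into raw and
#' clamped radii.  Experimental values outside their admissible limits are
#' transformed anyway and flagged with a warning, mirroring bench practice
#' (the score simply bottoms out).
#'
#' @param p a `basic_parameters` object (or plain named list of V values with
#'   a `batch_id` entry).
#' @param system `"odt"` (15 parameters) or `"classic"` (12 parameters).
#' @param registry parameter registry.
#' @return An object of class `radius_profile`: list with `batch_id`,
#'   `system`, and a data.frame `radii` holding `id`, `group`, `V`, `raw_r`,
#'   `clamped_r` in diagram order.
#' @export
#' @examples
#' p <- basic_parameters("demo", Da = 0.65, Dc = 0.71, Ie = 0.13, Ic = 8.45,
#'   Icd = 150, IH = 1.09, alpha = 24, t_flow = 4, HR = 2.9, H = 3.9,
#'   Pf = 4.4, Itheta = 0.014, DE = 8, DCD = 5, DSD = 7)
#' build_profile(p, "odt")
build_profile <- function(p, system = c("odt", "classic"),
                          registry = parameter_registry()) {
  system <- match.arg(system)
  ids <- system_parameter_ids(system, registry)
  present <- vapply(ids, function(id) !is.null(p[[id]]), logical(1))
  if (!all(present)) {
    abort_missing_field(sprintf(
      "parameter(s) %s missing for the %s system",
      paste(ids[!present], collapse = ", "), system))
  }
  V <- vapply(ids, function(id) as.numeric(p[[id]]), numeric(1))
  sub <- registry[match(ids, registry$id), ]
  out_of_limit <- V < sub$v_low | V > sub$v_high
  if (any(out_of_limit)) {
    warning(sprintf(
      "batch %s: experimental value(s) outside admissible limits for %s",
      p$batch_id, paste(ids[out_of_limit], collapse = ", ")), call. = FALSE)
  }
  raw_r <- sub$intercept + sub$slope * V
  structure(
    list(batch_id = p$batch_id,
         system = system,
         radii = data.frame(id = ids, group = sub$group, V = V,
                            raw_r = raw_r, clamped_r = clamp_radius(raw_r),
                            row.names = NULL, stringsAsFactors = FALSE)),
    class = "radius_profile"
  )
}

#' Build a radius profile from already-scored radii
#'
#' Literature tables report the transformed radii, not the underlying
#' experimental values; this constructor accepts them directly (V is
#' back-computed through the inverse factor for reference).
#'
#' @param batch_id batch label.
#' @param raw_r named numeric vector of raw radii (names are registry ids).
#' @param system `"odt"` or `"classic"`.
#' @param registry parameter registry.
#' @return A `radius_profile` object.
#' @export
radius_profile_from_radii <- function(batch_id, raw_r,
                                      system = c("odt", "classic"),
                                      registry = parameter_registry()) {
  system <- match.arg(system)
  ids <- system_parameter_ids(system, registry)
  if (!all(ids %in% names(raw_r))) {
    abort_missing_field(sprintf(
      "radius value(s) missing for: %s",
      paste(setdiff(ids, names(raw_r)), collapse = ", ")))
  }
  r <- as.numeric(raw_r[ids])
  if (any(!is.finite(r))) abort_invalid_measurement("radii must be finite")
  sub <- registry[match(ids, registry$id), ]
  structure(
    list(batch_id = batch_id,
         system = system,
         radii = data.frame(id = ids, group = sub$group,
                            V = (r - sub$intercept) / sub$slope,
                            raw_r = r, clamped_r = clamp_radius(r),
                            row.names = NULL, stringsAsFactors = FALSE)),
    class = "radius_profile"
  )
}

# Restrict an ODT profile to the classic 12-parameter subset
as_classic_profile <- function(profile) {
  stopifnot(inherits(profile, "radius_profile"))
  if (profile$system == "classic") return(profile)
  keep <- profile$radii$group != "Disgregability"
  structure(
    list(batch_id = profile$batch_id, system = "classic",
         radii = profile$radii[keep, , drop = FALSE]),
    class = "radius_profile"
  )
}

#' @export
print.radius_profile <- function(x, digits = 3, ...) {
  cat(sprintf("<radius_profile> batch %s, %s system (%d parameters)\n",
              x$batch_id, x$system, nrow(x$radii)))
  df <- x$radii
  df$raw_r <- round_half_up(df$raw_r, digits)
  df$clamped_r <- round_half_up(df$clamped_r, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
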