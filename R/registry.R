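#' The SeDeM-ODT parameter registry
#'
#' The expert system scores a powder or granule bed on 15 basic parameters,
#' grouped into six incidence factors.  Each parameter has an admissible
#' experimental range (`v_low`, `v_high`) and a fixed linear rescaling
#' ("applied factor") mapping the experimental value V onto a 0-10 radius:
#' `r = intercept + slope * V`.  The classic (non-ODT) SeDeM system uses the
#' 12 parameters outside the Disgregability group.
#'
#' The applied factors, in registry order, are: 10V (bulk density Da),
#' 10V (tapped density Dc), 10V/1.2 (inter-particle porosity Ie),
#' V/5 (Carr index Ic), V/20 (cohesion index Icd), (30-10V)/2 (Hausner
#' ratio IH), 10-V/5 (angle of repose alpha), 10-V/2 (flow time t_flow),
#' 10-V (loss on drying HR), 10-V/2 (hygroscopicity H), 10-V/5 (fines Pf),
#' 500V (homogeneity index Itheta), (5-V)x2 (effervescence time DE) and
#' (3-V)x3.33 for both disintegration times (DCD, DSD).  The constant is
#' 3.33 exactly as conventionally printed, so the most favourable
#' disintegration radius is 9.99, not 10.
#'
#' @param overrides optional named list; each element is itself a list with
#'   any of `v_low`, `v_high`, `intercept`, `slope`, replacing the default
#'   for that parameter id.  Intended for sensitivity studies only.
#' @return A data.frame with one row per parameter and columns `id`, `label`,
#'   `group`, `v_low`, `v_high`, `intercept`, `slope`, `favourable`
#'   (the V value scoring best) and `classic` (membership of the 12-parameter
#'   subset), in the canonical diagram order.
#' @export
#' @examples
#' reg <- parameter_registry()
#' table(reg$group)
parameter_registry <- function(overrides = NULL) {
  reg <- data.frame(
    id = c("Da", "Dc", "Ie", "Ic", "Icd", "IH", "alpha", "t_flow",
           "HR", "H", "Pf", "Itheta", "DE", "DCD", "DSD"),
    label = c("Bulk density", "Tapped density", "Inter-particle porosity",
              "Carr index", "Cohesion index", "Hausner ratio",
              "Angle of repose", "Powder flow", "Loss on drying",
              "Hygroscopicity", "Particles < 50 um", "Homogeneity index",
              "Effervescence time", "Disintegration time with disk",
              "Disintegration time without disk"),
    unit = c("g/mL", "g/mL", "-", "%", "N", "-", "deg", "s", "%", "%", "%",
             "-", "min", "min", "min"),
    group = c("Dimension", "Dimension",
              "Compressibility", "Compressibility", "Compressibility",
              "Flowability/Powder Flow", "Flowability/Powder Flow",
              "Flowability/Powder Flow",
              "Lubricity/Stability", "Lubricity/Stability",
              "Lubricity/Dosage", "Lubricity/Dosage",
              "Disgregability", "Disgregability", "Disgregability"),
    v_low = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    v_high = c(1, 1, 1.2, 50, 200, 3, 50, 20, 10, 20, 50, 0.02, 5, 3, 3),
    intercept = c(0, 0, 0, 0, 0, 15, 10, 10, 10, 10, 10, 0, 10, 9.99, 9.99),
    slope = c(10, 10, 10 / 1.2, 1 / 5, 1 / 20, -5, -1 / 5, -1 / 2, -1,
              -1 / 2, -1 / 5, 500, -2, -3.33, -3.33),
    stringsAsFactors = FALSE
  )
  # V value at which the factor reaches its ceiling (10, or 9.99 for DCD/DSD)
  reg$favourable <- ifelse(reg$slope > 0, reg$v_high, reg$v_low)
  reg$classic <- reg$group != "Disgregability"

  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% reg$id)) {
      abort_registry("override names must be parameter ids from the registry")
    }
    for (id in names(overrides)) {
      ov <- overrides[[id]]
      bad <- setdiff(names(ov), c("v_low", "v_high", "intercept", "slope"))
      if (length(bad)) {
        abort_registry(sprintf("unknown override field(s) for '%s': %s",
                               id, paste(bad, collapse = ", ")))
      }
      for (field in names(ov)) {
        reg[reg$id == id, field] <- ov[[field]]
      }
    }
    reg$favourable <- ifelse(reg$slope > 0, reg$v_high, reg$v_low)
  }
  reg
}

# Ids of a system's parameter set, in diagram order
system_parameter_ids <- function(system = c("odt", "classic"),
                                 registry = parameter_registry()) {
  system <- match.arg(system)
  if (system == "odt") registry$id else registry$id[registry$classic]
}

# Incidence-factor membership as a named list of id vectors
incidence_groups <- function(registry = parameter_registry()) {
  split(registry$id, factor(registry$group, levels = unique(registry$group)))
}
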