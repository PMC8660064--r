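#' Parametric index (IP)
#'
#' Fraction of the system's parameters whose raw radius reaches the
#' acceptability threshold of 5.  Thresholding uses raw radii, so radii
#' driven negative by out-of-limit experimental values can never count.
#'
#' @param profile a `radius_profile`.
#' @return IP in `[0, 1]`.
#' @export
parametric_index <- function(profile) {
  check_profile(profile)
  sum(profile$radii$raw_r >= 5) / nrow(profile$radii)
}

#' Parameter profile index (IPP)
#'
#' Arithmetic mean of the clamped radii over the system's parameter set:
#' negative raw radii contribute 0, radii above 10 contribute 10.
#'
#' @param profile a `radius_profile`.
#' @return IPP in `[0, 10]`.
#' @export
parameter_profile_index <- function(profile) {
  check_profile(profile)
  mean(profile$radii$clamped_r)
}

#' Reliability factor for a parameter count
#'
#' The polygon-to-circle area correction applied to IPP.  The conventional
#' published values 0.971 (n = 15), 0.952 (n = 12) and 0.900 (n = 8) are
#' returned verbatim; any other count falls back to the regular-polygon area
#' ratio `n * sin(2*pi/n) / (2*pi)`.  (The published n = 12 value, 0.952,
#' differs slightly from the polygon formula's 0.955 and takes precedence.)
#'
#' @param n_params number of parameters (>= 3).
#' @return Reliability factor f in `(0, 1]`.
#' @export
#' @examples
#' reliability_factor(15) # 0.971
#' reliability_factor(12) # 0.952
reliability_factor <- function(n_params) {
  ok <- is.numeric(n_params) && length(n_params) == 1L && !is.na(n_params)
  if (!ok || n_params < 3) {
    sedem_abort("reliability factor is defined for n >= 3 parameters",
                "sedem_domain")
  }
  lookup <- c(`15` = 0.971, `12` = 0.952, `8` = 0.900)
  key <- as.character(n_params)
  if (key %in% names(lookup)) return(unname(lookup[key]))
  if (is.infinite(n_params)) return(1)
  n_params * sin(2 * pi / n_params) / (2 * pi)
}

#' Good compressibility (and bucodispersibility) index
#'
#' `IGCB = IPP * f` for the 15-parameter ODT system; the same product over the
#' 12-parameter classic system is the good compressibility index IGC.
#' A value of at least 5 marks the material suitable.
#'
#' @param ipp parameter profile index, in `[0, 10]`.
#' @param f reliability factor, in `(0, 1]`.
#' @return The product.
#' @export
igcb <- function(ipp, f) {
  stopifnot_number(ipp, "ipp")
  stopifnot_number(f, "f")
  if (ipp < 0 || ipp > 10) abort_validation("ipp must be in [0, 10]")
  if (f <= 0 || f > 1) abort_validation("f must be in (0, 1]")
  ipp * f
}

#' Incidence factors of a profile
#'
#' Mean clamped radius of each of the six parameter groups (Dimension,
#' Compressibility, Flowability/Powder Flow, Lubricity/Stability,
#' Lubricity/Dosage, Disgregability).  For a classic profile the
#' Disgregability group is absent.
#'
#' @param profile a `radius_profile`.
#' @return Named numeric vector of group means, in registry group order.
#' @export
incidence_factors <- function(profile) {
  check_profile(profile)
  groups <- unique(parameter_registry()$group)
  groups <- groups[groups %in% profile$radii$group]
  vapply(groups, function(g) {
    mean(profile$radii$clamped_r[profile$radii$group == g])
  }, numeric(1))
}

#' Full index report for a batch
#'
#' Combines IP, IPP, the reliability factor, IGCB (or IGC for the classic
#' system), the six incidence factors and the suitability verdict
#' (suitable iff the index reaches 5).
#'
#' @param profile a `radius_profile`.
#' @return An object of class `index_report`: list with `batch_id`, `system`,
#'   `n_params`, `n_pass`, `IP`, `IPP`, `f`, `IGCB` (the `IPP * f` product,
#'   reported as IGC for classic profiles), `incidence` and `verdict`
#'   (`"suitable"` / `"not-suitable"`).
#' @export
#' @examples
#' tab5 <- load_paper_fixtures()$table5
#' prof <- radius_profile_from_radii("Trial-5", tab5[["Trial-5"]], "odt")
#' full_report(prof)
full_report <- function(profile) {
  check_profile(profile)
  n <- nrow(profile$radii)
  ipp <- parameter_profile_index(profile)
  f <- reliability_factor(n)
  index <- igcb(ipp, f)
  structure(
    list(batch_id = profile$batch_id,
         system = profile$system,
         n_params = n,
         n_pass = sum(profile$radii$raw_r >= 5),
         IP = parametric_index(profile),
         IPP = ipp,
         f = f,
         IGCB = index,
         incidence = incidence_factors(profile),
         verdict = if (index >= 5) "suitable" else "not-suitable"),
    class = "index_report"
  )
}

check_profile <- function(profile) {
  if (!inherits(profile, "radius_profile") || nrow(profile$radii) == 0) {
    abort_validation("a non-empty radius_profile is required")
  }
  expected <- length(system_parameter_ids(profile$system))
  if (nrow(profile$radii) != expected) {
    abort_validation(sprintf("%s profile must carry %d parameters, found %d",
                             profile$system, expected, nrow(profile$radii)))
  }
  invisible(profile)
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("<index_report> batch %s (%s system, n = %d)\n",
              x$batch_id, x$system, x$n_params))
  cat(sprintf("  IP   = %.3f  (%d of %d parameters with r >= 5)\n",
              x$IP, x$n_pass, x$n_params))
  cat(sprintf("  IPP  = %.2f\n", round_half_up(x$IPP, 2)))
  cat(sprintf("  %s = %.2f  (f = %.3f) -> %s\n",
              if (x$system == "odt") "IGCB" else "IGC ",
              round_half_up(x$IGCB, 2), x$f, x$verdict))
  cat("  incidence factors:\n")
  for (g in names(x$incidence)) {
    cat(sprintf("    %-24s %.3f\n", g, round_half_up(x$incidence[[g]], 3)))
  }
  invisible(x)
}
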