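#' Packaged study fixtures
#'
#' The package ships the printed results of a published 13-run high-shear
#' wet-granulation study of atenolol as plain-text fixtures, so the whole
#' reconstruction suite runs offline: the two-factor trial design
#' (granulation time 30/45/60 s crossed with binder concentration 5/10/15 %,
#' five centre-point replicates), the radius profiles of the ungranulated
#' drug and powder blend, the radius profiles of nine distinct granule
#' trials, the printed incidence factors and indices, and the tablet QC
#' table.
#'
#' @return A list with components:
#' \describe{
#'   \item{design}{data.frame of the 13 trials (coded and actual levels).}
#'   \item{table4}{named list of two named radius vectors (`Atenolol`,
#'     `Powder Blend`), 15 parameters each.}
#'   \item{table5}{named list of nine named radius vectors, one per granule
#'     trial.}
#'   \item{incidence}{data.frame of printed incidence factors.}
#'   \item{indices}{data.frame of printed IP/IPP/IGCB (ODT) and
#'     IP/IPP/IGC (classic) values.}
#'   \item{tablets}{data.frame of printed tablet QC metrics per trial.}
#' }
#' @export
#' @examples
#' fx <- load_paper_fixtures()
#' fx$table5[["Trial-5"]][["Icd"]] # 9.75
load_paper_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "sedemodt",
                                  mustWork = TRUE)
  read <- function(f, ...) utils::read.csv(path(f), check.names = FALSE,
                                           stringsAsFactors = FALSE, ...)
  radii_list <- function(df) {
    ids <- df$parameter
    cols <- setdiff(names(df), "parameter")
    stats::setNames(lapply(cols, function(cl) {
      stats::setNames(as.numeric(df[[cl]]), ids)
    }), cols)
  }
  list(design = read("table2_design.csv"),
       table4 = radii_list(read("table4_radii.csv")),
       table5 = radii_list(read("table5_radii.csv")),
       incidence = read("table6_incidence.csv"),
       indices = read("table7_indices.csv"),
       tablets = read("table8_tablets.csv"))
}

# Documented internal inconsistencies of the source tables: for these cells
# the printed value counts only the effervescence-time radius toward the
# Disgregability group (the positive with-disk radius was evidently dropped),
# so faithful recomputation cannot match print.  Reconstruction reports them
# as expected mismatches rather than silently special-casing the arithmetic.
documented_fixture_exceptions <- function() {
  data.frame(
    table = c("incidence", "incidence", "indices", "indices", "indices",
              "indices"),
    trial_id = c("Trial-9", "Trial-10", "Trial-9", "Trial-9", "Trial-10",
                 "Trial-10"),
    column = c("Disgregability", "Disgregability", "odt_IPP", "odt_IGCB",
               "odt_IPP", "odt_IGCB"),
    stringsAsFactors = FALSE
  )
}
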