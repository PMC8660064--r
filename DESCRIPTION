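Package: sedemodt
Title: SeDeM-ODT Expert-System Profiling of Granules and Tablet Quality
Version: 0.1.0
Authors@R:
    person("Quality", "Pipelines", email = "qp@example.org", role = c("aut", "cre"))
Description: Implements the SeDeM and SeDeM-ODT expert systems for
    pharmaceutical preformulation: computation of the 15 basic powder and
    granule parameters (bulk and tapped density, inter-particle porosity,
    Carr's index, cohesion index, Hausner ratio, angle of repose, flow
    time, loss on drying, hygroscopicity, fines, homogeneity index and
    compact disintegration times) from raw bench measurements, conversion
    to 0-10 radius values, polar (radar) diagrams, incidence factors and
    the suitability indices IP, IPP and IGCB/IGC.  Also provides USP-style
    tablet quality metrics (diametral tensile strength, specific crushing
    strength, friability, weight variation, drug content, cumulative
    dissolution with sampling-volume correction), a monotone-trend linkage
    between granule scores and tablet outcomes, and a synthetic study
    generator emulating a 13-run two-factor wet-granulation design for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
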