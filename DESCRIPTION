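Package: btzov
Title: Bortezomib and Oncolytic Virus Combination Therapy Simulator for Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples an intracellular IkB/NF-kB/Bax/RIP1 cell-death switch to a
    five-field reaction-diffusion model of glioblastoma growth under bortezomib
    (BTZ) and oncolytic herpes virus (oHSV) combination therapy. Provides
    steady-state and bifurcation analysis of the intracellular switch over the
    BTZ level, classification of anti-apoptotic, apoptotic and necroptotic cell
    states, an ADI/Strang operator-split PDE solver with adaptive time stepping
    on a no-flux unit square, scenario builders for injection patterns, CSPG
    extracellular-matrix barriers, heterogeneous tissue and resection, and
    summary metrics (tumor volume, regional populations, intracellular maps).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
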