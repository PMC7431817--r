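Package: egfrbind
Title: Equilibrium Models of EGF Receptor Ligand Binding, Dimerization and
    Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of epidermal growth factor
    receptor (EGFR) ligand binding on cells. Implements a closed-form solver
    for a twelve-species mass-action equilibrium coupling the closed/extended
    conformations of the extracellular domain, the active/inactive
    conformations of the kinase domain, two receptor dimerization pathways and
    stepwise EGF binding; global multi-dataset fitting of the nine equilibrium
    constants to flow-cytometric saturation-binding curves with profiled
    intensity scales and multi-start optimization; phenomenological Hill and
    Scatchard analysis of binding curves; homo-FRET fluorescence anisotropy
    analysis of receptor cluster size from photobleaching series with
    Monte-Carlo confidence intervals; and synthetic-data generators for both
    experiment types.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
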