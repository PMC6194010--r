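Package: chlorosip
Title: DNA Stable-Isotope Probing Analysis of the Soil Chloromethane Sink
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA stable-isotope probing (SIP) studies of trace-gas
    degrading soil bacteria. Fits first-order consumption rate constants to
    headspace gas time series and classifies sink activity against killed and
    anoxic controls; budgets pulse-amended carbon into mineralized (13C-CO2)
    and assimilated fractions; processes amplicon reads (length filtering,
    global-singleton removal, preclustering, greedy centroid OTU clustering,
    iterative identity-cutoff selection, degenerate-primer expansion); calls
    13C-labeled OTUs from heavy/light gradient-fraction count tables using
    four abundance criteria plus a labeling-proportion threshold; computes
    diversity summaries; and generates fully seeded synthetic datasets with
    planted ground truth so every stage can be validated without external
    sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    vegan,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
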