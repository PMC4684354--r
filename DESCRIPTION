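Package: ribowaves
Title: Codon Occupancy Profiles and Elongation-Disruption Waves in
    Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying codon-level translation dynamics from
    ribosome footprint data. Computes A/P/E-site codon occupancies and
    offset enrichment profiles from CDS-mapped footprints, quantifies the
    transient downstream waves of ribosome density created when
    codon-specific elongation rates are perturbed (as by cycloheximide
    pretreatment), tests the conservation relation between tRNA-binding-site
    occupancy changes and downstream wave areas, and recovers
    pre-perturbation decoding-time signatures via corrected aggregate
    enrichments. Includes a continuous-time stochastic simulator of
    translation elongation with codon-specific exponential dwell times, a
    deterministic master-equation model of density relaxation waves, a
    tRNA adaptation index calculator, and a synthetic-data generator so the
    full analysis is exercisable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    deSolve,
    stats,
    utils
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
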