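Package: cesscan
Title: Detecting Clonal Expansions in Spermatogonia from De Novo Mutation
    Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Statistical machinery to detect genes under positive selection
    in spermatogonia (CES) as hotspots of human de novo mutation. Implements
    synonymous-normalised mutational expectations from per-site baseline
    rates, Negative Binomial overdispersion control for rate-model errors,
    Multinomial/Dirichlet-Multinomial tests of phenotypic sampling
    homogeneity across trio subcohorts, ascertainment-bounded enrichment
    tests for gain-of-function and loss-of-function candidate sets, a
    Gamma-Poisson (Nei) mutation-selection-drift variance decomposition that
    separates mutation-rate inflation from relaxed selection in population
    allele counts, a data-driven multinomial site-frequency-spectrum model
    for per-gene heterozygous selection coefficients, and a seed-driven
    synthetic-data generator emulating trio cohorts, sperm sequencing and
    population variant catalogues so the whole pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
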