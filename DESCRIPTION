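Package: paleodecay
Title: Power-Law Degradation Kinetics of Biomolecules in Lake Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the post-burial degradation of biomolecule records
    (DNA marker gene copy numbers, lipid biomarkers, pigments, and
    macromolecules) in dated lake-sediment cores.  Fits power, exponential,
    and linear decay models to content-versus-age profiles, derives decay
    constants and age-dependent half-life schedules, flags unreliable fits,
    and contrasts decay constants between organism groups with exact
    Wilcoxon rank-sum tests.  Includes piecewise-linear age-depth models,
    amplicon community tools (relative abundances, abundance partitioning by
    total gene copies, Bray-Curtis dissimilarity, ANOSIM), a rule-based
    classifier for three biomolecule-preservation scenarios
    (adsorption/complexation, chemical reactivity, biotic exclusion by
    physical shielding), and a seeded synthetic-core generator so the whole
    pipeline can be exercised at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
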