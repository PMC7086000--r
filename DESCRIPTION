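Package: ndmtbi
Title: Network Diffusion Modeling of Neurodegeneration After Traumatic Brain Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spread of pathology on a structural brain connectome
    with a linear network diffusion model (graph Laplacian heat kernel), infers
    per-patient injury epicenters from cross-sectional regional gray-matter
    atrophy by a seed-screening and greedy seed-combination search, and
    characterizes group-level degeneration patterns with principal component
    analysis and covariate-adjusted correlations. Includes a synthetic-cohort
    generator (stochastic-block-model connectomes, control volume tables, and
    forward-simulated patients with known epicenters) so every stage of the
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
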