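Package: fraglod
Title: Log-Odds Scoring Metrics for Peptide-Spectrum Matching and
    Fragmentation Exploration
Version: 0.1.0
Authors@R:
    person("Leo", "Carver", email = "leo.carver@example.org",
           role = c("aut", "cre"))
Description: A framework for developing, validating, and comparing
    peptide-spectrum match (PSM) scoring metrics for tandem mass
    spectrometry. Digests a FASTA proteome into a mass-ordered peptide
    index with fixed and variable modifications, parses DTA spectra,
    selects candidates by precursor mass, y-ion hits, and an
    intensity-proportion preliminary score, and scores candidates with
    four progressively data-driven log-odds (LOD) metrics: a fixed
    correct-match probability against a uniform random-peak model,
    empirical mass-binned match-proportion tables for correct and decoy
    assignments, and mass-binned Gaussian models of fragment mass-error
    drift. Confidence is calibrated as a Z score against candidates from
    a reversed-protein decoy database. A sigmoidal 8-8-1 neural network
    predicts fragment peak intensities, scored by a dot product against a
    wrap-around rotation null. Includes tools for exploring fragmentation
    properties (complementary y/b ion isoelectric points, mass-error
    drift) and a seeded synthetic-data generator so the entire pipeline
    is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
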