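Package: qocindex
Title: Composite Quality-of-Care Indices for Health Facilities
Version: 0.1.0
Authors@R: person("qocindex", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Constructs composite quality-of-care scores for health facilities
    from multi-source indicator data organized on a quality-dimension by
    Donabedian-element matrix (structure, process, outcome). Reads indicator
    maps and raw survey tools, aggregates individual-level records to facility
    level, imputes missing values under configurable policies, screens
    within-cell indicator redundancy, and builds composite indices under a
    base construction and four one-decision-at-a-time alternatives (min-max
    indicator rescaling, geometric indicator aggregation, z-score cell
    standardization, geometric cell aggregation). Quantifies ranking
    robustness across constructions with tie-aware Spearman rank correlation
    and deconstructs composites into cell and element sub-scores with
    confidence intervals. Includes a synthetic multi-source data generator
    with known latent facility quality for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
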