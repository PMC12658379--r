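Package: engramtools
Title: Engram Reactivation Statistics, Recognition-Memory Scoring, and
    Dendritic Spine Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for chemogenetic engram-reactivation
    experiments: scoring of object-recognition exploration logs into
    discrimination indices and occupancy maps; chance-corrected c-Fos/mCherry
    ensemble-reactivation statistics from slice-level cell-count tables
    (densities, co-localization, overlap over chance, home-cage-normalized
    fold changes, single-cell intensity summaries); and dendritic spine
    morphometry from 3-D filament-reconstruction exports (refinement,
    frustum-plus-hemisphere geometry, five-class threshold classification,
    and z-score/PCA/k-means clustering with elbow-based model selection).
    A synthetic-data module with known ground-truth parameters closes the
    testing loop for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
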