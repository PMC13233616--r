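Package: divprior
Title: Spatial Biodiversity Prioritization from Occurrence Records and Phylogenies
Version: 0.1.0
Authors@R: person("divprior", "maintainers", email = "divprior@example.org", role = c("aut", "cre"))
Description: A tested pipeline for grid-based conservation prioritization of
    medicinal-plant (or any) floras: cleaning and gridding of raw occurrence
    records into presence-absence matrices on an equal-area grid; diversity
    surfaces (species richness, greedy complementarity, weighted endemism,
    phylogenetic diversity and endemism, and a composite phylogenetic index);
    multi-threshold hotspot identification by rank-sum overlay with Class I-III
    tiers; conservation-effectiveness and gap reports against national and
    provincial reserve layers; ethnic-use matrix analytics with binary sequence
    coding and distance-based cluster trees; and ensemble species-distribution
    post-processing (predictor screening, pseudo-absences, TSS/AUC evaluation,
    TSS-weighted ensembles, max-TSS binarization, stacked richness, and
    climate-scenario range-change assessment). Ships a synthetic-data generator
    with known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
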