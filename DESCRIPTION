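Package: haptrig
Title: Haploinsufficiency-Weighted Network Scoring of Somatic Copy-Number
    Alteration in Tumour Cohorts
Version: 0.1.0
Authors@R: person("HAPTRIG", "Maintainers", email = "maintainers@haptrig.dev",
    role = c("aut", "cre"))
Description: Scores the disruption of molecular pathways by somatic
    copy-number alterations (SCNAs) across a tumour cohort. Pathway gene
    sets are connected through protein-protein interactions, each
    interaction is weighted by gene dose-sensitivity evidence from yeast
    and mouse orthologues, and per-tumour module scores are normalized
    against the fully haploinsufficient state of the pathway. Significance
    is assigned by a tumour-paired permutation null with Bonferroni
    correction, the most impactful genes per pathway are ranked by their
    summed edge-score contribution, and annotated cohort-summary networks
    are exported for Cytoscape. A synthetic-cohort generator with known
    ground truth supports testing and calibration without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
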