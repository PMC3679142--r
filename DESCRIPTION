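Package: hdimer
Title: Prediction of Heterodimeric Protein Complexes from Weighted PPI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised classification of interacting protein pairs into
    heterodimeric (size-2) complexes versus pairs embedded in larger
    complexes. Implements seven interaction-weight and domain-count feature
    mappings computed from a weighted protein-protein interaction network, a
    positive semidefinite domain-composition indicator kernel over protein
    sets, a convex combination of the two, and class-weighted C-SVC with
    stratified 10-fold cross-validated precision/recall/F-measure evaluation.
    Includes readers for WI-PHI-style weighted edge lists, CYC2008-style
    complex membership tables and protein-domain annotations, the
    rule-based construction of positive and negative examples from a complex
    catalogue, and a synthetic benchmark generator with planted heterodimers
    and larger complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    kernlab,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
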