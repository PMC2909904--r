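Package: drugcipher
Title: Network-Based Drug Target Prioritization from Pharmacological and
    Genomic Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide prioritization of candidate drug targets by
    relating a drug's pharmacological similarity profile to network-based
    drug-protein closeness on a protein-protein interaction (PPI) network.
    Implements therapeutic similarity from ATC-code information content,
    chemical similarity from Tanimoto fingerprint comparison, shortest-path
    drug-protein closeness, and three concordance-scoring models (TS, CS
    and the combined MS regression model), together with leave-one-out
    validation, pooled rank-threshold ROC analysis, rank enrichment,
    genome-wide biological fingerprints with cosine activity resemblance,
    and a seeded synthetic-world generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
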