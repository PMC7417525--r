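Package: causalTiers
Title: Constraint-Based Causal Discovery with Temporal Tiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based causal network discovery for tiered
    observational cohort data with mixed variable types and block
    missingness. Implements local-to-global skeleton discovery (GLL-PC
    style interleaved inclusion/elimination), edge orientation from
    temporal tiers, collider (Y-structure) detection and Meek rule
    propagation, Markov-boundary extraction for a designated outcome,
    depth-bounded causal pathway enumeration with node-deletion influence
    ranking, and bootstrap edge-stability estimation. Ships a synthetic
    tiered-cohort generator with a d-separation oracle so the whole
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'causalTiers-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'schema-io.R'
    'network-io.R'
    'ci-test.R'
    'dsep.R'
    'gllpc.R'
    'orient.R'
    'markov-boundary.R'
    'paths.R'
    'bootstrap.R'
    'synthetic.R'
    'pipeline.R'
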