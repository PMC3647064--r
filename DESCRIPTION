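Package: paraprune
Title: Detection and Pruning of Misassigned Paralogs and Cross-Contamination
    in Phylogenomic Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens multi-gene (supermatrix) phylogenomic datasets for
    wrongly assigned paralogous sequences and cross-library contamination.
    Extracts highly supported clades from single-partition bootstrap trees,
    filters clades congruent with a-priori monophyletic groups, classifies
    the remainder as contamination (near-zero terminal branches plus
    near-identical overlapping sequences) or potential paralogy (best-hit
    gene-label comparison against primer taxa), and applies the resulting
    sequence- or partition-level prune actions to concatenated datasets.
    Also provides the accompanying diagnostics: branch-length ratios for
    flagged clades, leaf stability indices over bootstrap tree sets, and
    per-site log-likelihood differences between competing topologies under
    an amino-acid model with discrete-gamma rates and invariant sites.
    Includes a seeded simulator of the reciprocal-lack mechanism by which
    top-down reciprocal-best-hit orthology prediction misassigns paralogs,
    with ground truth for validating the screening pipeline end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
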