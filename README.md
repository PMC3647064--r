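# paraprune

Detection and pruning of wrongly assigned paralogous sequences and
cross-library contamination in multi-gene (supermatrix) phylogenomic
datasets, with the accompanying diagnostics and a ground-truthed
simulator of the misassignment mechanism.

## Why

Top-down orthology prediction (HaMStR-style reciprocal best hits against
a core ortholog set) can misassign a paralog through *reciprocal lack*:
for a gene family with close paralogs A and B, a query library holding
only B and a reference library holding only A will pass the reciprocity
check, and B silently joins the ortholog group of A. The affected taxa
then form spuriously well-supported clades in single-gene trees, and the
artifact can leak into the concatenated analysis. Cross-library
contamination (a transcript copied between libraries during sequencing
or via gut content) produces a similar signature: a near-zero-branch,
near-identical pair with high support. paraprune is for phylogenomics
practitioners who want to screen an assembled supermatrix for both
artifact classes *after* orthology prediction, prune what is compromised,
and quantify what the pruning changed.

## What it computes

Given per-partition amino-acid alignments, per-partition ML trees with
bootstrap supports, and tabular BLAST best hits:

1. every bipartition side with bootstrap support >= 95 (configurable) is
   flagged; clades congruent with a-priori monophyletic groups are set
   aside;
2. a flagged clade is **contamination** iff some member's terminal branch
   is <= eps (default 1e-6 subst/site) *and* some member pair is >= theta
   (default 0.99) identical over >= 20 shared columns — the pair is
   pruned;
3. otherwise the clade's best-hit gene labels are compared with the
   primer taxa's: any label split makes it a **potential paralog**. If
   the primer labels are consistent and unaffected, only the deviant
   sequences are pruned; if a primer taxon is affected or the primer
   labels disagree, the whole partition is excluded;
4. dataset variants AD / CPr / CPr&lt;id&gt; / CPPr are concatenated with
   coordinate charts (FASTA, sequential PHYLIP, RAxML-style partition
   files).

Diagnostics: the **branch ratio** (leading internal branch of a flagged
clade over the mean of all internal branch lengths), **leaf stability
indices** (triplet-based, over bootstrap tree sets), and **per-site
log-likelihood differences** `delta_psl(site) = lnL_H1 - lnL_H2` under
LG+Gamma+I (own Felsenstein-pruning evaluator; models pluggable), which
localize the support for a contested clade to individual partitions.

A seeded simulator reproduces the whole causal chain — duplication
predating speciation, per-branch paralog loss, Bernoulli EST detection,
5% contaminant transfer, reciprocal-best-hit emulation — with ground
truth, and the test suite verifies that the pipeline recovers exactly
the induced artifacts.

## Worked example

The package ships the screening campaign of the annelid case study as a
plain-text fixture (27 flagged clades in 24 partitions, with best-hit
labels and branch diagnostics). Running the full classifier over it:

```r
library(paraprune)
fx  <- annelid_screen_fixture()
cls <- classify_fixture(fx)
table(cls$assessment)
#>     contamination        no paralog potential paralog
#>                10                 7                10
subset(cls, partition %in% c("22433", "21904"))
#>   partition clade        assessment             action
#> 1     21904     A potential paralog partition excluded
#> 2     21904     B potential paralog partition excluded
#> 5     22433     A potential paralog sequences excluded
```

Ten clades are contamination (the affected pairs are pruned), ten are
potential paralogs — partition 22433's clade deviates from the primer
consensus so only its three sequences are pruned, while 21904's
inconsistent primer labels force exclusion of the whole partition — and
seven show no paralogy and trigger no action.

The branch-ratio diagnostic for the most extreme paralog clade, on a
tree constructed to match its recorded branch lengths:

```r
members <- fx$clades$members[[which(fx$clades$partition == "22433")]]
tree <- make_diagnostic_tree(members, leading = 4.1762, ratio = 13.40)
branch_diagnostics(tree, members)
#> $leading_branch_length  4.1762
#> $mean_internal_branch   0.3117
#> $branch_ratio           13.4
```

A ratio of 13.4 means the branch subtending the clade is thirteen times
the tree's average internal branch — but the no-paralog clades reach 3.7,
so branch length alone cannot separate the classes; the label comparison
does.

See `vignettes/paralogy-screening.Rmd` for the model, the decision rules,
the simulator's assumptions and the numerical conventions.

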