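---
title: "Screening supermatrices for misassigned paralogs and cross-contamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening supermatrices for misassigned paralogs and cross-contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraprune)
```

## The problem

Phylogenomic supermatrices assembled from EST/transcriptome libraries rely
on orthology prediction to group sequences into single-gene partitions.
Top-down, reciprocal-best-hit predictors (HaMStR-style) can be fooled by
*reciprocal lack*: a gene family holds two closely related paralogs A and
B; one taxon set samples only A, another only B. A hidden-Markov search
for A in a B-only library recovers B as the best hit, and the back-search
against a reference library that happens to lack B returns that
reference's A copy — reciprocity is "satisfied" and paralog B enters the
ortholog group. The affected taxa then share the paralog's deep
divergence and attract each other in the partition tree with strong
bootstrap support, which can propagate into the concatenated analysis.
Shallow libraries make this more likely, since gene absence from a
library is mostly a sampling effect.

A second artifact with a similar signature is cross-library
contamination: a transcript from one library ends up, essentially
verbatim, in another (parallel processing in a sequencing pipeline, gut
content, epibionts). The two taxa then form a spuriously supported clade
in any partition carrying the transferred transcript.

paraprune implements a screening procedure that finds both artifact
classes after orthology prediction, decides what to prune, rebuilds the
concatenated datasets, and supplies the diagnostics used to interrogate
suspicious clades.

## The procedure

1. **Bootstrap screen** (`screen_trees()`): from each single-partition
   ML tree, every internal edge with bootstrap support at or above a
   threshold (default 95) is extracted. Single-gene trees are unrooted,
   so a "clade" is implemented as *both sides of the bipartition*; each
   side carries the edge's support and leading branch length. Edges with
   absent support never qualify — absence of evidence is not a support
   value of zero.
2. **A-priori filter** (`filter_apriori()`): a flagged clade whose taxon
   set is a subset of a group with strong independent evidence of
   monophyly (e.g. Clitellata) is discarded; a clade that adds any taxon
   from outside such a group is kept for investigation.
3. **Contamination assessment** (`assess_contamination()`): a clade is
   contamination iff (a) at least one member's terminal branch length is
   at most `eps` and (b) some pair of members is at least `theta`
   identical over at least `min_overlap` shared alignment columns. Both
   criteria are required jointly. The affected pair is pruned from that
   partition: the true donor cannot be decided computationally, so both
   sequences go.
4. **Paralogy assessment** (`assess_paralogy()`): best-hit gene labels
   (from BLAST of the clade members and the primer taxa against one or
   more reference transcriptomes) are compared. If every available clade
   label equals every available primer label the clade is `no_paralog`;
   a label split in *any* reference makes it `potential_paralog`. A
   member with no hit is ignored (no hit is not evidence of a different
   gene); if nothing has a hit the record is `indeterminate` and triggers
   no action.
5. **Prune decision** (`decide_prune_action()`): if the primer labels are
   internally consistent and no primer taxon is among the affected
   (deviant-labeled) sequences, only the affected sequences are pruned;
   otherwise the core-ortholog gene is taken to be a paralog mixture and
   the entire partition is excluded.
6. **Dataset construction** (`apply_prune_actions()`,
   `concatenate_partitions()`): variants AD (all data), CPr
   (contamination pruned), one CPr<id> per paralogy case, and CPPr
   (everything pruned) are concatenated with a coordinate chart.
   Sequence-level pruning empties cells but never deletes columns, so AD
   and CPr have identical coordinates; partition exclusion deletes the
   partition's columns.

`run_screen_pipeline()` composes steps 1–6 and writes TSV reports plus
FASTA/PHYLIP/partition-file output.

## Diagnostics

* **Branch ratio** (`branch_diagnostics()`): the length of the internal
  branch leading to a flagged clade divided by the mean of *all*
  internal branch lengths (including the leading branch itself — with a
  single internal edge the ratio is 1 by construction). Tabulating this
  for confirmed-paralog versus no-paralog clades shows the two classes
  overlap (the case study's ranges are 0.77–13.40 vs 0.98–3.70), which is
  why branch lengths alone cannot drive automatic pruning.
* **Leaf stability** (`leaf_stability()`): per taxon, the mean over pairs
  of co-occurring taxa of the most frequent triplet resolution across a
  bootstrap tree set. We implement the triplet "maximum" variant
  (Thorley & Wilkinson family, as in Phyutility). Trees are read as
  rooted for triplet resolution; a triplet left unresolved by a tree
  (e.g. at a basal polytomy) does not enter that pair's denominator, and
  pairs never resolved are skipped — this is what makes identical tree
  sets score exactly 1 regardless of polytomies, which the alternative
  convention (counting unresolved trees in the denominator) violates.
  The exact variant in circulation differs between tools, so results are
  labeled with the variant implemented.
* **Per-site likelihood differences** (`delta_psl()`): for two candidate
  topologies evaluated on the same supermatrix, the per-site difference
  in log-likelihood localizes which partitions carry the support for a
  clade of interest. Support concentrated in a single partition is a red
  flag for artifact signal; support spread along the alignment is not.

## The likelihood engine

`site_log_likelihoods()` is an *evaluator*: branch lengths, the gamma
shape `alpha` and the invariant-site proportion `pinv` are inputs, never
optimized (the trees come from external ML software). The model is a
reversible 20-state chain built from exchangeabilities `s` and
frequencies `pi` (`Q[i,j] = s[i,j] pi[j]`, rows summing to zero, scaled
to one expected substitution per site). The LG matrix is bundled as the
published constants; any PAML-format matrix can be substituted
(`read_paml_matrix()`).

Numerical choices worth stating explicitly:

* Per site, `L = pinv * pi_x * [constant with residue x] +
  (1 - pinv) * (1/K) * sum_k L_pruning(r_k)`. The discrete-gamma rates
  are **not** rescaled by `1/(1 - pinv)`; programs differ on this
  convention, so ours is stated and tested (totals consequently differ
  from implementations that do rescale, e.g. phangorn's `+I` handling,
  while the plain-gamma and single-rate cases agree to numerical
  precision).
* "Constant" means all non-missing residues identical; gaps, `X` and `?`
  are marginalized as uninformative; an all-missing site contributes
  `ln L = 0`.
* Gamma categories are equal-probability with conditional-mean rates,
  renormalized to mean exactly 1.
* Partial likelihoods are rescaled per node with the log-scale carried
  separately, so long trees do not underflow.
* Category mixing happens in log space (log-mean-exp).

## The simulator and what it does (and does not) emulate

`simulate_gene_family()` duplicates a species tree at the root into
paralog subtrees A and B separated by an inter-paralog `divergence`
branch, applies per-branch loss (inherited by descendants), and evolves
sequences along the resulting gene tree with the same model engine used
by the likelihood module (one code path, one set of tests).
`sample_est_library()` thins genome content into libraries by Bernoulli
detection — the mechanism that creates reciprocal-lack patterns.
`inject_contamination()` copies a fraction of one library verbatim into
another; the default study condition for the contamination experiments is
a 5% transfer, matching the cross-talk level documented in the case
study. `emulate_orthology_assignment()` reproduces the top-down
predictor: forward best score against the core set's A sequences, back
best score against each reference library, acceptance iff the back-hit is
the reference's core member (strict "all references" mode by default).

Design choices:

* The "HMM search" is approximated by the maximum pairwise
  global-alignment score (BLOSUM62, affine gaps) against the core-set
  members. HaMStR's *representative* option, which can concatenate
  non-overlapping hits into chimeras, is deliberately not emulated —
  chimera detection needs sub-gene methods and is out of scope.
* The generator *verifies score separation* (minimum same-paralog score
  above maximum cross-paralog score) and refuses configurations where it
  fails. This makes the closed-form truth condition — a taxon is
  misassigned iff its library lacks A, holds B, and every reference
  library holds A but lacks B — provable, hence testable: the emulator
  must match it exactly, replicate for replicate.
* Default study conditions for the end-to-end experiments: a 9-taxon
  species tree with three primer taxa, one reference taxon,
  inter-paralog divergence 2.5 substitutions/site, per-branch loss 0.1,
  detection probability 0.8, 150 amino-acid sites per partition, 100
  bootstrap replicates on neighbor-joining partition trees. The sizes
  keep each simulated campaign in the seconds range while leaving the
  induced clade's support essentially at 100; they are small-scale
  emulations, not reproductions of a full 231-partition dataset.

What passing simulations show — and what they do not: the synthetic data
have no alignment error, no masking, no indels, no compositional
heterogeneity and no assembly chimeras. Detection of artifacts in this
setting demonstrates that the statistics and decision rules behave as
specified under their own assumptions, not that real EST campaigns are
this clean.

## Packaged case-study fixture

The 27 flagged clades of the annelid screening campaign, their best-hit
labels/e-values, and the branch-length diagnostics table ship as plain
TSVs (`annelid_screen_fixture()`). Quantities the published tables give
only qualitatively (the "identical sequences" / "zero branch length"
contamination evidence) are encoded as representative numeric evidence
columns, and `fixture_partition_inputs()` reconstructs alignments and
trees embodying that evidence so the *real* classifiers run end to end on
raw inputs; greek letters in gene names are transliterated, and one
"highly similar to X" hit is stored under its curated canonical label
(label curation is the accession-map's job by design). The classifier
reproduces all 27 assessment and action cells: 10 contamination, 10
potential paralog (3 partitions excluded, 5 sequence-pruned), 7 no
paralog. Where the running text and the diagnostics table disagree on one
branch length (0.0389 vs 0.0379 for one no-paralog clade), the table is
taken as canonical.

## Worked example

```{r example}
fx <- annelid_screen_fixture()
cls <- classify_fixture(fx)
table(cls$assessment)
subset(cls, partition %in% c("22433", "21904"))
```

```{r diagnostics}
members <- fx$clades$members[[which(fx$clades$partition == "22433")]]
tree <- make_diagnostic_tree(members, leading = 4.1762, ratio = 13.40)
branch_diagnostics(tree, members)
```

A synthetic campaign end to end:

```{r simulated}
sp <- ape::read.tree(text = paste0(
  "(((P1:0.15,P2:0.15):0.1,(P3:0.15,(Q1:0.12,Q2:0.12):0.08):0.08):0.1,",
  "((Q3:0.15,Q4:0.15):0.1,(Q5:0.15,Q6:0.15):0.1):0.1);"))
cfg <- sim_config(sp, divergence = 2.5, loss_prob = 0.1,
                  detect_prob = 0.8, primer_taxa = c("P1", "P2", "P3"),
                  reference_taxa = "P1", sites = 150, seed = 1)
bundle <- simulate_screening_bundle(cfg, n_partitions = 4,
                                    misassigned_taxa = c("Q1", "Q3", "Q5"),
                                    contam_donor = "Q2",
                                    contam_recipient = "Q6")
report <- suppressWarnings(run_screen_pipeline(
  bundle$trees, bundle$alignments, bundle$primer_taxa,
  groups = bundle$apriori_groups, labels = bundle$labels))
report
```

## Known limitations

* The screening consumes externally computed trees and BLAST tables; it
  neither aligns, masks, searches nor bootstraps real data.
* Contamination thresholds (`eps = 1e-6` substitutions/site,
  `theta = 0.99`, `min_overlap = 20` columns) operationalize "zero or
  very short branch" and "nearly identical"; the source procedure left
  them qualitative, so they are explicit, configurable, and echoed into
  every report for auditability.
* Gene-label equality is string equality after whitespace/case
  normalization; synonymous labels must be unified upstream in the
  accession-to-label map.
* The leaf stability variant is one of several in circulation; compare
  absolute values across tools with care.
* `delta_psl()` evaluates both hypotheses on the branch lengths supplied;
  it does not re-optimize branch lengths per hypothesis.
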