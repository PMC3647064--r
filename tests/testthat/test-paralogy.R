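test_that("label comparison classifies no-paralog and paralog cases", {
  # all taxa return the same gene: no paralogy
  rec <- assess_paralogy(
    c("Urechis caupo", "Capitella teleta", "Arenicola marina"),
    c("Urechis caupo" = "NSA2 ribosome biogenesis homolog",
      "Capitella teleta" = "NSA2 ribosome biogenesis homolog",
      "Arenicola marina" = "NSA2 ribosome biogenesis homolog"),
    c("Helobdella robusta" = "NSA2 ribosome biogenesis homolog",
      "Lottia gigantea" = "NSA2 ribosome biogenesis homolog"))
  expect_equal(rec$category, "no_paralog")

  # clade gene differs from the primer consensus
  rec2 <- assess_paralogy(
    c("Scoloplos armiger", "Sthenelais boa", "Eurythoe complanata"),
    c("Scoloplos armiger" = "PSMA2", "Sthenelais boa" = "PSMA2",
      "Eurythoe complanata" = "PSMA2"),
    c("Helobdella robusta" = "PSMA8", "Lottia gigantea" = "PSMA8",
      "Capitella teleta" = "PSMA8"))
  expect_equal(rec2$category, "potential_paralog")

  # internally inconsistent primer labels suffice on their own
  rec3 <- assess_paralogy(
    c("t1", "t2"), c(t1 = "alpha", t2 = "alpha"),
    c(p1 = "alpha", p2 = "alpha", p3 = "beta"))
  expect_equal(rec3$category, "potential_paralog")
})

test_that("no-hit labels are ignored, and all-no-hit is indeterminate", {
  rec <- assess_paralogy(
    c("t1", "t2"), c(t1 = "geneA", t2 = NA),
    c(p1 = "geneA", p2 = "geneA"))
  expect_equal(rec$category, "no_paralog")
  expect_match(paste(rec$notes, collapse = " "), "no-hit")

  rec2 <- assess_paralogy(c("t1", "t2"), c(t1 = NA, t2 = NA),
                          c(p1 = NA, p2 = NA))
  expect_equal(rec2$category, "indeterminate")
  act <- decide_prune_action(rec2, c("p1", "p2"))
  expect_equal(act$kind, "none")
})

test_that("labels are compared per reference; any split means paralogy", {
  # first reference agrees everywhere, the second reveals the split
  clade <- data.frame(
    taxon = rep(c("Owenia fusiformis", "Cerebratulus lacteus"), 2),
    reference = rep(c("Bos taurus", "Branchiostoma floridae"), each = 2),
    label = c("CETN1", "CETN1", "CETN3", "CETN3"),
    stringsAsFactors = FALSE)
  primer <- data.frame(
    taxon = rep(c("Capitella teleta", "Helobdella robusta"), 2),
    reference = rep(c("Bos taurus", "Branchiostoma floridae"), each = 2),
    label = c("CETN1", "CETN1", "CETN2", "CETN2"),
    stringsAsFactors = FALSE)
  rec <- assess_paralogy(c("Owenia fusiformis", "Cerebratulus lacteus"),
                         clade, primer)
  expect_equal(rec$category, "potential_paralog")

  # first reference alone would say no paralog
  rec_bt <- assess_paralogy(
    c("Owenia fusiformis", "Cerebratulus lacteus"),
    clade[clade$reference == "Bos taurus", ],
    primer[primer$reference == "Bos taurus", ])
  expect_equal(rec_bt$category, "no_paralog")
})

test_that("prune decisions follow the primer-taxon rule", {
  primer_taxa <- c("Lottia gigantea", "Capitella teleta",
                   "Helobdella robusta")
  # primers unaffected: prune only the deviant sequences
  rec <- assess_paralogy(
    c("Scoloplos armiger", "Sthenelais boa", "Eurythoe complanata"),
    c("Scoloplos armiger" = "PSMA2", "Sthenelais boa" = "PSMA2",
      "Eurythoe complanata" = "PSMA2"),
    c("Helobdella robusta" = "PSMA8", "Lottia gigantea" = "PSMA8",
      "Capitella teleta" = "PSMA8"), partition_id = "22433")
  act <- decide_prune_action(rec, primer_taxa)
  expect_equal(act$kind, "prune_sequences")
  expect_equal(act$target_taxa,
               sort(c("Scoloplos armiger", "Sthenelais boa",
                      "Eurythoe complanata")))

  # inconsistent primer labels: the whole partition goes
  rec2 <- assess_paralogy(
    c("Urechis caupo", "Lottia gigantea"),
    c("Urechis caupo" = "Rho GDI beta", "Lottia gigantea" = "Rho GDI beta"),
    c("Capitella teleta" = "Rho GDI alpha",
      "Helobdella robusta" = "Rho GDI beta"), partition_id = "21904")
  act2 <- decide_prune_action(rec2, primer_taxa)
  expect_equal(act2$kind, "exclude_partition")

  # a primer taxon among the affected sequences: partition excluded
  rec3 <- assess_paralogy(
    c("Lottia gigantea", "Themiste lageniformis"),
    c("Lottia gigantea" = "XIRP2",
      "Themiste lageniformis" = "LASP1-like"),
    c("Helobdella robusta" = "CSRP3", "Capitella teleta" = "CSRP3"),
    partition_id = "24126")
  act3 <- decide_prune_action(rec3, primer_taxa)
  expect_equal(act3$kind, "exclude_partition")

  # no paralogy: no action
  none <- decide_prune_action(
    assess_paralogy(c("a", "b"), c(a = "g", b = "g"), c(p = "g")),
    primer_taxa)
  expect_equal(none$kind, "none")
})

test_that("label comparison is whitespace- and case-insensitive", {
  rec <- assess_paralogy(
    c("t1"), c(t1 = "  Heat shock 70 kDa   protein 8 "),
    c(p1 = "heat shock 70 kda protein 8"))
  expect_equal(rec$category, "no_paralog")
})

test_that("branch diagnostics match their definition", {
  # all internal branches equal: ratio 1
  st <- parse_support_tree(
    "(((A:1,B:1):0.3,C:1):0.3,(D:1,E:1):0.3,F:1);", "eq")
  d <- branch_diagnostics(st, c("A", "B"))
  expect_equal(d$branch_ratio, 1.0)

  # tree with one internal edge
  one <- parse_support_tree("((A:1,B:1):0.7,C:1,D:1);", "one")
  expect_equal(branch_diagnostics(one, c("A", "B"))$branch_ratio, 1.0)

  expect_error(branch_diagnostics(st, c("A", "C")), "not an edge")
})

test_that("a 17-leaf construction reproduces the extreme ratio", {
  members <- c("Scoloplos armiger", "Sthenelais boa", "Eurythoe complanata")
  st <- make_diagnostic_tree(members, leading = 4.1762, ratio = 13.40)
  expect_equal(ape::Ntip(st$phylo), 17L)
  d <- branch_diagnostics(st, members)
  expect_equal(d$leading_branch_length, 4.1762)
  expect_equal(d$branch_ratio, 13.40, tolerance = 0.005 / 13.40)
})

test_that("branch ratio equals brute force and is scale invariant", {
  set.seed(81)
  for (rep in 1:8) {
    st <- random_support_tree(12, p_absent = 0)
    phy <- st$phylo
    ie_child <- phy$edge[, 2L][phy$edge[, 2L] > ape::Ntip(phy)]
    node <- sample(ie_child, 1)
    clade <- paraprune:::tips_below(phy, node)
    d <- branch_diagnostics(st, clade)
    # brute force straight off the edge table
    internal <- phy$edge[, 2L] > ape::Ntip(phy)
    expect_equal(d$mean_internal_branch,
                 sum(phy$edge.length[internal]) / sum(internal))
    expect_equal(d$branch_ratio,
                 phy$edge.length[match(node, phy$edge[, 2L])] /
                   mean(phy$edge.length[internal]))
    # scaling all branch lengths leaves the ratio unchanged
    st2 <- st
    st2$phylo$edge.length <- st2$phylo$edge.length * 7.3
    expect_equal(branch_diagnostics(st2, clade)$branch_ratio,
                 d$branch_ratio)
  }
})
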