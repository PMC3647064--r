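mk_part <- function(id, seqs) partition_alignment(seqs, id)

test_that("redundant partitions are detected by taxon set and content", {
  p1 <- mk_part("RPS4x", c(a = "MKV", b = "MLV"))
  p2 <- mk_part("RPS4y", c(a = "MKV", b = "MLV"))
  p3 <- mk_part("g3", c(a = "MKV", b = "MLI"))       # one residue differs
  p4 <- mk_part("g4", c(c = "MKV", d = "MLV"))       # disjoint taxa
  red <- detect_redundant_partitions(list(p1, p2, p3, p4))
  expect_equal(red$kept_id, "RPS4x")
  expect_equal(red$dropped_id, "RPS4y")
  kept <- drop_redundant_partitions(list(p1, p2, p3, p4))
  expect_equal(vapply(kept, `[[`, "", "partition_id"),
               c("RPS4x", "g3", "g4"))
})

test_that("redundancy detection equals an all-pairs comparison oracle", {
  set.seed(91)
  parts <- lapply(1:20, function(i) {
    taxa <- paste0("t", sort(sample(1:8, sample(3:6, 1))))
    random_alignment(taxa, 30, gap_frac = 0, id = sprintf("p%02d", i))
  })
  # plant two identical pairs
  parts[[5]] <- mk_part("p05", parts[[12]]$seqs)
  parts[[18]] <- mk_part("p18", parts[[3]]$seqs)
  red <- detect_redundant_partitions(parts)

  same <- function(a, b) {
    setequal(names(a$seqs), names(b$seqs)) &&
      all(a$seqs[sort(names(a$seqs))] == b$seqs[sort(names(b$seqs))])
  }
  oracle <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    if (same(parts[[i]], parts[[j]])) {
      oracle <- c(oracle, paste(sort(c(parts[[i]]$partition_id,
                                       parts[[j]]$partition_id)),
                                collapse = "+"))
    }
  }
  got <- paste(red$kept_id, red$dropped_id, sep = "+")
  expect_setequal(got, oracle)
  # exactly one member of each identical pair survives
  expect_false(any(red$kept_id %in% red$dropped_id))
  expect_equal(length(red$dropped_id), length(oracle))
})

test_that("prune actions edit rows and partitions as specified", {
  parts <- list(mk_part("a", c(t1 = "AAAAA", t2 = "CCCCC", t3 = "DDDDD")),
                mk_part("b", c(t1 = "EE", t2 = "FF")))
  acts <- list(
    structure(list(kind = "prune_sequences", partition_id = "a",
                   target_taxa = "t2"), class = "prune_action"),
    structure(list(kind = "exclude_partition", partition_id = "b",
                   target_taxa = character()), class = "prune_action"))
  out <- apply_prune_actions(parts, acts)
  expect_equal(names(out), "a")
  expect_equal(paraprune:::aln_taxa(out$a), c("t1", "t3"))
  expect_equal(out$a$length, 5L)  # columns untouched

  # idempotence for the same action set
  expect_warning(out2 <- apply_prune_actions(out, acts), "nothing to prune")
  expect_identical(out2, out)

  expect_warning(apply_prune_actions(parts, list(structure(
    list(kind = "prune_sequences", partition_id = "a",
         target_taxa = "zz"), class = "prune_action"))), "nothing to prune")
  expect_warning(apply_prune_actions(parts, list(structure(
    list(kind = "prune_sequences", partition_id = "nope",
         target_taxa = "t1"), class = "prune_action"))), "not present")
})

test_that("concatenation fills missing cells and charts coordinates", {
  parts <- list(mk_part("p1", c(A = "AAAAA", B = "CCCCC")),
                mk_part("p2", c(B = "DDDDDDD", C = "EEEEEEE")))
  sm <- concatenate_partitions(parts)
  expect_equal(length(sm$matrix), 3L)
  expect_equal(sm$length, 12L)
  expect_equal(unname(sm$matrix["A"]), "AAAAA-------")
  expect_equal(unname(sm$matrix["C"]), "-----EEEEEEE")
  expect_equal(sm$chart$start, c(0L, 5L))
  expect_equal(sm$chart$end, c(5L, 12L))

  # single partition: identity plus a one-segment chart
  sm1 <- concatenate_partitions(parts[1])
  expect_equal(sm1$matrix, parts[[1]]$seqs[c("A", "B")])
  expect_equal(nrow(sm1$chart), 1L)
})

test_that("sequence pruning conserves columns; exclusion removes them", {
  set.seed(101)
  parts <- lapply(1:6, function(i) {
    random_alignment(paste0("t", 1:9), 20 + i, id = sprintf("p%d", i))
  })
  ad <- concatenate_partitions(parts)
  pruned <- apply_prune_actions(parts, list(structure(
    list(kind = "prune_sequences", partition_id = "p3",
         target_taxa = c("t1", "t2", "t3")), class = "prune_action")))
  cpr <- concatenate_partitions(pruned, taxa_order = names(ad$matrix))
  expect_equal(cpr$length, ad$length)       # positions conserved
  expect_equal(names(cpr$matrix), names(ad$matrix))

  excluded <- apply_prune_actions(parts, list(structure(
    list(kind = "exclude_partition", partition_id = "p3",
         target_taxa = character()), class = "prune_action")))
  expect_equal(concatenate_partitions(excluded)$length,
               ad$length - parts[[3]]$length)

  # per-taxon non-gap cells: column conservation under row pruning
  count_data <- function(sm, tx) {
    sum(strsplit(sm$matrix[[tx]], "")[[1]] != "-")
  }
  expect_lte(count_data(cpr, "t1"), count_data(ad, "t1"))
  expect_equal(count_data(cpr, "t9"), count_data(ad, "t9"))
})

test_that("supermatrix output formats round-trip", {
  parts <- list(mk_part("22433", c(A = "MKVLM", B = "MKVIM")),
                mk_part("22606", c(A = "GG", B = "GA")))
  sm <- concatenate_partitions(parts)
  base <- tempfile()
  files <- write_supermatrix(sm, base)
  chart <- read_partition_chart(paste0(base, ".partitions"))
  expect_equal(chart, sm$chart)
  fa <- read_partition_alignment(paste0(base, ".fasta"), "sm")
  expect_equal(fa$seqs, sm$matrix)
  phy_lines <- readLines(paste0(base, ".phy"))
  expect_equal(phy_lines[1], "2 7")
})
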