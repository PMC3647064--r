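# Ready-to-screen synthetic datasets: partition alignments with
# bootstrap-supported trees, an induced reciprocal-lack paralogy case and an
# injected contamination pair, plus the ground truth needed to validate the
# whole screening pipeline.

#' Neighbor-joining tree with bootstrap supports for one partition
#'
#' p-distance (over shared non-missing columns) neighbor joining, with
#' supports from column-resampling bootstrap replicates. Negative NJ branch
#' lengths are clamped to zero.
#'
#' @param alignment A [partition_alignment()] with >= 4 taxa.
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling.
#' @return A `support_tree`.
#' @export
build_partition_tree <- function(alignment, n_boot = 100L, seed = 1L) {
  mat <- aln_matrix(alignment)
  if (nrow(mat) < 4L) {
    stop("need >= 4 taxa to build a partition tree", call. = FALSE)
  }
  nj_fun <- function(m) {
    tr <- ape::nj(p_distance_matrix(m))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  }
  phy <- nj_fun(mat)
  if (n_boot > 0L) {
    counts <- with_seed(seed, {
      ape::boot.phylo(phy, mat, nj_fun, B = n_boot, quiet = TRUE,
                      rooted = FALSE)
    })
    sup <- round(100 * counts / n_boot)
    sup[1L] <- NA  # root pseudo-node carries no bipartition
    phy$node.label <- ifelse(is.na(sup), "", as.character(as.integer(sup)))
  }
  support_tree(phy, alignment$partition_id)
}

# pairwise p-distance over shared non-missing columns
p_distance_matrix <- function(mat) {
  n <- nrow(mat)
  ok <- !is_missing_residue(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- ok[i, ] & ok[j, ]
      d[i, j] <- d[j, i] <- if (any(shared)) {
        mean(mat[i, shared] != mat[j, shared])
      } else 0.5
    }
  }
  stats::as.dist(d)
}

#' Simulate a ready-to-screen dataset with known artifacts
#'
#' Builds `n_partitions` single-gene partitions on the configured species
#' tree. One partition carries an induced reciprocal-lack paralogy case:
#' the taxa in `misassigned_taxa` contribute their paralog-B sequence
#' (their libraries lack A and every reference library lacks B), so the
#' orthology emulator accepts them and they form a spurious,
#' highly supported clade in that partition's tree. One clean partition
#' receives an injected contamination pair: the recipient's sequence is the
#' donor's, verbatim. Everything else is single-copy data evolved on the
#' species tree.
#'
#' @param config A [sim_config()]; `misassigned_taxa` must be non-primer
#'   leaves.
#' @param n_partitions Total partitions (>= 3).
#' @param misassigned_taxa Taxa induced to carry paralog B in the paralogy
#'   partition (>= 2 for a clade to form).
#' @param contam_donor,contam_recipient Taxa of the contamination pair.
#' @param n_boot Bootstrap replicates per partition tree.
#' @return List of class `screen_bundle`: `alignments`, `trees`,
#'   `labels` (per-partition per-taxon best-hit gene labels),
#'   `primer_taxa`, `apriori_groups` (the true species-tree clades) and
#'   `truth` (paralogy partition, misassigned taxa, contamination pair).
#' @export
simulate_screening_bundle <- function(config, n_partitions = 5L,
                                      misassigned_taxa,
                                      contam_donor, contam_recipient,
                                      n_boot = 100L) {
  stopifnot(inherits(config, "sim_config"), n_partitions >= 3L,
            length(misassigned_taxa) >= 2L)
  taxa <- config$species_tree$tip.label
  stopifnot(all(misassigned_taxa %in% taxa),
            !any(misassigned_taxa %in% config$primer_taxa),
            contam_donor %in% taxa, contam_recipient %in% taxa)
  paralogy_pid <- "gene01"
  contam_pid <- "gene02"
  pids <- sprintf("gene%02d", seq_len(n_partitions))

  alignments <- list()
  labels <- list()
  for (i in seq_along(pids)) {
    pid <- pids[i]
    pseed <- config$seed + i * 1000L
    if (pid == paralogy_pid) {
      part <- simulate_paralogy_partition(config, pid, misassigned_taxa,
                                          pseed)
    } else {
      part <- simulate_clean_partition(config, pid, pseed)
    }
    alignments[[pid]] <- part$alignment
    labels[[pid]] <- part$labels
  }

  # contamination: the recipient's sequence in one clean partition is
  # replaced by the donor's copy (library cross-talk)
  ca <- alignments[[contam_pid]]
  ca$seqs[[contam_recipient]] <- ca$seqs[[contam_donor]]
  alignments[[contam_pid]] <- ca

  trees <- lapply(alignments, function(a) {
    build_partition_tree(a, n_boot = n_boot,
                         seed = config$seed + a_seed_offset(a$partition_id))
  })
  names(trees) <- names(alignments)

  structure(list(alignments = alignments, trees = trees, labels = labels,
                 primer_taxa = config$primer_taxa,
                 apriori_groups = species_tree_groups(config$species_tree),
                 truth = list(paralogy_partition = paralogy_pid,
                              misassigned_taxa = sort(misassigned_taxa),
                              contamination_partition = contam_pid,
                              contamination_pair =
                                sort(c(contam_donor, contam_recipient))),
                 config = config),
            class = "screen_bundle")
}

a_seed_offset <- function(pid) {
  sum(utf8ToInt(pid)) %% 1000L
}

# a single-copy gene evolved on the species tree; labels all "<pid>-ortho"
simulate_clean_partition <- function(config, pid, seed) {
  seqs <- with_seed(seed, {
    simulate_sequences(config$species_tree, config$model, config$sites)
  })
  aln <- partition_alignment(seqs, pid)
  labels <- stats::setNames(rep(paste0(pid, "-orthologA"), length(seqs)),
                            names(seqs))
  list(alignment = aln, labels = labels)
}

# the reciprocal-lack partition: library masks are engineered so the
# emulator accepts paralog B for `misassigned_taxa`; the partition
# alignment holds each taxon's accepted sequence and the labels are the
# paralog annotations a reference-proteome blast would return
simulate_paralogy_partition <- function(config, pid, misassigned_taxa,
                                        seed) {
  cfg <- config
  cfg$seed <- seed
  fam <- simulate_gene_family(sim_config(
    species_tree = cfg$species_tree, divergence = cfg$divergence,
    loss_prob = 0, detect_prob = 1, primer_taxa = cfg$primer_taxa,
    reference_taxa = cfg$reference_taxa, sites = cfg$sites,
    model = cfg$model, seed = seed))
  taxa <- cfg$species_tree$tip.label
  pmat <- matrix(0, length(taxa), 2L, dimnames = list(taxa, c("A", "B")))
  pmat[, "A"] <- 1
  pmat[misassigned_taxa, "A"] <- 0
  pmat[misassigned_taxa, "B"] <- 1
  pmat[cfg$reference_taxa, "B"] <- 0
  libs <- sample_est_library(fam, detect_prob = pmat, seed = seed + 1L)
  core <- stats::setNames(
    fam$sequences[paste0(cfg$primer_taxa, "|A")], cfg$primer_taxa)
  assign_df <- emulate_orthology_assignment(libs, core,
                                            cfg$reference_taxa,
                                            mode = "all")
  seqs <- core
  for (r in seq_len(nrow(assign_df))) {
    if (assign_df$accepted[r]) {
      tx <- assign_df$taxon[r]
      seqs[[tx]] <- libs$libraries[[tx]][[assign_df$transcript[r]]]
    }
  }
  aln <- partition_alignment(seqs, pid)
  truth_par <- stats::setNames(rep("A", length(seqs)), names(seqs))
  truth_par[names(seqs) %in%
              assign_df$taxon[assign_df$misassigned]] <- "B"
  labels <- stats::setNames(paste0(pid, "-paralog", truth_par),
                            names(seqs))
  names(labels) <- names(seqs)
  labels[labels == paste0(pid, "-paralogA")] <- paste0(pid, "-orthologA")
  list(alignment = aln, labels = labels)
}

# every non-trivial clade of the (rooted) species tree, as an a-priori
# group set: clades of the true tree are taken as independently supported
species_tree_groups <- function(species_tree) {
  phy <- species_tree
  ntip <- ape::Ntip(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  groups <- lapply(nodes, function(n) sort(tips_below(phy, n)))
  groups <- Filter(function(g) {
    length(g) >= 2L && length(g) < ntip
  }, groups)
  names(groups) <- paste0("clade", seq_along(groups))
  groups
}

#' Generate a partition set with planted redundant duplicates
#'
#' Emulates the duplicate-partition structure that arises when two ortholog
#' sets overlap (the same gene entering the supermatrix twice under two
#' IDs): `n` partitions with random taxon subsets and sequences, of which
#' `n_duplicate_pairs` pairs are byte-identical per taxon. Used to exercise
#' [detect_redundant_partitions()].
#'
#' @param n Total number of partitions.
#' @param n_duplicate_pairs Number of planted identical pairs.
#' @param taxa Taxon name pool.
#' @param seed Integer seed.
#' @return Named list of [partition_alignment()] objects.
#' @export
synthetic_redundant_partitions <- function(n = 231L, n_duplicate_pairs = 2L,
                                           taxa = sprintf("taxon%02d", 1:39),
                                           seed) {
  stopifnot(n >= 2L * n_duplicate_pairs + 1L)
  with_seed(seed, {
    parts <- lapply(seq_len(n), function(i) {
      sub <- sort(sample(taxa, sample(8:min(20, length(taxa)), 1L)))
      len <- sample(60:300, 1L)
      seqs <- vapply(sub, function(tx) random_aa_string(len), "")
      partition_alignment(seqs, sprintf("part%03d", i))
    })
    names(parts) <- vapply(parts, `[[`, "", "partition_id")
    # plant byte-identical pairs (same taxa, same sequences, new ID)
    src <- sample(n, n_duplicate_pairs)
    dst <- sample(setdiff(seq_len(n), src), n_duplicate_pairs)
    for (k in seq_len(n_duplicate_pairs)) {
      id <- parts[[dst[k]]]$partition_id
      parts[[dst[k]]] <- partition_alignment(parts[[src[k]]]$seqs, id)
    }
    parts
  })
}
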