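# Packaged case-study fixture: the annelid EST screening campaign's flagged
# clades, their best-hit gene labels and the branch-length diagnostics,
# transcribed from the published assessment tables. Quantities the tables
# only describe qualitatively (the "identical sequences" / "zero branch
# length" contamination evidence) are encoded as representative numeric
# evidence columns; raw alignments and trees embodying that evidence are
# reconstructed deterministically by [fixture_partition_inputs()].

#' Load the annelid screening fixture
#'
#' 27 flagged clades in 24 partitions, their contamination evidence
#' (minimum terminal branch, best-pair identity and overlap), the
#' per-taxon best-hit gene labels with e-values, and the branch-length
#' diagnostics table (bootstrap value, leading branch length, branch
#' ratio) for the 17 clades assessed for paralogy.
#'
#' @return List with `clades`, `hits`, `diagnostics` data.frames and
#'   `primer_taxa`.
#' @export
annelid_screen_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "paraprune",
                                  mustWork = TRUE)
  clades <- utils::read.table(path("annelid_clades.tsv"), sep = "\t",
                              header = TRUE, quote = "",
                              stringsAsFactors = FALSE, check.names = FALSE)
  clades$members <- strsplit(clades$members, ";", fixed = TRUE)
  hits <- utils::read.table(path("annelid_best_hits.tsv"), sep = "\t",
                            header = TRUE, quote = "",
                            stringsAsFactors = FALSE)
  diagnostics <- utils::read.table(path("annelid_branch_diagnostics.tsv"),
                                   sep = "\t", header = TRUE, quote = "",
                                   stringsAsFactors = FALSE)
  list(clades = clades, hits = hits, diagnostics = diagnostics,
       primer_taxa = c("Lottia gigantea", "Capitella teleta",
                       "Helobdella robusta"))
}

#' Reconstruct raw partition inputs from the fixture's evidence
#'
#' Builds, for every fixture partition, an alignment and a tree that embody
#' the recorded evidence: each clade's designated pair (its first two
#' members) shares exactly `pair_overlap` non-gap columns at exactly
#' `pair_identity` identity, and every clade member's terminal branch
#' equals the clade's `min_terminal_branch` (one member of a contaminated
#' pair gets a slightly longer branch, as only one zero branch is
#' required). Other sequence pairs are unrelated. Deterministic.
#'
#' @param fixture From [annelid_screen_fixture()].
#' @return List with named lists `alignments` and `trees` keyed by
#'   partition ID.
#' @export
fixture_partition_inputs <- function(fixture = annelid_screen_fixture()) {
  clades <- fixture$clades
  aln_len <- 260L
  alignments <- list()
  trees <- list()
  for (pid in unique(clades$partition)) {
    rows <- clades[clades$partition == pid, , drop = FALSE]
    taxa <- unique(unlist(rows$members))
    seed <- 77000L + sum(utf8ToInt(pid))
    seqs <- with_seed(seed, {
      s <- vapply(taxa, function(tx) random_aa_string(aln_len), "")
      for (r in seq_len(nrow(rows))) {
        pair <- rows$members[[r]][1:2]
        o <- rows$pair_overlap[r]
        q <- rows$pair_identity[r]
        a <- random_aa_string(o)
        b <- mutate_string(a, round((1 - q) * o))
        pad <- strrep("-", aln_len - o)
        s[pair[1L]] <- paste0(a, pad)
        s[pair[2L]] <- paste0(b, pad)
      }
      s
    })
    alignments[[pid]] <- partition_alignment(seqs, pid)
    tb <- stats::setNames(rep(0.4, length(taxa)), taxa)
    for (r in seq_len(nrow(rows))) {
      members <- rows$members[[r]]
      tb[members] <- pmin(tb[members],
                          rows$min_terminal_branch[r] +
                            0.002 * (seq_along(members) - 1L))
    }
    nwk <- paste0("(", paste0(gsub(" ", "_", names(tb)), ":", tb,
                              collapse = ","), ");")
    phy <- ape::read.tree(text = nwk)
    phy$tip.label <- gsub("_", " ", phy$tip.label)
    trees[[pid]] <- support_tree(phy, pid)
  }
  list(alignments = alignments, trees = trees)
}

random_aa_string <- function(n) {
  paste(sample(AA_STATES, n, replace = TRUE), collapse = "")
}

# introduce exactly n mismatches at the first n positions
mutate_string <- function(s, n) {
  if (n <= 0L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (i in seq_len(n)) {
    ch[i] <- sample(setdiff(AA_STATES, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Classify the fixture clades
#'
#' Runs the full two-stage classifier over the fixture: contamination
#' first (on the reconstructed alignments and trees), then paralogy by
#' best-hit label comparison for the clades that are not contamination,
#' and finally the prune-action decision.
#'
#' @param fixture From [annelid_screen_fixture()].
#' @param eps,theta,min_overlap Contamination thresholds (see
#'   [assess_contamination()]).
#' @return `data.frame` with one row per clade: `partition`, `clade`,
#'   `assessment` (`"contamination"`, `"potential paralog"`,
#'   `"no paralog"`) and `action` (`"sequences excluded"`,
#'   `"partition excluded"`, `"none"`), plus the underlying verdicts,
#'   records and actions as attributes.
#' @export
classify_fixture <- function(fixture = annelid_screen_fixture(),
                             eps = 1e-6, theta = 0.99, min_overlap = 20L) {
  inputs <- fixture_partition_inputs(fixture)
  clades <- fixture$clades
  hits <- fixture$hits
  n <- nrow(clades)
  assessment <- character(n)
  action <- character(n)
  verdicts <- vector("list", n)
  records <- vector("list", n)
  actions <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- clades$partition[i]
    members <- clades$members[[i]]
    v <- assess_contamination(members, inputs$alignments[[pid]],
                              inputs$trees[[pid]], eps = eps,
                              theta = theta, min_overlap = min_overlap)
    verdicts[[i]] <- v
    if (v$is_contamination) {
      assessment[i] <- "contamination"
      action[i] <- "sequences excluded"
      actions[[i]] <- structure(list(kind = "prune_sequences",
                                     partition_id = pid,
                                     target_taxa = sort(v$best_pair)),
                                class = "prune_action")
      next
    }
    ph <- hits[hits$partition == pid, , drop = FALSE]
    labels <- stats::setNames(ph$label, ph$taxon)
    clade_labels <- stats::setNames(labels[members], members)
    primer_present <- intersect(fixture$primer_taxa, names(labels))
    primer_labels <- labels[primer_present]
    rec <- assess_paralogy(members, clade_labels, primer_labels,
                           partition_id = pid)
    act <- decide_prune_action(rec, fixture$primer_taxa)
    records[[i]] <- rec
    actions[[i]] <- act
    assessment[i] <- switch(rec$category,
                            potential_paralog = "potential paralog",
                            no_paralog = "no paralog",
                            rec$category)
    action[i] <- switch(act$kind,
                        prune_sequences = "sequences excluded",
                        exclude_partition = "partition excluded",
                        "none")
  }
  out <- data.frame(partition = clades$partition, clade = clades$clade,
                    assessment = assessment, action = action,
                    stringsAsFactors = FALSE)
  attr(out, "verdicts") <- verdicts
  attr(out, "records") <- records
  attr(out, "actions") <- actions
  out
}

#' Construct a tree reproducing given branch-length diagnostics
#'
#' Builds a pectinate (caterpillar) tree in which the edge subtending
#' `members` has length `leading` and all other internal edges share a
#' common length chosen so the mean of all internal branch lengths is
#' `leading / ratio`; [branch_diagnostics()] on the result therefore
#' recovers `ratio`. The number of internal edges grows with the ratio
#' (a ratio of 13.4 needs a 17-leaf tree).
#'
#' @param members Clade taxa (>= 2).
#' @param leading Leading internal branch length.
#' @param ratio Target branch ratio (> 0).
#' @return A `support_tree` whose tips are `members` plus filler taxa.
#' @export
make_diagnostic_tree <- function(members, leading, ratio) {
  stopifnot(length(members) >= 2L, leading > 0, ratio > 0)
  target_mean <- leading / ratio
  n_int <- max(3L, as.integer(ceiling(ratio)), length(members))
  n_leaves <- n_int + 3L
  fillers <- sprintf("filler%02d", seq_len(n_leaves - length(members)))
  leaves <- c(members, fillers)
  safe <- gsub(" ", "_", leaves)
  # rooted pectinate newick; unrooting leaves n_leaves - 3 internal edges
  nwk <- paste0("(", safe[1L], ":0.5,", safe[2L], ":0.5)")
  for (k in 3:n_leaves) nwk <- paste0("(", nwk, ":1,", safe[k], ":0.5)")
  phy <- ape::read.tree(text = paste0(nwk, ";"))
  phy$tip.label <- gsub("_", " ", phy$tip.label)
  st <- support_tree(phy)
  phy <- st$phylo
  ie <- internal_edges(phy)
  stopifnot(nrow(ie) == n_int)
  other <- (n_int * target_mean - leading) / (n_int - 1L)
  stopifnot(other >= 0)
  phy$edge.length[ie$edge] <- other
  # the leading edge subtends the clade
  sides <- lapply(ie$node, function(n) sort(tips_below(phy, n)))
  hit <- which(vapply(sides, identical, FALSE, y = sort(members)))
  stopifnot(length(hit) == 1L)
  phy$edge.length[ie$edge[hit]] <- leading
  support_tree(phy)
}
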