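# Contamination assessment: cross-library contamination shows up as a flagged
# clade in which (1) at least one member has a (near-)zero terminal branch and
# (2) two members are identical or nearly identical over the columns they
# share. Both criteria are required jointly.

#' Pairwise identity of two aligned sequences
#'
#' Overlap counts the columns where neither sequence has a gap (`-`) or
#' ambiguity (`X`); identity is matches divided by overlap. With zero
#' overlap the identity is undefined and reported as 0.
#'
#' @param seq_a,seq_b Equal-length aligned amino-acid strings.
#' @return List with `overlap` (integer columns) and `identity` (fraction).
#' @examples
#' pairwise_identity("ACD-F", "ACDEF")  # overlap 4, identity 1
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")", call. = FALSE)
  }
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  shared <- !is_missing_residue(a) & !is_missing_residue(b)
  overlap <- sum(shared)
  if (!overlap) return(list(overlap = 0L, identity = 0))
  list(overlap = as.integer(overlap),
       identity = sum(a[shared] == b[shared]) / overlap)
}

#' Classify a flagged clade as cross-contamination
#'
#' The verdict is positive iff some clade member's terminal branch length is
#' at most `eps` AND some pair of clade members is at least `theta`
#' identical over at least `min_overlap` shared columns. The extremal
#' values actually used (shortest terminal branch, best pair and its
#' identity/overlap) are recorded for auditability.
#'
#' @param clade Character vector of clade member taxa, or one row of a
#'   flagged-clades data.frame.
#' @param alignment The partition's [partition_alignment()].
#' @param tree The partition's `support_tree`.
#' @param eps Terminal-branch threshold, substitutions/site (default 1e-6,
#'   i.e. effectively a zero branch).
#' @param theta Identity threshold (default 0.99).
#' @param min_overlap Minimum shared columns for the identity to count
#'   (default 20).
#' @return List of class `contamination_verdict` with `is_contamination`,
#'   `min_terminal_branch`, `best_pair`, `best_pair_identity`,
#'   `overlap_columns`.
#' @export
assess_contamination <- function(clade, alignment, tree,
                                 eps = 1e-6, theta = 0.99,
                                 min_overlap = 20L) {
  taxa <- clade_taxa(clade)
  missing <- setdiff(taxa, aln_taxa(alignment))
  if (length(missing)) {
    stop("clade member(s) absent from alignment '",
         alignment$partition_id, "': ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  phy <- if (inherits(tree, "support_tree")) tree$phylo else tree
  tb <- terminal_branch_lengths(phy, taxa)
  min_tb <- min(tb)

  pairs <- utils::combn(taxa, 2L, simplify = FALSE)
  best <- list(pair = pairs[[1L]], identity = -1, overlap = 0L)
  best_qualifying <- NULL
  for (p in pairs) {
    pid <- pairwise_identity(alignment$seqs[[p[1L]]],
                             alignment$seqs[[p[2L]]])
    if (pid$overlap >= min_overlap &&
        (is.null(best_qualifying) ||
         pid$identity > best_qualifying$identity)) {
      best_qualifying <- list(pair = p, identity = pid$identity,
                              overlap = pid$overlap)
    }
    if (pid$identity > best$identity) {
      best <- list(pair = p, identity = pid$identity, overlap = pid$overlap)
    }
  }
  use <- best_qualifying %||% best
  short_branch <- min_tb <= eps
  near_identical <- !is.null(best_qualifying) &&
    best_qualifying$identity >= theta
  if (near_identical && !short_branch) {
    warning("clade in '", alignment$partition_id, "' has a near-identical ",
            "pair but no terminal branch <= eps; not flagged as ",
            "contamination", call. = FALSE)
  }
  structure(list(partition_id = alignment$partition_id,
                 taxa = taxa,
                 is_contamination = short_branch && near_identical,
                 min_terminal_branch = unname(min_tb),
                 best_pair = use$pair,
                 best_pair_identity = use$identity,
                 overlap_columns = as.integer(use$overlap)),
            class = "contamination_verdict")
}

#' @export
print.contamination_verdict <- function(x, ...) {
  cat("Clade {", paste(x$taxa, collapse = ", "), "} in '", x$partition_id,
      "': ", if (x$is_contamination) "CONTAMINATION" else "not contamination",
      "\n  min terminal branch ", signif(x$min_terminal_branch, 4),
      "; best pair ", paste(x$best_pair, collapse = "/"),
      " identity ", signif(x$best_pair_identity, 4),
      " over ", x$overlap_columns, " columns\n", sep = "")
  invisible(x)
}

clade_taxa <- function(clade) {
  if (is.character(clade)) return(clade)
  if (is.data.frame(clade)) return(clade$taxa[[1L]])
  if (is.list(clade) && !is.null(clade$taxa)) return(unlist(clade$taxa))
  stop("cannot interpret `clade`", call. = FALSE)
}

# verdicts for a whole flagged-clades table; alignments/trees are named
# lists keyed by partition id
assess_contamination_set <- function(clades, alignments, trees,
                                     eps = 1e-6, theta = 0.99,
                                     min_overlap = 20L) {
  lapply(seq_len(nrow(clades)), function(i) {
    pid <- clades$partition_id[i]
    assess_contamination(clades$taxa[[i]], alignments[[pid]], trees[[pid]],
                         eps = eps, theta = theta,
                         min_overlap = min_overlap)
  })
}
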