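# Leaf stability index over a set of (bootstrap) trees: the triplet-based
# "maximum" variant. For a focal taxon t and each unordered pair {i, j} of
# co-occurring taxa, the three resolutions ti|j, tj|i, ij|t are counted over
# the trees that contain all of t, i, j and resolve the triplet; the pair
# contributes the maximum relative frequency, and the index is the mean over
# pairs. A perfectly stable leaf scores 1.

#' Leaf stability index of a taxon
#'
#' @param trees List of trees (`phylo`, `support_tree` or `multiPhylo`),
#'   e.g. bootstrap replicates. Trees are read as rooted for triplet
#'   resolution, matching common practice.
#' @param taxon Focal taxon; must occur in at least one tree and co-occur
#'   with at least 2 other taxa.
#' @return Stability index in `[0, 1]`.
#' @export
leaf_stability <- function(trees, taxon) {
  trees <- as_tree_list(trees)
  has_t <- vapply(trees, function(p) taxon %in% p$tip.label, FALSE)
  if (!any(has_t)) {
    stop("taxon '", taxon, "' absent from all trees", call. = FALSE)
  }
  trees <- trees[has_t]
  others <- sort(unique(unlist(lapply(trees, function(p) p$tip.label))))
  others <- setdiff(others, taxon)
  if (length(others) < 2L) {
    stop("taxon '", taxon, "' co-occurs with fewer than 2 other taxa",
         call. = FALSE)
  }
  info <- lapply(trees, tree_triplet_info)
  pairs <- utils::combn(others, 2L, simplify = FALSE)
  per_pair <- vapply(pairs, function(pr) {
    counts <- c(ti = 0L, tj = 0L, ij = 0L)
    n_resolved <- 0L
    for (ti in info) {
      if (!all(c(taxon, pr) %in% ti$tips)) next
      res <- resolve_triplet(ti, taxon, pr[1L], pr[2L])
      if (is.na(res)) next
      counts[res] <- counts[res] + 1L
      n_resolved <- n_resolved + 1L
    }
    if (!n_resolved) return(NA_real_)
    max(counts) / n_resolved
  }, 0)
  per_pair <- per_pair[!is.na(per_pair)]
  if (!length(per_pair)) return(NA_real_)
  mean(per_pair)
}

#' Leaf stability table across tree sets
#'
#' Computes per-taxon leaf stability indices for each named tree set (e.g.
#' bootstrap replicates of the all-data, contamination-pruned and fully
#' pruned supermatrices) and the deltas between consecutive sets, for
#' spotting taxa whose stability shifts when suspect sequences are pruned.
#'
#' @param tree_sets Named list of tree lists.
#' @return `data.frame`: one row per taxon, one column per set, plus
#'   `delta_<B>_<A>` columns for consecutive sets A, B.
#' @export
leaf_stability_table <- function(tree_sets) {
  stopifnot(length(tree_sets) >= 1L, !is.null(names(tree_sets)))
  tree_sets <- lapply(tree_sets, as_tree_list)
  taxa <- sort(unique(unlist(lapply(tree_sets, function(set) {
    unlist(lapply(set, function(p) p$tip.label))
  }))))
  out <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (nm in names(tree_sets)) {
    out[[nm]] <- vapply(taxa, function(tx) {
      tryCatch(leaf_stability(tree_sets[[nm]], tx),
               error = function(e) NA_real_)
    }, 0)
  }
  sets <- names(tree_sets)
  if (length(sets) > 1L) {
    for (i in seq_len(length(sets) - 1L)) {
      out[[paste0("delta_", sets[i + 1L], "_", sets[i])]] <-
        out[[sets[i + 1L]]] - out[[sets[i]]]
    }
  }
  out
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  lapply(trees, function(t) {
    if (inherits(t, "support_tree")) t$phylo else t
  })
}

# per-tree precomputation for triplet resolution: pairwise MRCAs and
# topological node depths
tree_triplet_info <- function(phy) {
  list(tips = phy$tip.label,
       mrca = ape::mrca(phy, full = FALSE),
       depth = node_depths(phy))
}

node_depths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  depth <- integer(n)
  edges <- phy$edge[order(phy$edge[, 1L]), , drop = FALSE]
  # preorder traversal from the root
  phy2 <- stats::reorder(phy, "postorder")
  for (e in rev(seq_len(nrow(phy2$edge)))) {
    depth[phy2$edge[e, 2L]] <- depth[phy2$edge[e, 1L]] + 1L
  }
  depth
}

# resolution of triplet {t, i, j}: "ti", "tj" (t with i resp. j), "ij"
# (i with j), or NA when unresolved (all three pairwise MRCAs coincide)
resolve_triplet <- function(info, t, i, j) {
  m_ij <- info$mrca[i, j]
  m_ti <- info$mrca[t, i]
  m_tj <- info$mrca[t, j]
  d <- info$depth
  if (m_ij == m_ti && m_ij == m_tj) return(NA_character_)
  if (d[m_ij] > d[m_ti] && d[m_ij] > d[m_tj]) return("ij")
  if (d[m_ti] > d[m_ij] && d[m_ti] > d[m_tj]) return("ti")
  if (d[m_tj] > d[m_ij] && d[m_tj] > d[m_ti]) return("tj")
  NA_character_
}
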