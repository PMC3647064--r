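# Bootstrap screening: extract highly supported clades from single-partition
# trees and discard those congruent with a-priori monophyletic groups.

#' Extract clades with high bootstrap support
#'
#' On unrooted single-gene trees a "clade" is implemented as a side of a
#' bipartition: every internal edge whose support meets the threshold
#' contributes both of its sides (each with 2..N-2 taxa), sharing the edge's
#' support and leading branch length. Edges whose support is absent never
#' qualify.
#'
#' @param tree A `support_tree`.
#' @param threshold Minimum bootstrap support in 0..100 (default 95).
#' @return A `data.frame` of flagged clades with columns `partition_id`,
#'   `taxa` (list column of sorted taxon names), `support`,
#'   `leading_branch_length`, sorted by partition then by the
#'   lexicographically smallest member.
#' @export
extract_supported_clades <- function(tree, threshold = 95) {
  stopifnot(inherits(tree, "support_tree"))
  if (threshold < 0) {
    stop("`threshold` must be non-negative", call. = FALSE)
  }
  # values above 100 are allowed but unreachable: nothing qualifies
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  if (n < 4L) {
    message("tree '", tree$partition_id, "' has fewer than 4 leaves; ",
            "no internal edges to screen")
    return(flagged_clades())
  }
  bp <- tree_bipartitions(tree)
  keep <- which(!is.na(bp$edges$support) & bp$edges$support >= threshold)
  if (!length(keep)) return(flagged_clades())
  rows <- lapply(keep, function(i) {
    sides <- list(bp$sides[[i]], bp$complements[[i]])
    sides <- Filter(function(s) length(s) >= 2L && length(s) <= n - 2L, sides)
    lapply(sides, function(s) {
      list(partition_id = tree$partition_id, taxa = s,
           support = bp$edges$support[i],
           leading_branch_length = bp$edges$length[i])
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  flagged_clades(
    partition_id = vapply(rows, `[[`, "", "partition_id"),
    taxa = lapply(rows, `[[`, "taxa"),
    support = vapply(rows, `[[`, 0L, "support"),
    leading_branch_length = vapply(rows, `[[`, 0, "leading_branch_length"))
}

flagged_clades <- function(partition_id = character(), taxa = list(),
                           support = integer(),
                           leading_branch_length = numeric()) {
  df <- data.frame(partition_id = partition_id,
                   support = as.integer(support),
                   leading_branch_length = leading_branch_length,
                   stringsAsFactors = FALSE)
  df$taxa <- lapply(taxa, function(t) sort(as.character(t)))
  df <- df[, c("partition_id", "taxa", "support", "leading_branch_length")]
  if (nrow(df)) {
    first <- vapply(df$taxa, `[`, "", 1L)
    df <- df[order(df$partition_id, first), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("flagged_clades", "data.frame")
  df
}

#' Discard clades congruent with a-priori monophyletic groups
#'
#' A clade is discarded iff its taxon set is a subset of at least one group
#' with independent prior evidence of monophyly; a clade that adds any taxon
#' from outside the group (e.g. a clitellate clade that also contains a
#' capitellid) is retained for further investigation.
#'
#' @param clades Flagged clades from [extract_supported_clades()].
#' @param groups Named list of character vectors (group -> member taxa),
#'   e.g. from [read_apriori_groups()].
#' @return The retained clades, in input order.
#' @export
filter_apriori <- function(clades, groups) {
  if (!length(groups) || !nrow(clades)) return(clades)
  covered <- vapply(clades$taxa, function(taxa) {
    any(vapply(groups, function(g) all(taxa %in% g), FALSE))
  }, FALSE)
  out <- clades[!covered, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("flagged_clades", "data.frame")
  out
}

#' Read an a-priori group definition file
#'
#' Format: one group per line, `group-name TAB comma-separated taxa`.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_apriori_groups <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed group definition at line ", bad[1L], call. = FALSE)
  }
  groups <- lapply(parts, function(p) trimws(strsplit(p[[2L]], ",")[[1L]]))
  names(groups) <- vapply(parts, `[[`, "", 1L)
  small <- which(lengths(groups) < 2L)
  if (length(small)) {
    stop("group '", names(groups)[small[1L]], "' has fewer than 2 members",
         call. = FALSE)
  }
  groups
}

#' Screen a set of single-partition trees
#'
#' Composition of [extract_supported_clades()] and [filter_apriori()] over
#' all partitions, with per-partition and global counts reported with and
#' without the a-priori filter.
#'
#' @param trees List of `support_tree` objects.
#' @param threshold Minimum bootstrap support (default 95).
#' @param groups Optional a-priori groups (named list).
#' @return Object of class `screen_report`: list with `clades` (retained
#'   flagged clades), `n_flagged` (count after filtering), `n_unfiltered`
#'   (count before filtering) and `per_partition` counts.
#' @export
screen_trees <- function(trees, threshold = 95, groups = NULL) {
  if (!length(trees)) stop("no trees to screen", call. = FALSE)
  if (inherits(trees, "support_tree")) trees <- list(trees)
  all_clades <- do.call(rbind, lapply(trees, extract_supported_clades,
                                      threshold = threshold))
  all_clades <- flagged_clades(partition_id = all_clades$partition_id,
                               taxa = all_clades$taxa,
                               support = all_clades$support,
                               leading_branch_length =
                                 all_clades$leading_branch_length)
  kept <- filter_apriori(all_clades, groups %||% list())
  per_partition <- table(factor(kept$partition_id,
                                levels = vapply(trees, `[[`, "",
                                                "partition_id")))
  structure(list(clades = kept,
                 n_flagged = nrow(kept),
                 n_unfiltered = nrow(all_clades),
                 threshold = threshold,
                 per_partition = per_partition),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Bootstrap screen (threshold ", x$threshold, "): ",
      x$n_flagged, " clades retained (", x$n_unfiltered,
      " before the a-priori filter) in ",
      sum(x$per_partition > 0), " partitions\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write flagged clades as the report TSV (partition, members, support,
# leading branch length)
write_clades_tsv <- function(clades, path) {
  out <- data.frame(partition = clades$partition_id,
                    members = vapply(clades$taxa, paste, "", collapse = ";"),
                    support = clades$support,
                    leading_branch_length = clades$leading_branch_length)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_clades_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  flagged_clades(partition_id = df$partition,
                 taxa = strsplit(df$members, ";", fixed = TRUE),
                 support = df$support,
                 leading_branch_length = df$leading_branch_length)
}
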