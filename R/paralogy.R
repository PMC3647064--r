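# Paralogy assessment: compare best-hit gene labels of clade members against
# those of the primer taxa, decide the prune action, and compute the
# branch-length diagnostics for flagged clades.

#' Assess a flagged clade for paralogy from best-hit gene labels
#'
#' A clade is `no_paralog` iff every available clade label equals every
#' available primer label; it is `potential_paralog` if the clade labels
#' differ from the primer consensus or the primer labels are internally
#' inconsistent. Labels are compared by exact string equality after
#' whitespace normalization and case folding. A member with no hit is
#' ignored in the comparison (absence of a hit is not evidence of a
#' different gene) and noted. If all labels are no-hits the record is
#' `indeterminate` and triggers no action.
#'
#' With multiple reference transcriptomes, pass data.frames with columns
#' `taxon`, `reference`, `label`: labels are compared per reference and the
#' clade is `potential_paralog` if any reference yields a label split.
#'
#' @param clade Clade member taxa (character vector or flagged-clades row).
#' @param clade_labels Named character vector (taxon -> gene label, `NA` for
#'   no hit), or a data.frame `taxon`/`reference`/`label`.
#' @param primer_labels Labels of the primer taxa, same formats.
#' @param partition_id Optional partition identifier for the record.
#' @return List of class `assessment_record` with `category` (one of
#'   `"contamination"`, `"potential_paralog"`, `"no_paralog"`,
#'   `"indeterminate"`), the label maps, and `notes`.
#' @export
assess_paralogy <- function(clade, clade_labels, primer_labels,
                            partition_id = NULL) {
  taxa <- clade_taxa(clade)
  cl <- as_label_frame(clade_labels)
  pr <- as_label_frame(primer_labels)
  refs <- union(unique(cl$reference), unique(pr$reference))
  notes <- character()

  per_ref <- lapply(refs, function(r) {
    c_lab <- normalize_gene_label(cl$label[cl$reference == r])
    p_lab <- normalize_gene_label(pr$label[pr$reference == r])
    c_av <- c_lab[!is.na(c_lab)]
    p_av <- p_lab[!is.na(p_lab)]
    if (!length(c_av) || !length(p_av)) return("indeterminate")
    primer_consistent <- length(unique(p_av)) == 1L
    if (!primer_consistent) return("potential_paralog")
    if (all(c_av == p_av[1L])) "no_paralog" else "potential_paralog"
  })
  per_ref <- unlist(per_ref)

  if (all(per_ref == "indeterminate")) {
    category <- "indeterminate"
    notes <- c(notes, "no usable hits for clade and/or primer taxa")
  } else if (any(per_ref == "potential_paralog")) {
    category <- "potential_paralog"
  } else {
    category <- "no_paralog"
  }
  n_nohit <- sum(is.na(cl$label)) + sum(is.na(pr$label))
  if (n_nohit > 0 && category != "indeterminate") {
    notes <- c(notes, paste0(n_nohit, " no-hit label(s) ignored"))
  }
  structure(list(partition_id = partition_id %||% NA_character_,
                 taxa = taxa, category = category,
                 clade_labels = cl, primer_labels = pr,
                 notes = notes),
            class = "assessment_record")
}

#' @export
print.assessment_record <- function(x, ...) {
  cat("Clade {", paste(x$taxa, collapse = ", "), "}: ", x$category, "\n",
      sep = "")
  if (length(x$notes)) cat("  notes: ", paste(x$notes, collapse = "; "),
                           "\n", sep = "")
  invisible(x)
}

as_label_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("taxon", "label") %in% names(x)))
    if (is.null(x$reference)) x$reference <- "reference"
    return(x[, c("taxon", "reference", "label")])
  }
  data.frame(taxon = names(x), reference = "reference",
             label = as.character(x), stringsAsFactors = FALSE)
}

normalize_gene_label <- function(x) {
  out <- tolower(gsub("\\s+", " ", trimws(x)))
  out[!nzchar(out) | is.na(x)] <- NA_character_
  out
}

#' Decide the prune action for an assessment record
#'
#' `no_paralog` (and `indeterminate`/`contamination`) records trigger no
#' paralogy action here. For a `potential_paralog` record: if the primer
#' labels are internally consistent and no primer taxon sits inside the
#' flagged clade, only the clade members whose label differs from the
#' primer consensus are pruned; if a primer taxon is affected (inside the
#' clade) or the primer labels disagree among themselves, the core-ortholog
#' gene is taken to be already a paralog mixture and the entire partition
#' is excluded.
#'
#' @param record An `assessment_record`.
#' @param primer_taxa Character vector of primer taxon names.
#' @return List of class `prune_action` with `kind` (`"none"`,
#'   `"prune_sequences"` or `"exclude_partition"`), `partition_id` and
#'   `target_taxa`.
#' @export
decide_prune_action <- function(record, primer_taxa) {
  stopifnot(inherits(record, "assessment_record"))
  pid <- record$partition_id
  none <- structure(list(kind = "none", partition_id = pid,
                         target_taxa = character()),
                    class = "prune_action")
  if (record$category != "potential_paralog") return(none)

  pr <- record$primer_labels
  primer_inconsistent <- any(vapply(unique(pr$reference), function(r) {
    lab <- normalize_gene_label(pr$label[pr$reference == r])
    lab <- lab[!is.na(lab)]
    length(unique(lab)) > 1L
  }, FALSE))

  # the affected sequences: clade members whose label deviates from the
  # primer consensus in any reference
  cl <- record$clade_labels
  deviant <- unique(unlist(lapply(unique(pr$reference), function(r) {
    p_lab <- normalize_gene_label(pr$label[pr$reference == r])
    p_lab <- p_lab[!is.na(p_lab)]
    if (!length(p_lab) || length(unique(p_lab)) > 1L) return(character())
    consensus <- p_lab[1L]
    rows <- cl[cl$reference == r, , drop = FALSE]
    lab <- normalize_gene_label(rows$label)
    rows$taxon[!is.na(lab) & lab != consensus]
  })))

  if (primer_inconsistent || any(deviant %in% primer_taxa)) {
    return(structure(list(kind = "exclude_partition", partition_id = pid,
                          target_taxa = character()),
                     class = "prune_action"))
  }
  if (!length(deviant)) return(none)
  structure(list(kind = "prune_sequences", partition_id = pid,
                 target_taxa = sort(intersect(deviant, record$taxa))),
            class = "prune_action")
}

#' @export
print.prune_action <- function(x, ...) {
  cat("Action for '", x$partition_id, "': ", x$kind, sep = "")
  if (length(x$target_taxa)) {
    cat(" {", paste(x$target_taxa, collapse = ", "), "}")
  }
  cat("\n")
  invisible(x)
}

#' Branch-length diagnostics for a flagged clade
#'
#' Reports the length of the internal branch leading to the clade, the mean
#' over all internal branch lengths (including the leading branch itself),
#' and their ratio. For a tree with a single internal edge the ratio is 1
#' by construction.
#'
#' @param tree A `support_tree` (or `phylo`).
#' @param clade Clade taxa; must correspond to one side of an internal edge
#'   of the tree, else a hard error is raised.
#' @return List of class `branch_diagnostics` with
#'   `leading_branch_length`, `mean_internal_branch`, `branch_ratio`.
#' @export
branch_diagnostics <- function(tree, clade) {
  phy <- if (inherits(tree, "support_tree")) tree$phylo else tree
  taxa <- sort(clade_taxa(clade))
  bp <- tree_bipartitions(phy)
  hit <- which(vapply(seq_along(bp$sides), function(i) {
    identical(bp$sides[[i]], taxa) || identical(bp$complements[[i]], taxa)
  }, FALSE))
  if (!length(hit)) {
    stop("clade {", paste(taxa, collapse = ", "),
         "} is not an edge of the tree", call. = FALSE)
  }
  leading <- bp$edges$length[hit[1L]]
  mean_internal <- mean(bp$edges$length)
  structure(list(leading_branch_length = leading,
                 mean_internal_branch = mean_internal,
                 branch_ratio = if (mean_internal > 0)
                   leading / mean_internal else NA_real_),
            class = "branch_diagnostics")
}
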