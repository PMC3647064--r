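# End-to-end orchestration: screen -> contamination -> paralogy -> actions
# -> dataset variants (AD / CPr / CPr<id> / CPPr), with paper-style reports.

#' Run the full screening pipeline
#'
#' Composes the whole procedure over a partition set: extract clades with
#' bootstrap support at or above the threshold, drop those congruent with
#' the a-priori groups, classify the rest as contamination or (via
#' best-hit labels) paralogy, decide the prune actions, and build the
#' dataset variants: `AD` (all data, nothing pruned), `CPr` (contamination
#' pruned), one `CPr<id>` per paralogy case (contamination plus that single
#' case pruned) and `CPPr` (contamination and all paralogy pruned).
#'
#' @param trees Named list of `support_tree` objects (one per partition).
#' @param alignments Named list of [partition_alignment()] objects, same
#'   IDs.
#' @param primer_taxa Primer (core ortholog set) taxa.
#' @param groups Optional a-priori monophyletic groups (named list).
#' @param labels Optional per-partition best-hit gene labels: a named list
#'   `partition -> named character vector (taxon -> label)`, or a
#'   `best_hit_table` covering all partitions. Without labels every
#'   non-contamination clade is indeterminate and triggers no action.
#' @param threshold Bootstrap threshold (default 95).
#' @param eps,theta,min_overlap Contamination thresholds.
#' @param out_dir If given, reports (TSV) and matrices (FASTA, PHYLIP,
#'   partition files) are written there.
#' @return Object of class `pipeline_report`.
#' @export
run_screen_pipeline <- function(trees, alignments, primer_taxa,
                                groups = NULL, labels = NULL,
                                threshold = 95, eps = 1e-6, theta = 0.99,
                                min_overlap = 20L, out_dir = NULL) {
  ids <- vapply(alignments, `[[`, "", "partition_id")
  names(alignments) <- ids
  names(trees) <- vapply(trees, `[[`, "", "partition_id")
  if (!setequal(names(trees), ids)) {
    stop("stage screen: tree and alignment partition IDs differ",
         call. = FALSE)
  }

  report <- screen_trees(trees, threshold = threshold, groups = groups)
  clades <- report$clades

  n <- nrow(clades)
  assessment <- character(n)
  verdicts <- vector("list", n)
  actions <- list()
  records <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- clades$partition_id[i]
    members <- clades$taxa[[i]]
    v <- tryCatch(
      assess_contamination(members, alignments[[pid]], trees[[pid]],
                           eps = eps, theta = theta,
                           min_overlap = min_overlap),
      error = function(e) stop("stage contamination: partition '", pid,
                               "': ", conditionMessage(e), call. = FALSE))
    verdicts[[i]] <- v
    if (v$is_contamination) {
      assessment[i] <- "contamination"
      actions[[length(actions) + 1L]] <-
        structure(list(kind = "prune_sequences", partition_id = pid,
                       target_taxa = sort(v$best_pair),
                       reason = "contamination"),
                  class = "prune_action")
      next
    }
    lab <- partition_labels(labels, pid, union(members, primer_taxa))
    rec <- assess_paralogy(members, lab[members],
                           lab[intersect(primer_taxa, names(lab))],
                           partition_id = pid)
    act <- decide_prune_action(rec, primer_taxa)
    act$reason <- "paralogy"
    records[[i]] <- rec
    assessment[i] <- rec$category
    if (act$kind != "none") actions[[length(actions) + 1L]] <- act
  }

  # nested flagged clades can imply the same edit more than once
  actions <- actions[!duplicated(vapply(actions, function(a) {
    paste(a$kind, a$partition_id, paste(a$target_taxa, collapse = ";"))
  }, ""))]
  contam_actions <- Filter(function(a) a$reason == "contamination", actions)
  paralog_actions <- Filter(function(a) a$reason == "paralogy", actions)

  datasets <- list(AD = concatenate_partitions(alignments))
  cpr_parts <- apply_prune_actions(alignments, contam_actions)
  datasets$CPr <- concatenate_partitions(
    cpr_parts, taxa_order = names(datasets$AD$matrix))
  case_names <- make.unique(vapply(paralog_actions, function(a) {
    paste0("CPr", a$partition_id)
  }, ""), sep = "_")
  for (k in seq_along(paralog_actions)) {
    datasets[[case_names[k]]] <- concatenate_partitions(
      apply_prune_actions(cpr_parts, paralog_actions[k]),
      taxa_order = names(datasets$AD$matrix))
  }
  if (length(paralog_actions)) {
    datasets$CPPr <- concatenate_partitions(
      apply_prune_actions(cpr_parts, paralog_actions),
      taxa_order = names(datasets$AD$matrix))
  } else {
    datasets$CPPr <- datasets$CPr
  }

  out <- structure(list(
    screen = report,
    clades = clades,
    assessment = assessment,
    verdicts = verdicts,
    records = records,
    actions = actions,
    datasets = datasets,
    settings = list(threshold = threshold, eps = eps, theta = theta,
                    min_overlap = min_overlap),
    counts = c(flagged = n,
               contamination = sum(assessment == "contamination"),
               potential_paralog = sum(assessment == "potential_paralog"),
               no_paralog = sum(assessment == "no_paralog"),
               indeterminate = sum(assessment == "indeterminate"))),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(out, out_dir)
  out
}

partition_labels <- function(labels, pid, taxa) {
  if (is.null(labels)) {
    return(stats::setNames(rep(NA_character_, length(taxa)), taxa))
  }
  if (inherits(labels, "best_hit_table")) {
    got <- vapply(taxa, function(tx) {
      best_hit_label(labels, tx, pid)$label
    }, "")
    return(stats::setNames(got, taxa))
  }
  lab <- labels[[pid]]
  out <- stats::setNames(rep(NA_character_, length(taxa)), taxa)
  found <- intersect(taxa, names(lab))
  out[found] <- lab[found]
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Screening pipeline report\n")
  cat("  flagged clades:", x$counts[["flagged"]],
      "(threshold", x$settings$threshold, ")\n")
  cat("  contamination:", x$counts[["contamination"]],
      " potential paralog:", x$counts[["potential_paralog"]],
      " no paralog:", x$counts[["no_paralog"]],
      " indeterminate:", x$counts[["indeterminate"]], "\n")
  cat("  dataset variants:", paste(names(x$datasets), collapse = ", "),
      "\n")
  invisible(x)
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_clades_tsv(report$clades, file.path(out_dir, "screen.tsv"))
  n <- nrow(report$clades)
  assess_df <- data.frame(
    partition = report$clades$partition_id,
    members = vapply(report$clades$taxa, paste, "", collapse = ";"),
    support = report$clades$support,
    min_terminal_branch =
      vapply(report$verdicts, `[[`, 0, "min_terminal_branch"),
    best_pair_identity =
      vapply(report$verdicts, `[[`, 0, "best_pair_identity"),
    overlap = vapply(report$verdicts, `[[`, 0L, "overlap_columns"),
    assessment = report$assessment,
    stringsAsFactors = FALSE)
  utils::write.table(assess_df, file.path(out_dir, "assessment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  act_df <- data.frame(
    partition = vapply(report$actions, `[[`, "", "partition_id"),
    kind = vapply(report$actions, `[[`, "", "kind"),
    taxa = vapply(report$actions, function(a) {
      paste(a$target_taxa, collapse = ";")
    }, ""),
    reason = vapply(report$actions, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  utils::write.table(act_df, file.path(out_dir, "actions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  settings <- report$settings
  writeLines(paste(names(settings), unlist(settings), sep = "\t"),
             file.path(out_dir, "settings.tsv"))
  for (nm in names(report$datasets)) {
    write_supermatrix(report$datasets[[nm]], file.path(out_dir, nm))
  }
  invisible(out_dir)
}
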