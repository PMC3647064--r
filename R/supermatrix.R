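# Supermatrix construction: redundant-partition detection, application of
# prune actions, concatenation and standard-format output.

#' Detect redundant partitions
#'
#' Partitions are grouped by identical taxon composition; within a group,
#' partitions whose sequences are byte-identical for every taxon are
#' redundant duplicates. The lexicographically first partition ID of each
#' redundancy class is kept.
#'
#' @param partitions List of [partition_alignment()] objects.
#' @return `data.frame` with columns `kept_id`, `dropped_id` (one row per
#'   dropped partition; zero rows when nothing is redundant).
#' @export
detect_redundant_partitions <- function(partitions) {
  if (length(partitions) < 2L) {
    return(data.frame(kept_id = character(), dropped_id = character()))
  }
  ids <- vapply(partitions, `[[`, "", "partition_id")
  names(partitions) <- ids
  taxon_sig <- vapply(partitions, function(p) {
    paste(sort(aln_taxa(p)), collapse = "\r")
  }, "")
  kept <- character()
  dropped <- character()
  for (grp in split(ids, taxon_sig)) {
    if (length(grp) < 2L) next
    grp <- sort(grp)
    # content signature: taxon-sorted concatenation of the sequences
    content <- vapply(grp, function(id) {
      p <- partitions[[id]]
      paste(p$seqs[sort(aln_taxa(p))], collapse = "\r")
    }, "")
    for (cls in split(grp, content)) {
      if (length(cls) < 2L) next
      cls <- sort(cls)
      kept <- c(kept, rep(cls[1L], length(cls) - 1L))
      dropped <- c(dropped, cls[-1L])
    }
  }
  ord <- order(kept, dropped)
  data.frame(kept_id = kept[ord], dropped_id = dropped[ord],
             stringsAsFactors = FALSE)
}

#' Drop redundant partitions
#'
#' Convenience wrapper: runs [detect_redundant_partitions()] and returns
#' the partitions with the redundant duplicates removed.
#'
#' @inheritParams detect_redundant_partitions
#' @export
drop_redundant_partitions <- function(partitions) {
  red <- detect_redundant_partitions(partitions)
  ids <- vapply(partitions, `[[`, "", "partition_id")
  partitions[!ids %in% red$dropped_id]
}

#' Apply prune actions to a partition set
#'
#' `prune_sequences` removes the target taxa's rows from the named
#' partition (their cells become missing in any later concatenation;
#' columns are never deleted); `exclude_partition` removes the partition
#' entirely. Actions are independent and order-insensitive; pruning a taxon
#' absent from the partition is a warning and a no-op.
#'
#' @param partitions List of [partition_alignment()] objects.
#' @param actions List of `prune_action` objects
#'   (see [decide_prune_action()]).
#' @return The edited partition list.
#' @export
apply_prune_actions <- function(partitions, actions) {
  ids <- vapply(partitions, `[[`, "", "partition_id")
  names(partitions) <- ids
  if (inherits(actions, "prune_action")) actions <- list(actions)
  for (act in actions) {
    if (act$kind == "none") next
    pid <- act$partition_id
    if (!pid %in% names(partitions)) {
      # absent partition (e.g. already excluded): actions must stay
      # order-insensitive and idempotent, so this is a no-op
      if (act$kind == "prune_sequences") {
        warning("partition '", pid, "' not present; nothing to prune",
                call. = FALSE)
      }
      next
    }
    if (act$kind == "exclude_partition") {
      partitions[[pid]] <- NULL
    } else if (act$kind == "prune_sequences") {
      p <- partitions[[pid]]
      absent <- setdiff(act$target_taxa, aln_taxa(p))
      if (length(absent)) {
        warning("taxa not in partition '", pid, "', nothing to prune: ",
                paste(absent, collapse = ", "), call. = FALSE)
      }
      keep <- setdiff(aln_taxa(p), act$target_taxa)
      if (!length(keep)) {
        warning("all sequences pruned from partition '", pid,
                "'; partition dropped", call. = FALSE)
        partitions[[pid]] <- NULL
      } else {
        partitions[[pid]] <- partition_alignment(p$seqs[keep], pid)
      }
    } else {
      stop("unknown action kind '", act$kind, "'", call. = FALSE)
    }
  }
  partitions
}

#' Concatenate partitions into a supermatrix
#'
#' One row per taxon; a taxon missing from a partition gets gaps across that
#' partition's columns. The chart records each partition's coordinates in
#' internal 0-based half-open form.
#'
#' @param partitions List of [partition_alignment()] objects.
#' @param taxa_order Row order; defaults to the sorted union of all
#'   partition taxa.
#' @return Object of class `supermatrix`: list with `matrix` (named
#'   character vector of concatenated rows), `chart`
#'   (`partition_id`/`start`/`end` data.frame) and `length`.
#' @export
concatenate_partitions <- function(partitions, taxa_order = NULL) {
  if (!length(partitions)) stop("no partitions to concatenate", call. = FALSE)
  ids <- vapply(partitions, `[[`, "", "partition_id")
  if (is.null(taxa_order)) {
    taxa_order <- sort(unique(unlist(lapply(partitions, aln_taxa))))
  }
  lens <- vapply(partitions, `[[`, 0L, "length")
  ends <- cumsum(lens)
  starts <- ends - lens
  rows <- vapply(taxa_order, function(tx) {
    paste(vapply(partitions, function(p) {
      if (tx %in% aln_taxa(p)) p$seqs[[tx]] else strrep("-", p$length)
    }, ""), collapse = "")
  }, "")
  structure(list(matrix = rows,
                 chart = data.frame(partition_id = ids, start = starts,
                                    end = ends, stringsAsFactors = FALSE,
                                    row.names = NULL),
                 length = unname(ends[length(ends)])),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  empty <- sum(!grepl("[^-X?]", x$matrix))
  cat("Supermatrix: ", length(x$matrix), " taxa x ", x$length,
      " aa positions, ", nrow(x$chart), " partitions\n", sep = "")
  if (empty) cat("  note: ", empty, " taxon row(s) contain no data\n",
                 sep = "")
  invisible(x)
}

#' Write a supermatrix in standard formats
#'
#' Emits FASTA, sequential PHYLIP and a RAxML-style partition file
#' (1-based inclusive coordinates, e.g. `"LG, 22433 = 101-358"`).
#'
#' @param sm A `supermatrix`.
#' @param basepath Output path without extension; `.fasta`, `.phy` and
#'   `.partitions` are appended.
#' @param model Model tag written into the partition file (default
#'   `"LG"`).
#' @return Invisibly, the vector of files written.
#' @export
write_supermatrix <- function(sm, basepath, model = "LG") {
  stopifnot(inherits(sm, "supermatrix"))
  fa <- paste0(basepath, ".fasta")
  Biostrings::writeXStringSet(Biostrings::BStringSet(sm$matrix), fa)
  phy <- paste0(basepath, ".phy")
  con <- file(phy, "w")
  writeLines(paste(length(sm$matrix), sm$length), con)
  writeLines(paste(format(names(sm$matrix), width = 10), sm$matrix), con)
  close(con)
  parts <- paste0(basepath, ".partitions")
  writeLines(sprintf("%s, %s = %d-%d", model, sm$chart$partition_id,
                     sm$chart$start + 1L, sm$chart$end), parts)
  invisible(c(fa, phy, parts))
}

#' Read a RAxML-style partition file
#'
#' Parses lines of the form `"LG, 22433 = 101-358"` (1-based inclusive)
#' into the internal 0-based half-open chart.
#'
#' @param path Partition file.
#' @return `data.frame` with `partition_id`, `start`, `end`.
#' @export
read_partition_chart <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec(
    "^\\s*[^,]+,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) {
    stop("malformed partition definition at line ", bad[1L], call. = FALSE)
  }
  data.frame(partition_id = vapply(m, `[[`, "", 2L),
             start = as.integer(vapply(m, `[[`, "", 3L)) - 1L,
             end = as.integer(vapply(m, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}
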