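# Partition alignments: one gene's masked amino-acid alignment.

#' Construct a partition alignment
#'
#' A partition is one gene's aligned (and typically masked) amino-acid block.
#' Sequences use the 20 amino-acid letters plus `X` (ambiguity) and `-`
#' (gap); both are treated as missing data downstream.
#'
#' @param seqs Named character vector of aligned sequences (taxon -> string).
#' @param partition_id Stable identifier of the partition.
#' @return Object of class `partition_alignment` with fields `partition_id`,
#'   `seqs` and `length`.
#' @export
partition_alignment <- function(seqs, partition_id) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named by taxon", call. = FALSE)
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) {
    stop("duplicate taxon in partition '", partition_id, "': ",
         dup[1L], call. = FALSE)
  }
  seqs <- stats::setNames(toupper(unname(unlist(seqs))), names(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[which(lens != lens[1L])[1L]]
    stop("ragged alignment in partition '", partition_id,
         "': sequence of '", bad, "' has length ", nchar(seqs[bad]),
         ", expected ", lens[1L], call. = FALSE)
  }
  if (lens[1L] < 1L) stop("alignment has zero columns", call. = FALSE)
  structure(list(partition_id = as.character(partition_id),
                 seqs = seqs, length = unname(lens[1L])),
            class = "partition_alignment")
}

#' Read a partition alignment from FASTA
#'
#' @param path FASTA file with aligned amino-acid sequences.
#' @param id Partition identifier; defaults to the file name without
#'   extension.
#' @return A [partition_alignment()]. Input taxon order is preserved;
#'   lowercase residues are uppercased.
#' @export
read_partition_alignment <- function(path, id = NULL) {
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  set <- Biostrings::readBStringSet(path)
  partition_alignment(stats::setNames(as.character(set), names(set)), id)
}

#' Write a partition alignment to FASTA
#'
#' @param x A [partition_alignment()].
#' @param path Output file.
#' @export
write_partition_alignment <- function(x, path) {
  stopifnot(inherits(x, "partition_alignment"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x$seqs), path)
  invisible(path)
}

#' @export
print.partition_alignment <- function(x, ...) {
  cat("Partition '", x$partition_id, "': ", length(x$seqs), " taxa, ",
      x$length, " aa columns\n", sep = "")
  invisible(x)
}

aln_taxa <- function(x) names(x$seqs)

# character matrix view (taxa x columns)
aln_matrix <- function(x) {
  do.call(rbind, lapply(x$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]]))
}

is_missing_residue <- function(ch) ch == "-" | ch == "X" | ch == "?"
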