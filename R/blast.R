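# BLAST tabular (outfmt 6) parsing and best-hit extraction.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a BLAST tabular hit file (outfmt 6)
#'
#' Subject accessions are resolved to gene labels through
#' `accession_label_map`; rows with an unmapped accession keep the
#' accession as their label and a warning is raised. Scientific-notation
#' e-values, including bare exponents like `"1e-62"`, are parsed to reals.
#'
#' @param path Tab-separated BLAST file, 12 standard outfmt-6 columns.
#' @param accession_label_map Named character vector (accession -> gene
#'   label), or path to a 2-column TSV with accession and label.
#' @param partition_id Partition the queries belong to; defaults to the file
#'   name without extension.
#' @return A `data.frame` of class `best_hit_table` with columns `query`,
#'   `partition_id`, `subject`, `label`, `evalue`, `bitscore`.
#' @export
read_blast_table <- function(path, accession_label_map = NULL,
                             partition_id = NULL) {
  if (is.null(partition_id)) {
    partition_id <- tools::file_path_sans_ext(basename(path))
  }
  if (is.character(accession_label_map) && length(accession_label_map) == 1L &&
      is.null(names(accession_label_map)) && file.exists(accession_label_map)) {
    m <- utils::read.table(accession_label_map, sep = "\t", header = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
    accession_label_map <- stats::setNames(m[[2L]], m[[1L]])
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(best_hit_table(empty = TRUE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 12L)
  if (length(bad)) {
    stop("malformed BLAST row at line ", bad[1L], " of '", path,
         "': expected 12 tab-separated fields, got ", n_fields[bad[1L]],
         call. = FALSE)
  }
  row_mat <- do.call(rbind, lapply(fields, `[`, seq_len(12L)))
  evalue <- parse_evalue(row_mat[, 11L])
  bitscore <- suppressWarnings(as.numeric(row_mat[, 12L]))
  if (anyNA(evalue) || anyNA(bitscore)) {
    bad <- which(is.na(evalue) | is.na(bitscore))[1L]
    stop("malformed BLAST row at line ", bad, " of '", path,
         "': unparseable evalue/bitscore", call. = FALSE)
  }
  subject <- row_mat[, 2L]
  label <- subject
  if (!is.null(accession_label_map)) {
    mapped <- accession_label_map[subject]
    unmapped <- is.na(mapped)
    if (any(unmapped)) {
      warning("unmapped subject accession(s): ",
              paste(unique(subject[unmapped]), collapse = ", "),
              "; accession kept as gene label", call. = FALSE)
    }
    label <- unname(ifelse(unmapped, subject, mapped))
  }
  best_hit_table(data.frame(query = row_mat[, 1L],
                            partition_id = partition_id,
                            subject = subject, label = label,
                            evalue = evalue, bitscore = bitscore,
                            stringsAsFactors = FALSE))
}

best_hit_table <- function(df = NULL, empty = FALSE) {
  if (empty || is.null(df)) {
    df <- data.frame(query = character(), partition_id = character(),
                     subject = character(), label = character(),
                     evalue = numeric(), bitscore = numeric(),
                     stringsAsFactors = FALSE)
  }
  if (any(df$evalue < 0)) stop("negative e-value", call. = FALSE)
  class(df) <- c("best_hit_table", "data.frame")
  df
}

parse_evalue <- function(x) {
  x <- trimws(x)
  # tolerate the bare-exponent dialect "e-62"
  x <- sub("^e([+-][0-9]+)$", "1e\\1", x)
  suppressWarnings(as.numeric(x))
}

#' Best hit for a taxon in a partition
#'
#' Returns the hit with minimal e-value; ties are broken by maximal
#' bitscore, then lexicographically smallest gene label, so the result is
#' deterministic.
#'
#' @param table A `best_hit_table`.
#' @param taxon Query taxon name.
#' @param partition_id Partition identifier.
#' @return List with `label`, `evalue`, `bitscore` and `no_hit`. When the
#'   table has no row for the query, `no_hit` is `TRUE` and `label` is `NA`
#'   (a distinguished result, not an error).
#' @export
best_hit_label <- function(table, taxon, partition_id) {
  rows <- table[table$query == taxon & table$partition_id == partition_id, ,
                drop = FALSE]
  if (!nrow(rows)) {
    return(list(label = NA_character_, evalue = NA_real_,
                bitscore = NA_real_, no_hit = TRUE))
  }
  ord <- order(rows$evalue, -rows$bitscore, rows$label)
  top <- rows[ord[1L], ]
  list(label = top$label, evalue = top$evalue, bitscore = top$bitscore,
       no_hit = FALSE)
}
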