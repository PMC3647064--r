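# Support trees: unrooted trees with branch lengths and integer bootstrap
# supports on internal edges.

#' Parse a newick tree with bootstrap supports
#'
#' Reads a newick string into an unrooted `support_tree`. Supports are taken
#' from internal node labels (the RAxML convention); the alternative dialect
#' with supports in square brackets after the branch length
#' (`"):0.5[95]"`) is accepted via `dialect = "branch_label"`. Missing
#' supports stay missing: they are never defaulted to a number.
#'
#' @param text Newick string.
#' @param id Partition identifier.
#' @param dialect `"node_label"` (default) or `"branch_label"`.
#' @return Object of class `support_tree`: a list with `partition_id` and
#'   `phylo` (an unrooted [ape::read.tree()] tree whose `node.label` holds
#'   supports as integers, `NA` where absent).
#' @export
parse_support_tree <- function(text, id = "",
                               dialect = c("node_label", "branch_label")) {
  dialect <- match.arg(dialect)
  text <- trimws(text)
  if (dialect == "branch_label") {
    text <- gsub("\\):([0-9.eE+-]+)\\[([0-9.]+)\\]", ")\\2:\\1", text)
  }
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) {
    stop("unparseable newick for '", id, "' (near character ",
         newick_error_offset(text), ")", call. = FALSE)
  }
  support_tree(phy, id)
}

#' Read a support tree from a newick file
#'
#' @inheritParams parse_support_tree
#' @param path File containing one newick tree.
#' @export
read_support_tree <- function(path, id = NULL,
                              dialect = c("node_label", "branch_label")) {
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_support_tree(txt, id, dialect)
}

#' Wrap an ape tree as a support tree
#'
#' Unroots the tree if needed and validates branch lengths (non-negative)
#' and node-label supports (integers in 0..100, or absent).
#'
#' @param phy A `phylo` object.
#' @param id Partition identifier.
#' @export
support_tree <- function(phy, id = "") {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  if (ape::Ntip(phy) > 2L && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  if (any(phy$edge.length < 0)) {
    stop("negative branch length in tree '", id, "'", call. = FALSE)
  }
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup)) {
    stop("duplicate leaf name '", dup[1L], "' in tree '", id, "'",
         call. = FALSE)
  }
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep(NA_character_, phy$Nnode)
  sup <- suppressWarnings(as.numeric(lab))
  sup[!nzchar(trimws(ifelse(is.na(lab), "", lab)))] <- NA
  bad <- which(!is.na(lab) & nzchar(trimws(lab)) & is.na(sup))
  if (length(bad)) {
    stop("non-numeric internal node label '", lab[bad[1L]], "' in tree '",
         id, "'", call. = FALSE)
  }
  if (any(!is.na(sup) & (sup < 0 | sup > 100 | sup != round(sup)))) {
    stop("bootstrap support outside [0, 100] in tree '", id, "'",
         call. = FALSE)
  }
  phy$node.label <- ifelse(is.na(sup), "", as.character(as.integer(sup)))
  structure(list(partition_id = as.character(id), phylo = phy),
            class = "support_tree")
}

#' Write a support tree as newick
#'
#' @param x A `support_tree`.
#' @param path Output file; if `NULL` the newick string is returned.
#' @export
write_support_tree <- function(x, path = NULL) {
  stopifnot(inherits(x, "support_tree"))
  txt <- ape::write.tree(x$phylo)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.support_tree <- function(x, ...) {
  ie <- internal_edges(x$phylo)
  cat("Support tree '", x$partition_id, "': ", ape::Ntip(x$phylo),
      " leaves, ", nrow(ie), " internal edges\n", sep = "")
  invisible(x)
}

# Internal edges of an unrooted phylo: edges whose child is an internal node
# (the root has no incoming edge). Returns a data.frame with the child node,
# branch length, support (NA if absent) and the tip side below the child.
internal_edges <- function(phy) {
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  child <- phy$edge[, 2L]
  idx <- which(child > ntip)
  sup <- rep(NA_integer_, length(idx))
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label[child[idx] - ntip]
    sup <- suppressWarnings(as.integer(lab))
  }
  data.frame(edge = idx, node = child[idx],
             length = phy$edge.length[idx], support = sup)
}

# tips (labels) descending from an internal node
tips_below <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  desc <- node
  stack <- node
  kids_of <- split(phy$edge[, 2L], phy$edge[, 1L])
  tips <- integer(0)
  while (length(stack)) {
    n <- stack[[1L]]; stack <- stack[-1L]
    kids <- kids_of[[as.character(n)]]
    if (is.null(kids)) next
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  phy$tip.label[tips]
}

# all bipartitions (one per internal edge) with support and length
tree_bipartitions <- function(st) {
  phy <- if (inherits(st, "support_tree")) st$phylo else st
  ie <- internal_edges(phy)
  all_tips <- phy$tip.label
  sides <- lapply(ie$node, function(n) sort(tips_below(phy, n)))
  list(edges = ie, sides = sides, complements =
         lapply(sides, function(s) sort(setdiff(all_tips, s))))
}

check_newick_syntax <- function(text) {
  off <- newick_error_offset(text)
  if (!is.na(off)) {
    stop("unparseable newick (near character ", off, ")", call. = FALSE)
  }
  invisible(TRUE)
}

# first character offset at which the newick structure fails, else NA
newick_error_offset <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (!length(chars)) return(1L)
  depth <- 0L
  closed_root <- FALSE
  ended <- FALSE
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (ended && !grepl("^\\s$", c)) return(i)
    if (c == "(") {
      if (closed_root) return(i)
      depth <- depth + 1L
    } else if (c == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
      if (depth == 0L) closed_root <- TRUE
    } else if (c == ",") {
      if (depth == 0L) return(i)
    } else if (c == ";") {
      if (depth != 0L) return(i)
      ended <- TRUE
    }
  }
  if (depth != 0L) return(length(chars))
  if (!ended) return(length(chars))
  NA_integer_
}

# terminal branch length of each named tip
terminal_branch_lengths <- function(phy, taxa = phy$tip.label) {
  idx <- match(taxa, phy$tip.label)
  if (anyNA(idx)) {
    stop("taxa absent from tree: ",
         paste(taxa[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  pos <- match(idx, phy$edge[, 2L])
  stats::setNames(phy$edge.length[pos], taxa)
}
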