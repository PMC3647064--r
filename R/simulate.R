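# Seeded simulator of the reciprocal-lack mechanism: a gene family with a
# duplication predating speciation (paralogs A and B), per-branch paralog
# loss, per-taxon transcript detection producing reciprocal-lack patterns,
# near-identical contaminant transfer between libraries, and an emulator of
# top-down reciprocal-best-hit orthology assignment with ground truth.

#' Simulation configuration
#'
#' @param species_tree A rooted `phylo` with branch lengths (substitutions
#'   per site), or a newick string.
#' @param divergence Extra branch length separating the A and B paralog
#'   subtrees at the pre-speciation duplication (substitutions/site). Must
#'   be large enough that same-paralog alignment scores dominate
#'   cross-paralog scores; the generator verifies this.
#' @param loss_prob Per-branch probability that a paralog copy is lost on
#'   that branch (loss is inherited by all descendants).
#' @param detect_prob Per-taxon probability that a genome-present
#'   transcript enters the EST library; scalar, named vector, or a
#'   taxa-by-paralog matrix for fine control.
#' @param primer_taxa Taxa of the core ortholog set (their paralog-A
#'   sequences seed the search).
#' @param reference_taxa Subset of the primer taxa used for the back-blast
#'   reciprocity check.
#' @param sites Number of amino-acid sites to simulate.
#' @param model An [substitution_model()]; defaults to LG with no rate
#'   heterogeneity.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(species_tree, divergence = 1.5, loss_prob = 0.15,
                       detect_prob = 0.7, primer_taxa,
                       reference_taxa = primer_taxa[1L], sites = 200L,
                       model = substitution_model(alpha = 1, pinv = 0,
                                                  n_categories = 1L),
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory", call. = FALSE)
  }
  if (is.character(species_tree)) {
    species_tree <- ape::read.tree(text = species_tree)
  }
  stopifnot(inherits(species_tree, "phylo"),
            !is.null(species_tree$edge.length))
  if (loss_prob < 0 || loss_prob > 1) stop("loss_prob in [0,1]", call. = FALSE)
  if (any(unlist(detect_prob) < 0) || any(unlist(detect_prob) > 1)) {
    stop("detect_prob in [0,1]", call. = FALSE)
  }
  if (!all(reference_taxa %in% primer_taxa)) {
    stop("reference taxa must be a subset of the primer taxa", call. = FALSE)
  }
  if (!all(primer_taxa %in% species_tree$tip.label)) {
    stop("primer taxa must be leaves of the species tree", call. = FALSE)
  }
  structure(list(species_tree = species_tree, divergence = divergence,
                 loss_prob = loss_prob, detect_prob = detect_prob,
                 primer_taxa = primer_taxa, reference_taxa = reference_taxa,
                 sites = as.integer(sites), model = model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-paralog gene family with loss
#'
#' Duplicates the species tree at the root into paralog subtrees A and B
#' separated by `divergence`, applies per-branch loss independently in each
#' subtree, and evolves sequences along the resulting gene tree under the
#' configured model. If the loss pattern leaves zero sequences the family
#' is regenerated (up to `max_retries`). Reproducible per seed.
#'
#' @param config A [sim_config()].
#' @param max_retries Retry cap for all-lost loss patterns.
#' @return List of class `gene_family_sim`: `sequences` (named by
#'   `"taxon|paralog"`), `genome_presence` (taxa x c("A","B") logical),
#'   `gene_tree` (full, pre-loss), `pruned_gene_tree` (post-loss, `NULL`
#'   if < 2 survivors), `truth` (per-sequence paralog identity) and the
#'   config.
#' @export
simulate_gene_family <- function(config, max_retries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    taxa <- config$species_tree$tip.label
    gene_tree <- paralog_pair_tree(config$species_tree, config$divergence)
    for (attempt in seq_len(max_retries)) {
      presence <- vapply(c("A", "B"), function(par) {
        simulate_loss_mask(config$species_tree, config$loss_prob)
      }, logical(length(taxa)))
      rownames(presence) <- taxa
      if (any(presence)) break
      if (attempt == max_retries) {
        stop("loss pattern left zero sequences after ", max_retries,
             " attempts; lower `loss_prob`", call. = FALSE)
      }
    }
    seqs <- simulate_sequences(gene_tree, config$model, config$sites)
    present_names <- c(paste0(taxa[presence[, "A"]], "|A"),
                       paste0(taxa[presence[, "B"]], "|B"))
    seqs <- seqs[present_names]
    pruned <- NULL
    if (length(present_names) >= 2L) {
      drop <- setdiff(gene_tree$tip.label, present_names)
      pruned <- if (length(drop)) ape::drop.tip(gene_tree, drop) else gene_tree
    }
    truth <- data.frame(
      sequence = present_names,
      taxon = sub("\\|[AB]$", "", present_names),
      paralog = sub("^.*\\|", "", present_names),
      stringsAsFactors = FALSE)
    fam <- list(sequences = seqs, genome_presence = presence,
                gene_tree = gene_tree, pruned_gene_tree = pruned,
                truth = truth, config = config)
    class(fam) <- "gene_family_sim"
    validate_score_separation(fam)
    fam
  })
}

# two mirrored copies of the species tree joined by the inter-paralog
# divergence branch
paralog_pair_tree <- function(species_tree, divergence) {
  lab <- function(tree, par) {
    tree$tip.label <- paste0(tree$tip.label, "|", par)
    tree
  }
  nw <- function(tree) sub(";$", "", ape::write.tree(tree))
  txt <- paste0("(", nw(lab(species_tree, "A")), ":", divergence / 2, ",",
                nw(lab(species_tree, "B")), ":", divergence / 2, ");")
  ape::read.tree(text = txt)
}

# per-branch loss with inheritance: a tip retains the copy iff no edge on
# its root-to-tip path lost it
simulate_loss_mask <- function(species_tree, loss_prob) {
  phy <- stats::reorder(species_tree, "postorder")
  ntip <- ape::Ntip(phy)
  lost_edge <- stats::runif(nrow(phy$edge)) < loss_prob
  lost_node <- rep(FALSE, ntip + phy$Nnode)
  for (e in rev(seq_len(nrow(phy$edge)))) {   # preorder
    lost_node[phy$edge[e, 2L]] <- lost_node[phy$edge[e, 1L]] | lost_edge[e]
  }
  stats::setNames(!lost_node[seq_len(ntip)], phy$tip.label)
}

# evolve sequences along a tree: root drawn from the stationary
# frequencies, children by the model's transition probabilities; per-site
# gamma category resampled once per family
simulate_sequences <- function(phy, model, sites) {
  phy <- stats::reorder(phy, "postorder")
  ntip <- ape::Ntip(phy)
  n_nodes <- ntip + phy$Nnode
  cat_of_site <- sample.int(model$n_categories, sites, replace = TRUE)
  states <- matrix(NA_integer_, n_nodes, sites)
  root <- phy$edge[nrow(phy$edge), 1L]
  states[root, ] <- sample.int(20L, sites, replace = TRUE,
                               prob = model$frequencies)
  for (e in rev(seq_len(nrow(phy$edge)))) {  # preorder
    parent <- phy$edge[e, 1L]
    child <- phy$edge[e, 2L]
    for (ci in unique(cat_of_site)) {
      idx <- which(cat_of_site == ci)
      p <- prob_matrix(model, phy$edge.length[e] * model$rates[ci])
      par_states <- states[parent, idx]
      for (s in unique(par_states)) {
        at <- idx[par_states == s]
        states[child, at] <- sample.int(20L, length(at), replace = TRUE,
                                        prob = p[s, ])
      }
    }
  }
  out <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(row) {
    paste(AA_STATES[row], collapse = "")
  })
  stats::setNames(out, phy$tip.label)
}

# guard: same-paralog similarity must dominate cross-paralog similarity,
# otherwise the reciprocal-lack truth condition is not provable
validate_score_separation <- function(fam, scorer = align_score) {
  seqs <- fam$sequences
  par <- sub("^.*\\|", "", names(seqs))
  if (length(unique(par)) < 2L || length(seqs) < 3L) return(invisible(TRUE))
  same_min <- Inf
  cross_max <- -Inf
  for (i in seq_along(seqs)) {
    for (j in seq_len(i - 1L)) {
      sc <- scorer(seqs[[i]], seqs[[j]])
      if (par[i] == par[j]) same_min <- min(same_min, sc)
      else cross_max <- max(cross_max, sc)
    }
  }
  if (is.finite(same_min) && is.finite(cross_max) && same_min <= cross_max) {
    stop("insufficient inter-paralog divergence: same-paralog score ",
         signif(same_min, 4), " <= cross-paralog score ",
         signif(cross_max, 4), "; increase `divergence` or shorten the ",
         "species tree", call. = FALSE)
  }
  invisible(TRUE)
}

#' Global-alignment similarity score
#'
#' Default scorer for the orthology-assignment emulator: Needleman-Wunsch
#' global alignment under BLOSUM62 with affine gaps (opening 10,
#' extension 1). Deterministic.
#'
#' @param a,b Amino-acid strings.
#' @return Numeric alignment score.
#' @export
align_score <- function(a, b) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                Biostrings::AAString(b),
                                substitutionMatrix = data_env$BLOSUM62,
                                gapOpening = 10, gapExtension = 1,
                                type = "global", scoreOnly = TRUE)
}

#' Sample EST libraries from genome content
#'
#' Each genome-present transcript enters its taxon's library independently
#' with the detection probability: the sampling mechanism by which shallow
#' EST libraries miss genes and create reciprocal-lack patterns.
#'
#' @param fam A [simulate_gene_family()] result.
#' @param detect_prob Scalar, per-taxon named vector, or taxa-by-paralog
#'   matrix of inclusion probabilities; defaults to the config's.
#' @param seed Integer seed.
#' @return List of class `est_libraries`: `libraries` (per taxon, named
#'   character vector of transcripts), `library_presence` (taxa x paralogs
#'   logical) and `truth`.
#' @export
sample_est_library <- function(fam, detect_prob = NULL, seed) {
  stopifnot(inherits(fam, "gene_family_sim"))
  p <- detect_prob %||% fam$config$detect_prob
  taxa <- rownames(fam$genome_presence)
  pmat <- detect_prob_matrix(p, taxa)
  with_seed(seed, {
    lib_presence <- fam$genome_presence &
      (matrix(stats::runif(length(fam$genome_presence)),
              nrow(fam$genome_presence)) < pmat)
    dimnames(lib_presence) <- dimnames(fam$genome_presence)
    libraries <- lapply(taxa, function(tx) {
      pars <- c("A", "B")[lib_presence[tx, ]]
      if (!length(pars)) return(stats::setNames(character(), character()))
      nm <- paste0(tx, "|", pars)
      stats::setNames(fam$sequences[nm], pars)
    })
    names(libraries) <- taxa
    structure(list(libraries = libraries, library_presence = lib_presence,
                   truth = fam$truth, config = fam$config),
              class = "est_libraries")
  })
}

detect_prob_matrix <- function(p, taxa) {
  if (is.matrix(p)) {
    stopifnot(all(taxa %in% rownames(p)))
    return(p[taxa, c("A", "B"), drop = FALSE])
  }
  if (!is.null(names(p))) p <- p[taxa]
  matrix(rep(as.numeric(p), length.out = length(taxa)), length(taxa), 2L,
         dimnames = list(taxa, c("A", "B")))
}

#' Inject cross-library contamination
#'
#' Copies `ceiling(fraction * |donor library|)` donor transcripts verbatim
#' into the recipient library (emulating libraries processed in parallel in
#' a sequencing pipeline), tagging them in the returned record.
#'
#' @param libs An `est_libraries` object, or a plain named list of
#'   libraries.
#' @param donor,recipient Taxon names.
#' @param fraction Fraction of donor transcripts transferred (e.g. 0.05).
#' @param seed Integer seed (selects which transcripts transfer).
#' @return The input with the recipient library extended; injected entries
#'   are named `"contam:<donor>:<transcript>"` and listed in `$injected`.
#' @export
inject_contamination <- function(libs, donor, recipient, fraction, seed) {
  if (fraction < 0 || fraction > 1) stop("fraction in [0,1]", call. = FALSE)
  libraries <- if (inherits(libs, "est_libraries")) libs$libraries else libs
  stopifnot(donor %in% names(libraries), recipient %in% names(libraries))
  dn <- libraries[[donor]]
  n <- ceiling(fraction * length(dn))
  injected <- character()
  if (n > 0L) {
    pick <- with_seed(seed, sample(seq_along(dn), n))
    add <- stats::setNames(dn[pick],
                           paste0("contam:", donor, ":", names(dn)[pick]))
    libraries[[recipient]] <- c(libraries[[recipient]], add)
    injected <- names(add)
  }
  if (inherits(libs, "est_libraries")) {
    libs$libraries <- libraries
    libs$injected <- data.frame(donor = donor, recipient = recipient,
                                transcript = injected,
                                stringsAsFactors = FALSE)
    return(libs)
  }
  attr(libraries, "injected") <- injected
  libraries
}

#' Emulate top-down reciprocal-best-hit orthology assignment
#'
#' For each query taxon the forward step picks the library transcript that
#' best matches the core ortholog set (maximum score over the primer taxa's
#' paralog-A sequences); the back step finds that transcript's best match
#' in each reference taxon's library; the assignment is accepted iff the
#' back-hit is the reference's own core-set member, for at least one
#' (`mode = "any"`) or every (`mode = "all"`) reference. This is how
#' reciprocal lack turns paralog B into a false ortholog: when the query
#' holds only B and every reference library lacks B, the back-hit is the
#' reference's A copy and reciprocity is spuriously satisfied.
#'
#' @param libs An `est_libraries` object or named list of libraries.
#' @param core_set Named character vector: primer taxon -> its paralog-A
#'   sequence.
#' @param reference_taxa Reference taxa for the back step (must have
#'   entries in `core_set`).
#' @param scorer Deterministic pairwise similarity (default
#'   [align_score()]).
#' @param mode `"all"` (strict: every reference must reciprocate) or
#'   `"any"`.
#' @return `data.frame` of class `orthology_assignment`: per query taxon
#'   the chosen transcript, its true paralog, whether it was accepted, and
#'   whether the accepted assignment is a misassignment (true paralog B).
#' @export
emulate_orthology_assignment <- function(libs, core_set, reference_taxa,
                                         scorer = align_score,
                                         mode = c("all", "any")) {
  mode <- match.arg(mode)
  libraries <- if (inherits(libs, "est_libraries")) libs$libraries else libs
  stopifnot(all(reference_taxa %in% names(core_set)))
  queries <- setdiff(names(libraries), names(core_set))
  rows <- lapply(queries, function(tx) {
    lib <- libraries[[tx]]
    if (!length(lib)) {
      return(data.frame(taxon = tx, transcript = NA_character_,
                        true_paralog = NA_character_, accepted = FALSE,
                        misassigned = FALSE, stringsAsFactors = FALSE))
    }
    fwd <- vapply(lib, function(s) {
      max(vapply(core_set, scorer, 0, b = s))
    }, 0)
    best <- which.max(fwd)
    chosen <- lib[[best]]
    chosen_name <- names(lib)[best]
    recip <- vapply(reference_taxa, function(ref) {
      rlib <- libraries[[ref]]
      if (!length(rlib)) return(FALSE)
      back <- vapply(rlib, scorer, 0, b = chosen)
      rlib[[which.max(back)]] == core_set[[ref]]
    }, FALSE)
    accepted <- if (mode == "all") all(recip) else any(recip)
    true_par <- if (chosen_name %in% c("A", "B")) chosen_name
                else sub("^contam:[^:]+:", "", chosen_name)
    data.frame(taxon = tx, transcript = chosen_name,
               true_paralog = true_par, accepted = accepted,
               misassigned = accepted && identical(true_par, "B"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("orthology_assignment", "data.frame")
  out
}

#' Expected misassignment set under reciprocal lack
#'
#' Closed-form truth condition for the emulator: under the strict
#' (`"all"`) reciprocity mode, a query taxon is expected to be misassigned
#' iff its library lacks paralog A, contains paralog B, and every reference
#' library lacks B while containing A (so each back-hit is the reference's
#' A copy).
#'
#' @param library_presence Taxa x c("A","B") logical matrix of library
#'   content.
#' @param reference_taxa Reference taxa.
#' @param primer_taxa Primer taxa (excluded from the query set).
#' @param mode `"all"` or `"any"` reference acceptance.
#' @return Sorted character vector of expected-misassigned taxa.
#' @export
misassignment_truth <- function(library_presence, reference_taxa,
                                primer_taxa = reference_taxa,
                                mode = c("all", "any")) {
  mode <- match.arg(mode)
  lp <- library_presence
  queries <- setdiff(rownames(lp), primer_taxa)
  ref_ok <- vapply(reference_taxa, function(r) {
    lp[r, "A"] && !lp[r, "B"]
  }, FALSE)
  ref_cond <- if (mode == "all") all(ref_ok) else any(ref_ok)
  if (!ref_cond) return(character())
  sort(queries[!lp[queries, "A"] & lp[queries, "B"]])
}

# evaluate a block with a private RNG state, restoring the caller's
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
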