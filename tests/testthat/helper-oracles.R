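# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# random support tree: random topology, uniform branch lengths, random
# integer supports with a share of absent ones
random_support_tree <- function(n_tips, id = "rnd", p_absent = 0.2) {
  phy <- ape::rtree(n_tips)
  phy <- ape::unroot(phy)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.01, 1)
  lab <- as.character(sample(0:100, phy$Nnode, replace = TRUE))
  lab[stats::runif(phy$Nnode) < p_absent] <- ""
  phy$node.label <- lab
  support_tree(phy, id)
}

# brute-force clade extraction via ape::prop.part (different machinery
# from the package's own edge traversal)
oracle_clades <- function(st, threshold) {
  phy <- st$phylo
  n <- ape::Ntip(phy)
  pp <- ape::prop.part(phy)
  labels <- attr(pp, "labels")
  out <- list()
  # prop.part lists the tip sets below each internal node, root first
  for (k in seq_along(pp)[-1L]) {
    node <- n + k
    sup <- suppressWarnings(as.integer(phy$node.label[k]))
    if (is.na(sup) || sup < threshold) next
    side <- sort(labels[pp[[k]]])
    comp <- sort(setdiff(labels, side))
    edge_len <- phy$edge.length[match(node, phy$edge[, 2L])]
    for (s in list(side, comp)) {
      if (length(s) >= 2L && length(s) <= n - 2L) {
        out[[length(out) + 1L]] <- list(taxa = s, support = sup,
                                        length = edge_len)
      }
    }
  }
  out
}

clade_signature <- function(taxa, support, length) {
  paste(paste(taxa, collapse = ";"), support, signif(length, 10))
}

# exhaustive-state per-site likelihoods: enumerate every assignment of
# states to internal nodes (feasible for <= 3 internal nodes)
oracle_site_lik <- function(phy, alignment, model) {
  seqs <- alignment$seqs[phy$tip.label]
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  state <- matrix(match(chars, paraprune:::AA_STATES), nrow(chars))
  miss <- is.na(state)
  ntip <- nrow(state)
  n_sites <- ncol(state)
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  colnames(grid) <- internal
  root <- internal[1L]
  k <- model$n_categories
  lik_cat <- matrix(0, k, n_sites)
  for (ci in seq_len(k)) {
    total <- matrix(rep(model$frequencies[grid[, as.character(root)]],
                        n_sites), nrow(grid), n_sites)
    for (e in seq_len(nrow(phy$edge))) {
      parent <- phy$edge[e, 1L]
      child <- phy$edge[e, 2L]
      pm <- paraprune:::prob_matrix(model,
                                    phy$edge.length[e] * model$rates[ci])
      gp <- grid[, as.character(parent)]
      if (child <= ntip) {
        fac <- matrix(1, nrow(grid), n_sites)
        obs <- which(!miss[child, ])
        if (length(obs)) {
          fac[, obs] <- pm[gp, state[child, obs], drop = FALSE]
        }
      } else {
        fac <- matrix(rep(pm[cbind(gp, grid[, as.character(child)])],
                          n_sites), nrow(grid), n_sites)
      }
      total <- total * fac
    }
    lik_cat[ci, ] <- colSums(total)
  }
  lik_var <- colMeans(lik_cat)
  pinv <- model$pinv
  out <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    obs <- state[, s][!miss[, s]]
    if (!length(obs)) {
      out[s] <- 0
    } else if (length(unique(obs)) == 1L && pinv > 0) {
      out[s] <- log(pinv * model$frequencies[obs[1L]] +
                      (1 - pinv) * lik_var[s])
    } else {
      out[s] <- log((1 - pinv) * lik_var[s])
    }
  }
  out
}

# random reversible amino-acid model
random_model <- function(alpha = NULL, pinv = NULL, k = NULL) {
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- stats::runif(190, 0.05, 3)
  s <- s + t(s)
  f <- stats::runif(20, 0.5, 2)
  substitution_model(exchangeabilities = s, frequencies = f / sum(f),
                     alpha = alpha %||% stats::runif(1, 0.3, 2),
                     pinv = pinv %||% sample(c(0, 0.2), 1),
                     n_categories = k %||% sample(1:3, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random aligned partition with some gaps/ambiguity
random_alignment <- function(taxa, n_sites, gap_frac = 0.1, id = "aln") {
  seqs <- vapply(taxa, function(tx) {
    ch <- sample(paraprune:::AA_STATES, n_sites, replace = TRUE)
    n_gap <- rbinom(1, n_sites, gap_frac)
    if (n_gap) {
      at <- sample(n_sites, n_gap)
      ch[at] <- sample(c("-", "X"), n_gap, replace = TRUE)
    }
    paste(ch, collapse = "")
  }, "")
  partition_alignment(seqs, id)
}

# exhaustive leaf-stability oracle via ape::keep.tip topology inspection
oracle_leaf_stability <- function(trees, taxon) {
  trees <- lapply(trees, function(t) {
    if (inherits(t, "support_tree")) t$phylo else t
  })
  trees <- Filter(function(p) taxon %in% p$tip.label, trees)
  others <- sort(setdiff(unique(unlist(lapply(trees, `[[`, "tip.label"))),
                         taxon))
  pair_vals <- c()
  for (i in seq_along(others)) {
    for (j in seq_len(length(others))[-seq_len(i)]) {
      a <- others[i]; b <- others[j]
      counts <- c(0, 0, 0)  # ta|b, tb|a, ab|t
      for (p in trees) {
        if (!all(c(a, b) %in% p$tip.label)) next
        tri <- ape::keep.tip(p, c(taxon, a, b))
        pp <- ape::prop.part(tri)
        labels <- attr(pp, "labels")
        res <- NA
        for (kk in seq_along(pp)[-1L]) {
          pair <- sort(labels[pp[[kk]]])
          if (length(pair) != 2L) next
          if (setequal(pair, c(taxon, a))) res <- 1
          if (setequal(pair, c(taxon, b))) res <- 2
          if (setequal(pair, c(a, b))) res <- 3
        }
        if (!is.na(res)) counts[res] <- counts[res] + 1
      }
      if (sum(counts) > 0) {
        pair_vals <- c(pair_vals, max(counts) / sum(counts))
      }
    }
  }
  if (!length(pair_vals)) return(NA_real_)
  mean(pair_vals)
}

# write a temporary fasta
tmp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), f)
  f
}
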