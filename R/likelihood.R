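# Per-site log-likelihoods by Felsenstein pruning under a reversible
# amino-acid model with discrete-gamma rates and invariant sites, and the
# per-site likelihood-difference diagnostic for comparing two topologies.

#' Per-site log-likelihoods of an alignment on a fixed tree
#'
#' Evaluates, for each alignment column, the likelihood
#' `L = pinv * pi_x * [site constant with residue x] +
#' (1 - pinv) * (1/K) * sum_k L_pruning(rate_k)` on the given tree with
#' branch lengths taken as-is (no optimization). Gaps, `X` and `?` are
#' marginalized as uninformative (partial-likelihood vector of ones). A
#' site is "constant" when all non-missing residues are identical; a site
#' with no data at all gets `ln L = 0`.
#'
#' @param tree A `support_tree` or `phylo` with branch lengths; its leaves
#'   must all occur in the alignment.
#' @param alignment A [partition_alignment()] or [concatenate_partitions()]
#'   supermatrix.
#' @param model An [substitution_model()] object.
#' @return Numeric vector of natural-log likelihoods, one per column.
#' @export
site_log_likelihoods <- function(tree, alignment, model) {
  phy <- if (inherits(tree, "support_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"), inherits(model, "aa_model"))
  seqs <- if (inherits(alignment, "supermatrix")) alignment$matrix
          else alignment$seqs
  missing <- setdiff(phy$tip.label, names(seqs))
  if (length(missing)) {
    stop("tree taxa missing from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chars <- do.call(rbind, lapply(seqs[phy$tip.label], function(s) {
    strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  }))
  n_sites <- ncol(chars)
  state_idx <- matrix(match(chars, AA_STATES), nrow(chars), n_sites)
  miss <- is.na(state_idx)

  # mixture bookkeeping
  pinv <- model$pinv
  k <- model$n_categories
  rates <- model$rates
  log_lik_cat <- matrix(0, k, n_sites)
  for (ci in seq_len(k)) {
    log_lik_cat[ci, ] <- prune_loglik(phy, state_idx, miss, model, rates[ci])
  }
  # log-mean-exp across categories
  mx <- apply(log_lik_cat, 2L, max)
  log_var <- mx + log(colMeans(exp(sweep(log_lik_cat, 2L, mx, "-"))))

  out <- if (pinv > 0) {
    const_state <- apply(state_idx, 2L, function(col) {
      v <- unique(col[!is.na(col)])
      if (length(v) == 1L) v else NA_integer_
    })
    all_missing <- colSums(!miss) == 0L
    res <- log1p(-pinv) + log_var
    is_const <- !is.na(const_state)
    if (any(is_const)) {
      a <- log(pinv) + log(model$frequencies[const_state[is_const]])
      b <- res[is_const]
      m <- pmax(a, b)
      res[is_const] <- m + log(exp(a - m) + exp(b - m))
    }
    res[all_missing] <- 0
    res
  } else {
    all_missing <- colSums(!miss) == 0L
    log_var[all_missing] <- 0
    log_var
  }
  unname(out)
}

# Felsenstein pruning for one rate category; returns per-site log L.
# Partials are rescaled per node; the scale log is accumulated per site.
prune_loglik <- function(phy, state_idx, miss, model, rate) {
  ntip <- nrow(state_idx)
  n_sites <- ncol(state_idx)
  nnode <- phy$Nnode
  phy <- stats::reorder(phy, "postorder")
  partial <- vector("list", ntip + nnode)
  scale_log <- matrix(0, ntip + nnode, n_sites)

  tip_partial <- function(i) {
    m <- matrix(0, 20L, n_sites)
    idx <- state_idx[i, ]
    obs <- which(!miss[i, ])
    if (length(obs)) m[cbind(idx[obs], obs)] <- 1
    if (any(miss[i, ])) m[, miss[i, ]] <- 1
    m
  }

  edges <- phy$edge
  elens <- phy$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]
    child <- edges[e, 2L]
    cp <- if (child <= ntip) tip_partial(child) else partial[[child]]
    p_mat <- prob_matrix(model, elens[e] * rate)
    contrib <- p_mat %*% cp
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
    }
    if (child > ntip) {
      scale_log[parent, ] <- scale_log[parent, ] + scale_log[child, ]
    }
    # rescale to guard against underflow on long trees
    mx <- apply(partial[[parent]], 2L, max)
    pos <- mx > 0
    if (any(pos)) {
      partial[[parent]][, pos] <-
        sweep(partial[[parent]][, pos, drop = FALSE], 2L, mx[pos], "/")
      scale_log[parent, pos] <- scale_log[parent, pos] + log(mx[pos])
    }
  }
  root <- edges[nrow(edges), 1L]
  lik <- colSums(model$frequencies * partial[[root]])
  log(lik) + scale_log[root, ]
}

#' Per-site likelihood differences between two topologies
#'
#' Computes `delta_psl(site) = lnL_site(H1) - lnL_site(H2)` for two trees
#' evaluated on the same alignment and model, plus per-partition sums when
#' a coordinate chart is available. Positive values support H1.
#'
#' @param tree_h1,tree_h2 Trees (`support_tree` or `phylo`) over the same
#'   leaf set.
#' @param alignment A [partition_alignment()] or supermatrix.
#' @param model An [substitution_model()].
#' @param chart Optional partition chart (`partition_id`/`start`/`end`,
#'   0-based half-open); defaults to the supermatrix's own chart.
#' @return List of class `delta_psl` with `sites` (data.frame `site`,
#'   `lnl1`, `lnl2`, `delta`, `partition`) and `partition_sums`.
#' @export
delta_psl <- function(tree_h1, tree_h2, alignment, model, chart = NULL) {
  p1 <- if (inherits(tree_h1, "support_tree")) tree_h1$phylo else tree_h1
  p2 <- if (inherits(tree_h2, "support_tree")) tree_h2$phylo else tree_h2
  d12 <- setdiff(p1$tip.label, p2$tip.label)
  d21 <- setdiff(p2$tip.label, p1$tip.label)
  if (length(d12) || length(d21)) {
    stop("leaf sets differ between hypotheses: only in H1 {",
         paste(d12, collapse = ", "), "}; only in H2 {",
         paste(d21, collapse = ", "), "}", call. = FALSE)
  }
  lnl1 <- site_log_likelihoods(p1, alignment, model)
  lnl2 <- site_log_likelihoods(p2, alignment, model)
  if (is.null(chart) && inherits(alignment, "supermatrix")) {
    chart <- alignment$chart
  }
  part <- rep(NA_character_, length(lnl1))
  if (!is.null(chart)) {
    for (i in seq_len(nrow(chart))) {
      part[(chart$start[i] + 1L):chart$end[i]] <- chart$partition_id[i]
    }
  }
  sites <- data.frame(site = seq_along(lnl1), lnl1 = lnl1, lnl2 = lnl2,
                      delta = lnl1 - lnl2, partition = part,
                      stringsAsFactors = FALSE)
  partition_sums <- NULL
  if (!is.null(chart)) {
    sums <- tapply(sites$delta, sites$partition, sum)
    partition_sums <- data.frame(partition_id = names(sums),
                                 delta_sum = as.numeric(sums),
                                 stringsAsFactors = FALSE)
    partition_sums <-
      partition_sums[match(chart$partition_id, partition_sums$partition_id),
                     , drop = FALSE]
    rownames(partition_sums) <- NULL
  }
  structure(list(sites = sites, partition_sums = partition_sums,
                 total = sum(sites$delta)),
            class = "delta_psl")
}

#' @export
print.delta_psl <- function(x, ...) {
  cat("Per-site likelihood differences over ", nrow(x$sites), " sites; ",
      "total lnL(H1) - lnL(H2) = ", signif(x$total, 6), "\n", sep = "")
  if (!is.null(x$partition_sums)) {
    top <- x$partition_sums[order(-abs(x$partition_sums$delta_sum)), ]
    cat("  largest partition contribution: ", top$partition_id[1L], " (",
        signif(top$delta_sum[1L], 4), ")\n", sep = "")
  }
  invisible(x)
}

#' Plot per-site likelihood differences
#'
#' Site-wise delta-psL with partition boundaries; optionally highlights a
#' set of partitions (e.g. those holding data for a focal taxon).
#'
#' @param x A [delta_psl()] result with partition information.
#' @param highlight Character vector of partition IDs to shade.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_delta_psl <- function(x, highlight = NULL, ...) {
  s <- x$sites
  graphics::plot(s$site, s$delta, type = "h", xlab = "alignment position",
                 ylab = expression(Delta * "psL"), ...)
  if (!is.null(highlight) && length(unique(stats::na.omit(s$partition)))) {
    runs <- rle(s$partition)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values %in% highlight)) {
      graphics::rect(starts[i], graphics::par("usr")[3L], ends[i],
                     graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("grey", 0.3), border = NA)
    }
  }
  graphics::abline(h = 0, col = "grey40")
  invisible(x)
}
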