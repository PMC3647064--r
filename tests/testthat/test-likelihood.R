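test_that("discrete-gamma categories have unit mean and match quadrature", {
  expect_equal(discrete_gamma_rates(0.7, 1), 1)
  for (alpha in c(0.2, 0.5, 1, 2, 10)) {
    for (k in c(2, 4, 8)) {
      r <- discrete_gamma_rates(alpha, k)
      expect_equal(mean(r), 1, tolerance = 1e-12)
      expect_true(all(diff(r) > 0))
    }
  }
  # band means by numerical integration of the Gamma(alpha, alpha) density
  alpha <- 0.5; k <- 4
  breaks <- qgamma(seq(0, 1, length.out = k + 1), alpha, rate = alpha)
  quad <- vapply(seq_len(k), function(i) {
    num <- integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                     breaks[i], breaks[i + 1], rel.tol = 1e-10)$value
    num / (1 / k)
  }, 0)
  expect_equal(discrete_gamma_rates(alpha, k), quad / mean(quad),
               tolerance = 1e-7)
  expect_error(discrete_gamma_rates(0, 4), "positive")
  expect_error(discrete_gamma_rates(-1, 4), "positive")
})

test_that("gamma discretization agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  for (alpha in c(0.3, 1.1)) {
    expect_equal(discrete_gamma_rates(alpha, 4),
                 phangorn::discrete.gamma(alpha, 4), tolerance = 1e-6)
  }
})

test_that("degenerate trees give closed-form site likelihoods", {
  m <- substitution_model(alpha = 1, pinv = 0, n_categories = 1)
  # single leaf: ln pi_a
  one <- ape::read.tree(text = "(A:0.7);")
  aln <- partition_alignment(c(A = "AR-"), "p")
  lnl <- site_log_likelihoods(one, aln, m)
  expect_equal(lnl[1], log(m$frequencies[1]))
  expect_equal(lnl[2], log(m$frequencies[2]))
  expect_equal(lnl[3], 0)  # all-missing site

  # zero-branch star, identical residue: ln pi_a
  star <- ape::read.tree(text = "(A:0,B:0,C:0);")
  aln2 <- partition_alignment(c(A = "C", B = "C", C = "C"), "p")
  expect_equal(site_log_likelihoods(star, aln2, m),
               log(m$frequencies[5]))

  expect_error(
    site_log_likelihoods(star, partition_alignment(c(A = "C"), "p"), m),
    "missing from alignment")
})

test_that("pruning equals the exhaustive-state oracle on small trees", {
  set.seed(111)
  for (rep in 1:8) {
    n <- sample(4:5, 1)
    phy <- ape::unroot(ape::rtree(n))
    phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.8)
    aln <- random_alignment(phy$tip.label, 30, gap_frac = 0.15)
    m <- random_model()
    expect_equal(site_log_likelihoods(phy, aln, m),
                 oracle_site_lik(phy, aln, m), tolerance = 1e-8)
  }
})

test_that("the likelihood is invariant to re-rooting", {
  set.seed(121)
  phy <- ape::unroot(ape::rtree(8))
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.6)
  aln <- random_alignment(phy$tip.label, 40, gap_frac = 0.1)
  m <- substitution_model(alpha = 0.8, pinv = 0.15, n_categories = 4)
  base <- sum(site_log_likelihoods(phy, aln, m))
  for (tip in sample(phy$tip.label, 5)) {
    rooted <- ape::root(phy, outgroup = tip, resolve.root = TRUE)
    expect_equal(sum(site_log_likelihoods(rooted, aln, m)), base,
                 tolerance = 1e-8)
  }
})

test_that("the single-rate model matches an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(131)
  phy <- ape::unroot(ape::rtree(7))
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.6)
  aln <- random_alignment(phy$tip.label, 60, gap_frac = 0)
  m <- substitution_model(alpha = 1, pinv = 0, n_categories = 1)
  mine <- sum(site_log_likelihoods(phy, aln, m))
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  fit <- phangorn::pml(phy, phangorn::phyDat(mat, type = "AA"),
                       model = "LG", k = 1)
  expect_equal(mine, as.numeric(fit$logLik), tolerance = 1e-6)
})

test_that("delta-psL is zero for identical hypotheses and sums to the
           total difference", {
  set.seed(141)
  phy1 <- ape::unroot(ape::rtree(6))
  phy1$edge.length <- runif(nrow(phy1$edge), 0.05, 0.5)
  phy2 <- ape::unroot(ape::rtree(6))
  phy2$tip.label <- phy1$tip.label
  phy2$edge.length <- runif(nrow(phy2$edge), 0.05, 0.5)
  parts <- lapply(1:3, function(i) {
    random_alignment(phy1$tip.label, 25, id = sprintf("g%d", i))
  })
  sm <- concatenate_partitions(parts)
  m <- substitution_model(alpha = 0.9, pinv = 0.1, n_categories = 4)

  self <- delta_psl(phy1, phy1, sm, m)
  expect_true(all(self$sites$delta == 0))

  dps <- delta_psl(phy1, phy2, sm, m)
  expect_equal(sum(dps$sites$delta),
               sum(site_log_likelihoods(phy1, sm, m)) -
                 sum(site_log_likelihoods(phy2, sm, m)),
               tolerance = 1e-8)
  expect_equal(sum(dps$partition_sums$delta_sum), dps$total,
               tolerance = 1e-8)

  phy3 <- phy2
  phy3$tip.label[1] <- "somebody_else"
  expect_error(delta_psl(phy1, phy3, sm, m), "leaf sets differ")
})

test_that("the partition simulated on H1 dominates the delta-psL sums", {
  set.seed(151)
  h2 <- ape::read.tree(text =
    "((a:0.2,b:0.2):0.15,(c:0.2,d:0.2):0.15,(e:0.2,f:0.2):0.15);")
  # H1 differs by swapping b and c
  h1 <- ape::read.tree(text =
    "((a:0.2,c:0.2):0.15,(b:0.2,d:0.2):0.15,(e:0.2,f:0.2):0.15);")
  m <- substitution_model(alpha = 1, pinv = 0, n_categories = 1)
  hits <- 0L
  for (seed in 1:3) {
    parts <- lapply(1:4, function(i) {
      src <- if (i == 2) h1 else h2
      seqs <- paraprune:::with_seed(seed * 100 + i, {
        paraprune:::simulate_sequences(src, m, 60)
      })
      partition_alignment(seqs, sprintf("g%d", i))
    })
    sm <- concatenate_partitions(parts)
    dps <- delta_psl(h1, h2, sm, m)
    best <- dps$partition_sums$partition_id[
      which.max(dps$partition_sums$delta_sum)]
    hits <- hits + (best == "g2")
  }
  expect_equal(hits, 3L)
})
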