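chain_tree <- function() {
  ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.2);")
}

test_that("gene families respect loss settings and are seed-reproducible", {
  cfg <- sim_config(chain_tree(), divergence = 3, loss_prob = 0,
                    primer_taxa = "A", sites = 40, seed = 3)
  fam <- simulate_gene_family(cfg)
  expect_true(all(fam$genome_presence))        # no loss, both paralogs
  expect_equal(sort(names(fam$sequences)),
               sort(paste0(rep(c("A", "B", "C"), each = 2), "|",
                           c("A", "B"))))
  fam2 <- simulate_gene_family(cfg)
  expect_identical(fam$sequences, fam2$sequences)  # same seed, same data

  cfg2 <- sim_config(chain_tree(), divergence = 3, loss_prob = 0,
                     primer_taxa = "A", sites = 40, seed = 4)
  expect_false(identical(simulate_gene_family(cfg2)$sequences,
                         fam$sequences))
})

test_that("presence frequency follows (1-q)^k along a root-to-tip path", {
  q <- 0.2
  present <- 0L
  n_ok <- 0L
  for (seed in 1:300) {
    cfg <- sim_config(chain_tree(), divergence = 3, loss_prob = q,
                      primer_taxa = "A", sites = 15, seed = seed)
    fam <- tryCatch(simulate_gene_family(cfg), error = function(e) NULL)
    if (is.null(fam)) next  # score-separation guard on a sparse family
    n_ok <- n_ok + 1L
    present <- present + fam$genome_presence["A", "A"]
  }
  expect_gt(n_ok, 250)
  # taxon A sits 2 branches from the root: P(present) = (1-q)^2
  p_hat <- present / n_ok
  p_exp <- (1 - q)^2
  sigma <- sqrt(p_exp * (1 - p_exp) / n_ok)
  expect_lt(abs(p_hat - p_exp), 3 * sigma + 0.01)
})

test_that("EST library sampling is Bernoulli per transcript", {
  cfg <- sim_config(chain_tree(), divergence = 3, loss_prob = 0,
                    primer_taxa = "A", sites = 10, seed = 5)
  fam <- simulate_gene_family(cfg)
  all_in <- sample_est_library(fam, detect_prob = 1, seed = 1)
  expect_true(all(all_in$library_presence))
  none <- sample_est_library(fam, detect_prob = 0, seed = 1)
  expect_false(any(none$library_presence))

  # 1000 transcripts at p = 0.3: inclusion within the binomial 99% CI
  big <- fam
  taxa <- sprintf("t%03d", 1:500)
  big$genome_presence <- matrix(TRUE, 500, 2,
                                dimnames = list(taxa, c("A", "B")))
  big$sequences <- setNames(rep("MKV", 1000),
                            paste0(rep(taxa, 2), "|",
                                   rep(c("A", "B"), each = 500)))
  big$truth <- data.frame(sequence = names(big$sequences))
  lib <- sample_est_library(big, detect_prob = 0.3, seed = 6)
  n_in <- sum(lib$library_presence)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(n_in, ci[1])
  expect_lte(n_in, ci[2])
})

test_that("contamination injection copies the exact donor transcripts", {
  libs <- list(don = setNames(sprintf("SEQ%03d", 1:100),
                              sprintf("g%03d", 1:100)),
               rec = c(g1 = "AAA"))
  out0 <- inject_contamination(libs, "don", "rec", 0, seed = 1)
  expect_identical(out0$rec, libs$rec)

  out <- inject_contamination(libs, "don", "rec", 0.05, seed = 1)
  injected <- setdiff(names(out$rec), names(libs$rec))
  expect_length(injected, 5L)  # ceiling(0.05 * 100)
  expect_true(all(startsWith(injected, "contam:don:")))
  src <- sub("^contam:don:", "", injected)
  expect_identical(unname(out$rec[injected]), unname(libs$don[src]))
})

test_that("the emulator reproduces the reciprocal-lack misassignment", {
  sp <- ape::read.tree(
    text = "((P1:0.12,P2:0.12):0.1,(Q1:0.12,Q2:0.12):0.1);")
  cfg <- sim_config(sp, divergence = 3, loss_prob = 0,
                    primer_taxa = c("P1", "P2"), reference_taxa = "P1",
                    sites = 80, seed = 9)
  fam <- simulate_gene_family(cfg)
  core <- setNames(fam$sequences[c("P1|A", "P2|A")], c("P1", "P2"))

  # reciprocal lack: queries hold only B, references only A
  pm <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
               dimnames = list(c("P1", "P2", "Q1", "Q2"), c("A", "B")))
  libs <- sample_est_library(fam, detect_prob = pm, seed = 10)
  asn <- emulate_orthology_assignment(libs, core, "P1")
  expect_true(all(asn$misassigned[asn$taxon %in% c("Q1", "Q2")]))
  expect_equal(sort(asn$taxon[asn$misassigned]),
               misassignment_truth(libs$library_presence, "P1",
                                   c("P1", "P2")))

  # a reference that retains B breaks the spurious reciprocity
  pm2 <- pm; pm2["P2", "B"] <- 1
  libs2 <- sample_est_library(fam, detect_prob = pm2, seed = 10)
  asn2 <- emulate_orthology_assignment(libs2, core, c("P1", "P2"),
                                       mode = "all")
  expect_false(any(asn2$misassigned))
  expect_equal(misassignment_truth(libs2$library_presence,
                                   c("P1", "P2"), c("P1", "P2")),
               character())

  # a query holding both paralogs is assigned its true ortholog
  pm3 <- pm; pm3["Q1", "A"] <- 1
  libs3 <- sample_est_library(fam, detect_prob = pm3, seed = 10)
  asn3 <- emulate_orthology_assignment(libs3, core, "P1")
  q1 <- asn3[asn3$taxon == "Q1", ]
  expect_true(q1$accepted)
  expect_equal(q1$true_paralog, "A")
  expect_false(q1$misassigned)
})

test_that("emulator and closed-form truth agree on random library masks", {
  sp <- ape::read.tree(text = paste0(
    "((P1:0.12,P2:0.12):0.1,((Q1:0.1,Q2:0.1):0.08,Q3:0.15):0.1);"))
  cfg <- sim_config(sp, divergence = 3, loss_prob = 0,
                    primer_taxa = c("P1", "P2"), reference_taxa = "P1",
                    sites = 60, seed = 20)
  fam <- simulate_gene_family(cfg)
  core <- setNames(fam$sequences[c("P1|A", "P2|A")], c("P1", "P2"))
  for (seed in 1:10) {
    pm <- paraprune:::with_seed(seed, {
      matrix(runif(10) < 0.6, 5, 2,
             dimnames = list(sp$tip.label, c("A", "B")))
    }) * 1
    libs <- sample_est_library(fam, detect_prob = pm, seed = seed)
    asn <- emulate_orthology_assignment(libs, core, "P1")
    expect_equal(sort(asn$taxon[asn$misassigned]),
                 misassignment_truth(libs$library_presence, "P1",
                                     c("P1", "P2")),
                 info = paste("seed", seed))
  }
})

test_that("misassignment is non-increasing in the number of references", {
  set.seed(191)
  taxa <- c(paste0("P", 1:3), paste0("Q", 1:5))
  rates <- vapply(1:3, function(n_ref) {
    refs <- paste0("P", seq_len(n_ref))
    mean(vapply(1:400, function(i) {
      lp <- matrix(runif(16) < 0.5, 8, 2,
                   dimnames = list(taxa, c("A", "B")))
      length(misassignment_truth(lp, refs, paste0("P", 1:3)))
    }, 0))
  }, 0)
  expect_true(all(diff(rates) <= 0))
})

test_that("insufficient divergence is refused at generation time", {
  cfg <- sim_config(chain_tree(), divergence = 0.0001, loss_prob = 0,
                    primer_taxa = "A", sites = 40, seed = 12)
  expect_error(simulate_gene_family(cfg), "divergence")
})
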