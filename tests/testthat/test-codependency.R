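test_that("pairwise z-scores follow the Fisher/Stouffer identities", {
  set.seed(41)
  n <- 60
  m1 <- matrix(rnorm(3 * n), nrow = 3,
               dimnames = list(c("A", "B", "C"), paste0("s", 1:n)))
  m2 <- m1  # identical replicate: z1 == z2, combined = z * sqrt(2)
  sc <- pairwise_z(m1, m2)
  expect_equal(sc$z1, sc$z2)
  expect_equal(sc$z_combined, sc$z1 * sqrt(2))
  # hand-check one pair against the closed form
  r <- cor(m1["A", ], m1["B", ])
  i <- which(sc$gene_a == "A" & sc$gene_b == "B")
  expect_equal(sc$r1[i], r)
  expect_equal(sc$z1[i], atanh(r) * sqrt(n - 3))
  expect_equal(sc$p[i], 2 * pnorm(-abs(sc$z_combined[i])))
  # opposite z's cancel under Stouffer
  expect_equal((5 + -5) / sqrt(2), 0)
  # dataset order invariance
  sc_rev <- pairwise_z(m2, m1)
  expect_equal(sc_rev$z_combined, sc$z_combined)
})

test_that("planted correlated pairs produce the expected combined z", {
  cfg <- sim_config(seed = 17, codep = list(genes = 10, samples = 500,
                                            n_planted = 2, rho = 0.5,
                                            noise_sd = 1))
  dep <- generate_dependency_matrices(cfg)
  sc <- pairwise_z(dep$m1, dep$m2)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted <- key(dep$planted$gene_a, dep$planted$gene_b)
  hit <- sc[key(sc$gene_a, sc$gene_b) %in% planted, ]
  expected <- 2 * atanh(0.5) * sqrt(497) / sqrt(2)
  expect_true(all(abs(hit$z_combined - expected) < 3 + 3))
  expect_true(all(abs(hit$r1 - 0.5) < 0.1))
  # replicates differ
  expect_false(identical(dep$m1, dep$m2))
  # unplanted pairs center near zero
  bg <- sc[!(key(sc$gene_a, sc$gene_b) %in% planted), ]
  expect_lt(mean(abs(bg$z_combined)), 2)
})

test_that("insufficient sample overlap skips pairs", {
  m1 <- matrix(rnorm(20), nrow = 2, dimnames = list(c("A", "B"), NULL))
  m1["B", 1:8] <- NA
  m2 <- matrix(rnorm(20), nrow = 2, dimnames = list(c("A", "B"), NULL))
  expect_message(sc <- pairwise_z(m1, m2, min_overlap = 4), "skipped")
  expect_equal(nrow(sc), 0)
})

test_that("mitochondrial exclusion removes among-mito pairs only", {
  sc <- data.frame(gene_a = c("M1", "M1", "A"),
                   gene_b = c("M2", "A", "B"),
                   p = c(0.01, 0.02, 0.03))
  out <- exclude_mito_pairs(sc, c("M1", "M2"))
  expect_equal(nrow(out), 2)
  exc <- attr(out, "excluded_mito")
  expect_equal(nrow(exc), 1)
  expect_equal(exc$label, "excluded_mito")
  expect_true("M1" %in% out$gene_a)            # one-mito pair retained
  # empty set is the identity
  expect_equal(nrow(exclude_mito_pairs(sc, character(0))), 3)
})

test_that("multiplicity corrections match hand-derived worked example", {
  sc <- data.frame(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4),
                   p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(significant_pairs(sc, "bh")$summary$n_significant, 4)
  expect_equal(significant_pairs(sc, "bonferroni")$summary$n_significant,
               1)
  expect_equal(significant_pairs(sc, "by")$summary$n_significant, 0)
  expect_error(significant_pairs(sc, "weird"))
})

test_that("corrections agree with brute-force threshold-scan oracles", {
  # step-up/step-down scans implemented directly from the definitions
  bh_oracle <- function(p, alpha, cm = 1) {
    m <- length(p); o <- order(p)
    ks <- which(p[o] <= (seq_len(m) * alpha) / (m * cm))
    sig <- logical(m)
    if (length(ks)) sig[o[seq_len(max(ks))]] <- TRUE
    sig
  }
  bonf_oracle <- function(p, alpha) p <= alpha / length(p)
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(c(5, 50, 500, 1000), 1)
    p <- runif(n)^sample(1:3, 1)
    sc <- data.frame(gene_a = paste0("g", seq_len(n)),
                     gene_b = paste0("h", seq_len(n)), p = p)
    alpha <- 0.05
    expect_equal(significant_pairs(sc, "bh", alpha)$scores$significant,
                 bh_oracle(p, alpha))
    expect_equal(significant_pairs(sc, "by", alpha)$scores$significant,
                 bh_oracle(p, alpha, cm = sum(1 / seq_len(n))))
    expect_equal(
      significant_pairs(sc, "bonferroni", alpha)$scores$significant,
      bonf_oracle(p, alpha))
  }
})

test_that("network priors restrict hypotheses consistently", {
  set.seed(67)
  n <- 400
  p <- c(runif(20, 0, 1e-4), runif(n - 20))
  sc <- data.frame(gene_a = paste0("g", seq_len(n)),
                   gene_b = paste0("h", seq_len(n)), p = p)
  prior <- data.frame(a = paste0("g", 1:40), b = paste0("h", 1:40))
  res <- significant_pairs(sc, "by", prior_pairs = prior)
  expect_lte(res$summary$n_tests_prior, res$summary$n_tests)
  expect_equal(res$summary$n_tests_prior, 40)
  # prior-only pairs are exactly those rescued by the restriction
  expect_true(all(res$scores$significant_prior[res$scores$prior_only]))
  expect_false(any(res$scores$significant[res$scores$prior_only]))
  # restricting can only help inside the prior set
  expect_gte(res$summary$n_significant_prior,
             sum(res$scores$significant[
               res$scores$significant_prior | res$scores$prior_only]))
})

test_that("explanation labels follow the priority order", {
  og <- kinase_ontology()
  net <- data.frame(subject = c("MAP2K1", "RSK"),
                    object = c("MAPK1", "CREB1"))
  sc <- data.frame(
    gene_a = c("MAP2K1", "MAP2K1", "RPS6KA1", "BRAF"),
    gene_b = c("MAPK1", "MAP2K2", "CREB1", "MAPK1"))
  out <- explain_pairs(sc, net, og)
  expect_equal(out$label, c("direct", "family_complex", "parent_link",
                            "unexplained"))
  # direct outranks family/parent when several would match
  net2 <- rbind(net, data.frame(subject = "MAP2K1", object = "MAP2K2"))
  out2 <- explain_pairs(sc, net2, og)
  expect_equal(out2$label[2], "direct")
  # determinism
  expect_identical(explain_pairs(sc, net, og)$label, out$label)
})

test_that("belief-binned reference comparison estimates uncurated correct
           statements", {
  a <- function(nm, id) agent(nm, c(HGNC = id))
  mk <- function(g1, g2, bel) {
    s <- statement("Complex", list(a(g1, g1), a(g2, g2)),
                   evidence = list(evidence("r1")))
    s$belief <- bel
    s
  }
  stmts <- list(mk("A", "B", 0.95), mk("C", "D", 0.85), mk("E", "F", 0.9),
                mk("G", "H", 0.15))
  ref <- data.frame(x = c("A", "C"), y = c("B", "D"))
  res <- ppi_belief_comparison(stmts, ref)
  expect_equal(res$expected_uncurated_correct, 0.9 + 0.15)
  hi <- res$bins[res$bins$belief_lo == 0.9, ]
  expect_equal(hi$n_in_ref, 1)           # A-B at 0.95
  expect_equal(hi$n_not_in_ref, 1)       # E-F at 0.9
  expect_equal(hi$fraction_in_ref, 0.5)
  expect_equal(res$yield$expected_correct, cumsum(c(0.9, 0.15)))
  # all-in-reference: fraction 1 in every nonempty bin
  res2 <- ppi_belief_comparison(stmts[1:2], ref)
  nb <- res2$bins[res2$bins$n_in_ref + res2$bins$n_not_in_ref > 0, ]
  expect_true(all(nb$fraction_in_ref == 1))
})

test_that("calibrated beliefs recover the planted number of true
           uncurated interactions", {
  set.seed(71)
  n <- 600
  correct <- runif(n) < 0.7
  # calibrated beliefs: statement's belief is its true correctness rate
  bel <- ifelse(correct, rbeta(n, 8, 2), rbeta(n, 2, 8))
  # reference contains a random half of the true pairs
  in_ref <- correct & runif(n) < 0.5
  stmts <- lapply(seq_len(n), function(i) {
    s <- statement("Complex",
                   list(agent(paste0("A", i), c(HGNC = as.character(i))),
                        agent(paste0("B", i),
                              c(HGNC = as.character(i + n)))),
                   evidence = list(evidence("r1")))
    s$belief <- bel[i]
    s
  })
  ref <- data.frame(x = paste0("A", which(in_ref)),
                    y = paste0("B", which(in_ref)))
  res <- ppi_belief_comparison(stmts, ref)
  truth <- sum(correct & !in_ref)
  expect_lt(abs(res$expected_uncurated_correct - truth) / truth, 0.15)
})
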