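test_that("single-source belief algebra matches hand-computed values", {
  # 1 - (0.2 + 0.4^1 * 0.8) = 0.48
  expect_equal(belief_simple(1, 0.2, 0.4), 0.48)
  # no random error: plateau at 1 - e_syst for any n
  expect_equal(belief_simple(c(1, 5, 50), 0.3, 0), rep(0.7, 3))
  # large-n asymptote
  expect_equal(belief_simple(500, 0.05, 0.9), 0.95, tolerance = 1e-10)
  expect_error(belief_simple(0, 0.1, 0.1), "n must be")
})

test_that("multi-source belief combines per-source joint errors", {
  # binomial: 1 - 0.5^2 * 0.1^1
  expect_equal(belief_multisource(
    c(A = 2, B = 1),
    list(A = list(e_rand = 0.5), B = list(e_rand = 0.1)), "binomial"),
    0.975)
  # beta-binomial single source, alpha = beta = 1, N = 1:
  # Beta(1,2)/Beta(1,1) = 1/2
  expect_equal(belief_multisource(
    c(A = 1), list(A = list(alpha = 1, beta = 1)), "beta_binomial"), 0.5)
  # one-source two-parameter model reduces to belief_simple
  for (n in 1:6)
    expect_equal(belief_multisource(
      c(A = n), list(A = list(e_syst = 0.17, e_rand = 0.42)), "indra"),
      belief_simple(n, 0.17, 0.42))
  # zero-count source is a no-op
  p <- list(A = list(e_syst = 0.1, e_rand = 0.3),
            B = list(e_syst = 0.5, e_rand = 0.5))
  expect_equal(belief_multisource(c(A = 2, B = 0), p, "indra"),
               belief_multisource(c(A = 2), p["A"], "indra"))
  # unknown source errors by name; default profile covers it
  expect_error(belief_multisource(c(Z = 1), p, "indra"), "Z")
  p$`__default__` <- list(e_syst = 0.01, e_rand = 0.05)
  expect_equal(belief_multisource(c(Z = 1), p, "indra"),
               belief_simple(1, 0.01, 0.05))
})

test_that("belief invariants hold across random parameter draws", {
  set.seed(101)
  for (rep in 1:200) {
    es <- runif(1, 0.01, 0.6); er <- runif(1, 0.01, 0.95)
    al <- 10^runif(1, -1, 1); be <- 10^runif(1, -1, 1)
    n <- sample(1:30, 5)
    for (model in c("indra", "binomial", "beta_binomial")) {
      p <- list(S = switch(model, indra = list(e_syst = es, e_rand = er),
                           binomial = list(e_rand = er),
                           beta_binomial = list(alpha = al, beta = be)))
      b <- vapply(sort(n), function(k)
        belief_multisource(c(S = k), p, model), numeric(1))
      expect_true(all(b >= 0 & b <= 1))
      expect_lt(belief_multisource(c(S = 1), p, model), 1)  # strict at n=1
      expect_true(all(diff(b) > -1e-12))          # monotone in counts
    }
    # binomial is the e_syst = 0 special case of the two-parameter model
    expect_equal(
      belief_multisource(c(S = n[1]),
                         list(S = list(e_syst = 0, e_rand = er)), "indra"),
      belief_multisource(c(S = n[1]), list(S = list(e_rand = er)),
                         "binomial"))
    # asymptote: belief -> 1 - prod(e_syst) over supporting sources
    p2 <- list(A = list(e_syst = es, e_rand = er),
               B = list(e_syst = 0.2, e_rand = 0.5))
    expect_equal(belief_multisource(c(A = 4000, B = 4000), p2, "indra"),
                 1 - es * 0.2, tolerance = 1e-6)
  }
})

test_that("beliefs over refinement-extended evidence dominate direct-only
           beliefs", {
  og <- kinase_ontology()
  chain <- deep_phos_chain()
  corp <- assemble_corpus(unname(chain), og)
  params <- list(reader1 = list(e_syst = 0.05, e_rand = 0.3))
  b_ext <- belief_with_refinements(corp, params, "indra")
  b_dir <- belief_with_refinements(corp, params, "indra", extended = FALSE)
  expect_true(all(b_ext >= b_dir - 1e-12))
  # along the chain (each statement 1 direct evidence), belief grows
  # monotonically toward the generic bottom statement
  keys <- names(chain)
  expect_true(all(diff(b_ext[keys]) <= 1e-12))
  expect_equal(unname(b_ext[keys[9]]), unname(b_dir[keys[9]]))  # leaf
  # isolated statement equals direct multisource belief
  iso_key <- keys[9]
  expect_equal(unname(b_dir[iso_key]),
               belief_multisource(corp$counts[iso_key, ], params, "indra"))
})

test_that("negative log-likelihood matches a direct per-item oracle", {
  set.seed(55)
  counts <- matrix(sample(0:5, 20, replace = TRUE), ncol = 2,
                   dimnames = list(NULL, c("A", "B")))
  counts[rowSums(counts) == 0, 1] <- 1
  correct <- runif(10) < 0.6
  params <- list(A = list(e_syst = 0.1, e_rand = 0.4),
                 B = list(e_syst = 0.2, e_rand = 0.3))
  nll <- neg_log_likelihood(params, list(counts = counts,
                                         correct = correct), "indra")
  oracle <- 0
  for (i in 1:10) {
    B <- belief_multisource(counts[i, ], params, "indra")
    oracle <- oracle - (correct[i] * log(B) + (1 - correct[i]) * log(1 - B))
  }
  expect_equal(nll, oracle)
  # single statement at B = 0.5 gives log 2
  p5 <- list(A = list(e_rand = 0.5))
  expect_equal(neg_log_likelihood(
    p5, list(counts = matrix(1, dimnames = list(NULL, "A")),
             correct = TRUE), "binomial"),
    log(2))
  # grouped internal likelihood agrees with the public function
  f <- mechassembly:::.grouped_nll_fun(
    list(counts = counts, correct = correct), "indra")
  th <- c(0.1, 0.4, 0.2, 0.3)
  expect_equal(f(th, c("A", "B")), nll, tolerance = 1e-9)
})

test_that("MCMC recovers generating parameters on simulated curations", {
  dat <- simulate_curated_statements(2000, e_syst = 0.1, e_rand = 0.35,
                                     seed = 7)
  fit <- fit_belief(dat, "indra", "mcmc", seed = 7)
  expect_lt(abs(fit$params$reader1$e_syst - 0.1), 0.05)
  expect_lt(abs(fit$params$reader1$e_rand - 0.35), 0.05)
  # deterministic ML path lands in the same place
  fit_ml <- fit_belief(dat, "indra", "ml")
  expect_lt(abs(fit_ml$params$reader1$e_syst -
                  fit$params$reader1$e_syst), 0.03)
  expect_lte(fit_ml$nll, fit$nll + 0.5)
  # methods behave
  expect_named(coef(fit), c("reader1.e_syst", "reader1.e_rand"))
  expect_s3_class(logLik(fit), "logLik")
  expect_output(print(fit), "indra")
  sm <- summary(fit)
  expect_true("posterior" %in% names(sm))
  b <- predict(fit, 1:10)
  expect_true(all(diff(b) > 0))
  r <- residuals(fit, dat)
  expect_true(all(abs(r) <= 1))
  sim <- simulate(fit, nsim = 2, seed = 1, newdata = dat$counts)
  expect_equal(dim(sim), c(2000L, 2L))
  # one-mention heuristic equals B(1)
  expect_equal(unname(single_mention_precision(fit)["reader1"]),
               belief_simple(1, fit$params$reader1$e_syst,
                             fit$params$reader1$e_rand))
})

test_that("binomial fit on error-free data hits the zero boundary", {
  dat <- simulate_curated_statements(300, e_syst = 0, e_rand = 0, seed = 3)
  expect_warning(fit <- fit_belief(dat, "binomial", "ml"), "degenerate")
  expect_lt(fit$params$reader1$e_rand, 0.01)
})

test_that("two-parameter models beat binomial when systematic errors
           exist", {
  dat <- simulate_curated_statements(2000, e_syst = 0.15, e_rand = 0.3,
                                     seed = 19)
  nll_indra <- fit_belief(dat, "indra", "ml")$nll
  nll_bb <- fit_belief(dat, "beta_binomial", "ml")$nll
  nll_bin <- fit_belief(dat, "binomial", "ml")$nll
  expect_lt(nll_indra, nll_bin)
  expect_lt(nll_bb, nll_bin)
})

test_that("feature encoding is deterministic with fixed column semantics", {
  og <- kinase_ontology()
  a <- gene_agent("MAP2K1", "6840"); b <- gene_agent("MAPK1", "6871")
  mk_ev <- function(src, pmid, txt)
    evidence(src, pmid = pmid, text = txt)
  s1 <- statement("Phosphorylation", list(a, b), evidence = list(
    mk_ev("reach", "1", paste(rep("w", 10), collapse = " ")),
    mk_ev("reach", "2", paste(rep("w", 12), collapse = " ")),
    mk_ev("sparser", "1", paste(rep("w", 8), collapse = " "))))
  s2 <- statement("Activation", list(a, b), evidence = list(
    mk_ev("reach", "3", "the promoter region binds"),
    mk_ev("reach", "4", "aa bb cc"),
    mk_ev("reach", "5", "dd ee ff"),
    mk_ev("reach", "6", "gg hh ii")))
  corp <- assemble_corpus(list(s1, s2), og)
  X <- encode_features(corp)
  k1 <- matches_key(s1); k2 <- matches_key(s2)
  expect_equal(unname(X[k1, c("src_reach", "src_sparser")]), c(2, 1))
  expect_equal(unname(X[k1, "n_pmids"]), 2)
  expect_equal(unname(X[k1, "mean_evidence_length"]), 10)
  expect_equal(unname(X[k1, "promoter_freq"]), 0)
  expect_equal(unname(X[k2, "promoter_freq"]), 0.25)
  expect_equal(unname(X[k1, "type_Phosphorylation"]), 1)
  expect_equal(unname(X[k1, "type_Activation"]), 0)
  # extended columns are added, never overwritten
  Xe <- encode_features(corp, extended = TRUE)
  expect_true(all(c("src_reach", "ext_reach", "n_pmids_ext") %in%
                    colnames(Xe)))
  expect_equal(Xe[, "src_reach"], X[, "src_reach"])
})

test_that("cross-validated AUPRC behaves at the reference points", {
  set.seed(23)
  # perfectly separable features
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(f = ifelse(y, 5, 0) + rnorm(n, sd = 0.1), g = rnorm(n))
  res <- train_and_evaluate(X, y, "logistic", folds = 5, seed = 1)
  expect_gt(res$mean_auprc, 0.99)
  # random scores give AUPRC near prevalence
  p <- 0.3; m <- 4000
  yr <- runif(m) < p
  expect_lt(abs(auprc(runif(m), yr) - p), 0.03)
  # informative counts beat the prevalence baseline by a margin
  dat <- simulate_curated_statements(1500, 0.2, 0.8, seed = 4)
  Xc <- cbind(dat$counts, noise = rnorm(1500))
  rf <- train_and_evaluate(Xc, dat$correct, "rf", folds = 5, seed = 2)
  expect_gt(rf$mean_auprc, rf$prevalence + 0.1)
})

test_that("knn and svc classifiers run through the same evaluation path", {
  set.seed(29)
  n <- 120
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(a = ifelse(y, 2, 0) + rnorm(n), b = rnorm(n))
  for (spec in c("knn", "svc")) {
    res <- train_and_evaluate(X, y, spec, folds = 4, seed = 3)
    expect_gt(res$mean_auprc, 0.7)
  }
})
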