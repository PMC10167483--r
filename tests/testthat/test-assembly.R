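test_that("combine_duplicates merges groups and deduplicates evidence", {
  a <- gene_agent("A", "1"); b <- gene_agent("B", "2")
  e1 <- evidence("r1", pmid = "10", text = "t1")
  e2 <- evidence("r2", pmid = "11", text = "t2")
  s1 <- statement("Activation", list(a, b), evidence = list(e1))
  s2 <- statement("Activation", list(a, b), evidence = list(e2))
  s3 <- statement("Activation", list(a, b), evidence = list(e1))  # repeat
  out <- combine_duplicates(list(s1, s2, s3))
  expect_length(out, 1)
  expect_length(out[[1]]$evidence, 2)
  # same sentence from two readers stays two evidences
  e3 <- evidence("r1", pmid = "10", text = "same")
  e4 <- evidence("r2", pmid = "10", text = "same")
  out2 <- combine_duplicates(list(
    statement("Activation", list(a, b), evidence = list(e3)),
    statement("Activation", list(a, b), evidence = list(e4))))
  expect_length(out2[[1]]$evidence, 2)
  # idempotent
  expect_identical(combine_duplicates(out), out)
})

test_that("deduplication output size equals distinct key count on
           synthetic corpora", {
  sim <- simulate_corpus(sim_config(seed = 21, n_mechanisms = 80))
  keys <- vapply(sim$statements, matches_key, character(1))
  uniq <- combine_duplicates(sim$statements)
  expect_length(uniq, length(unique(keys)))
})

test_that("refines captures entity, context and site specificity", {
  og <- kinase_ontology()
  map2k1 <- gene_agent("MAP2K1", "6840")
  mapk1 <- gene_agent("MAPK1", "6871")
  mek <- agent("MEK", c(FPLX = "MEK"))
  erk <- agent("ERK", c(FPLX = "ERK"))
  # bound condition + site refine the plain statement
  bound <- agent("MAP2K1", c(HGNC = "6840"),
                 bound_conditions = list(list(
                   agent = gene_agent("BRAF", "1097"), is_bound = TRUE)))
  spec <- statement("Phosphorylation", list(bound, mapk1), residue = "T",
                    position = "185")
  gen <- statement("Phosphorylation", list(map2k1, mapk1))
  expect_true(refines(spec, gen, og))
  expect_false(refines(gen, spec, og))
  # member refines family statement
  s_fam <- statement("Phosphorylation", list(mek, erk))
  expect_true(refines(gen, s_fam, og))
  # opposite specificity in different slots: no refinement either way
  s_mixed_a <- statement("Phosphorylation", list(map2k1, erk))
  s_mixed_b <- statement("Phosphorylation", list(mek, mapk1))
  expect_false(refines(s_mixed_a, s_mixed_b, og))
  expect_false(refines(s_mixed_b, s_mixed_a, og))
  # strictness: identical statements do not refine each other
  expect_false(refines(gen, gen, og))
  # specified agent refines the unspecified slot
  s_nosubj <- statement("Phosphorylation", list(NULL, mapk1))
  expect_true(refines(gen, s_nosubj, og))
  expect_false(refines(s_nosubj, gen, og))
  # complexes refine member-wise regardless of order
  c_spec <- statement("Complex", list(mapk1, map2k1))
  c_gen <- statement("Complex", list(mek, erk))
  expect_true(refines(c_spec, c_gen, og))
  expect_false(refines(c_gen, c_spec, og))
})

test_that("deep phosphorylation hierarchy has nine levels and one top
           statement", {
  og <- kinase_ontology()
  chain <- deep_phos_chain()
  rg <- build_refinement_graph(chain, og)
  expect_gte(longest_refinement_path(rg), 8)
  top <- filter_top_level(chain, rg)
  expect_length(top, 1)
  # the retained statement is the fully specified one
  expect_equal(length(top[[1]]$agents[[1]]$mods), 6)
  # transitive reduction of a 9-chain has 8 edges and closes back up
  red <- transitive_reduction(rg)
  expect_equal(nrow(red$edges), 8)
  closure_of <- function(g) {
    ig <- igraph::graph_from_data_frame(
      g$edges, vertices = data.frame(name = g$keys))
    paths <- igraph::distances(ig, mode = "out")
    which(is.finite(paths) & paths > 0, arr.ind = TRUE)
  }
  expect_equal(nrow(closure_of(red)), nrow(rg$edges))
})

test_that("indexed refinement graph equals the brute-force oracle on 200
           synthetic statements", {
  sim <- simulate_corpus(sim_config(seed = 77, n_mechanisms = 150))
  uniq <- combine_duplicates(sim$statements)
  uniq <- uniq[seq_len(min(200, length(uniq)))]
  fast <- build_refinement_graph(uniq, sim$ontology, method = "index")
  slow <- build_refinement_graph(uniq, sim$ontology, method = "brute")
  expect_gt(nrow(slow$edges), 0)
  expect_setequal(paste(fast$edges$from, fast$edges$to, sep = ">"),
                  paste(slow$edges$from, slow$edges$to, sep = ">"))
})

test_that("refines is a strict partial order on unique synthetic
           statements", {
  sim <- simulate_corpus(sim_config(seed = 9, n_mechanisms = 60))
  uniq <- combine_duplicates(sim$statements)
  uniq <- uniq[seq_len(min(60, length(uniq)))]
  og <- sim$ontology
  n <- length(uniq)
  rel <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j)
    rel[i, j] <- refines(uniq[[i]], uniq[[j]], og)
  expect_false(any(diag(rel)))
  expect_false(any(rel & t(rel)))
  for (i in 1:n) for (j in 1:n) if (rel[i, j])
    for (k in 1:n) if (rel[j, k]) expect_true(rel[i, k])
})

test_that("extended evidence unions along refinement chains and diamonds", {
  og <- kinase_ontology()
  chain <- deep_phos_chain()
  rg <- build_refinement_graph(chain, og)
  keys <- names(chain)
  # bottom of the chain receives all 9 evidences; the top only its own
  expect_length(extended_evidence(keys[1], chain, rg), 9)
  expect_length(extended_evidence(keys[9], chain, rg), 1)
  expect_length(extended_evidence(keys[5], chain, rg), 5)
  # diamond with shared evidence counted once
  shared <- evidence("r1", pmid = "77", text = "shared")
  mapk1 <- gene_agent("MAPK1", "6871")
  mek <- agent("MEK", c(FPLX = "MEK"))
  erk <- agent("ERK", c(FPLX = "ERK"))
  d <- list(
    statement("Phosphorylation", list(gene_agent("MAP2K1", "6840"), mapk1),
              evidence = list(shared)),
    statement("Phosphorylation", list(gene_agent("MAP2K2", "6842"), mapk1),
              evidence = list(shared)),
    statement("Phosphorylation", list(mek, erk),
              evidence = list(evidence("r2", pmid = "78"))))
  d <- stats::setNames(d, vapply(d, matches_key, character(1)))
  rgd <- build_refinement_graph(d, og)
  ext <- extended_evidence(names(d)[3], d, rgd)
  expect_length(ext, 2)   # shared counted once + own
})

test_that("extended counts dominate direct counts in assembled corpora", {
  sim <- simulate_corpus(sim_config(seed = 15, n_mechanisms = 80))
  corp <- assemble_corpus(sim$statements, sim$ontology)
  expect_true(all(corp$counts_ext >= corp$counts))
  expect_true(all(corp$pmids_ext >= corp$pmids))
})

test_that("flatten_to_network emits typed edges with merged accounting", {
  a <- gene_agent("A", "1"); b <- gene_agent("B", "2")
  s_act <- statement("Activation", list(a, b), belief = 0.7,
                     evidence = list(evidence("r1", pmid = "1")))
  net1 <- flatten_to_network(list(s_act))
  expect_equal(nrow(net1), 1)
  expect_equal(net1$type, "Activation")
  expect_false(net1$undirected)
  # complex gives a symmetric pair
  s_cx <- statement("Complex", list(a, b), belief = 0.4,
                    evidence = list(evidence("r1", pmid = "2")))
  net2 <- flatten_to_network(list(s_cx))
  expect_equal(nrow(net2), 2)
  expect_true(all(net2$undirected))
  # duplicate-typed statements merge: evidence summed, belief maxed
  s_act2 <- statement("Activation", list(a, b), belief = 0.9,
                      evidence = list(evidence("r2", pmid = "3"),
                                      evidence("r2", pmid = "4")))
  net3 <- flatten_to_network(list(s_act, s_act2))
  expect_equal(nrow(net3), 1)
  expect_equal(net3$n_evidence, 3)
  expect_equal(net3$belief, 0.9)
  expect_equal(net3$sources, "r1,r2")
})
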