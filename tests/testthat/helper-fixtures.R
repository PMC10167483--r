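# Shared fixtures: tiny ontologies, a deep kinase/substrate refinement
# hierarchy, and a random-statement generator for property tests.

gene_agent <- function(name, hgnc, ...) agent(name, c(HGNC = hgnc), ...)

# Kinase/substrate family ontology: RPS6KA1 isa P90RSK isa RSK;
# CREB1 isa CREB; MAP2K1/MAP2K2 isa MEK; MAPK1 isa ERK; BRAF isa RAF.
kinase_ontology <- function() {
  e <- function(sns, sid, snm, rel, dns, did, dnm)
    data.frame(src_ns = sns, src_id = sid, src_name = snm, rel = rel,
               dst_ns = dns, dst_id = did, dst_name = dnm)
  ontology_graph(rbind(
    e("HGNC", "10430", "RPS6KA1", "isa", "FPLX", "P90RSK", "P90RSK"),
    e("FPLX", "P90RSK", "P90RSK", "isa", "FPLX", "RSK", "RSK"),
    e("HGNC", "1385", "CREB1", "isa", "FPLX", "CREB", "CREB"),
    e("HGNC", "6840", "MAP2K1", "isa", "FPLX", "MEK", "MEK"),
    e("HGNC", "6842", "MAP2K2", "isa", "FPLX", "MEK", "MEK"),
    e("HGNC", "6871", "MAPK1", "isa", "FPLX", "ERK", "ERK"),
    e("HGNC", "1097", "BRAF", "isa", "FPLX", "RAF", "RAF"),
    e("HGNC", "6840", "MAP2K1", "xref", "UP", "Q02750", "MAP2K1"),
    e("HGNC", "6871", "MAPK1", "xref", "UP", "P28482", "MAPK1")))
}

rps6ka1 <- function(mods = list())
  agent("RPS6KA1", c(HGNC = "10430"), mods = mods)
p90rsk <- function() agent("P90RSK", c(FPLX = "P90RSK"))
rsk_fam <- function() agent("RSK", c(FPLX = "RSK"))
creb1 <- function() agent("CREB1", c(HGNC = "1385"))
creb_fam <- function() agent("CREB", c(FPLX = "CREB"))
pmod <- function(res, pos) mod_condition("phosphorylation", res, pos)

# Nine statements forming a refinement chain from "CREB is phosphorylated"
# up to a fully specified multi-site kinase phosphorylating CREB1 on S133;
# each level strictly refines the previous, giving an 8-edge longest path.
deep_phos_chain <- function() {
  sites <- list(pmod("S", "221"), pmod("S", "380"), pmod("T", "573"),
                pmod("S", "363"), pmod("T", "359"), pmod("S", "732"))
  ev <- function(i) list(evidence("reader1", pmid = as.character(i)))
  stmts <- list(
    statement("Phosphorylation", list(NULL, creb_fam()), evidence = ev(1)),
    statement("Phosphorylation", list(NULL, creb1()), evidence = ev(2)),
    statement("Phosphorylation", list(NULL, creb1()), residue = "S",
              position = "133", evidence = ev(3)),
    statement("Phosphorylation", list(rsk_fam(), creb1()), residue = "S",
              position = "133", evidence = ev(4)),
    statement("Phosphorylation", list(p90rsk(), creb1()), residue = "S",
              position = "133", evidence = ev(5)),
    statement("Phosphorylation", list(rps6ka1(), creb1()), residue = "S",
              position = "133", evidence = ev(6)),
    statement("Phosphorylation", list(rps6ka1(sites[1]), creb1()),
              residue = "S", position = "133", evidence = ev(7)),
    statement("Phosphorylation", list(rps6ka1(sites[1:3]), creb1()),
              residue = "S", position = "133", evidence = ev(8)),
    statement("Phosphorylation", list(rps6ka1(sites), creb1()),
              residue = "S", position = "133", evidence = ev(9)))
  stats::setNames(stmts, vapply(stmts, matches_key, character(1)))
}

# xref test graph: a chemical with a two-step xref chain and an overlap
chem_ontology <- function() {
  e <- function(sns, sid, snm, rel, dns, did, dnm)
    data.frame(src_ns = sns, src_id = sid, src_name = snm, rel = rel,
               dst_ns = dns, dst_id = did, dst_name = dnm)
  ontology_graph(rbind(
    e("CHEBI", "15551", "prostaglandin E2", "xref",
      "MESH", "D015232", "Dinoprostone"),
    e("MESH", "D015232", "Dinoprostone", "xref",
      "PUBCHEM", "5280360", "Dinoprostone"),
    e("HMDB", "HMDB0001220", "Prostaglandin E2", "xref",
      "CHEBI", "15551", "prostaglandin E2")))
}

random_statement <- function() {
  rnd_agent <- function(depth = 0) {
    nm <- paste0("GENE", sample(99, 1))
    refs <- c(HGNC = as.character(sample(9999, 1)))
    if (stats::runif(1) < 0.3)
      refs <- c(refs, UP = paste0("P", sample(9999, 1)))
    mods <- if (stats::runif(1) < 0.4)
      list(mod_condition("phosphorylation",
                         sample(c("S", "T", "Y"), 1),
                         as.character(sample(500, 1)))) else list()
    bcs <- if (depth == 0 && stats::runif(1) < 0.3)
      list(list(agent = rnd_agent(1), is_bound = TRUE)) else list()
    act <- if (stats::runif(1) < 0.2)
      list(activity_type = "kinase", is_active = TRUE) else NULL
    agent(nm, refs, mods = mods, bound_conditions = bcs, activity = act,
          location = if (stats::runif(1) < 0.2) "nucleus" else NA)
  }
  tp <- sample(c("Phosphorylation", "Activation", "Complex"), 1)
  evs <- lapply(seq_len(sample(3, 1)), function(i)
    evidence(sample(c("reader1", "reader2", "db"), 1),
             pmid = as.character(sample(999, 1)),
             text = paste("some text", sample(99, 1)),
             hypothesis = stats::runif(1) < 0.1,
             annotations = list(tag = "x")))
  if (tp == "Phosphorylation") {
    statement(tp, list(if (stats::runif(1) < 0.3) NULL else rnd_agent(),
                       rnd_agent()),
              residue = sample(c(NA, "S", "T"), 1),
              position = if (stats::runif(1) < 0.5)
                as.character(sample(500, 1)) else NA,
              evidence = evs)
  } else if (tp == "Complex") {
    statement(tp, lapply(seq_len(sample(2:3, 1)), function(i) rnd_agent()),
              evidence = evs)
  } else {
    statement(tp, list(rnd_agent(), rnd_agent()), evidence = evs)
  }
}

# random DAG ontology over n nodes (single namespace + family namespace)
random_dag_ontology <- function(n_nodes = 20, p_edge = 0.15) {
  rows <- list()
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (j <= i) next   # edges only low -> high index: acyclic
      if (stats::runif(1) < p_edge) {
        rows[[length(rows) + 1L]] <- data.frame(
          src_ns = "X", src_id = as.character(i), src_name = paste0("N", i),
          rel = sample(c("isa", "partof"), 1),
          dst_ns = "X", dst_id = as.character(j),
          dst_name = paste0("N", j))
      }
    }
  }
  if (!length(rows)) return(NULL)
  ontology_graph(do.call(rbind, rows))
}
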