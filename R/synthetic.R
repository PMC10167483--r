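#' @title Synthetic corpora and simulation generators
#' @description Generators that emulate the statistical structure of a
#'   multi-source extraction corpus: a toy entity ontology of gene families,
#'   true mechanisms with power-law mention counts, per-source
#'   systematic/random extraction errors, per-mention specificity
#'   degradation (creating refinement structure), stratified curation
#'   sampling, and paired noisy gene-effect matrices with planted
#'   correlated pairs. All outputs are deterministic under a fixed seed.
#' @name synthetic_data
NULL

#' Sample from a discrete power law
#'
#' Exact inverse-CDF sampling from `p(x) = x^(-alpha)/zeta(alpha, xmin)`
#' tabulated up to `min(xmax, 1e6)` (the truncated tail mass beyond the
#' table is negligible for the exponents used here); values are capped at
#' `xmax`.
#'
#' @param n sample size
#' @param alpha exponent (> 1)
#' @param xmin minimum value (default 1)
#' @param xmax truncation point (default `Inf`)
#' @return integer vector
#' @export
rpowerlaw <- function(n, alpha, xmin = 1, xmax = Inf) {
  N <- as.integer(min(xmax, 1e6))
  x <- xmin:N
  w <- x^(-alpha)
  tail_mass <- if (is.finite(xmax)) 0 else
    (N + 0.5)^(1 - alpha) / (alpha - 1)
  cdf <- cumsum(w) / (sum(w) + tail_mass)
  as.integer(pmin(xmin - 1L + findInterval(stats::runif(n), cdf) + 1L, N))
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a mention-count power law with exponent 2.38 (the long-tailed
#' regime a large literature corpus exhibits), three reading-system sources
#' with systematic/random error rates of 0.1/0.35 (a mid-range reader
#' profile) and one high-reliability database source (0.01/0.05), and
#' moderate per-mention specificity degradation so that generic and
#' specific statement variants coexist.
#'
#' @param seed RNG seed fixing all downstream randomness
#' @param n_families,members_per_family ontology size
#' @param n_mechanisms number of true mechanisms
#' @param sources source names
#' @param e_syst,e_rand named per-source error rates
#' @param alpha,max_mentions mention-count power-law exponent and cap
#' @param p_drop_site probability a mention drops the modification site
#' @param p_generalize probability a mention generalizes a gene to its
#'   family
#' @param p_promoter probability a mention text contains "promoter"
#' @param codep list: `genes`, `samples`, `n_planted`, `rho`, `noise_sd`
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_families = 6L, members_per_family = 4L,
                       n_mechanisms = 300L,
                       sources = c("reader1", "reader2", "reader3", "db"),
                       e_syst = c(reader1 = 0.1, reader2 = 0.1,
                                  reader3 = 0.1, db = 0.01),
                       e_rand = c(reader1 = 0.35, reader2 = 0.35,
                                  reader3 = 0.35, db = 0.05),
                       alpha = 2.38, max_mentions = 1000L,
                       p_drop_site = 0.3, p_generalize = 0.2,
                       p_promoter = 0.05,
                       codep = list(genes = 40L, samples = 500L,
                                    n_planted = 20L, rho = 0.5,
                                    noise_sd = 1)) {
  stopifnot(all(e_syst >= 0 & e_syst <= 1), all(e_rand >= 0 & e_rand <= 1),
            all(sources %in% names(e_syst)),
            all(sources %in% names(e_rand)))
  structure(list(seed = as.integer(seed), n_families = n_families,
                 members_per_family = members_per_family,
                 n_mechanisms = n_mechanisms, sources = sources,
                 e_syst = e_syst, e_rand = e_rand, alpha = alpha,
                 max_mentions = max_mentions, p_drop_site = p_drop_site,
                 p_generalize = p_generalize, p_promoter = p_promoter,
                 codep = codep),
            class = "sim_config")
}

#' Generate a toy ontology of gene families
#'
#' `n_families` family nodes (FPLX) each with `members_per_family` member
#' genes (HGNC) connected by `isa` edges; each member also has an `xref`
#' alias in the UP namespace. The result is acyclic by construction.
#'
#' @param config a [sim_config()]
#' @return an [ontology_graph()]
#' @export
generate_ontology <- function(config) {
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fam_id <- paste0("F", f); fam_name <- paste0("FAM", f)
    for (m in seq_len(config$members_per_family)) {
      gid <- as.character(f * 100 + m)
      gname <- paste0("G", f, "_", m)
      rows[[length(rows) + 1L]] <- data.frame(
        src_ns = "HGNC", src_id = gid, src_name = gname, rel = "isa",
        dst_ns = "FPLX", dst_id = fam_id, dst_name = fam_name)
      rows[[length(rows) + 1L]] <- data.frame(
        src_ns = "HGNC", src_id = gid, src_name = gname, rel = "xref",
        dst_ns = "UP", dst_id = paste0("P", gid), dst_name = gname)
    }
  }
  ontology_graph(do.call(rbind, rows))
}

.sim_gene_agent <- function(og, idx = NULL) {
  genes <- og$nodes[og$nodes$ns == "HGNC", ]
  if (is.null(idx)) idx <- sample(nrow(genes), 1)
  agent(genes$name[idx], db_refs = c(HGNC = genes$id[idx]))
}

.family_of <- function(ag, og) {
  anc <- ancestor_closure("HGNC", ag$db_refs[["HGNC"]], og)
  if (!length(anc)) return(ag)
  i <- match(anc[1], og$nodes$key)
  agent(og$nodes$name[i],
        db_refs = stats::setNames(og$nodes$id[i], og$nodes$ns[i]))
}

.random_mechanism <- function(og) {
  genes <- og$nodes[og$nodes$ns == "HGNC", ]
  tp <- sample(c("Phosphorylation", "Activation", "Inhibition", "Complex"),
               1, prob = c(0.35, 0.25, 0.2, 0.2))
  ij <- sample(nrow(genes), 2)
  a1 <- .sim_gene_agent(og, ij[1]); a2 <- .sim_gene_agent(og, ij[2])
  if (tp == "Phosphorylation" && stats::runif(1) < 0.7) {
    statement(tp, list(a1, a2), residue = sample(c("S", "T", "Y"), 1),
              position = as.character(sample(1:600, 1)))
  } else if (tp == "Complex") {
    statement(tp, list(a1, a2))
  } else {
    statement(tp, list(a1, a2))
  }
}

# a corrupted variant of a mechanism: the object/partner entity is swapped
# for a different random gene (misgrounding-style error)
.corrupt <- function(stmt, og) {
  genes <- og$nodes[og$nodes$ns == "HGNC", ]
  cur <- stmt$agents[[length(stmt$agents)]]$name
  idx <- sample(which(genes$name != cur), 1)
  stmt$agents[[length(stmt$agents)]] <- .sim_gene_agent(og, idx)
  stmt
}

.degrade <- function(stmt, og, p_drop_site, p_generalize) {
  if (!is.na(stmt$position) && stats::runif(1) < p_drop_site) {
    stmt$residue <- NA_character_; stmt$position <- NA_character_
  }
  for (i in seq_along(stmt$agents)) {
    a <- stmt$agents[[i]]
    if (!is.null(a) && "HGNC" %in% names(a$db_refs) &&
        stats::runif(1) < p_generalize)
      stmt$agents[[i]] <- .family_of(a, og)
  }
  stmt
}

.sim_text <- function(p_promoter) {
  k <- 5L + stats::rpois(1, 8)
  words <- paste0("w", sample(999, k, replace = TRUE))
  if (stats::runif(1) < p_promoter) words[sample(k, 1)] <- "promoter"
  paste(words, collapse = " ")
}

#' Simulate a raw multi-source extraction corpus
#'
#' For each true mechanism a power-law mention count is drawn and each
#' mention assigned a source. Per (mechanism, source), a systematic-error
#' coin (`e_syst`) replaces the mechanism source-wide by one fixed
#' corrupted variant; otherwise each mention is independently corrupted
#' with probability `e_rand`. Mentions are then independently degraded in
#' specificity (site dropped, gene generalized to family), creating
#' refinement structure. Ground-truth per-evidence correctness is recorded
#' in each evidence's annotations (`correct`).
#'
#' @param config a [sim_config()]
#' @return `list(statements = <raw one-evidence statements>, mechanisms =
#'   <true statements>, ontology, config)`
#' @export
simulate_corpus <- function(config) {
  set.seed(config$seed)
  og <- generate_ontology(config)
  mechanisms <- lapply(seq_len(config$n_mechanisms),
                       function(i) .random_mechanism(og))
  raw <- list()
  for (mi in seq_along(mechanisms)) {
    mech <- mechanisms[[mi]]
    n <- rpowerlaw(1, config$alpha, xmax = config$max_mentions)
    srcs <- sample(config$sources, n, replace = TRUE)
    for (src in unique(srcs)) {
      k <- sum(srcs == src)
      systematic <- stats::runif(1) < config$e_syst[[src]]
      sys_variant <- if (systematic) .corrupt(mech, og)
      for (j in seq_len(k)) {
        if (systematic) {
          content <- sys_variant; correct <- FALSE
        } else if (stats::runif(1) < config$e_rand[[src]]) {
          content <- .corrupt(mech, og); correct <- FALSE
        } else {
          content <- mech; correct <- TRUE
        }
        content <- .degrade(content, og, config$p_drop_site,
                            config$p_generalize)
        content$evidence <- list(evidence(
          src, pmid = as.character(sample(9999, 1)),
          text = .sim_text(config$p_promoter),
          source_id = paste0(src, "-", mi, "-", j),
          annotations = list(correct = correct, mechanism = mi)))
        raw[[length(raw) + 1L]] <- content
      }
    }
  }
  list(statements = raw, mechanisms = mechanisms, ontology = og,
       config = config)
}

#' Ground-truth statement correctness of an assembled synthetic corpus
#'
#' A unique statement is correct iff at least one of its evidences was a
#' correct extraction (the same rule curation uses).
#'
#' @param corpus an [assemble_corpus()] result built from
#'   [simulate_corpus()] output
#' @return named logical vector over statement keys
#' @export
corpus_ground_truth <- function(corpus) {
  vapply(corpus$statements, function(s)
    any(vapply(s$evidence, function(e)
      isTRUE(e$annotations$correct), logical(1))), logical(1))
}

#' Stratified curation sampling from an assembled synthetic corpus
#'
#' Samples statements with replacement per (source, mention-count) stratum
#' and emits evidence-level curation rows whose labels are the generator's
#' ground truth.
#'
#' @param corpus assembled synthetic corpus
#' @param strata mention counts to sample (default 1:10)
#' @param per_stratum draws per stratum (default 10)
#' @param seed RNG seed
#' @return data.frame with columns `statement_key, evidence_key, label,
#'   curator, source, stratum, sample_id` (repeat draws share keys but get
#'   distinct sample ids)
#' @export
generate_curation_dataset <- function(corpus, strata = 1:10,
                                      per_stratum = 10L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  sid <- 0L
  for (src in corpus$sources) {
    for (k in strata) {
      pop <- rownames(corpus$counts)[corpus$counts[, src] == k]
      if (!length(pop)) next
      draws <- sample(pop, per_stratum, replace = TRUE)
      for (key in draws) {
        sid <- sid + 1L
        s <- corpus$statements[[key]]
        for (e in s$evidence) {
          if (!identical(e$source_api, src)) next
          rows[[length(rows) + 1L]] <- data.frame(
            statement_key = key, evidence_key = evidence_key(e),
            label = if (isTRUE(e$annotations$correct)) "correct" else
              "incorrect",
            curator = "synthetic", source = src, stratum = k,
            sample_id = sid)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate statement-level curated data for belief-model fitting
#'
#' Direct statement-level simulation under the two-parameter error model:
#' each statement draws a mention count uniformly over `strata`, is
#' systematically wrong with probability `e_syst`, and otherwise has each
#' mention independently wrong with probability `e_rand`; the statement is
#' correct iff at least one mention is correct.
#'
#' @param n number of statements
#' @param e_syst,e_rand generating error rates
#' @param source source name for the count column
#' @param strata mention counts sampled uniformly (default 1:10)
#' @param seed RNG seed
#' @return `list(counts = <n x 1 matrix>, correct = <logical>)`
#' @export
simulate_curated_statements <- function(n, e_syst, e_rand,
                                        source = "reader1", strata = 1:10,
                                        seed = 1L) {
  set.seed(seed)
  counts <- sample(strata, n, replace = TRUE)
  sys <- stats::runif(n) < e_syst
  n_wrong <- stats::rbinom(n, counts, e_rand)
  correct <- !sys & n_wrong < counts
  list(counts = matrix(as.numeric(counts), ncol = 1,
                       dimnames = list(NULL, source)),
       correct = correct)
}

#' Generate paired gene-effect matrices with planted codependencies
#'
#' Two replicate genes x samples matrices of standard-normal effects with
#' independent noise; for each planted pair the second gene's effects are
#' correlated with the first at level `rho`. When a network is supplied, a
#' configured fraction of planted pairs is drawn from its edges so that
#' explanations exist.
#'
#' @param config a [sim_config()] (uses the `codep` block and `seed`)
#' @param genes gene names (default `G1..Gn` per config)
#' @param network optional edge data.frame (`subject`, `object`) to align
#'   planted pairs with
#' @param network_fraction fraction of planted pairs taken from network
#'   edges (default 0.5)
#' @return `list(m1, m2, planted = data.frame(gene_a, gene_b))`
#' @export
generate_dependency_matrices <- function(config, genes = NULL,
                                         network = NULL,
                                         network_fraction = 0.5) {
  set.seed(config$seed + 1L)
  cd <- config$codep
  if (is.null(genes)) genes <- paste0("G", seq_len(cd$genes))
  ns <- cd$samples
  planted <- list()
  used <- character(0)
  if (!is.null(network) && nrow(network)) {
    edges <- unique(network[, c("subject", "object")])
    edges <- edges[edges$subject %in% genes & edges$object %in% genes &
                     edges$subject != edges$object, , drop = FALSE]
    n_net <- min(nrow(edges), round(cd$n_planted * network_fraction))
    if (n_net > 0) {
      pick <- edges[sample(nrow(edges), n_net), , drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        planted[[length(planted) + 1L]] <-
          c(pick$subject[i], pick$object[i])
        used <- c(used, pick$subject[i], pick$object[i])
      }
    }
  }
  free <- setdiff(genes, used)
  while (length(planted) < cd$n_planted && length(free) >= 2) {
    pr <- sample(free, 2)
    planted[[length(planted) + 1L]] <- pr
    free <- setdiff(free, pr)
  }
  planted_df <- data.frame(
    gene_a = vapply(planted, `[`, character(1), 1),
    gene_b = vapply(planted, `[`, character(1), 2))
  mk <- function() {
    m <- matrix(stats::rnorm(length(genes) * ns, sd = cd$noise_sd),
                nrow = length(genes),
                dimnames = list(genes, paste0("S", seq_len(ns))))
    for (i in seq_len(nrow(planted_df))) {
      a <- planted_df$gene_a[i]; b <- planted_df$gene_b[i]
      m[b, ] <- cd$rho * m[a, ] +
        sqrt(1 - cd$rho^2) * stats::rnorm(ns, sd = cd$noise_sd)
    }
    m
  }
  list(m1 = mk(), m2 = mk(), planted = planted_df)
}
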