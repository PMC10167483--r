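#' @title Gene codependency detection and explanation
#' @description Detects codependent gene pairs from paired perturbation
#'   effect matrices (Fisher-transformed signed z-scores combined across
#'   datasets by Stouffer's method), applies multiplicity control with an
#'   optional network prior, excludes among-mitochondrial correlations, and
#'   explains significant pairs against an assembled network and ontology.
#' @name codependency
NULL

.pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\x1f"), paste(b, a, sep = "\x1f"))
}

#' Pairwise codependency z-scores from two effect matrices
#'
#' For every unordered gene pair: Pearson correlation in each dataset
#' (pairwise-complete observations), signed Fisher z
#' `atanh(r) * sqrt(n - 3)`, Stouffer combination
#' `(z1 + z2)/sqrt(2)`, and a two-sided p-value. Pairs with fewer than
#' `min_overlap` complete samples in either dataset are skipped.
#'
#' @param m1,m2 numeric matrices, genes x samples (rownames = gene
#'   symbols); replicate datasets over the same genes
#' @param min_overlap minimum complete sample pairs (default 4)
#' @return data.frame of class `codep_scores`: `gene_a, gene_b, r1, r2,
#'   z1, z2, z_combined, p`
#' @export
pairwise_z <- function(m1, m2, min_overlap = 4) {
  genes <- intersect(rownames(m1), rownames(m2))
  if (length(genes) < 2) stop("matrices share fewer than 2 genes")
  m1 <- m1[genes, , drop = FALSE]; m2 <- m2[genes, , drop = FALSE]
  fisher_block <- function(m) {
    r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
    ok <- !is.na(m)
    n <- tcrossprod(ok * 1)
    z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(pmax(n - 3, 0))
    list(r = r, z = z, n = n)
  }
  b1 <- fisher_block(m1); b2 <- fisher_block(m2)
  ut <- which(upper.tri(b1$r), arr.ind = TRUE)
  keep <- b1$n[ut] >= min_overlap & b2$n[ut] >= min_overlap &
    !is.na(b1$r[ut]) & !is.na(b2$r[ut])
  n_skipped <- sum(!keep)
  if (n_skipped)
    message(n_skipped, " pair(s) skipped for insufficient sample overlap")
  ut <- ut[keep, , drop = FALSE]
  z1 <- b1$z[ut]; z2 <- b2$z[ut]
  zc <- (z1 + z2) / sqrt(2)
  out <- data.frame(gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
                    r1 = b1$r[ut], r2 = b2$r[ut], z1 = z1, z2 = z2,
                    z_combined = zc, p = 2 * stats::pnorm(-abs(zc)))
  class(out) <- c("codep_scores", class(out))
  out
}

#' Exclude among-mitochondrial pairs
#'
#' Mitochondrial genes co-vary pervasively in perturbation screens; pairs
#' where BOTH genes are in the mitochondrial set are labeled
#' `excluded_mito` and removed from testing (returned as an attribute).
#' Pairs with exactly one mitochondrial gene are retained.
#'
#' @param scores a `codep_scores` data.frame
#' @param mito_genes character vector of mitochondrial gene symbols
#' @return filtered scores; excluded rows in `attr(, "excluded_mito")`
#' @export
exclude_mito_pairs <- function(scores, mito_genes) {
  both <- scores$gene_a %in% mito_genes & scores$gene_b %in% mito_genes
  excluded <- scores[both, , drop = FALSE]
  if (nrow(excluded)) excluded$label <- "excluded_mito"
  out <- scores[!both, , drop = FALSE]
  attr(out, "excluded_mito") <- excluded
  out
}

#' Flag significant codependencies with multiple-testing control
#'
#' Controls the family-wise error rate (Bonferroni) or false discovery
#' rate (Benjamini-Hochberg / Benjamini-Yekutieli) over all tested pairs.
#' An optional prior pair set (e.g. edges of an assembled network)
#' restricts the hypotheses tested, which can recover pairs that the
#' unrestricted correction misses.
#'
#' @param scores a `codep_scores` data.frame
#' @param method `"bonferroni"`, `"bh"` or `"by"`
#' @param alpha significance level (default 0.05)
#' @param prior_pairs optional data.frame/matrix with two gene columns
#'   defining the prior hypothesis set (unordered match)
#' @return `list(scores = <df with significant / significant_prior /
#'   prior_only columns>, summary = <list of test and hit counts>)`
#' @export
significant_pairs <- function(scores, method = c("bh", "by", "bonferroni"),
                              alpha = 0.05, prior_pairs = NULL) {
  method <- match.arg(method)
  padj_method <- c(bh = "BH", by = "BY", bonferroni = "bonferroni")[method]
  scores$significant <- stats::p.adjust(scores$p, padj_method) <= alpha
  summary <- list(method = method, alpha = alpha,
                  n_tests = nrow(scores),
                  n_significant = sum(scores$significant))
  if (!is.null(prior_pairs)) {
    pk <- .pair_key(as.character(prior_pairs[[1]]),
                    as.character(prior_pairs[[2]]))
    in_prior <- .pair_key(scores$gene_a, scores$gene_b) %in% pk
    scores$significant_prior <- FALSE
    scores$significant_prior[in_prior] <-
      stats::p.adjust(scores$p[in_prior], padj_method) <= alpha
    scores$prior_only <- scores$significant_prior & !scores$significant
    summary$n_tests_prior <- sum(in_prior)
    summary$n_significant_prior <- sum(scores$significant_prior)
    summary$n_prior_only <- sum(scores$prior_only)
  }
  list(scores = scores, summary = summary)
}

# parent names of a gene symbol in the ontology (isa/partof ancestors)
.parent_names <- function(gene, og, use_partof = TRUE) {
  i <- which(og$nodes$name == gene)
  if (!length(i)) return(character(0))
  anc <- unique(unlist(lapply(i, function(j)
    ancestor_closure(og$nodes$ns[j], og$nodes$id[j], og, use_partof))))
  unique(og$nodes$name[match(anc, og$nodes$key)])
}

#' Explain codependent pairs against a network and ontology
#'
#' Labels each pair with the first matching single-edge explanation, in
#' priority order: `direct` (a network edge between the two genes, either
#' direction), `family_complex` (both genes share an isa/partof parent),
#' `parent_link` (an edge connects a gene or one of its parents to the
#' other gene or one of its parents, with at least one endpoint being a
#' parent rather than the gene itself), else `unexplained`. Multi-step
#' paths never count.
#'
#' @param scores a `codep_scores` data.frame
#' @param network data.frame with `subject`, `object` columns of gene or
#'   family names (e.g. from [flatten_to_network()])
#' @param og an [ontology_graph()] giving family membership
#' @param use_partof whether partof edges define parents
#' @return scores with a `label` column
#' @export
explain_pairs <- function(scores, network, og, use_partof = TRUE) {
  ekeys <- unique(.pair_key(as.character(network$subject),
                            as.character(network$object)))
  has_edge <- function(a, b) .pair_key(a, b) %in% ekeys
  scores$label <- vapply(seq_len(nrow(scores)), function(i) {
    g1 <- scores$gene_a[i]; g2 <- scores$gene_b[i]
    if (has_edge(g1, g2)) return("direct")
    p1 <- .parent_names(g1, og, use_partof)
    p2 <- .parent_names(g2, og, use_partof)
    if (length(intersect(p1, p2))) return("family_complex")
    for (x in c(g1, p1)) for (y in c(g2, p2)) {
      if ((x %in% p1 || y %in% p2) && has_edge(x, y))
        return("parent_link")
    }
    "unexplained"
  }, character(1))
  scores
}

#' Compare complex-forming statements against a reference interaction set
#'
#' Bins binary-complex statements by belief score and counts, per bin, how
#' many pairs appear in the reference protein-protein interaction list.
#' For statements absent from the reference ("uncurated"), the sum of
#' their beliefs estimates the number of correct-but-uncurated
#' interactions; the yield curve gives the expected number of correct
#' statements among the first `n` reviewed in descending belief order.
#'
#' @param stmts named list of statements with beliefs attached (Complex
#'   type is used; others ignored)
#' @param reference data.frame/matrix with two gene-symbol columns
#' @param bin_width belief bin width (default 0.1)
#' @return `list(bins = <data.frame belief_lo, belief_hi, n_in_ref,
#'   n_not_in_ref, fraction_in_ref>, expected_uncurated_correct,
#'   yield = <data.frame n_reviewed, expected_correct>)`
#' @export
ppi_belief_comparison <- function(stmts, reference, bin_width = 0.1) {
  ref <- unique(.pair_key(as.character(reference[[1]]),
                          as.character(reference[[2]])))
  rows <- list()
  for (s in stmts) {
    if (!identical(s$type, "Complex") || length(s$agents) != 2) next
    if (is.null(s$belief)) next
    nms <- vapply(s$agents, `[[`, character(1), "name")
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = nms[1], gene_b = nms[2], belief = s$belief,
      in_ref = .pair_key(nms[1], nms[2]) %in% ref)
  }
  if (!length(rows)) stop("no binary Complex statements with beliefs")
  df <- do.call(rbind, rows)
  lo <- seq(0, 1 - bin_width, by = bin_width)
  bins <- do.call(rbind, lapply(lo, function(b) {
    sel <- df$belief >= b & (df$belief < b + bin_width |
                               (b + bin_width >= 1 & df$belief <= 1))
    data.frame(belief_lo = b, belief_hi = b + bin_width,
               n_in_ref = sum(df$in_ref[sel]),
               n_not_in_ref = sum(!df$in_ref[sel]),
               fraction_in_ref = if (any(sel)) mean(df$in_ref[sel])
               else NA_real_)
  }))
  unc <- df[!df$in_ref, , drop = FALSE]
  unc <- unc[order(unc$belief, decreasing = TRUE), , drop = FALSE]
  yield <- data.frame(n_reviewed = seq_len(nrow(unc)),
                      expected_correct = cumsum(unc$belief))
  list(bins = bins, expected_uncurated_correct = sum(unc$belief),
       yield = yield, pairs = df)
}
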