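#' @title Statement assembly: deduplication and refinement
#' @description Collapses duplicate statements by equivalence key, decides
#'   pairwise refinement (one statement carrying all the information of
#'   another plus additional specificity), builds the refinement graph with
#'   near-linear candidate generation, computes refinement-extended evidence
#'   sets, and flattens assembled corpora to typed networks.
#' @name assembly
NULL

#' Collapse duplicate statements
#'
#' Groups statements by [matches_key()] and emits one statement per group
#' with the concatenated evidence, deduplicated by [evidence_key()].
#'
#' @param stmts list of statements (canonicalized)
#' @param namespace_priority ordered namespace preference
#' @return named list of unique statements (names are equivalence keys)
#' @export
combine_duplicates <- function(stmts,
                               namespace_priority = default_ns_priority()) {
  keys <- vapply(stmts, matches_key, character(1),
                 namespace_priority = namespace_priority)
  out <- list()
  for (i in seq_along(stmts)) {
    k <- keys[i]
    if (is.null(out[[k]])) {
      out[[k]] <- stmts[[i]]
    } else {
      out[[k]]$evidence <- c(out[[k]]$evidence, stmts[[i]]$evidence)
    }
  }
  lapply(out, function(s) {
    ek <- vapply(s$evidence, evidence_key, character(1))
    s$evidence <- s$evidence[!duplicated(ek)]
    s
  })
}

# ---- element-level comparison -----------------------------------------------
# Relations: "eq" (equal), "a" (first strictly more specific), "b" (second
# strictly more specific), "inc" (incomparable). A statement refines another
# iff every element is "eq" or "a" and at least one is "a".

.combine_cmp <- function(v) {
  if (any(v == "inc")) return("inc")
  ha <- any(v == "a"); hb <- any(v == "b")
  if (ha && hb) return("inc")
  if (ha) return("a")
  if (hb) return("b")
  "eq"
}

.cmp_scalar <- function(a, b) {
  if (is.na(a) && is.na(b)) return("eq")
  if (is.na(b)) return("a")
  if (is.na(a)) return("b")
  if (identical(a, b)) "eq" else "inc"
}

.cmp_entity <- function(a, b, og, np, use_partof, clo) {
  if (is.null(a) && is.null(b)) return("eq")
  if (is.null(b)) return("a")
  if (is.null(a)) return("b")
  cga <- canonical_grounding(a, np); cgb <- canonical_grounding(b, np)
  ka <- .node_key(cga[1], cga[2]); kb <- .node_key(cgb[1], cgb[2])
  if (ka == kb) return("eq")
  ca <- clo[[ka]]; cb <- clo[[kb]]
  if (kb %in% ca) return("a")
  if (ka %in% cb) return("b")
  "inc"
}

# mod_a refines-or-equals mod_b (same kind, b's site fields absent or equal)
.mod_ge <- function(ma, mb) {
  if (!identical(ma$mod_type, mb$mod_type)) return(FALSE)
  if (!identical(ma$is_modified, mb$is_modified)) return(FALSE)
  if (!is.na(mb$residue) && !identical(ma$residue, mb$residue)) return(FALSE)
  if (!is.na(mb$position) && !identical(ma$position, mb$position)) return(FALSE)
  TRUE
}

# can every element of `sub` be covered by a distinct element of `sup`
# under ge_fun(sup_el, sub_el)? (injective matching, backtracking)
.can_cover <- function(sup, sub, ge_fun) {
  n <- length(sub)
  if (n == 0) return(TRUE)
  if (length(sup) < n) return(FALSE)
  used <- rep(FALSE, length(sup))
  rec <- function(i) {
    if (i > n) return(TRUE)
    for (j in seq_along(sup)) {
      if (!used[j] && ge_fun(sup[[j]], sub[[i]])) {
        used[j] <<- TRUE
        if (rec(i + 1)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  rec(1)
}

.cmp_setlike <- function(la, lb, ge_fun) {
  a_ge <- .can_cover(la, lb, ge_fun)
  b_ge <- .can_cover(lb, la, ge_fun)
  if (a_ge && b_ge) "eq" else if (a_ge) "a" else if (b_ge) "b" else "inc"
}

.mut_eq <- function(x, y)
  identical(x$from_residue, y$from_residue) &&
  identical(x$position, y$position) && identical(x$to_residue, y$to_residue)

.cmp_activity <- function(a, b) {
  if (is.null(a) && is.null(b)) return("eq")
  if (is.null(b)) return("a")
  if (is.null(a)) return("b")
  if (identical(a$activity_type, b$activity_type) &&
      identical(isTRUE(a$is_active), isTRUE(b$is_active))) "eq" else "inc"
}

.cmp_agent <- function(a, b, og, np, use_partof, clo) {
  if (is.null(a) && is.null(b)) return("eq")
  if (is.null(b)) return("a")
  if (is.null(a)) return("b")
  bc_ge <- function(x, y) {
    identical(isTRUE(x$is_bound), isTRUE(y$is_bound)) &&
      .cmp_entity(x$agent, y$agent, og, np, use_partof, clo) %in% c("eq", "a")
  }
  .combine_cmp(c(
    .cmp_entity(a, b, og, np, use_partof, clo),
    .cmp_setlike(a$mods, b$mods, .mod_ge),
    .cmp_setlike(a$mutations, b$mutations,
                 function(x, y) .mut_eq(x, y)),
    .cmp_activity(a$activity, b$activity),
    .cmp_setlike(a$bound_conditions, b$bound_conditions, bc_ge),
    .cmp_scalar(a$location, b$location)))
}

.cmp_statement <- function(a, b, og, np, use_partof, clo) {
  if (!identical(a$type, b$type)) return("inc")
  if (length(a$agents) != length(b$agents)) return("inc")
  info <- .stmt_type_info(a$type)
  site_cmp <- .combine_cmp(c(.cmp_scalar(a$residue, b$residue),
                             .cmp_scalar(a$position, b$position)))
  if (isTRUE(info$unordered)) {
    # try member correspondences; accept the best achievable relation
    perms <- .permutations(length(b$agents))
    best <- "inc"
    for (p in perms) {
      cmps <- vapply(seq_along(a$agents), function(i)
        .cmp_agent(a$agents[[i]], b$agents[[p[i]]], og, np, use_partof, clo),
        character(1))
      r <- .combine_cmp(c(cmps, site_cmp))
      if (r == "a") return("a")
      if (r == "eq" && best == "inc") best <- "eq"
      if (r == "b" && best != "eq") best <- "b"
    }
    return(best)
  }
  cmps <- vapply(seq_along(a$agents), function(i)
    .cmp_agent(a$agents[[i]], b$agents[[i]], og, np, use_partof, clo),
    character(1))
  .combine_cmp(c(cmps, site_cmp))
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Does statement `a` refine statement `b`?
#'
#' TRUE iff the two statements have the same type, every element of `a`
#' (agents slot-by-slot including their states, and the residue/position
#' arguments) equals or strictly refines the corresponding element of `b`,
#' at least one element strictly refines, and no element of `b` strictly
#' refines the corresponding element of `a` (mixed specificity in opposite
#' directions is no refinement). Entity specificity follows the ontology's
#' isa/partof hierarchy; unspecified slots are the least specific element.
#'
#' @param a,b statements
#' @param og an [ontology_graph()]
#' @param namespace_priority ordered namespace preference
#' @param use_partof whether partof edges confer specificity
#' @return logical scalar; strict (identical statements give FALSE)
#' @export
refines <- function(a, b, og, namespace_priority = default_ns_priority(),
                    use_partof = TRUE) {
  clo <- .all_closures(og, use_partof)
  .cmp_statement(a, b, og, namespace_priority, use_partof, clo) == "a"
}

# ---- refinement graph -------------------------------------------------------

.slot_entity_keys <- function(s, np) {
  vapply(s$agents, function(a) {
    if (is.null(a)) return("~")
    cg <- canonical_grounding(a, np)
    .node_key(cg[1], cg[2])
  }, character(1))
}

#' Build the statement refinement graph
#'
#' Nodes are unique statement keys; a directed edge points from a more
#' specific statement to each statement it refines (all such ordered pairs,
#' i.e. the transitive closure; see [transitive_reduction()] for the
#' display view). Candidate pairs are generated from an index over
#' (type, slot, entity-or-ancestor) so the cost is near-linear in the
#' number of matching pairs; `method = "brute"` compares all pairs instead.
#'
#' @param stmts named list of unique statements (from [combine_duplicates()])
#' @param og an [ontology_graph()]
#' @param namespace_priority ordered namespace preference
#' @param use_partof whether partof edges confer specificity
#' @param method `"index"` (default) or `"brute"` (all-pairs reference path)
#' @return object of class `refinement_graph`: `list(keys, edges =
#'   data.frame(from, to))`
#' @export
build_refinement_graph <- function(stmts, og,
                                   namespace_priority = default_ns_priority(),
                                   use_partof = TRUE,
                                   method = c("index", "brute")) {
  method <- match.arg(method)
  np <- namespace_priority
  keys <- names(stmts)
  if (is.null(keys))
    keys <- vapply(stmts, matches_key, character(1),
                   namespace_priority = np)
  if (anyDuplicated(keys)) stop("statements must be deduplicated first")
  n <- length(stmts)
  clo <- .all_closures(og, use_partof)
  from <- character(0); to <- character(0)

  if (method == "brute" || n <= 2) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (.cmp_statement(stmts[[i]], stmts[[j]], og, np, use_partof,
                         clo) == "a") {
        from <- c(from, keys[i]); to <- c(to, keys[j])
      }
    }
  } else {
    types <- vapply(stmts, `[[`, character(1), "type")
    arity <- vapply(stmts, function(s) length(s$agents), integer(1))
    unord <- vapply(types, function(tp) isTRUE(.stmt_type_info(tp)$unordered),
                    logical(1))
    ekeys <- lapply(stmts, .slot_entity_keys, np = np)
    # index: (type, arity, slot-label, entity-key) -> statement ids
    idx <- new.env(parent = emptyenv(), hash = TRUE)
    for (i in seq_len(n)) {
      slots <- if (unord[i]) rep("m", arity[i]) else
        as.character(seq_len(arity[i]))
      for (s in seq_len(arity[i])) {
        k <- paste(types[i], arity[i], slots[s], ekeys[[i]][s], sep = "\x1f")
        idx[[k]] <- c(idx[[k]], i)
      }
    }
    lookup <- function(tp, ar, slot, ents) {
      hits <- integer(0)
      for (e in ents) {
        k <- paste(tp, ar, slot, e, sep = "\x1f")
        v <- idx[[k]]
        if (!is.null(v)) hits <- c(hits, v)
      }
      unique(hits)
    }
    for (i in seq_len(n)) {
      allowed <- lapply(seq_len(arity[i]), function(s) {
        ek <- ekeys[[i]][s]
        if (ek == "~") "~" else c(ek, clo[[ek]], "~")
      })
      if (unord[i]) {
        cand <- lookup(types[i], arity[i], "m",
                       unique(unlist(allowed)))
      } else {
        cand <- NULL
        for (s in seq_len(arity[i])) {
          hits <- lookup(types[i], arity[i], as.character(s), allowed[[s]])
          cand <- if (is.null(cand)) hits else intersect(cand, hits)
          if (!length(cand)) break
        }
      }
      for (j in setdiff(cand, i)) {
        if (.cmp_statement(stmts[[i]], stmts[[j]], og, np, use_partof,
                           clo) == "a") {
          from <- c(from, keys[i]); to <- c(to, keys[j])
        }
      }
    }
  }
  edges <- data.frame(from = from, to = to)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = keys))
    if (!igraph::is_dag(g))
      stop("internal error: refinement graph has a cycle (broken ontology?)")
  }
  structure(list(keys = keys, edges = edges), class = "refinement_graph")
}

#' @export
print.refinement_graph <- function(x, ...) {
  cat(sprintf("<refinement_graph> %d statements, %d refinement edges\n",
              length(x$keys), nrow(x$edges)))
  invisible(x)
}

.rg_igraph <- function(rg)
  igraph::graph_from_data_frame(rg$edges, directed = TRUE,
                                vertices = data.frame(name = rg$keys))

#' Transitive reduction of a refinement graph (display view)
#'
#' Removes every edge implied by a longer path; closing the reduction back
#' up reproduces the transitive closure of the original graph.
#'
#' @param rg a `refinement_graph`
#' @return a `refinement_graph` with the reduced edge set
#' @export
transitive_reduction <- function(rg) {
  e <- rg$edges
  if (!nrow(e)) return(rg)
  succ <- split(e$to, e$from)
  keep <- vapply(seq_len(nrow(e)), function(i) {
    mids <- setdiff(succ[[e$from[i]]], e$to[i])
    !any(vapply(mids, function(m)
      e$to[i] %in% succ[[m]], logical(1)), na.rm = TRUE)
  }, logical(1))
  structure(list(keys = rg$keys, edges = e[keep, , drop = FALSE]),
            class = "refinement_graph")
}

#' Length of the longest refinement chain
#'
#' @param rg a `refinement_graph`
#' @return longest directed path length in edges (0 for an edgeless graph)
#' @export
longest_refinement_path <- function(rg) {
  if (!nrow(rg$edges)) return(0L)
  g <- .rg_igraph(rg)
  ord <- names(igraph::topo_sort(g))
  depth <- stats::setNames(rep(0L, length(ord)), ord)
  for (v in ord) {
    for (w in names(igraph::neighbors(g, v, mode = "out")))
      depth[w] <- max(depth[w], depth[v] + 1L)
  }
  max(depth)
}

#' Keep only top-level (most specific) statements
#'
#' Retains statements not refined by any other statement, i.e. nodes with
#' no incoming refinement edge.
#'
#' @param stmts named list of unique statements
#' @param rg the corresponding `refinement_graph`
#' @return filtered named list
#' @export
filter_top_level <- function(stmts, rg) {
  refined <- unique(rg$edges$to)
  stmts[setdiff(names(stmts), refined)]
}

# ---- evidence accounting ----------------------------------------------------

.dedup_evidence <- function(evs) {
  ek <- vapply(evs, evidence_key, character(1))
  evs[!duplicated(ek)]
}

#' Per-source evidence counts of an evidence list
#'
#' @param evs list of [evidence()] objects (deduplicated by identity first)
#' @return named integer vector, source -> mention count
#' @export
source_counts <- function(evs) {
  evs <- .dedup_evidence(evs)
  srcs <- vapply(evs, `[[`, character(1), "source_api")
  tab <- table(srcs)
  stats::setNames(as.integer(tab), names(tab))
}

#' Refinement-extended evidence of a statement
#'
#' The extended evidence set is the union of the statement's own evidence
#' with the evidence of every statement that refines it (transitively),
#' deduplicated by evidence identity. Counts per source on the union are
#' therefore componentwise at least the direct counts.
#'
#' @param key statement key
#' @param stmts named list of unique statements
#' @param rg `refinement_graph` over those statements
#' @return list of [evidence()] objects
#' @export
extended_evidence <- function(key, stmts, rg) {
  refiners <- rg$edges$from[rg$edges$to == key]
  evs <- stmts[[key]]$evidence
  for (k in refiners) evs <- c(evs, stmts[[k]]$evidence)
  .dedup_evidence(evs)
}

# ---- assembled corpus -------------------------------------------------------

#' Assemble a corpus from filtered statements
#'
#' Runs deduplication and refinement-graph construction and precomputes the
#' per-statement direct and refinement-extended source count matrices and
#' unique-publication counts.
#'
#' @param stmts filtered statement list
#' @param og an [ontology_graph()]
#' @param namespace_priority ordered namespace preference
#' @param use_partof whether partof edges confer specificity
#' @return object of class `assembled_corpus` with elements `statements`
#'   (named list), `graph` (`refinement_graph`), `sources`, `counts` and
#'   `counts_ext` (statement x source matrices), `pmids` and `pmids_ext`
#'   (unique publication counts)
#' @export
assemble_corpus <- function(stmts, og,
                            namespace_priority = default_ns_priority(),
                            use_partof = TRUE) {
  uniq <- combine_duplicates(stmts, namespace_priority)
  rg <- build_refinement_graph(uniq, og, namespace_priority, use_partof)
  keys <- names(uniq)
  ext <- lapply(keys, extended_evidence, stmts = uniq, rg = rg)
  names(ext) <- keys
  all_sources <- sort(unique(unlist(lapply(uniq, function(s)
    vapply(s$evidence, `[[`, character(1), "source_api")))))
  mk_counts <- function(evlists) {
    m <- matrix(0L, nrow = length(keys), ncol = length(all_sources),
                dimnames = list(keys, all_sources))
    for (k in keys) {
      sc <- source_counts(evlists[[k]])
      m[k, names(sc)] <- sc
    }
    m
  }
  direct_ev <- lapply(uniq, `[[`, "evidence")
  npmid <- function(evs)
    length(unique(stats::na.omit(vapply(evs, `[[`, character(1), "pmid"))))
  structure(list(
    statements = uniq, graph = rg, sources = all_sources,
    counts = mk_counts(direct_ev), counts_ext = mk_counts(ext),
    pmids = vapply(direct_ev, npmid, integer(1)),
    pmids_ext = vapply(ext, npmid, integer(1))),
    class = "assembled_corpus")
}

#' @export
print.assembled_corpus <- function(x, ...) {
  cat(sprintf(paste0("<assembled_corpus> %d unique statements, %d sources,",
                     " %d refinement edges\n"),
              length(x$statements), length(x$sources), nrow(x$graph$edges)))
  invisible(x)
}

#' Flatten statements to a typed directed edge list
#'
#' One edge per (subject, object, type); `Complex` members yield symmetric
#' directed edge pairs flagged undirected (all member pairs for larger
#' complexes). Edges arising from several statements of the same type and
#' endpoints are merged: evidence counts summed, belief taken as the
#' maximum.
#'
#' @param stmts named list of statements (with beliefs attached if desired)
#' @return data.frame with columns `subject, object, type, belief,
#'   n_evidence, sources, undirected`
#' @export
flatten_to_network <- function(stmts) {
  rows <- list()
  add <- function(su, ob, tp, bel, nev, src, und) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = su, object = ob, type = tp,
      belief = if (is.null(bel)) NA_real_ else bel,
      n_evidence = nev, sources = src, undirected = und)
  }
  for (s in stmts) {
    nev <- length(.dedup_evidence(s$evidence))
    src <- paste(sort(unique(vapply(s$evidence, `[[`, character(1),
                                    "source_api"))), collapse = ",")
    nm <- function(a) if (is.null(a)) NA_character_ else a$name
    if (isTRUE(.stmt_type_info(s$type)$unordered)) {
      nms <- vapply(s$agents, nm, character(1))
      for (i in seq_along(nms)) for (j in seq_along(nms)) {
        if (i == j) next
        add(nms[i], nms[j], s$type, s$belief, nev, src, TRUE)
      }
    } else if (length(s$agents) >= 2) {
      add(nm(s$agents[[1]]), nm(s$agents[[2]]), s$type, s$belief, nev, src,
          FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(subject = character(), object = character(),
                      type = character(), belief = numeric(),
                      n_evidence = integer(), sources = character(),
                      undirected = logical()))
  df <- do.call(rbind, rows)
  key <- paste(df$subject, df$object, df$type, sep = "\x1f")
  agg <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    r <- df[idx[1], ]
    r$n_evidence <- sum(df$n_evidence[idx])
    r$belief <- if (all(is.na(df$belief[idx]))) NA_real_ else
      max(df$belief[idx], na.rm = TRUE)
    r$sources <- paste(sort(unique(unlist(
      strsplit(df$sources[idx], ",", fixed = TRUE)))), collapse = ",")
    r$undirected <- any(df$undirected[idx])
    r
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
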