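#' @title Entity ontology graph
#' @description A typed directed graph over grounded entities supporting
#'   grounding standardization (xref traversal), canonical naming, ancestor
#'   closures over isa/partof edges, and entity-level refinement tests.
#' @name ontology
NULL

.node_key <- function(ns, id) paste0(ns, ":", id)

#' Construct an ontology graph from a typed edge list
#'
#' Edge relations are `isa` (member -> family), `partof` (component ->
#' complex) and `xref` (equivalent grounding in another namespace). The
#' isa/partof subgraph must be acyclic; xref edges must connect distinct
#' namespaces; every node carries a standard name.
#'
#' @param edges data.frame with columns `src_ns, src_id, src_name, rel,
#'   dst_ns, dst_id, dst_name`
#' @return object of class `ontology_graph`
#' @export
ontology_graph <- function(edges) {
  need <- c("src_ns", "src_id", "src_name", "rel", "dst_ns", "dst_id",
            "dst_name")
  if (!all(need %in% names(edges)))
    stop("ontology edge list must have columns: ", paste(need, collapse = ", "))
  if (!all(edges$rel %in% c("isa", "partof", "xref")))
    stop("unknown edge relation(s): ",
         paste(setdiff(unique(edges$rel), c("isa", "partof", "xref")),
               collapse = ", "))
  bad <- edges$rel == "xref" & edges$src_ns == edges$dst_ns
  if (any(bad)) stop("xref edges must connect distinct namespaces")

  nodes <- unique(rbind(
    data.frame(key = .node_key(edges$src_ns, edges$src_id),
               ns = edges$src_ns, id = edges$src_id, name = edges$src_name),
    data.frame(key = .node_key(edges$dst_ns, edges$dst_id),
               ns = edges$dst_ns, id = edges$dst_id, name = edges$dst_name)))
  nodes <- nodes[!duplicated(nodes$key), ]
  if (any(is.na(nodes$name) | !nzchar(nodes$name)))
    stop("every ontology node must have a name")

  g <- igraph::graph_from_data_frame(
    data.frame(from = .node_key(edges$src_ns, edges$src_id),
               to = .node_key(edges$dst_ns, edges$dst_id),
               rel = edges$rel),
    directed = TRUE,
    vertices = data.frame(key = nodes$key, ns = nodes$ns, id = nodes$id,
                          std_name = nodes$name))
  hier <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$rel %in% c("isa", "partof")],
    delete.vertices = FALSE)
  if (!igraph::is_dag(hier)) stop("isa/partof subgraph must be acyclic")

  structure(list(edges = edges, graph = g, nodes = nodes,
                 cache = new.env(parent = emptyenv())),
            class = "ontology_graph")
}

#' Read an ontology graph from a TSV edge list
#'
#' @param path TSV with columns `src_ns, src_id, src_name, rel, dst_ns,
#'   dst_id, dst_name` (header required)
#' @return an [ontology_graph()]
#' @export
read_ontology_tsv <- function(path) {
  ontology_graph(utils::read.delim(path, colClasses = "character"))
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(names(table(x$edges$rel)), table(x$edges$rel),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

.rel_subgraph <- function(og, rels) {
  key <- paste(rels, collapse = "+")
  if (is.null(og$cache[[key]]))
    og$cache[[key]] <- igraph::subgraph_from_edges(
      og$graph, igraph::E(og$graph)[igraph::E(og$graph)$rel %in% rels],
      delete.vertices = FALSE)
  og$cache[[key]]
}

.reachable <- function(sub, key) {
  if (!(key %in% igraph::V(sub)$name)) return(character(0))
  out <- igraph::subcomponent(sub, key, mode = "out")
  setdiff(names(out), key)
}

#' Ancestor closure of an ontology node
#'
#' All nodes reachable from `(ns, id)` via directed `isa` (and, by default,
#' `partof`) paths, excluding the node itself.
#'
#' @param ns,id namespace and identifier of the node
#' @param og an [ontology_graph()]
#' @param use_partof whether `partof` edges participate (default TRUE)
#' @return character vector of node keys (`"NS:ID"`)
#' @export
ancestor_closure <- function(ns, id, og, use_partof = TRUE) {
  rels <- if (use_partof) c("isa", "partof") else "isa"
  .reachable(.rel_subgraph(og, rels), .node_key(ns, id))
}

# Closure map for every node, cached: named list key -> ancestor keys.
.all_closures <- function(og, use_partof = TRUE) {
  ck <- paste0("clo_", use_partof)
  if (is.null(og$cache[[ck]])) {
    sub <- .rel_subgraph(og, if (use_partof) c("isa", "partof") else "isa")
    keys <- igraph::V(sub)$name
    eg <- igraph::ego(sub, order = igraph::vcount(sub), nodes = keys,
                      mode = "out")
    clo <- lapply(seq_along(keys), function(i)
      setdiff(names(eg[[i]]), keys[i]))
    names(clo) <- keys
    og$cache[[ck]] <- clo
  }
  og$cache[[ck]]
}

#' Look up the standard name of a node
#'
#' @param ns,id namespace and identifier
#' @param og an [ontology_graph()]
#' @return name, or `NA_character_` if the node is absent
#' @export
node_name <- function(ns, id, og) {
  i <- match(.node_key(ns, id), og$nodes$key)
  if (is.na(i)) NA_character_ else og$nodes$name[i]
}

#' Standardize a grounding set via xref traversal
#'
#' Follows all directed `xref` paths from each input grounding and returns
#' the union of groundings reached, together with the standard name of the
#' canonical grounding under the namespace priority. When two paths reach
#' the same namespace with different identifiers, the first identifier
#' reached in breadth-first order wins. Groundings absent from the graph
#' pass through unchanged.
#'
#' @param db_refs named character vector (namespace -> identifier)
#' @param og an [ontology_graph()]
#' @param namespace_priority ordered namespace preference
#' @return `list(db_refs = <named chr>, name = <chr or NA>)`
#' @export
standardize_grounding <- function(db_refs, og,
                                  namespace_priority = default_ns_priority()) {
  if (!length(db_refs))
    return(list(db_refs = db_refs, name = NA_character_))
  sub <- .rel_subgraph(og, "xref")
  refs <- db_refs
  for (ns in names(db_refs)) {
    key <- .node_key(ns, db_refs[[ns]])
    if (!(key %in% igraph::V(sub)$name)) next
    bfs <- igraph::bfs(sub, root = key, mode = "out", unreachable = FALSE,
                       order = TRUE)
    reached <- names(bfs$order)[!is.na(bfs$order)]
    for (k in reached) {
      i <- match(k, og$nodes$key)
      nsk <- og$nodes$ns[i]
      if (!(nsk %in% names(refs))) refs[[nsk]] <- og$nodes$id[i]
    }
  }
  # canonical name from the highest-priority grounding that is in the graph
  nm <- NA_character_
  ag0 <- agent("", db_refs = refs)
  cg <- canonical_grounding(ag0, namespace_priority)
  nm <- node_name(cg[1], cg[2], og)
  if (is.na(nm)) {
    for (ns in c(namespace_priority, sort(names(refs)))) {
      if (ns %in% names(refs)) {
        cand <- node_name(ns, refs[[ns]], og)
        if (!is.na(cand)) { nm <- cand; break }
      }
    }
  }
  list(db_refs = refs, name = nm)
}

#' Apply a grounding-override table to an agent
#'
#' The table maps raw entity text to a replacement grounding (or to the
#' explicit marker `"ungrounded"`, which empties the agent's groundings);
#' this is the disambiguation hook for ambiguous strings like "ER". After
#' any replacement the grounding set is standardized over the ontology.
#'
#' @param ag an [agent()]
#' @param raw_text the raw text the agent was extracted from
#' @param map data.frame with columns `raw_text, namespace, identifier`;
#'   `namespace == "ungrounded"` marks deliberate ungrounding
#' @param og an [ontology_graph()]
#' @param namespace_priority ordered namespace preference
#' @return the updated agent
#' @export
apply_grounding_overrides <- function(ag, raw_text, map, og,
                                      namespace_priority = default_ns_priority()) {
  if (!all(c("raw_text", "namespace", "identifier") %in% names(map)))
    stop("grounding map needs columns raw_text, namespace, identifier")
  i <- match(raw_text, map$raw_text)
  if (!is.na(i)) {
    if (identical(map$namespace[i], "ungrounded")) {
      ag$db_refs <- stats::setNames(character(0), character(0))
      return(ag)
    }
    ag$db_refs <- stats::setNames(as.character(map$identifier[i]),
                                  map$namespace[i])
  }
  std <- standardize_grounding(ag$db_refs, og, namespace_priority)
  ag$db_refs <- std$db_refs
  if (!is.na(std$name)) ag$name <- std$name
  ag
}

#' Entity-level refinement between two groundings
#'
#' `TRUE` iff the canonical groundings are equal, or `b` lies in the
#' isa/partof ancestor closure of `a` (i.e. `a` is a more specific entity),
#' or `b` is an unspecified slot (`NULL`) while `a` is specified.
#'
#' @param a,b [agent()] objects or `NULL` (unspecified slot)
#' @param og an [ontology_graph()]
#' @param namespace_priority ordered namespace preference
#' @param use_partof whether `partof` edges count toward specificity
#' @return logical scalar
#' @export
entity_refines <- function(a, b, og,
                           namespace_priority = default_ns_priority(),
                           use_partof = TRUE) {
  if (is.null(b)) return(!is.null(a))
  if (is.null(a)) return(FALSE)
  cga <- canonical_grounding(a, namespace_priority)
  cgb <- canonical_grounding(b, namespace_priority)
  ka <- .node_key(cga[1], cga[2]); kb <- .node_key(cgb[1], cgb[2])
  if (ka == kb) return(TRUE)
  kb %in% ancestor_closure(cga[1], cga[2], og, use_partof)
}
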