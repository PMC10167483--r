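#' @title Normalization and filter pipeline
#' @description Configurable filter/normalization stages applied to raw
#'   statement lists before assembly: epistemic filtering, grounding
#'   normalization, grounded/genes/human filters, and modification-site
#'   mapping, plus a driver that runs an ordered stage list with per-stage
#'   accounting.
#' @name pipeline
NULL

.nonnull_agents <- function(s) Filter(Negate(is.null), s$agents)

#' Remove hypothesis and negated evidence
#'
#' Drops evidences flagged as hypotheses (speculative phrasing) or negated
#' assertions; statements left without evidence are removed.
#'
#' @param stmts list of statements
#' @param drop_hypothesis,drop_negated which epistemic flags to honor
#' @return filtered statement list
#' @export
filter_no_hypothesis <- function(stmts, drop_hypothesis = TRUE,
                                 drop_negated = TRUE) {
  out <- lapply(stmts, function(s) {
    keep <- vapply(s$evidence, function(e) {
      !((drop_hypothesis && isTRUE(e$epistemics$hypothesis)) ||
          (drop_negated && isTRUE(e$epistemics$negated)))
    }, logical(1))
    s$evidence <- s$evidence[keep]
    s
  })
  Filter(function(s) length(s$evidence) > 0, out)
}

#' Keep only statements whose agents are all grounded
#'
#' An agent with no namespace identifiers beyond its text name is
#' ungrounded; statements with any ungrounded agent are removed. Unspecified
#' (absent) slots do not count as ungrounded.
#'
#' @param stmts list of statements
#' @return filtered statement list
#' @export
filter_grounded_only <- function(stmts) {
  Filter(function(s)
    all(vapply(.nonnull_agents(s), function(a) length(a$db_refs) > 0,
               logical(1))),
    stmts)
}

GENE_NAMESPACES <- c("HGNC", "UP", "FPLX")

#' Keep only statements whose agents are genes, proteins or families
#'
#' An agent counts as a gene/protein if it carries an HGNC, UP (UniProt) or
#' FPLX (family/complex) grounding; statements with any other kind of agent
#' (chemicals, processes, ...) are removed.
#'
#' @param stmts list of statements
#' @return filtered statement list
#' @export
filter_genes_only <- function(stmts) {
  Filter(function(s)
    all(vapply(.nonnull_agents(s), function(a)
      any(GENE_NAMESPACES %in% names(a$db_refs)), logical(1))),
    stmts)
}

#' Keep only statements about human genes (and families)
#'
#' Gene-level agents (HGNC/UP groundings) must appear in the supplied human
#' gene set; family/complex (FPLX) agents are retained, since families of
#' human genes are in scope.
#'
#' @param stmts list of statements
#' @param human_gene_set character vector of human gene node keys
#'   (`"HGNC:<id>"` / `"UP:<id>"`)
#' @return filtered statement list
#' @export
filter_human_only <- function(stmts, human_gene_set) {
  is_human <- function(a) {
    gns <- intersect(c("HGNC", "UP"), names(a$db_refs))
    if (!length(gns)) return(TRUE)          # family-level or non-gene agent
    any(.node_key(gns, a$db_refs[gns]) %in% human_gene_set)
  }
  Filter(function(s) all(vapply(.nonnull_agents(s), is_human, logical(1))),
         stmts)
}

#' Construct a site map
#'
#' A stand-in for reference-sequence site validation: each row classifies a
#' claimed (protein, residue, position) as `valid`, `mapped` (with
#' replacement coordinates) or `invalid`. Claimed sites not in the table are
#' treated as valid.
#'
#' @param df data.frame with columns `protein_key, residue, position,
#'   status` and, for `mapped` rows, `mapped_residue, mapped_position`
#' @return the validated data.frame, class `site_map`
#' @export
site_map <- function(df) {
  need <- c("protein_key", "residue", "position", "status")
  if (!all(need %in% names(df)))
    stop("site map needs columns: ", paste(need, collapse = ", "))
  if (!all(df$status %in% c("valid", "mapped", "invalid")))
    stop("site map status must be valid/mapped/invalid")
  m <- df$status == "mapped"
  if (any(m)) {
    if (!all(c("mapped_residue", "mapped_position") %in% names(df)))
      stop("mapped rows need mapped_residue and mapped_position")
    ok <- df$mapped_residue[m] %in% AA_CODES &
      !is.na(suppressWarnings(as.integer(df$mapped_position[m]))) &
      suppressWarnings(as.integer(df$mapped_position[m])) > 0
    if (!all(ok)) stop("mapped site targets must themselves be valid sites")
  }
  class(df) <- c("site_map", class(df))
  df
}

#' Read a site map from TSV
#' @param path TSV path with the [site_map()] columns
#' @return a `site_map`
#' @export
read_site_map_tsv <- function(path)
  site_map(utils::read.delim(path, colClasses = "character"))

.site_lookup <- function(sm, protein_key, residue, position) {
  i <- which(sm$protein_key == protein_key &
               sm$residue == residue & sm$position == position)
  if (!length(i)) return(list(status = "valid"))
  list(status = sm$status[i[1]],
       residue = if (sm$status[i[1]] == "mapped") sm$mapped_residue[i[1]],
       position = if (sm$status[i[1]] == "mapped") sm$mapped_position[i[1]])
}

#' Normalize modification sites and drop invalid ones
#'
#' For each modification site (statement-level residue/position of a
#' modification statement, keyed by the substrate agent, and agent-level
#' modification conditions): `valid` sites pass unchanged, `mapped` sites
#' have their coordinates overwritten, and any `invalid` site removes the
#' whole statement (non-reference positions are typically reading errors).
#' The fraction of site-bearing statements removed is attached as
#' `attr(, "site_report")`.
#'
#' @param stmts list of statements
#' @param sm a [site_map()]
#' @param namespace_priority ordered namespace preference for protein keys
#' @return filtered statement list with a `site_report` attribute
#' @export
map_and_filter_sites <- function(stmts, sm,
                                 namespace_priority = default_ns_priority()) {
  n_site_bearing <- 0L
  n_removed <- 0L
  out <- vector("list", length(stmts))
  keep <- logical(length(stmts))
  for (i in seq_along(stmts)) {
    s <- stmts[[i]]
    bad <- FALSE
    has_site <- FALSE
    info <- .stmt_type_info(s$type)
    if (isTRUE(info$is_modification) && !is.na(s$position)) {
      has_site <- TRUE
      sub <- s$agents[[2]]
      if (!is.null(sub)) {
        cg <- canonical_grounding(sub, namespace_priority)
        r <- .site_lookup(sm, .node_key(cg[1], cg[2]),
                          ifelse(is.na(s$residue), "", s$residue), s$position)
        if (r$status == "invalid") bad <- TRUE
        if (r$status == "mapped") {
          s$residue <- r$residue; s$position <- r$position
        }
      }
    }
    for (j in seq_along(s$agents)) {
      a <- s$agents[[j]]
      if (is.null(a) || !length(a$mods)) next
      cg <- canonical_grounding(a, namespace_priority)
      pk <- .node_key(cg[1], cg[2])
      for (k in seq_along(a$mods)) {
        m <- a$mods[[k]]
        if (is.na(m$position)) next
        has_site <- TRUE
        r <- .site_lookup(sm, pk, ifelse(is.na(m$residue), "", m$residue),
                          m$position)
        if (r$status == "invalid") bad <- TRUE
        if (r$status == "mapped") {
          a$mods[[k]]$residue <- r$residue
          a$mods[[k]]$position <- r$position
        }
      }
      s$agents[[j]] <- a
    }
    if (has_site) n_site_bearing <- n_site_bearing + 1L
    if (bad) n_removed <- n_removed + 1L
    keep[i] <- !bad
    out[[i]] <- s
  }
  res <- out[keep]
  attr(res, "site_report") <- list(
    n_site_bearing = n_site_bearing, n_removed = n_removed,
    fraction_removed = if (n_site_bearing) n_removed / n_site_bearing else 0)
  res
}

#' Apply grounding overrides to every agent of every statement
#'
#' Uses each agent's display name as the raw text looked up in the override
#' map, then standardizes groundings over the ontology (xref traversal and
#' canonical naming).
#'
#' @param stmts list of statements
#' @param og an [ontology_graph()]
#' @param gmap override table (see [apply_grounding_overrides()]); may be
#'   `NULL` for standardization only
#' @param namespace_priority ordered namespace preference
#' @return statement list with normalized agents
#' @export
map_grounding <- function(stmts, og, gmap = NULL,
                          namespace_priority = default_ns_priority()) {
  if (is.null(gmap))
    gmap <- data.frame(raw_text = character(), namespace = character(),
                       identifier = character())
  lapply(stmts, function(s) {
    s$agents <- lapply(s$agents, function(a) {
      if (is.null(a)) return(NULL)
      apply_grounding_overrides(a, a$name, gmap, og, namespace_priority)
    })
    s
  })
}

#' Default pipeline stage order
#' @return character vector of stage names
#' @export
default_pipeline_stages <- function()
  c("hypothesis", "grounding", "grounded", "genes", "human", "sites",
    "dedup")

#' Run the normalization/filter pipeline
#'
#' Applies an ordered list of named stages and records per-stage
#' input/output statement counts. Available stages: `hypothesis`,
#' `grounding`, `grounded`, `genes`, `human`, `sites`, `dedup`.
#'
#' @param stmts raw statement list
#' @param stages character vector of stage names (default
#'   [default_pipeline_stages()]); unknown names are a configuration error
#' @param ontology [ontology_graph()] (needed by `grounding`)
#' @param grounding_map override table for `grounding` (optional)
#' @param human_gene_set human gene keys for `human` (optional; stage is a
#'   no-op when `NULL`)
#' @param sitemap a [site_map()] for `sites` (optional; no-op when `NULL`)
#' @return `list(statements = <list>, report = <data.frame stage,n_in,
#'   n_out,n_removed>)`
#' @export
run_pipeline <- function(stmts, stages = default_pipeline_stages(),
                         ontology = NULL, grounding_map = NULL,
                         human_gene_set = NULL, sitemap = NULL) {
  known <- c("hypothesis", "grounding", "grounded", "genes", "human",
             "sites", "dedup")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  report <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer(), n_removed = integer())
  for (st in stages) {
    n_in <- length(stmts)
    stmts <- switch(st,
      hypothesis = filter_no_hypothesis(stmts),
      grounding = {
        if (is.null(ontology)) stop("stage 'grounding' requires an ontology")
        map_grounding(stmts, ontology, grounding_map)
      },
      grounded = filter_grounded_only(stmts),
      genes = filter_genes_only(stmts),
      human = if (is.null(human_gene_set)) stmts else
        filter_human_only(stmts, human_gene_set),
      sites = if (is.null(sitemap)) stmts else
        map_and_filter_sites(stmts, sitemap),
      dedup = combine_duplicates(stmts))
    attr(stmts, "site_report") <- NULL
    report <- rbind(report, data.frame(
      stage = st, n_in = n_in, n_out = length(stmts),
      n_removed = n_in - length(stmts)))
  }
  list(statements = stmts, report = report)
}
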