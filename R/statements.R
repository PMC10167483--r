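#' @title Mechanistic statement model
#' @description Constructors and core operations for typed mechanistic
#'   statements ("Statements"): entity agents with multi-namespace groundings
#'   and molecular state, evidence records with provenance, canonical
#'   equivalence keys, JSON round-tripping and English rendering.
#' @name statements
NULL

AA_CODES <- c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F","P",
              "S","T","W","Y","V")

# Extensible statement-type registry. The taxonomy is larger in the wild;
# these are the types exercised here, and register_statement_type() extends it.
.stmt_registry <- new.env(parent = emptyenv())

.default_stmt_types <- function() {
  rbind(
    data.frame(type = c("Phosphorylation", "Dephosphorylation",
                        "Ubiquitination", "Deubiquitination",
                        "Acetylation", "Methylation", "Sumoylation"),
               arity = 2L, is_modification = TRUE, unordered = FALSE),
    data.frame(type = c("Activation", "Inhibition",
                        "IncreaseAmount", "DecreaseAmount"),
               arity = 2L, is_modification = FALSE, unordered = FALSE),
    data.frame(type = "Complex", arity = NA_integer_,
               is_modification = FALSE, unordered = TRUE),
    data.frame(type = "ActiveForm", arity = 1L,
               is_modification = FALSE, unordered = FALSE)
  )
}

#' Table of registered statement types
#'
#' @return data.frame with columns `type`, `arity` (NA = variable, minimum 2),
#'   `is_modification`, `unordered`.
#' @export
statement_types <- function() {
  if (is.null(.stmt_registry$types)) .stmt_registry$types <- .default_stmt_types()
  .stmt_registry$types
}

#' Register an additional statement type
#'
#' @param type type name, e.g. "Glycosylation"
#' @param arity number of agent slots (NA for variable-arity, unordered types)
#' @param is_modification whether the type carries residue/position arguments
#' @param unordered whether agent order is irrelevant (Complex-like)
#' @export
register_statement_type <- function(type, arity = 2L, is_modification = FALSE,
                                    unordered = FALSE) {
  tab <- statement_types()
  tab <- tab[tab$type != type, ]
  .stmt_registry$types <- rbind(tab, data.frame(
    type = type, arity = as.integer(arity),
    is_modification = is_modification, unordered = unordered))
  invisible(.stmt_registry$types)
}

.stmt_type_info <- function(type) {
  tab <- statement_types()
  i <- match(type, tab$type)
  if (is.na(i)) stop("unknown statement type: ", type)
  tab[i, ]
}

#' Modification-state condition on an agent
#'
#' @param mod_type modification kind (e.g. "phosphorylation")
#' @param residue optional one-letter amino-acid code
#' @param position optional positive-integer position (stored as string)
#' @param is_modified whether the state asserts presence of the modification
#' @return an object of class `mod_condition`
#' @export
mod_condition <- function(mod_type, residue = NA_character_,
                          position = NA_character_, is_modified = TRUE) {
  residue <- as.character(residue)
  position <- as.character(position)
  if (!is.na(residue) && !(residue %in% AA_CODES))
    stop("invalid amino-acid residue: ", residue)
  if (!is.na(position) &&
      (is.na(suppressWarnings(as.integer(position))) || as.integer(position) <= 0))
    stop("position must parse as a positive integer: ", position)
  structure(list(mod_type = mod_type, residue = residue,
                 position = position, is_modified = isTRUE(is_modified)),
            class = "mod_condition")
}

#' Biological entity participant in a statement
#'
#' Groundings are namespace/identifier pairs (`db_refs`), at most one
#' identifier per namespace; an agent with none is "ungrounded". Bound
#' conditions nest one level only: a bound agent carries no bound conditions
#' of its own.
#'
#' @param name display string
#' @param db_refs named character vector of groundings
#'   (e.g. `c(HGNC = "6840")`); names are namespaces
#' @param mods list of [mod_condition()] objects
#' @param mutations list of `list(from_residue, position, to_residue)`
#' @param activity optional `list(activity_type =, is_active =)`
#' @param bound_conditions list of `list(agent =, is_bound =)`
#' @param location optional cellular-compartment identifier
#' @return object of class `agent`
#' @export
agent <- function(name, db_refs = character(), mods = list(),
                  mutations = list(), activity = NULL,
                  bound_conditions = list(), location = NA_character_) {
  db_refs <- unlist(db_refs)
  if (length(db_refs)) {
    db_refs <- vapply(db_refs, as.character, character(1))
    if (is.null(names(db_refs)) || any(!nzchar(names(db_refs))))
      stop("db_refs must be a named vector (namespace -> identifier)")
    if (anyDuplicated(names(db_refs)))
      stop("duplicate namespace in db_refs for agent ", name)
  } else db_refs <- stats::setNames(character(0), character(0))
  mods <- lapply(mods, function(m)
    if (inherits(m, "mod_condition")) m else do.call(mod_condition, m))
  for (bc in bound_conditions) {
    if (!inherits(bc$agent, "agent")) stop("bound condition must carry an agent")
    if (length(bc$agent$bound_conditions))
      stop("bound agents may not carry bound conditions themselves")
  }
  mutations <- lapply(mutations, function(m)
    list(from_residue = as.character(m[[1]]), position = as.character(m[[2]]),
         to_residue = as.character(m[[3]])))
  structure(list(name = as.character(name), db_refs = db_refs, mods = mods,
                 mutations = mutations, activity = activity,
                 bound_conditions = bound_conditions,
                 location = as.character(location)),
            class = "agent")
}

#' A single extraction (mention) or database record supporting a statement
#'
#' @param source_api source name (reader or database identifier); required
#' @param pmid optional publication identifier
#' @param text optional sentence string
#' @param source_id optional source record identifier
#' @param hypothesis,negated epistemic flags
#' @param annotations free-form key-value list
#' @return object of class `evidence`
#' @export
evidence <- function(source_api, pmid = NA_character_, text = NA_character_,
                     source_id = NA_character_, hypothesis = FALSE,
                     negated = FALSE, annotations = list()) {
  if (!nzchar(source_api)) stop("source_api must be non-empty")
  structure(list(source_api = as.character(source_api),
                 pmid = as.character(pmid), text = as.character(text),
                 source_id = as.character(source_id),
                 epistemics = list(hypothesis = isTRUE(hypothesis),
                                   negated = isTRUE(negated)),
                 annotations = annotations),
            class = "evidence")
}

#' Identity key of an evidence record
#'
#' Two evidences are the same extraction iff source, publication, sentence
#' and record id all agree; the same sentence read by two systems remains two
#' evidences.
#'
#' @param ev an [evidence()] object
#' @return scalar character key
#' @export
evidence_key <- function(ev) {
  f <- function(x) if (is.na(x)) "" else x
  paste(f(ev$source_api), f(ev$pmid), f(ev$text), f(ev$source_id),
        sep = "\x1f")
}

#' A typed mechanistic statement
#'
#' @param type statement type (see [statement_types()])
#' @param agents ordered list of [agent()] objects; `NULL` entries are
#'   explicit unspecified slots (e.g. an unknown enzyme). `Complex` takes an
#'   unordered member list of length >= 2 with no `NULL`s.
#' @param residue,position optional modification site (modification types
#'   only)
#' @param evidence list of [evidence()] objects
#' @param belief optional reliability score in `[0, 1]`
#' @return object of class `statement`
#' @export
statement <- function(type, agents, residue = NA_character_,
                      position = NA_character_, evidence = list(),
                      belief = NULL) {
  info <- .stmt_type_info(type)
  if (is.na(info$arity)) {
    if (length(agents) < 2) stop(type, " requires at least 2 members")
    if (any(vapply(agents, is.null, logical(1))))
      stop(type, " members must all be specified")
  } else if (length(agents) != info$arity) {
    stop(type, " takes ", info$arity, " agent slots, got ", length(agents))
  }
  for (a in agents) if (!is.null(a) && !inherits(a, "agent"))
    stop("agents must be agent objects or NULL")
  residue <- as.character(residue)
  position <- as.character(position)
  if (!info$is_modification && (!is.na(residue) || !is.na(position)))
    stop("residue/position only apply to modification statements")
  if (!is.na(residue) && !(residue %in% AA_CODES))
    stop("invalid residue: ", residue)
  if (!is.null(belief) && (belief < 0 || belief > 1))
    stop("belief must lie in [0, 1]")
  structure(list(type = type, agents = agents, residue = residue,
                 position = position, evidence = evidence, belief = belief),
            class = "statement")
}

# ---- canonical grounding and equivalence keys -------------------------------

#' Default namespace priority for canonical grounding
#'
#' Families (FPLX) out-rank member namespaces so family-level agents
#' canonicalize stably; a bare name is the fallback when no grounding exists.
#' @return character vector of namespaces, most preferred first
#' @export
default_ns_priority <- function() c("FPLX", "HGNC", "UP", "CHEBI", "GO", "MESH")

#' Canonical grounding of an agent
#'
#' @param ag an [agent()]
#' @param namespace_priority ordered namespace preference
#' @return `c(namespace, identifier)`; namespace is `"NAME"` with the display
#'   name as identifier when the agent is ungrounded
#' @export
canonical_grounding <- function(ag, namespace_priority = default_ns_priority()) {
  for (ns in namespace_priority)
    if (ns %in% names(ag$db_refs)) return(c(ns, unname(ag$db_refs[[ns]])))
  if (length(ag$db_refs)) {
    ns <- sort(names(ag$db_refs))[1]
    return(c(ns, unname(ag$db_refs[[ns]])))
  }
  c("NAME", ag$name)
}

.mod_key <- function(m)
  paste(m$mod_type, ifelse(is.na(m$residue), "", m$residue),
        ifelse(is.na(m$position), "", m$position),
        if (m$is_modified) "1" else "0", sep = ",")

.agent_key <- function(ag, namespace_priority) {
  if (is.null(ag)) return("~")
  cg <- canonical_grounding(ag, namespace_priority)
  mods <- sort(vapply(ag$mods, .mod_key, character(1)))
  muts <- sort(vapply(ag$mutations, function(m)
    paste(m$from_residue, m$position, m$to_residue, sep = ","), character(1)))
  act <- if (is.null(ag$activity)) "" else
    paste(ag$activity$activity_type, as.integer(isTRUE(ag$activity$is_active)),
          sep = ",")
  bcs <- sort(vapply(ag$bound_conditions, function(bc)
    paste0(.agent_key(bc$agent, namespace_priority), "@",
           as.integer(isTRUE(bc$is_bound))), character(1)))
  loc <- if (is.na(ag$location)) "" else ag$location
  paste(paste0(cg[1], ":", cg[2]),
        paste(mods, collapse = "+"), paste(muts, collapse = "+"),
        act, paste(bcs, collapse = "+"), loc, sep = "|")
}

#' Canonical equivalence key of a statement
#'
#' A deterministic string over (i) the statement type, (ii) each agent's
#' canonical grounding under the namespace priority (name fallback), (iii)
#' all agent states and (iv) all other statement arguments. Equal keys
#' identify duplicate statements; evidence never enters the key, and Complex
#' member order is irrelevant.
#'
#' @param stmt a [statement()]
#' @param namespace_priority ordered namespace preference
#' @return scalar character key
#' @export
matches_key <- function(stmt, namespace_priority = default_ns_priority()) {
  info <- .stmt_type_info(stmt$type)
  aks <- vapply(stmt$agents, .agent_key, character(1),
                namespace_priority = namespace_priority)
  if (info$unordered) aks <- sort(aks)
  paste(stmt$type, paste(aks, collapse = ";"),
        ifelse(is.na(stmt$residue), "", stmt$residue),
        ifelse(is.na(stmt$position), "", stmt$position), sep = "#")
}

# ---- JSON serialization -----------------------------------------------------

.agent_to_list <- function(ag) {
  if (is.null(ag)) return(NULL)
  list(
    name = ag$name,
    db_refs = as.list(ag$db_refs),
    mods = lapply(ag$mods, function(m) list(
      mod_type = m$mod_type, residue = m$residue, position = m$position,
      is_modified = m$is_modified)),
    mutations = ag$mutations,
    activity = ag$activity,
    bound_conditions = lapply(ag$bound_conditions, function(bc) list(
      agent = .agent_to_list(bc$agent), is_bound = isTRUE(bc$is_bound))),
    location = ag$location)
}

.stmt_to_list <- function(s) {
  list(type = s$type,
       agents = lapply(s$agents, .agent_to_list),
       residue = s$residue, position = s$position,
       evidence = lapply(s$evidence, function(e) list(
         source_api = e$source_api, pmid = e$pmid, text = e$text,
         source_id = e$source_id, epistemics = e$epistemics,
         annotations = e$annotations)),
       belief = s$belief)
}

.chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)

.agent_from_list <- function(x, where) {
  if (is.null(x)) return(NULL)
  if (is.null(x$name)) stop("JSON parse error: missing field 'name' in ", where)
  agent(name = x$name,
        db_refs = unlist(x$db_refs),
        mods = lapply(x$mods, function(m) mod_condition(
          m$mod_type, .chr1(m$residue), .chr1(m$position),
          isTRUE(m$is_modified))),
        mutations = x$mutations,
        activity = x$activity,
        bound_conditions = lapply(x$bound_conditions, function(bc) list(
          agent = .agent_from_list(bc$agent, where),
          is_bound = isTRUE(bc$is_bound))),
        location = .chr1(x$location))
}

.stmt_from_list <- function(x, i) {
  where <- paste0("statement ", i)
  if (is.null(x$type))
    stop("JSON parse error: missing field 'type' in ", where)
  statement(
    type = x$type,
    agents = lapply(x$agents, .agent_from_list, where = where),
    residue = .chr1(x$residue), position = .chr1(x$position),
    evidence = lapply(x$evidence, function(e) {
      if (is.null(e$source_api))
        stop("JSON parse error: missing field 'source_api' in ", where)
      evidence(e$source_api, .chr1(e$pmid), .chr1(e$text), .chr1(e$source_id),
               hypothesis = isTRUE(e$epistemics$hypothesis),
               negated = isTRUE(e$epistemics$negated),
               annotations = if (is.null(e$annotations)) list() else e$annotations)
    }),
    belief = x$belief)
}

#' Serialize statements to JSON
#'
#' @param stmts list of [statement()] objects
#' @return JSON text (character scalar)
#' @export
statements_to_json <- function(stmts) {
  as.character(jsonlite::toJSON(lapply(stmts, .stmt_to_list),
                                auto_unbox = TRUE, null = "null",
                                na = "null", digits = NA))
}

#' Parse statements from JSON
#'
#' Inverse of [statements_to_json()]; `from_json(to_json(x))` reproduces `x`
#' exactly. Schema violations raise an error naming the offending field.
#'
#' @param txt JSON text or a file path to it
#' @return list of [statement()] objects
#' @export
statements_from_json <- function(txt) {
  raw <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  lapply(seq_along(raw), function(i) .stmt_from_list(raw[[i]], i))
}

# ---- rendering --------------------------------------------------------------

.site_phrase <- function(residue, position) {
  if (is.na(residue) && is.na(position)) return("")
  paste0(" on ", ifelse(is.na(residue), "", residue),
         ifelse(is.na(position), "", position))
}

#' Render a statement as an English sentence
#'
#' Deterministic template rendering for display, e.g.
#' `"MAP2K1 phosphorylates MAPK1 on T185"`.
#'
#' @param stmt a [statement()]
#' @return character scalar
#' @export
render_english <- function(stmt) {
  info <- .stmt_type_info(stmt$type)
  nm <- function(a) if (is.null(a)) NA_character_ else a$name
  if (stmt$type == "Complex") {
    members <- vapply(stmt$agents, nm, character(1))
    return(paste(members[1], "binds",
                 paste(members[-1], collapse = " and ")))
  }
  if (isTRUE(info$is_modification)) {
    verb <- sub("ation$", "ates", tolower(stmt$type))
    site <- .site_phrase(stmt$residue, stmt$position)
    subj <- nm(stmt$agents[[1]]); obj <- nm(stmt$agents[[2]])
    if (is.na(subj))
      return(paste0(obj, " is ", sub("ation$", "ated", tolower(stmt$type)),
                    site))
    return(paste0(subj, " ", verb, " ", obj, site))
  }
  if (stmt$type == "ActiveForm") {
    a <- stmt$agents[[1]]
    state <- if (!is.null(a$activity) && !isTRUE(a$activity$is_active))
      "inactive" else "active"
    return(paste(a$name, "is", state))
  }
  verbs <- c(Activation = "activates", Inhibition = "inhibits",
             IncreaseAmount = "increases the amount of",
             DecreaseAmount = "decreases the amount of")
  v <- verbs[[stmt$type]]
  if (is.null(v)) v <- tolower(stmt$type)
  paste(nm(stmt$agents[[1]]), v, nm(stmt$agents[[2]]))
}

#' @export
print.statement <- function(x, ...) {
  cat(sprintf("<statement> %s  [%d evidence%s]%s\n", render_english(x),
              length(x$evidence), if (length(x$evidence) == 1) "" else "s",
              if (!is.null(x$belief))
                sprintf("  belief=%.3f", x$belief) else ""))
  invisible(x)
}

#' @export
print.agent <- function(x, ...) {
  g <- canonical_grounding(x)
  cat(sprintf("<agent> %s (%s:%s)\n", x$name, g[1], g[2]))
  invisible(x)
}

# ---- curation records -------------------------------------------------------

#' Build a curation table
#'
#' One row per curated (statement, evidence, curator) triple. When multiple
#' curators label the same evidence, [resolve_curations()] collapses to one
#' label per evidence.
#'
#' @param statement_key statement equivalence keys
#' @param evidence_key evidence identity keys
#' @param label `"correct"` or `"incorrect"`
#' @param curator curator identifier
#' @return data.frame of class `curation_table`
#' @export
curation_table <- function(statement_key, evidence_key, label, curator) {
  stopifnot(all(label %in% c("correct", "incorrect")))
  df <- data.frame(statement_key = statement_key, evidence_key = evidence_key,
                   label = label, curator = curator)
  if (anyDuplicated(df[c("statement_key", "evidence_key", "curator")]))
    stop("one label per (statement, evidence, curator) allowed")
  class(df) <- c("curation_table", class(df))
  df
}

#' Collapse multi-curator labels to one label per evidence
#'
#' Conflicting labels resolve to `"correct"` if any curator marked the
#' evidence correct (mirroring the at-least-one-correct statement rule);
#' conflicts are reported via message.
#'
#' @param cur a [curation_table()]
#' @return data.frame with one row per (statement_key, evidence_key)
#' @export
resolve_curations <- function(cur) {
  key <- paste(cur$statement_key, cur$evidence_key, sep = "\x1f")
  sp <- split(seq_len(nrow(cur)), key)
  rows <- lapply(sp, function(idx) {
    labs <- unique(cur$label[idx])
    if (length(labs) > 1)
      message("conflicting curations for evidence of statement ",
              cur$statement_key[idx[1]], "; resolving to 'correct'")
    data.frame(statement_key = cur$statement_key[idx[1]],
               evidence_key = cur$evidence_key[idx[1]],
               label = if ("correct" %in% labs) "correct" else "incorrect")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Statement-level correctness from evidence-level labels
#'
#' A statement is correct if supported by at least one correctly extracted
#' mention; if every curated mention is incorrect, the statement is
#' incorrect (incomplete curation permitted). No curations gives `NA`.
#'
#' @param labels character vector of `"correct"`/`"incorrect"` labels for one
#'   statement's curated evidences
#' @return logical scalar (or NA)
#' @export
statement_correct <- function(labels) {
  if (!length(labels)) return(NA)
  any(labels == "correct")
}
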