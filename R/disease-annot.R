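# Disease tagging and propagation. A disease term attached to a physical
# entity is assigned to every reaction the entity participates in, to every
# pathway containing such a reaction, and transitively to parent pathways.

#' Tag a pathway entity with a disease term
#'
#' Adds a [disease_term()] to an entity's disease set (set semantics:
#' tagging twice is a no-op).
#'
#' @param graph a [pathway_graph()].
#' @param entity_id entity node id.
#' @param term a [disease_term()].
#' @return The updated [pathway_graph()].
#' @export
#' @examples
#' g <- pathway_graph(entities = list(list(id = "egfrviii", name = "EGFRvIII")))
#' g <- tag_entity(g, "egfrviii", disease_term(3075, "adult glioblastoma multiforme"))
#' entity_diseases(g, "egfrviii")[[1]]$do_id  # 3075
tag_entity <- function(graph, entity_id, term) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(term, "disease_term"))
  if (!entity_id %in% names(graph$entities))
    stop("unknown entity id '", entity_id, "'")
  ent <- graph$entities[[entity_id]]
  ent$diseases <- union_terms(ent$diseases, list(term))
  graph$entities[[entity_id]] <- ent
  graph
}

#' @rdname tag_entity
#' @export
entity_diseases <- function(graph, entity_id) {
  if (!entity_id %in% names(graph$entities))
    stop("unknown entity id '", entity_id, "'")
  graph$entities[[entity_id]]$diseases
}

#' Propagate disease tags from entities to events and pathways
#'
#' Every event whose inputs, outputs or catalysts include a disease-tagged
#' entity receives the union of those terms; every pathway containing a
#' tagged event receives them, transitively up the pathway-containment tree.
#' No tags are ever removed, so propagation is monotone, and it is
#' idempotent: a second run is a no-op.
#'
#' @param graph a [pathway_graph()].
#' @return The updated [pathway_graph()].
#' @export
propagate_disease <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  for (eid in names(graph$events)) {
    ev <- graph$events[[eid]]
    for (pid in event_participants(ev)) {
      ev$diseases <- union_terms(ev$diseases,
                                 graph$entities[[pid]]$diseases)
    }
    graph$events[[eid]] <- ev
  }
  for (pid in names(graph$pathways)) {
    pw <- graph$pathways[[pid]]
    for (eid in pw$events)
      pw$diseases <- union_terms(pw$diseases, graph$events[[eid]]$diseases)
    graph$pathways[[pid]] <- pw
  }
  # transitive closure up the containment tree; loop bounded by depth
  repeat {
    changed <- FALSE
    for (pid in names(graph$pathways)) {
      pw <- graph$pathways[[pid]]
      if (is.na(pw$parent)) next
      parent <- graph$pathways[[pw$parent]]
      before <- length(parent$diseases)
      parent$diseases <- union_terms(parent$diseases, pw$diseases)
      if (length(parent$diseases) != before) {
        graph$pathways[[pw$parent]] <- parent
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  graph
}

#' @rdname tag_entity
#' @param node_id an event or pathway id.
#' @export
node_diseases <- function(graph, node_id) {
  if (node_id %in% names(graph$entities))
    return(graph$entities[[node_id]]$diseases)
  if (node_id %in% names(graph$events))
    return(graph$events[[node_id]]$diseases %||% list())
  if (node_id %in% names(graph$pathways))
    return(graph$pathways[[node_id]]$diseases %||% list())
  stop("unknown node id '", node_id, "'")
}

#' Query variant records by disease
#'
#' Returns the sorted set of gene symbols whose `disease` field matches the
#' query, using case-insensitive substring matching over the
#' `";"`-normalized disease list. Substring matching tolerates granularity
#' differences between free-text disease names.
#'
#' @param records variant record data frame ([read_variant_table()]).
#' @param term_text disease text to search for, e.g. `"glioblastoma"`.
#' @return Sorted character vector of gene symbols (possibly empty).
#' @export
#' @examples
#' \dontrun{
#' query_by_disease(read_variant_table(), "rhabdomyosarcoma")  # "FGFR4"
#' }
query_by_disease <- function(records, term_text) {
  stopifnot(is.data.frame(records), is.character(term_text))
  hit <- grepl(tolower(term_text), tolower(records$disease), fixed = TRUE)
  sort(unique(records$gene[hit]))
}

#' Resolve database cross-references of a record
#'
#' Emits the opaque cross-reference pairs carried by a [variant_entity()], a
#' variant record row, or a [therapeutic()]: COSMIC mutation ids, Disease
#' Ontology (and NCIt) ids, and reference molecule ids. Identifiers are
#' opaque; no lookups are performed.
#'
#' @param x a [variant_entity()], a one-row variant record data frame, or a
#'   [therapeutic()].
#' @return Data frame with columns `database` and `identifier` (zero rows
#'   when there are no cross-references).
#' @export
resolve_xrefs <- function(x) {
  pairs <- list()
  add <- function(db, id) pairs[[length(pairs) + 1L]] <<- c(db, id)
  if (inherits(x, "variant_entity")) {
    for (id in x$cosmic_ids) add("COSMIC", id)
    for (t in x$diseases) {
      add("DO", as.character(t$do_id))
      if (!is.na(t$ncit_xref) && nzchar(t$ncit_xref)) add("NCIt", t$ncit_xref)
    }
  } else if (inherits(x, "therapeutic")) {
    if (!x$reference_id %in% c("", "Pending", "Recombinant antibody"))
      add("reference", x$reference_id)
  } else if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    ids <- x$cosmic_ids[[1]]
    for (id in ids) add("COSMIC", id)
    if ("do_terms" %in% names(x))
      for (t in x$do_terms[[1]]) add("DO", as.character(t$do_id))
  } else {
    stop("cannot resolve cross-references for objects of class ",
         paste(class(x), collapse = "/"))
  }
  if (length(pairs) == 0L)
    return(data.frame(database = character(), identifier = character(),
                      stringsAsFactors = FALSE))
  data.frame(database = vapply(pairs, `[[`, character(1), 1L),
             identifier = vapply(pairs, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Load the bundled disease-term mapping
#'
#' Maps free-text disease atoms from the variant corpus to Disease Ontology
#' terms for the handful of diseases used in worked examples. The mapping is
#' curator-supplied; identifiers are opaque.
#'
#' @param path TSV path; defaults to the bundled file.
#' @return Data frame with columns `atom`, `do_id`, `name`, `ncit_xref`.
#' @export
load_disease_terms <- function(path = system.file("extdata",
                                                  "disease_terms.tsv",
                                                  package = "pathvar")) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, fill = TRUE,
                          colClasses = "character")
  if (!"ncit_xref" %in% names(df)) df$ncit_xref <- NA_character_
  df$ncit_xref[is.na(df$ncit_xref) | df$ncit_xref == ""] <- NA_character_
  df
}

#' Match disease-text atoms to Disease Ontology terms
#'
#' @param disease_text `";"`-separated disease atoms (a variant record's
#'   `disease` field).
#' @param terms disease-term mapping ([load_disease_terms()]).
#' @return List of [disease_term()]s for atoms with a mapping (set
#'   semantics); unmapped atoms are skipped.
#' @export
match_disease_terms <- function(disease_text, terms = load_disease_terms()) {
  atoms <- tolower(trimws(strsplit(disease_text, ";", fixed = TRUE)[[1]]))
  out <- list()
  for (i in seq_len(nrow(terms))) {
    if (any(grepl(terms$atom[i], atoms, fixed = TRUE))) {
      nc <- terms$ncit_xref[i]
      out[[length(out) + 1L]] <- disease_term(
        as.integer(terms$do_id[i]), terms$name[i],
        ncit_xref = if (is.na(nc) || !nzchar(nc)) NA_character_ else nc)
    }
  }
  union_terms(list(), out)
}
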