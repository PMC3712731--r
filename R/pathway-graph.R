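# Pathway graphs: physical entities converted by reaction events, grouped
# into (possibly nested) pathways. Stored as plain lists keyed by id and
# serialized in a small JSON dialect.

#' Pathway graph
#'
#' A reaction-centric pathway model: `entities` are physical-entity nodes,
#' `events` are reactions with input/output/catalyst entity-id lists, and
#' `pathways` group event ids and may nest via a `parent` pathway id. Both
#' entities and events may carry [disease_term()] tags. Construction checks
#' that every event participant resolves to an entity node and that pathway
#' containment is acyclic.
#'
#' @param entities list of entity nodes, each a list with `id`, `name` and
#'   optional `diseases` (list of [disease_term()]).
#' @param events list of event nodes, each with `id`, `name`, `inputs`,
#'   `outputs`, `catalysts` (character vectors of entity ids) and optional
#'   `diseases`.
#' @param pathways list of pathway groupings, each with `id`, `name`,
#'   `events` (character vector of event ids) and optional `parent`
#'   (pathway id or `NA`).
#' @return An object of class `pathway_graph` with entities/events/pathways
#'   stored as named lists keyed by id.
#' @export
#' @examples
#' g <- pathway_graph(
#'   entities = list(list(id = "egfr", name = "EGFR")),
#'   events = list(list(id = "r1", name = "EGFR autophosphorylation",
#'                      inputs = "egfr", outputs = "egfr")),
#'   pathways = list(list(id = "p1", name = "Signaling by EGFR",
#'                        events = "r1")))
pathway_graph <- function(entities = list(), events = list(),
                          pathways = list()) {
  norm_terms <- function(x) {
    x <- x %||% list()
    lapply(x, function(t) if (inherits(t, "disease_term")) t
           else disease_term(t$do_id, t$name,
                             if (is.null(t$ncit_xref)) NA_character_ else t$ncit_xref))
  }
  norm_node <- function(n, kind) {
    if (is.null(n$id) || !nzchar(n$id)) stop(kind, " node without an id")
    n$name <- n$name %||% n$id
    n$diseases <- norm_terms(n$diseases)
    if (kind == "event") {
      n$inputs <- as.character(n$inputs %||% character())
      n$outputs <- as.character(n$outputs %||% character())
      n$catalysts <- as.character(n$catalysts %||% character())
    }
    if (kind == "pathway") {
      n$events <- as.character(n$events %||% character())
      n$parent <- if (is.null(n$parent) || is.na(n$parent) || !nzchar(n$parent))
        NA_character_ else as.character(n$parent)
    }
    n
  }
  entities <- lapply(entities, norm_node, kind = "entity")
  events <- lapply(events, norm_node, kind = "event")
  pathways <- lapply(pathways, norm_node, kind = "pathway")
  names(entities) <- vapply(entities, `[[`, character(1), "id")
  names(events) <- vapply(events, `[[`, character(1), "id")
  names(pathways) <- vapply(pathways, `[[`, character(1), "id")
  if (anyDuplicated(names(entities)) || anyDuplicated(names(events)) ||
      anyDuplicated(names(pathways)))
    stop("duplicate node ids in pathway graph")
  g <- structure(list(entities = entities, events = events,
                      pathways = pathways), class = "pathway_graph")
  for (ev in events) {
    missing <- setdiff(event_participants(ev), names(entities))
    if (length(missing))
      stop("event '", ev$id, "' references unknown entities: ",
           paste(missing, collapse = ", "))
  }
  for (pw in pathways) {
    missing <- setdiff(pw$events, names(events))
    if (length(missing))
      stop("pathway '", pw$id, "' references unknown events: ",
           paste(missing, collapse = ", "))
    bad_parent <- !is.na(pw$parent) && !pw$parent %in% names(pathways)
    if (bad_parent)
      stop("pathway '", pw$id, "' has unknown parent '", pw$parent, "'")
  }
  check_containment_acyclic(g)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

event_participants <- function(ev) unique(c(ev$inputs, ev$outputs, ev$catalysts))

check_containment_acyclic <- function(graph) {
  for (id in names(graph$pathways)) {
    seen <- character()
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop("pathway containment cycle involving '", cur, "'")
      seen <- c(seen, cur)
      cur <- graph$pathways[[cur]]$parent
    }
  }
  invisible(TRUE)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", length(x$entities), " entities, ",
      length(x$events), " events, ", length(x$pathways), " pathways\n",
      sep = "")
  invisible(x)
}

graph_node_ids <- function(graph) c(names(graph$entities), names(graph$events))

# ---- JSON dialect ----------------------------------------------------------

graph_to_list <- function(graph) {
  terms_out <- function(terms) lapply(terms, function(t)
    list(do_id = t$do_id, name = t$name, ncit_xref = t$ncit_xref))
  list(
    entities = unname(lapply(graph$entities, function(n)
      list(id = n$id, name = n$name, diseases = terms_out(n$diseases)))),
    events = unname(lapply(graph$events, function(n)
      list(id = n$id, name = n$name, inputs = as.list(n$inputs),
           outputs = as.list(n$outputs), catalysts = as.list(n$catalysts),
           diseases = terms_out(n$diseases)))),
    pathways = unname(lapply(graph$pathways, function(n)
      list(id = n$id, name = n$name, events = as.list(n$events),
           parent = n$parent, diseases = terms_out(n$diseases))))
  )
}

graph_from_list <- function(x) {
  as_chr <- function(v) vapply(v, as.character, character(1))
  fix <- function(n, kind) {
    if (kind == "event") {
      n$inputs <- as_chr(n$inputs %||% list())
      n$outputs <- as_chr(n$outputs %||% list())
      n$catalysts <- as_chr(n$catalysts %||% list())
    }
    if (kind == "pathway") {
      n$events <- as_chr(n$events %||% list())
      if (is.null(n$parent)) n$parent <- NA_character_
    }
    n
  }
  pathway_graph(
    entities = lapply(x$entities %||% list(), fix, kind = "entity"),
    events = lapply(x$events %||% list(), fix, kind = "event"),
    pathways = lapply(x$pathways %||% list(), fix, kind = "pathway"))
}

#' Read and write pathway graphs as JSON
#'
#' @param graph a [pathway_graph()].
#' @param path file path.
#' @return `read_pathway_graph()` returns a [pathway_graph()];
#'   `write_pathway_graph()` returns `path` invisibly.
#' @export
write_pathway_graph <- function(graph, path) {
  jsonlite::write_json(graph_to_list(graph), path, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pathway_graph
#' @export
read_pathway_graph <- function(path) {
  graph_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
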