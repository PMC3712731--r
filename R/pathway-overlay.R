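# Render-state semantics for a pathway diagram shared between a wild-type
# pathway and its disease counterpart. States are abstract enums; no
# graphics are produced.

.view_states <- c("visible", "hidden", "faded", "disease_highlighted")

#' Compute the render state of every diagram node
#'
#' The diagram nodes are the graph's physical entities and events
#' (pathway groupings organize events but are not drawn as nodes).
#' [propagate_disease()] must have been applied first so that events carry
#' the tags of their participants.
#'
#' In `wild_type` mode, disease-tagged events are hidden, together with
#' entities that appear *only* in disease-tagged events; everything else is
#' visible. An entity shared between normal and disease events therefore
#' stays visible, as does an entity participating in no event at all.
#'
#' In `disease` mode, disease-tagged events and disease-tagged entities are
#' `disease_highlighted` (the red-outline flag of the diseased diagram) and
#' all untagged nodes are `faded` (the gray shading of normal events).
#'
#' @param graph a [pathway_graph()] after [propagate_disease()].
#' @param mode `"wild_type"` or `"disease"`.
#' @return An object of class `view_state`: a named character vector mapping
#'   every node id to one of `visible`, `hidden`, `faded`,
#'   `disease_highlighted`.
#' @export
compute_view <- function(graph, mode = c("wild_type", "disease")) {
  stopifnot(inherits(graph, "pathway_graph"))
  mode <- match.arg(mode)
  has_disease <- function(n) length(n$diseases %||% list()) > 0L
  ev_tagged <- vapply(graph$events, has_disease, logical(1))
  ent_tagged <- vapply(graph$entities, has_disease, logical(1))

  # events each entity participates in
  ent_events <- lapply(graph$entities, function(e) character())
  for (ev in graph$events)
    for (pid in event_participants(ev))
      ent_events[[pid]] <- c(ent_events[[pid]], ev$id)

  states <- character()
  if (mode == "wild_type") {
    for (id in names(graph$events))
      states[[id]] <- if (ev_tagged[[id]]) "hidden" else "visible"
    for (id in names(graph$entities)) {
      evs <- ent_events[[id]]
      disease_only <- length(evs) > 0L && all(ev_tagged[evs])
      states[[id]] <- if (disease_only) "hidden" else "visible"
    }
  } else {
    for (id in names(graph$events))
      states[[id]] <- if (ev_tagged[[id]]) "disease_highlighted" else "faded"
    for (id in names(graph$entities))
      states[[id]] <- if (ent_tagged[[id]]) "disease_highlighted" else "faded"
  }
  structure(states[graph_node_ids(graph)], class = "view_state", mode = mode)
}

#' @export
print.view_state <- function(x, ...) {
  cat("<view_state mode=", attr(x, "mode"), ">\n", sep = "")
  print(stats::setNames(as.character(x), names(x)))
  invisible(x)
}

#' Difference between two view states
#'
#' @param a,b [compute_view()] results over the same node universe.
#' @return Sorted character vector of node ids whose state differs; empty
#'   iff the states are identical. Symmetric in its arguments.
#' @export
diff_views <- function(a, b) {
  stopifnot(inherits(a, "view_state"), inherits(b, "view_state"))
  if (!setequal(names(a), names(b)))
    stop("view states cover different node universes")
  ids <- names(a)
  sort(ids[as.character(a[ids]) != as.character(b[ids])])
}

#' Serialize a view state to JSON
#'
#' @param state a [compute_view()] result.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
view_state_json <- function(state, path = NULL) {
  obj <- list(mode = attr(state, "mode"),
              node_states = as.list(stats::setNames(as.character(state),
                                                    names(state))))
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
  }
}
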