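#' Scene-graph entity (node)
#'
#' @param node_id Stable string identifier of the node within a take.
#' @param class_name Entity class label (must be in the entity vocabulary).
#' @param centroid Optional numeric xyz position in meters (right-handed,
#'   z-up).
#' @param role Optional clinical role; only meaningful on human-class nodes.
#' @return An object of class `or_entity`.
#' @export
entity <- function(node_id, class_name, centroid = NULL, role = NULL) {
  stopifnot(is.character(node_id), length(node_id) == 1L, nzchar(node_id))
  if (!is.null(centroid)) {
    centroid <- as.numeric(centroid)
    stopifnot(length(centroid) == 3L, all(is.finite(centroid)))
  }
  if (!is.null(role)) stopifnot(role %in% clinical_roles())
  structure(list(node_id = node_id, class_name = class_name,
                 centroid = centroid, role = role), class = "or_entity")
}

#' Semantic scene graph for one time point
#'
#' Nodes are typed entities; edges are directed (subject, relation, object)
#' triplets with at most one relation per ordered node pair and no
#' self-loops. The reserved relation `"None"` is never stored.
#'
#' @param frame_id Integer time index (frames are sampled at `fps`, 1 Hz by
#'   default).
#' @param nodes List of [entity()] objects.
#' @param edges Data frame with character columns `subject`, `relation`,
#'   `object` (node ids and a relation label), or NULL for an edgeless graph.
#' @return An object of class `ssg_graph`.
#' @export
scene_graph <- function(frame_id, nodes = list(), edges = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(subject = character(), relation = character(),
                        object = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(subject = as.character(edges$subject),
                        relation = as.character(edges$relation),
                        object = as.character(edges$object),
                        stringsAsFactors = FALSE)
  }
  nodes <- unname(nodes)
  ids <- vapply(nodes, function(n) n$node_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate node ids in scene graph")
  names(nodes) <- ids
  structure(list(frame_id = as.integer(frame_id), nodes = nodes,
                 edges = edges), class = "ssg_graph")
}

#' @export
print.ssg_graph <- function(x, ...) {
  cat(sprintf("<scene graph> frame %d: %d nodes, %d edges\n",
              x$frame_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

node_ids <- function(graph) names(graph$nodes)

node_classes <- function(graph)
  vapply(graph$nodes, function(n) n$class_name, character(1))

#' Effective label of a node
#'
#' The clinical role if one is assigned, otherwise the entity class. Clinical
#' roles are themselves entity classes, so a role-augmented graph can be
#' queried with role labels transparently.
#' @param node An [entity()].
#' @return Character label.
#' @export
node_label <- function(node) {
  if (!is.null(node$role)) node$role else node$class_name
}

#' Validate a scene graph
#'
#' Checks every structural invariant and returns human-readable violations
#' instead of raising: unknown classes, edge endpoints missing from the node
#' set, self-loops, duplicate ordered pairs, unknown or reserved relation
#' labels, and roles on non-human nodes.
#'
#' @param graph A [scene_graph()].
#' @param entities An [entity_vocabulary()].
#' @param relations A [relation_vocabulary()].
#' @return Character vector of violation descriptions; empty iff the graph is
#'   admissible to every downstream operation.
#' @export
validate_graph <- function(graph, entities = entity_vocabulary(),
                           relations = relation_vocabulary()) {
  v <- character()
  ids <- node_ids(graph)
  human_classes <- c(clinical_roles(), "human")
  for (n in graph$nodes) {
    if (!(n$class_name %in% entities$names))
      v <- c(v, sprintf("node '%s': unknown entity class '%s'",
                        n$node_id, n$class_name))
    if (!is.null(n$role) && !(n$class_name %in% human_classes))
      v <- c(v, sprintf("node '%s': role set on non-human class '%s'",
                        n$node_id, n$class_name))
  }
  e <- graph$edges
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      if (!(e$subject[k] %in% ids))
        v <- c(v, sprintf("edge %d: subject '%s' not in node set", k, e$subject[k]))
      if (!(e$object[k] %in% ids))
        v <- c(v, sprintf("edge %d: object '%s' not in node set", k, e$object[k]))
      if (e$subject[k] == e$object[k])
        v <- c(v, sprintf("edge %d: self-loop on '%s'", k, e$subject[k]))
      if (e$relation[k] == relations$none)
        v <- c(v, sprintf("edge %d: reserved relation '%s' stored as edge",
                          k, relations$none))
      else if (!(e$relation[k] %in% relations$names))
        v <- c(v, sprintf("edge %d: unknown relation '%s'", k, e$relation[k]))
    }
    key <- paste(e$subject, e$object, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      v <- c(v, sprintf("multiple relations on ordered pair (%s)",
                        gsub("\r", ", ", dup)))
    }
  }
  v
}

#' Query a graph for a class-level triplet
#'
#' True iff some edge's subject node carries `subject_class`, the relation
#' matches, and the object node carries `object_class`. Matching is
#' class-level (role-aware via [node_label()]), not node-id level; edges are
#' directed, so argument order matters.
#'
#' @param graph A [scene_graph()].
#' @param subject_class,object_class Entity class (or clinical role) labels.
#' @param relation Relation label.
#' @param entities,relations Vocabularies used to reject unknown labels.
#' @return Logical scalar.
#' @export
#' @examples
#' g <- scene_graph(1,
#'   list(entity("hs1", "head surgeon"), entity("p1", "patient")),
#'   data.frame(subject = "hs1", relation = "Sawing", object = "p1"))
#' has_triplet(g, "head surgeon", "Sawing", "patient") # TRUE
#' has_triplet(g, "patient", "Sawing", "head surgeon") # FALSE
has_triplet <- function(graph, subject_class, relation, object_class,
                        entities = entity_vocabulary(),
                        relations = relation_vocabulary()) {
  check_label(subject_class, entities$names, "entity")
  check_label(object_class, entities$names, "entity")
  check_label(relation, relations$names, "relation")
  e <- graph$edges
  if (!nrow(e)) return(FALSE)
  for (k in seq_len(nrow(e))) {
    if (e$relation[k] != relation) next
    s <- graph$nodes[[e$subject[k]]]
    o <- graph$nodes[[e$object[k]]]
    if (is.null(s) || is.null(o)) next
    if ((node_label(s) == subject_class || s$class_name == subject_class) &&
        (node_label(o) == object_class || o$class_name == object_class))
      return(TRUE)
  }
  FALSE
}

#' Flatten a graph to triplets
#'
#' @param graph A valid [scene_graph()].
#' @return Data frame with one row per edge: `subject_id`, `subject_class`,
#'   `relation`, `object_id`, `object_class`.
#' @export
graph_to_triplets <- function(graph) {
  v <- validate_graph(graph)
  if (length(v)) stop("invalid graph: ", paste(v, collapse = "; "))
  e <- graph$edges
  cls <- node_classes(graph)
  data.frame(subject_id = e$subject, subject_class = unname(cls[e$subject]),
             relation = e$relation, object_id = e$object,
             object_class = unname(cls[e$object]), stringsAsFactors = FALSE)
}

#' Rebuild a graph from flat triplets
#'
#' Inverse of [graph_to_triplets()] given the node set.
#' @param frame_id Integer frame index.
#' @param triplets Data frame as produced by [graph_to_triplets()].
#' @param nodes List of [entity()] covering at least all triplet endpoints.
#' @return A [scene_graph()].
#' @export
triplets_to_graph <- function(frame_id, triplets, nodes) {
  edges <- if (NROW(triplets)) {
    data.frame(subject = triplets$subject_id, relation = triplets$relation,
               object = triplets$object_id, stringsAsFactors = FALSE)
  } else NULL
  scene_graph(frame_id, nodes, edges)
}

#' Scene sequence (one take)
#'
#' @param take_id String identifier of the take.
#' @param graphs List of [scene_graph()] with strictly increasing `frame_id`.
#' @param fps Frames per second; the 4D-OR capture protocol is 1 Hz.
#' @return An object of class `ssg_sequence`.
#' @export
scene_sequence <- function(take_id, graphs = list(), fps = 1) {
  stopifnot(is.character(take_id), fps > 0)
  fids <- vapply(graphs, function(g) g$frame_id, integer(1))
  if (length(fids) > 1 && any(diff(fids) <= 0))
    stop("frame_ids must be strictly increasing")
  structure(list(take_id = take_id, graphs = graphs, fps = fps),
            class = "ssg_sequence")
}

#' @export
print.ssg_sequence <- function(x, ...) {
  cat(sprintf("<scene sequence> take '%s': %d frames @ %g fps\n",
              x$take_id, length(x$graphs), x$fps))
  invisible(x)
}

#' Assign clinical roles onto a sequence's human nodes
#'
#' @param sequence A [scene_sequence()].
#' @param roles Named character vector mapping human node ids to clinical
#'   roles.
#' @return The sequence with `role` set on every matching node.
#' @export
apply_roles <- function(sequence, roles) {
  stopifnot(all(roles %in% clinical_roles()))
  sequence$graphs <- lapply(sequence$graphs, function(g) {
    for (id in intersect(names(roles), node_ids(g)))
      g$nodes[[id]]$role <- unname(roles[[id]])
    g
  })
  sequence
}

graph_to_list <- function(g) {
  list(frame_id = g$frame_id,
       nodes = lapply(unname(g$nodes), function(n) {
         out <- list(id = n$node_id, class = n$class_name)
         if (!is.null(n$centroid)) out$centroid <- n$centroid
         if (!is.null(n$role)) out$role <- n$role
         out
       }),
       edges = unname(Map(function(s, r, o) c(s, r, o),
                          g$edges$subject, g$edges$relation, g$edges$object)))
}

graph_from_list <- function(gl, entities, relations, where) {
  nodes <- lapply(gl$nodes, function(n) {
    check_label(n$class, entities$names, "entity")
    entity(n$id, n$class, centroid = n$centroid, role = n$role)
  })
  edges <- if (length(gl$edges)) {
    m <- do.call(rbind, lapply(gl$edges, function(e) {
      if (length(e) != 3L)
        stop(sprintf("parse error at %s: edge is not a [subject, relation, object] triple", where))
      as.character(e)
    }))
    data.frame(subject = m[, 1], relation = m[, 2], object = m[, 3],
               stringsAsFactors = FALSE)
  } else NULL
  g <- scene_graph(gl$frame_id, nodes, edges)
  bad <- setdiff(g$edges$relation, relations$names)
  if (length(bad))
    stop(sprintf("parse error at %s: unknown relation '%s'", where, bad[1]))
  g
}

#' Read or write a scene sequence as JSON
#'
#' Schema: `{take_id, fps, frames: [{frame_id, nodes: [{id, class, centroid,
#' role}], edges: [[subj, rel, obj]]}]}`. UTF-8; coordinates in meters,
#' right-handed, z-up. `read_scene_sequence(write_scene_sequence(s))` is the
#' identity.
#'
#' @param sequence A [scene_sequence()].
#' @param path File path.
#' @param entities,relations Vocabularies used to validate labels on read.
#' @return `read_scene_sequence` returns an `ssg_sequence`;
#'   `write_scene_sequence` returns `path` invisibly.
#' @export
write_scene_sequence <- function(sequence, path) {
  stopifnot(inherits(sequence, "ssg_sequence"))
  obj <- list(take_id = sequence$take_id, fps = sequence$fps,
              frames = lapply(sequence$graphs, graph_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_sequence
#' @export
read_scene_sequence <- function(path, entities = entity_vocabulary(),
                                relations = relation_vocabulary()) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  frames <- obj$frames
  graphs <- vector("list", length(frames))
  fids <- integer(length(frames))
  for (i in seq_along(frames)) {
    graphs[[i]] <- graph_from_list(frames[[i]], entities, relations,
                                   sprintf("frame index %d", i))
    fids[i] <- graphs[[i]]$frame_id
  }
  if (anyDuplicated(fids))
    stop(sprintf("parse error at frame index %d: duplicate frame_id %d",
                 which(duplicated(fids))[1], fids[duplicated(fids)][1]))
  scene_sequence(obj$take_id, graphs, fps = obj$fps %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
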