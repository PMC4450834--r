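#' Build a validated is-a ontology
#'
#' Constructs an `ontology` object from an edge table of child/parent concept
#' pairs. The hierarchy must be a rooted directed acyclic graph: every
#' is-a edge points from a child concept to one of its parents, exactly one
#' concept (the root) has no parent, and no cycles are allowed. Concepts may
#' have multiple parents.
#'
#' @param edges A data frame whose first two columns are the child and parent
#'   concept ids (`child_id`, `parent_id`).
#' @param synonyms Optional data frame with columns `concept_id` and `synonym`,
#'   one row per synonym. Concepts absent from the table get empty synonym
#'   lists.
#' @param names Optional data frame with columns `concept_id` and
#'   `preferred_name`; defaults to using the id as the name.
#'
#' @return An object of class `ontology`: a list with elements `concepts`
#'   (tibble of `concept_id`, `preferred_name`, `synonyms` list-column),
#'   `edges` (tibble of `child_id`, `parent_id`), `root_id`, and `levels`
#'   (named numeric vector; root is level 0, otherwise 1 + the minimum parent
#'   level).
#' @export
#' @examples
#' ont <- ontology(data.frame(child_id = c("B", "C"), parent_id = c("A", "B")))
#' concept_level(ont, c("A", "B", "C"))
ontology <- function(edges, synonyms = NULL, names = NULL) {
  edges <- as_tibble(edges)
  if (ncol(edges) < 2) {
    abort_ontosim("`edges` needs two columns: child_id, parent_id.", "format")
  }
  edges <- tibble(
    child_id = as.character(edges[[1]]),
    parent_id = as.character(edges[[2]])
  )
  if (nrow(edges) == 0) {
    abort_ontosim("Ontology edge table is empty.", "format")
  }
  if (anyNA(edges) || any(edges$child_id == "") || any(edges$parent_id == "")) {
    abort_ontosim("Ontology edge table contains missing or empty ids.", "format")
  }
  if (any(edges$child_id == edges$parent_id)) {
    bad <- edges$child_id[edges$child_id == edges$parent_id][1]
    abort_ontosim(
      sprintf("Self is-a edge on concept '%s'.", bad), "validation"
    )
  }
  edges <- distinct(edges)

  ids <- sort_c(unique(c(edges$child_id, edges$parent_id)))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
      which(comp$csize > 1)[1]]
    abort_ontosim(
      sprintf("Hierarchy contains a cycle through: %s.",
              paste(sort_c(cyc), collapse = " -> ")),
      "validation", cycle = cyc
    )
  }
  roots <- ids[igraph::degree(g, mode = "out") == 0]
  if (length(roots) == 0) {
    abort_ontosim("Hierarchy has no root concept.", "validation")
  }
  if (length(roots) > 1) {
    abort_ontosim(
      sprintf("Hierarchy has %d parentless concepts (%s); exactly one root is required.",
              length(roots), paste(head(roots, 5), collapse = ", ")),
      "validation", roots = roots
    )
  }
  root_id <- roots

  # level = minimum is-a edge count up to root; in a single-root DAG every
  # maximal upward path terminates at the root, so all levels are finite
  lev <- as.numeric(igraph::distances(g, v = ids, to = root_id, mode = "out"))
  names(lev) <- ids

  concepts <- tibble(concept_id = ids, preferred_name = ids)
  if (!is.null(names)) {
    names <- as_tibble(names)
    nm <- setNames(as.character(names$preferred_name), names$concept_id)
    hit <- concepts$concept_id %in% base::names(nm)
    concepts$preferred_name[hit] <- unname(nm[concepts$concept_id[hit]])
  }
  if (any(concepts$preferred_name == "")) {
    abort_ontosim("Every concept needs a non-empty preferred name.", "validation")
  }
  syn_list <- rep(list(character(0)), length(ids))
  names(syn_list) <- ids
  if (!is.null(synonyms) && nrow(as_tibble(synonyms)) > 0) {
    synonyms <- as_tibble(synonyms)
    synonyms <- tibble(
      concept_id = as.character(synonyms[[1]]),
      synonym = as.character(synonyms[[2]])
    )
    unknown <- setdiff(unique(synonyms$concept_id), ids)
    if (length(unknown) > 0) {
      abort_ontosim(
        sprintf("Synonyms given for unknown concepts: %s.",
                paste(head(unknown, 5), collapse = ", ")),
        "lookup"
      )
    }
    sp <- split(synonyms$synonym, synonyms$concept_id)
    syn_list[base::names(sp)] <- lapply(sp, unique)
  }
  concepts$synonyms <- unname(syn_list[concepts$concept_id])

  structure(
    list(concepts = concepts, edges = edges, root_id = root_id,
         levels = lev, graph = g),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology> %d concepts, %d is-a edges, root '%s', max level %d\n",
    nrow(x$concepts), nrow(x$edges), x$root_id, max(x$levels)
  ))
  invisible(x)
}

check_concepts <- function(ont, ids) {
  unknown <- setdiff(unique(ids), ont$concepts$concept_id)
  if (length(unknown) > 0) {
    abort_ontosim(
      sprintf("Unknown concept id(s): %s.",
              paste(head(unknown, 5), collapse = ", ")),
      "lookup", ids = unknown
    )
  }
  invisible(TRUE)
}

#' Hierarchy level of concepts
#'
#' The level of a concept is the minimum number of is-a edges on any path from
#' the concept up to the root. By convention the root sits at level
#' `root_level` (0 by default; set 1 for the alternative one-based counting).
#'
#' @param ont An [ontology()] object.
#' @param concept_ids Character vector of concept ids.
#' @param root_level Level assigned to the root concept (default 0).
#' @return Numeric vector of levels, one per id.
#' @export
concept_level <- function(ont, concept_ids, root_level = 0) {
  stopifnot(inherits(ont, "ontology"))
  check_concepts(ont, concept_ids)
  unname(ont$levels[concept_ids]) + root_level
}

#' Edge-count semantic distance from extracted terms to feature concepts
#'
#' The semantic distance from an extracted term to a feature concept follows
#' three rules: if the term *is* the feature concept the distance is 0; if the
#' term is a descendant of the feature concept it is the minimum number of
#' is-a edges on any upward path between them; otherwise the term is not
#' comparable to that feature concept and the distance is `Inf` (unreachable).
#' The distance is directional: it is only defined walking *up* the hierarchy,
#' so `semantic_distance(ont, parent, child)` is `Inf` unless the parent also
#' happens to descend from the child.
#'
#' @param ont An [ontology()] object.
#' @param term_ids,feature_ids Character vectors of concept ids, recycled to a
#'   common length; distances are computed elementwise.
#' @return Numeric vector of distances (`0`, positive integers, or `Inf`).
#' @export
#' @examples
#' ont <- ontology(data.frame(child = c("B", "C"), parent = c("A", "B")))
#' semantic_distance(ont, "C", "A")  # 2
#' semantic_distance(ont, "A", "C")  # Inf: A is not a descendant of C
semantic_distance <- function(ont, term_ids, feature_ids) {
  stopifnot(inherits(ont, "ontology"))
  n <- max(length(term_ids), length(feature_ids))
  term_ids <- rep_len(as.character(term_ids), n)
  feature_ids <- rep_len(as.character(feature_ids), n)
  m <- semantic_distance_matrix(ont, unique(term_ids), unique(feature_ids))
  m[cbind(term_ids, feature_ids)]
}

#' Semantic distance matrix
#'
#' All pairwise upward edge-count distances from a set of extracted terms
#' (rows) to a set of feature concepts (columns); `Inf` marks non-descendants.
#'
#' @inheritParams semantic_distance
#' @return Numeric matrix with `term_ids` as rownames and `feature_ids` as
#'   colnames.
#' @export
semantic_distance_matrix <- function(ont, term_ids, feature_ids) {
  stopifnot(inherits(ont, "ontology"))
  term_ids <- unique(as.character(term_ids))
  feature_ids <- unique(as.character(feature_ids))
  check_concepts(ont, c(term_ids, feature_ids))
  if (length(term_ids) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = length(feature_ids),
                  dimnames = list(NULL, feature_ids)))
  }
  d <- igraph::distances(ont$graph, v = term_ids, to = feature_ids,
                         mode = "out")
  # igraph returns a plain matrix with dimnames already set to the ids
  d[term_ids, feature_ids, drop = FALSE]
}

#' Feature concepts at a hierarchy level
#'
#' Selects every concept sitting at the requested level as a feature concept.
#' The returned order (lexicographic by concept id, C locale) is the feature
#' vector element order and is stable across sessions.
#'
#' @inheritParams concept_level
#' @param level Requested level, counted in the `root_level` convention.
#' @return A `feature_space` tibble with columns `feature_id` and
#'   `preferred_name`, carrying the level as an attribute.
#' @export
feature_space <- function(ont, level = 4, root_level = 0) {
  stopifnot(inherits(ont, "ontology"))
  raw <- level - root_level
  if (raw < 0) {
    abort_ontosim("Requested level is above the root.", "empty_feature_space")
  }
  ids <- sort_c(names(ont$levels)[ont$levels == raw])
  if (length(ids) == 0) {
    abort_ontosim(
      sprintf("No concept at level %s (root_level = %s).", level, root_level),
      "empty_feature_space"
    )
  }
  out <- tibble(
    feature_id = ids,
    preferred_name = ont$concepts$preferred_name[
      match(ids, ont$concepts$concept_id)]
  )
  attr(out, "level") <- level
  attr(out, "root_level") <- root_level
  class(out) <- c("feature_space", class(out))
  out
}

# name + synonyms of a concept, as a query group
concept_group <- function(ont, concept_id) {
  i <- match(concept_id, ont$concepts$concept_id)
  query_group(c(ont$concepts$preferred_name[i], ont$concepts$synonyms[[i]]))
}
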