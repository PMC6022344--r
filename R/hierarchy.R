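#' Build the hierarchy graph of an ontology
#'
#' Collects the relation table into a directed acyclic graph with edges
#' pointing child -> parent.  Nodes in the resource namespace are families
#' and complexes; nodes in any other namespace are gene-level leaves.  Both
#' `isa` and `partof` edges participate in traversal; the relation type is
#' kept as an edge attribute.  Entities with no relations (placeholders) are
#' included as isolated nodes.
#'
#' @param ont a validated [ontology()]
#' @return an object of class `famground_graph` with elements `nodes`
#'   (character refs), `children`/`parents` (adjacency lists), `edges`
#'   (data.frame child, parent, rel) and `namespace`
#' @export
#' @examples
#' g <- hierarchy_graph(inpaper_ontology())
#' gene_members(g, "AMPK")
hierarchy_graph <- function(ont) {
  stopifnot(inherits(ont, "famground_ontology"))
  rel <- ont$relations
  child <- if (nrow(rel)) entity_ref(rel$subject_ns, rel$subject_id) else character()
  parent <- if (nrow(rel)) entity_ref(rel$object_ns, rel$object_id) else character()
  nodes <- unique(c(entity_ref(ont$namespace, ont$entities), child, parent))
  edges <- data.frame(child = child, parent = parent,
                      rel = rel$rel %||% character(), stringsAsFactors = FALSE)
  structure(
    list(
      nodes = nodes,
      children = split(child, factor(parent, levels = nodes)),
      parents = split(parent, factor(child, levels = nodes)),
      edges = edges,
      namespace = ont$namespace
    ),
    class = "famground_graph"
  )
}

#' @export
print.famground_graph <- function(x, ...) {
  cat(sprintf("<%s hierarchy: %d nodes, %d edges>\n",
              x$namespace, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Resolve user input to a full node reference: bare identifiers are assumed
# to live in the resource's own namespace.
resolve_node <- function(graph, node) {
  ref <- if (grepl(":", node, fixed = TRUE)) node else entity_ref(graph$namespace, node)
  if (!ref %in% graph$nodes) {
    stop(sprintf("unknown node '%s'", ref), call. = FALSE)
  }
  ref
}

# BFS closure along one adjacency direction, excluding the start node.
reach <- function(adj, start) {
  seen <- character()
  frontier <- adj[[start]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  seen
}

#' Transitive ancestors and descendants
#'
#' `ancestors()` returns every node reachable by following child -> parent
#' edges; `descendants()` follows parent -> child edges.  The start node is
#' excluded.  Bare identifiers are interpreted in the resource namespace;
#' gene-level nodes must be given as full `"NS:ID"` references.
#'
#' @param graph a [hierarchy_graph()]
#' @param node node identifier or full reference
#' @return character vector of full node references
#' @export
ancestors <- function(graph, node) {
  reach(graph$parents, resolve_node(graph, node))
}

#' @rdname ancestors
#' @export
descendants <- function(graph, node) {
  reach(graph$children, resolve_node(graph, node))
}

is_leaf_ref <- function(graph, ref) ref_ns(ref) != graph$namespace

#' Gene-level members of a family or complex
#'
#' Expands a family/complex into its constituent gene-level leaves — the
#' relationship-resolution step that lets information extracted about e.g. a
#' complex be connected to data on the individual genes it comprises.  A
#' gene-level node returns itself; a placeholder (no children) returns an
#' empty set.
#'
#' @inheritParams ancestors
#' @return character vector of gene-level node references
#' @export
gene_members <- function(graph, node) {
  ref <- resolve_node(graph, node)
  if (is_leaf_ref(graph, ref)) return(ref)
  desc <- reach(graph$children, ref)
  desc[ref_ns(desc) != graph$namespace]
}

#' Classify resource entries by hierarchy position
#'
#' Every entry in the resource namespace is classified as `top` (has at
#' least one child, no parent), `intermediate` (has both parent and child),
#' or `placeholder` (no parent and no child; broad functional categories
#' such as GTPase).  An entry with a parent but no children cannot arise in
#' a well-formed resource (families always enumerate members); if present it
#' is classed `intermediate`.
#'
#' @param graph a [hierarchy_graph()]
#' @return named character vector: identifier -> class
#' @export
classify_levels <- function(graph) {
  own <- graph$nodes[ref_ns(graph$nodes) == graph$namespace]
  n_child <- lengths(graph$children[own])
  n_parent <- lengths(graph$parents[own])
  cls <- ifelse(n_child > 0L & n_parent == 0L, "top",
         ifelse(n_child == 0L & n_parent == 0L, "placeholder", "intermediate"))
  stats::setNames(cls, ref_id(own))
}

#' Subsumed depth of an entry
#'
#' The number of hierarchy levels an entry subsumes: the length of the
#' longest child-chain from the node down to a leaf.  A gene-level leaf (and
#' a placeholder) has depth 0; a family resolving directly to genes has
#' depth 1; a family of subfamilies of genes has depth 2.
#'
#' @inheritParams ancestors
#' @return non-negative integer
#' @export
subsumed_depth <- function(graph, node) {
  ref <- resolve_node(graph, node)
  memo <- new.env(parent = emptyenv())
  depth <- function(r) {
    if (!is.null(memo[[r]])) return(memo[[r]])
    kids <- graph$children[[r]]
    d <- if (length(kids) == 0L) 0L else 1L + max(vapply(kids, depth, integer(1)))
    memo[[r]] <- d
    d
  }
  depth(ref)
}

#' Direct child counts
#'
#' `child_count()` counts direct (isa or partof) children of one node.
#' `child_stats()` summarises child counts over resource-namespace entries
#' that have at least one child.
#'
#' @inheritParams ancestors
#' @return `child_count()`: integer. `child_stats()`: named numeric vector
#'   with `mean`, `sd` and `median`.
#' @export
child_count <- function(graph, node) {
  length(graph$children[[resolve_node(graph, node)]])
}

#' @rdname child_count
#' @export
child_stats <- function(graph) {
  own <- graph$nodes[ref_ns(graph$nodes) == graph$namespace]
  counts <- lengths(graph$children[own])
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) {
    return(c(mean = NA_real_, sd = NA_real_, median = NA_real_))
  }
  c(mean = mean(counts), sd = stats::sd(counts), median = stats::median(counts))
}

#' Grounding level of an entity within a top-level sub-hierarchy
#'
#' Classifies a grounded entity relative to a named top-level entry:
#' `"top"` if it is the entry itself, `"gene"` if it is a gene-level leaf,
#' `"intermediate"` otherwise.  The entity must belong to the entry's
#' sub-hierarchy.
#'
#' @inheritParams ancestors
#' @param entity node identifier or reference to classify
#' @param top_entry the top-level entry anchoring the sub-hierarchy
#' @return one of `"gene"`, `"intermediate"`, `"top"`
#' @export
grounding_level <- function(graph, entity, top_entry) {
  e <- resolve_node(graph, entity)
  t <- resolve_node(graph, top_entry)
  if (e == t) return("top")
  if (!e %in% reach(graph$children, t)) {
    stop(sprintf("'%s' is not in the sub-hierarchy of '%s'", e, t), call. = FALSE)
  }
  if (is_leaf_ref(graph, e)) "gene" else "intermediate"
}
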