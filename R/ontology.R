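#' Construct a family/complex ontology
#'
#' Bundles the five components of the resource: the entity list (local
#' identifiers in the resource's own namespace), the isa/partof relation
#' table, the grounding map (surface string to namespaced identifier), the
#' cross-database equivalence table, and the gene/protein affix table.
#'
#' @param entities character vector of local identifiers
#' @param relations data.frame with columns subject_ns, subject_id, rel,
#'   object_ns, object_id; `rel` is `"isa"` (family membership) or
#'   `"partof"` (complex membership); edges point child -> parent
#' @param grounding_map data.frame with columns text, target_ns, target_id;
#'   `text` keys are verbatim, case-preserved surface strings
#' @param equivalences data.frame with columns external_ns, external_id,
#'   famplex_id mapping an external database identifier to a local one
#' @param affixes data.frame with columns pattern, position, category,
#'   species_tag; `pattern` carries a single `{Gene name}` placeholder
#' @param namespace the resource's own namespace token (default `"FPLX"`)
#' @param namespaces controlled vocabulary of accepted namespace tokens
#' @return an object of class `famground_ontology`
#' @seealso [load_ontology()], [validate()], [export_obo()]
#' @export
ontology <- function(entities = character(),
                     relations = empty_relations(),
                     grounding_map = empty_grounding_map(),
                     equivalences = empty_equivalences(),
                     affixes = empty_affixes(),
                     namespace = "FPLX",
                     namespaces = default_namespaces()) {
  stopifnot_scalar_chr(namespace, "namespace")
  if (!namespace %in% namespaces) namespaces <- c(namespace, namespaces)
  relations <- as_chr_df(relations, names(empty_relations()))
  grounding_map <- as_chr_df(grounding_map, names(empty_grounding_map()))
  equivalences <- as_chr_df(equivalences, names(empty_equivalences()))
  affixes <- as_chr_df(affixes, names(empty_affixes()))
  structure(
    list(
      entities = as.character(entities),
      relations = relations,
      grounding_map = grounding_map,
      equivalences = equivalences,
      affixes = affixes,
      namespace = namespace,
      namespaces = unique(namespaces)
    ),
    class = "famground_ontology"
  )
}

empty_relations <- function() {
  chr_frame(c("subject_ns", "subject_id", "rel", "object_ns", "object_id"))
}
empty_grounding_map <- function() chr_frame(c("text", "target_ns", "target_id"))
empty_equivalences <- function() chr_frame(c("external_ns", "external_id", "famplex_id"))
empty_affixes <- function() chr_frame(c("pattern", "position", "category", "species_tag"))

as_chr_df <- function(df, cols) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, cols, drop = FALSE]
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  rownames(df) <- NULL
  df
}

#' @export
print.famground_ontology <- function(x, ...) {
  cat(sprintf(
    "<%s ontology: %d entities, %d relations, %d synonyms, %d equivalences, %d affixes>\n",
    x$namespace, length(x$entities), nrow(x$relations),
    nrow(x$grounding_map), nrow(x$equivalences), nrow(x$affixes)
  ))
  invisible(x)
}

#' Validate an ontology against its structural invariants
#'
#' Checks every invariant of the resource format: unique entity identifiers,
#' relation tokens drawn from \{isa, partof\}, no self-relations, relation
#' endpoints and equivalence/grounding targets in the resource namespace
#' present in the entity list, unique grounding-map text keys, well-formed
#' affixes, namespace tokens from the controlled vocabulary, and acyclicity
#' of the directed relation graph (isa and partof edges considered together).
#'
#' @param ont a [ontology()] object
#' @return a data.frame of validation issues (see [validation_issue()]);
#'   zero rows if and only if every invariant holds
#' @export
#' @examples
#' ont <- inpaper_ontology()
#' nrow(validate(ont))  # 0
validate <- function(ont) {
  stopifnot(inherits(ont, "famground_ontology"))
  iss <- list(no_issues())
  own <- ont$namespace

  dup <- unique(ont$entities[duplicated(ont$entities)])
  for (d in dup) {
    iss[[length(iss) + 1L]] <- validation_issue(
      "error", "duplicate_entity", sprintf("entity '%s' listed more than once", d),
      file = "entities.csv"
    )
  }

  rel <- ont$relations
  if (nrow(rel) > 0L) {
    bad <- which(!rel$rel %in% c("isa", "partof"))
    for (i in bad) {
      iss[[length(iss) + 1L]] <- validation_issue(
        "error", "invalid_relation",
        sprintf("unknown relation token '%s'", rel$rel[i]),
        file = "relations.csv", row = i
      )
    }
    self <- which(rel$subject_ns == rel$object_ns & rel$subject_id == rel$object_id)
    for (i in self) {
      iss[[length(iss) + 1L]] <- validation_issue(
        "error", "self_relation",
        sprintf("relation with identical subject and object '%s:%s'",
                rel$subject_ns[i], rel$subject_id[i]),
        file = "relations.csv", row = i
      )
    }
    for (side in c("subject", "object")) {
      ns <- rel[[paste0(side, "_ns")]]
      id <- rel[[paste0(side, "_id")]]
      bad <- which(ns == own & !id %in% ont$entities)
      for (i in bad) {
        iss[[length(iss) + 1L]] <- validation_issue(
          "error", "dangling_relation",
          sprintf("relation %s '%s:%s' not in entity list", side, ns[i], id[i]),
          file = "relations.csv", row = i
        )
      }
    }
  }

  gm <- ont$grounding_map
  if (nrow(gm) > 0L) {
    dup <- which(duplicated(gm$text))
    for (i in dup) {
      iss[[length(iss) + 1L]] <- validation_issue(
        "error", "duplicate_synonym",
        sprintf("grounding-map text '%s' has multiple targets", gm$text[i]),
        file = "grounding_map.csv", row = i
      )
    }
    bad <- which(gm$target_ns == own & !gm$target_id %in% ont$entities)
    for (i in bad) {
      iss[[length(iss) + 1L]] <- validation_issue(
        "error", "dangling_grounding",
        sprintf("grounding target '%s:%s' not in entity list", gm$target_ns[i], gm$target_id[i]),
        file = "grounding_map.csv", row = i
      )
    }
  }

  eq <- ont$equivalences
  if (nrow(eq) > 0L) {
    bad <- which(!eq$famplex_id %in% ont$entities)
    for (i in bad) {
      iss[[length(iss) + 1L]] <- validation_issue(
        "error", "dangling_equivalence",
        sprintf("equivalence refers to unknown identifier '%s'", eq$famplex_id[i]),
        file = "equivalences.csv", row = i
      )
    }
  }

  af <- ont$affixes
  if (nrow(af) > 0L) {
    n_ph <- vapply(af$pattern, function(p) {
      length(gregexpr(AFFIX_PLACEHOLDER, p, fixed = TRUE)[[1]][
        gregexpr(AFFIX_PLACEHOLDER, p, fixed = TRUE)[[1]] > 0])
    }, integer(1))
    bad <- which(n_ph != 1L)
    for (i in bad) {
      iss[[length(iss) + 1L]] <- validation_issue(
        "error", "malformed_affix",
        sprintf("affix pattern '%s' must contain exactly one '%s' placeholder",
                af$pattern[i], AFFIX_PLACEHOLDER),
        file = "gene_prefixes.csv", row = i
      )
    }
    bad <- which(!af$category %in% affix_categories() | !af$position %in% c("prefix", "suffix"))
    for (i in bad) {
      iss[[length(iss) + 1L]] <- validation_issue(
        "error", "invalid_affix",
        sprintf("affix '%s' has invalid category '%s' or position '%s'",
                af$pattern[i], af$category[i], af$position[i]),
        file = "gene_prefixes.csv", row = i
      )
    }
  }

  seen_ns <- unique(c(
    rel$subject_ns, rel$object_ns, gm$target_ns, eq$external_ns
  ))
  for (ns in setdiff(seen_ns, ont$namespaces)) {
    iss[[length(iss) + 1L]] <- validation_issue(
      "warning", "invalid_namespace",
      sprintf("namespace '%s' is outside the controlled vocabulary", ns)
    )
  }

  cyc <- find_cycle(ont)
  if (!is.null(cyc)) {
    iss[[length(iss) + 1L]] <- validation_issue(
      "error", "cycle",
      sprintf("relation graph contains a cycle: %s", paste(cyc, collapse = " -> ")),
      file = "relations.csv"
    )
  }

  out <- do.call(rbind, iss)
  rownames(out) <- NULL
  out
}

# Kahn-style topological elimination; on failure, walk the residual graph to
# report one concrete cycle (node reference list, first node repeated at end).
find_cycle <- function(ont) {
  rel <- ont$relations
  # self-loops are reported separately as self_relation issues
  rel <- rel[!(rel$subject_ns == rel$object_ns & rel$subject_id == rel$object_id), ,
             drop = FALSE]
  if (nrow(rel) == 0L) return(NULL)
  from <- entity_ref(rel$subject_ns, rel$subject_id)
  to <- entity_ref(rel$object_ns, rel$object_id)
  nodes <- unique(c(from, to))
  out_edges <- split(to, factor(from, levels = nodes))
  indeg <- table(factor(to, levels = nodes))
  queue <- nodes[indeg == 0L]
  removed <- 0L
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  while (length(queue) > 0L) {
    n <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    for (m in out_edges[[n]]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) queue <- c(queue, m)
    }
  }
  if (removed == length(nodes)) return(NULL)
  resid <- names(indeg)[indeg > 0L]
  # follow edges inside the residual set until a node repeats
  cur <- resid[[1L]]
  path <- character()
  while (!cur %in% path) {
    path <- c(path, cur)
    nxt <- intersect(out_edges[[cur]], resid)
    cur <- nxt[[1L]]
  }
  cycle <- c(path[which(path == cur):length(path)], cur)
  cycle
}

#' Test two ontologies for structural equality
#'
#' Compares entity sets, relation sets, grounding maps, equivalences and
#' affixes up to row order.  Used by the load/save and OBO round-trip
#' checks, where file order is not semantically meaningful.
#'
#' @param a,b ontologies
#' @param affixes also compare affix tables (OBO export does not carry them)
#' @return TRUE or FALSE
#' @export
ontology_equal <- function(a, b, affixes = TRUE) {
  sort_df <- function(df) {
    if (nrow(df) == 0L) return(df)
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  ok <- setequal(a$entities, b$entities) &&
    identical(sort_df(a$relations), sort_df(b$relations)) &&
    identical(sort_df(a$grounding_map), sort_df(b$grounding_map)) &&
    identical(sort_df(a$equivalences), sort_df(b$equivalences)) &&
    identical(a$namespace, b$namespace)
  if (ok && affixes) ok <- identical(sort_df(a$affixes), sort_df(b$affixes))
  ok
}
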