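#' Member tables for cross-ontology comparison
#'
#' A member table maps each family/complex identifier to the set of
#' gene-level members it resolves to, with genes drawn from one shared
#' namespace so sets from different resources are comparable.  Accepted
#' forms: a named list of character vectors, or a two-column data.frame
#' (group id, gene id).
#'
#' @param x named list or two-column data.frame
#' @return named list of unique character vectors
#' @export
as_member_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2L)
    x <- split(as.character(x[[2L]]), as.character(x[[1L]]))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("member table groups must be named", call. = FALSE)
  }
  lapply(x, function(v) unique(as.character(v)))
}

#' Member table of an ontology's families and complexes
#'
#' @param ont a validated [ontology()]
#' @param graph optional pre-built [hierarchy_graph()]
#' @return named list: identifier -> character vector of gene references
#' @export
member_table <- function(ont, graph = NULL) {
  graph <- graph %||% hierarchy_graph(ont)
  members <- lapply(ont$entities, function(e) gene_members(graph, e))
  stats::setNames(members, ont$entities)
}

#' Propose cross-ontology equivalences by member-set comparison
#'
#' Supports the semi-automated curation step in which each family/complex is
#' compared, by its gene-level member set, against the families of an
#' external resource.  `exact_set` mode (the default) proposes a mapping
#' only when the member sets are identical — so e.g. a 3-gene family is not
#' mapped to a 145-member external family that merely contains it.
#' `subset` mode also proposes containments; `jaccard` mode scores all
#' pairs by \eqn{|A \cap B| / |A \cup B|} and keeps those at or above
#' `threshold`.  Proposals are curation candidates, never auto-merged.
#'
#' @param famplex_members member table of this resource (see
#'   [as_member_table()])
#' @param external_members member table of the external resource
#' @param mode `"exact_set"`, `"subset"` or `"jaccard"`
#' @param threshold minimum Jaccard score (jaccard mode), in `[0, 1]`
#' @return data.frame with columns famplex_id, external_id, match_mode,
#'   score, sorted by famplex_id then score (descending) then external_id;
#'   groups with empty member sets are skipped with a warning
#' @export
propose_equivalences <- function(famplex_members, external_members,
                                 mode = c("exact_set", "subset", "jaccard"),
                                 threshold = 0.8) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  fam <- as_member_table(famplex_members)
  ext <- as_member_table(external_members)
  drop_empty <- function(tab, label) {
    empty <- lengths(tab) == 0L
    if (any(empty)) {
      warning(sprintf("skipping %s group(s) with empty member sets: %s", label,
                      paste(names(tab)[empty], collapse = ", ")), call. = FALSE)
    }
    tab[!empty]
  }
  fam <- drop_empty(fam, "famplex")
  ext <- drop_empty(ext, "external")

  out <- list()
  for (f in names(fam)) {
    for (e in names(ext)) {
      a <- fam[[f]]
      b <- ext[[e]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      keep <- switch(mode,
        exact_set = setequal(a, b),
        subset = all(a %in% b) || all(b %in% a),
        jaccard = jac >= threshold
      )
      if (keep) {
        out[[length(out) + 1L]] <- data.frame(
          famplex_id = f, external_id = e, match_mode = mode, score = jac,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(famplex_id = character(), external_id = character(),
                      match_mode = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$famplex_id, -res$score, res$external_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Levenshtein edit distance
#'
#' Unit-cost edit distance (insertions, deletions, substitutions), the
#' fuzzy-matching primitive used to surface synonym candidates during
#' curation.  Case-sensitive by default because gene symbols are
#' case-meaningful.
#'
#' @param a,b character vectors (recycled to a common length)
#' @param case_sensitive compare case-sensitively (default)
#' @return integer vector of distances
#' @export
#' @examples
#' levenshtein("ERK1/2", "ERK 1/2")  # 1
levenshtein <- function(a, b, case_sensitive = TRUE) {
  if (!case_sensitive) {
    a <- tolower(a)
    b <- tolower(b)
  }
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  as.integer(diag(utils::adist(a, b, costs = 1L)))
}

#' Similarity score between two strings
#'
#' `1 - d / max(nchar(a), nchar(b))` where `d` is the Levenshtein distance;
#' 1 exactly when the strings are identical, 0 when they share nothing.
#' Two empty strings are identical (similarity 1).
#'
#' @inheritParams levenshtein
#' @return numeric vector in `[0, 1]`
#' @export
string_similarity <- function(a, b, case_sensitive = TRUE) {
  d <- levenshtein(a, b, case_sensitive)
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  maxlen <- pmax(nchar(a), nchar(b))
  ifelse(maxlen == 0L, 1, 1 - d / maxlen)
}

#' Propose synonym candidates by fuzzy string matching
#'
#' Compares entity names (and existing synonyms) against strings observed in
#' a corpus and returns close matches for manual curation.
#'
#' @param entity_names character vector of known names/synonyms
#' @param corpus_strings character vector of candidate surface strings
#' @param threshold minimum similarity (see [string_similarity()]) to keep
#' @param case_sensitive compare case-sensitively (default)
#' @return data.frame with columns entity_name, corpus_string, distance,
#'   similarity; sorted by similarity (descending), then entity_name, then
#'   corpus_string
#' @export
propose_synonyms <- function(entity_names, corpus_strings, threshold = 0.8,
                             case_sensitive = TRUE) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  entity_names <- unique(as.character(entity_names))
  corpus_strings <- unique(as.character(corpus_strings))
  if (length(entity_names) == 0L || length(corpus_strings) == 0L) {
    return(data.frame(entity_name = character(), corpus_string = character(),
                      distance = integer(), similarity = numeric(),
                      stringsAsFactors = FALSE))
  }
  ea <- if (case_sensitive) entity_names else tolower(entity_names)
  cb <- if (case_sensitive) corpus_strings else tolower(corpus_strings)
  d <- utils::adist(ea, cb, costs = 1L)
  maxlen <- outer(nchar(entity_names), nchar(corpus_strings), pmax)
  sim <- ifelse(maxlen == 0L, 1, 1 - d / maxlen)
  keep <- which(sim >= threshold, arr.ind = TRUE)
  res <- data.frame(
    entity_name = entity_names[keep[, 1L]],
    corpus_string = corpus_strings[keep[, 2L]],
    distance = as.integer(d[keep]),
    similarity = as.numeric(sim[keep]),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$similarity, res$entity_name, res$corpus_string,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}
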