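# Independent brute-force oracles. These work directly on the relation
# table (edge list) or on plain strings, deliberately avoiding the package's
# adjacency-list traversal, DP edit distance and OBO writer code paths.

# All nodes reachable from `start` along edges in the given direction, by
# exhaustive path enumeration over the raw edge list.
oracle_reach <- function(relations, start, direction = c("up", "down")) {
  direction <- match.arg(direction)
  from <- paste0(relations$subject_ns, ":", relations$subject_id)
  to <- paste0(relations$object_ns, ":", relations$object_id)
  if (direction == "down") {
    tmp <- from
    from <- to
    to <- tmp
  }
  seen <- character()
  stack <- to[from == start]
  while (length(stack) > 0L) {
    n <- stack[[1L]]
    stack <- stack[-1L]
    if (n %in% seen) next
    seen <- c(seen, n)
    stack <- c(stack, to[from == n])
  }
  sort(seen)
}

# Longest chain from `node` down to a childless node, by recursive DFS on
# the raw edge list.
oracle_depth <- function(relations, node) {
  from <- paste0(relations$subject_ns, ":", relations$subject_id)
  to <- paste0(relations$object_ns, ":", relations$object_id)
  recurse <- function(n) {
    kids <- from[to == n]
    if (length(kids) == 0L) return(0L)
    1L + max(vapply(kids, recurse, integer(1)))
  }
  recurse(node)
}

# Naive memoized recursive Levenshtein distance.
oracle_lev <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0L) {
      j
    } else if (j == 0L) {
      i
    } else {
      cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
      min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L, rec(i - 1L, j - 1L) + cost)
    }
    memo[[key]] <- res
    res
  }
  rec(nchar(a), nchar(b))
}

# All-pairs Jaccard ranking by explicit element counting.
oracle_jaccard_pairs <- function(fam, ext) {
  out <- list()
  for (f in names(fam)) {
    for (e in names(ext)) {
      u <- unique(c(fam[[f]], ext[[e]]))
      inter <- sum(vapply(u, function(g) g %in% fam[[f]] && g %in% ext[[e]], logical(1)))
      out[[length(out) + 1L]] <- data.frame(
        famplex_id = f, external_id = e, score = inter / length(u),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# Minimal regex-based OBO reader, independent of parse_obo(), used as the
# round-trip oracle: extracts term ids, synonym texts and is_a/part_of edges.
oracle_obo_extract <- function(obo_text) {
  lines <- strsplit(obo_text, "\n", fixed = TRUE)[[1]]
  ids <- sub("^id: ", "", grep("^id: ", lines, value = TRUE))
  syn <- sub('^synonym: "(.*)" EXACT \\[\\]$', "\\1", grep("^synonym: ", lines, value = TRUE))
  isa <- sub("^is_a: ", "", grep("^is_a: ", lines, value = TRUE))
  partof <- sub("^relationship: part_of ", "", grep("^relationship: part_of ", lines, value = TRUE))
  list(ids = ids, synonyms = gsub('\\\\"', '"', syn), isa = isa, partof = partof)
}

# Write an ontology-like set of raw CSV fixture files for the IO tests.
write_fixture_csv <- function(lines, name, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

# A small hand-written resource directory (valid) for load tests.
make_resource_dir <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  writeLines(c("AKT", "AMPK", "RAS"), file.path(dir, "entities.csv"))
  writeLines(c(
    "HGNC,AKT1,isa,FPLX,AKT",
    "HGNC,KRAS,isa,FPLX,RAS",
    "HGNC,NRAS,isa,FPLX,RAS"
  ), file.path(dir, "relations.csv"))
  writeLines(c(
    'Akt,FPLX,AKT',
    '"RAS, wild-type",FPLX,RAS',
    "AKT1,HGNC,AKT1"
  ), file.path(dir, "grounding_map.csv"))
  writeLines("BEL,akt-family,AKT", file.path(dir, "equivalences.csv"))
  writeLines(c(
    "phospho-{Gene name},prefix,protein_state",
    "mmu-{Gene name},prefix,species,mouse"
  ), file.path(dir, "gene_prefixes.csv"))
  dir
}
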