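#' @name resource_files
#' @title The five-file tabular resource format
#' @description
#' The resource lives in five comma-separated, UTF-8, headerless CSV files
#' in one directory (quoted fields allowed):
#' \describe{
#'   \item{entities.csv}{one local identifier per row}
#'   \item{relations.csv}{subject_ns, subject_id, relation, object_ns,
#'     object_id — relation is `isa` or `partof`, edges child -> parent}
#'   \item{grounding_map.csv}{text, target_ns, target_id — text keys
#'     verbatim, case preserved}
#'   \item{equivalences.csv}{external_ns, external_id, famplex_id}
#'   \item{gene_prefixes.csv}{pattern, position, category\[, species_tag\] —
#'     pattern carries a single `{Gene name}` placeholder}
#' }
#' Written files are sorted (C locale) so exports are diff-stable.
NULL

resource_file_names <- function() {
  c(entities = "entities.csv", relations = "relations.csv",
    grounding_map = "grounding_map.csv", equivalences = "equivalences.csv",
    affixes = "gene_prefixes.csv")
}

# Parse a headerless CSV into a list of character-vector rows plus issues.
# Field counts outside [n_min, n_max] yield malformed_row issues and the row
# is dropped; an empty file yields an empty_file warning.
read_csv_rows <- function(path, n_min, n_max, file_label) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  rows <- vector("list", sum(keep))
  rownum <- integer(sum(keep))
  j <- 0L
  issues <- no_issues()
  for (i in which(keep)) {
    fields <- scan(text = lines[[i]], what = character(), sep = ",",
                   quote = "\"", quiet = TRUE, na.strings = character(),
                   strip.white = FALSE)
    if (length(fields) < n_min || length(fields) > n_max) {
      issues <- rbind(issues, validation_issue(
        "error", "malformed_row",
        sprintf("expected %s fields, found %d",
                if (n_min == n_max) n_min else paste(n_min, "to", n_max),
                length(fields)),
        file = file_label, row = i
      ))
      next
    }
    j <- j + 1L
    rows[[j]] <- fields
    rownum[[j]] <- i
  }
  if (j == 0L && nrow(issues) == 0L) {
    issues <- rbind(issues, validation_issue(
      "warning", "empty_file", sprintf("%s contains no rows", file_label),
      file = file_label
    ))
  }
  list(rows = rows[seq_len(j)], rownum = rownum[seq_len(j)], issues = issues)
}

rows_to_frame <- function(rows, cols, pad = FALSE) {
  if (length(rows) == 0L) return(chr_frame(cols))
  if (pad) {
    rows <- lapply(rows, function(r) c(r, rep("", length(cols) - length(r))))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  as.data.frame(m, stringsAsFactors = FALSE)
}

#' Load the entity list
#'
#' @param path path to `entities.csv` (one identifier per row)
#' @param strict stop on error-severity issues (default); otherwise the
#'   issues are attached as the `"issues"` attribute
#' @return character vector of identifiers (file order, duplicates removed)
#' @export
load_entities <- function(path, strict = TRUE) {
  parsed <- read_csv_rows(path, 1L, 1L, "entities.csv")
  ids <- trimws(vapply(parsed$rows, `[[`, character(1), 1L))
  issues <- parsed$issues
  dup <- which(duplicated(ids))
  for (i in dup) {
    issues <- rbind(issues, validation_issue(
      "error", "duplicate_entity",
      sprintf("entity '%s' listed more than once", ids[i]),
      file = "entities.csv", row = parsed$rownum[i]
    ))
  }
  raise_issues(issues, strict)
  structure(unique(ids), issues = issues)
}

#' Load the relation table
#'
#' @param path path to `relations.csv`
#' @inheritParams load_entities
#' @return data.frame (file order) with columns subject_ns, subject_id, rel,
#'   object_ns, object_id
#' @export
load_relations <- function(path, strict = TRUE) {
  parsed <- read_csv_rows(path, 5L, 5L, "relations.csv")
  df <- rows_to_frame(parsed$rows, names(empty_relations()))
  issues <- parsed$issues
  bad <- which(!df$rel %in% c("isa", "partof"))
  for (i in bad) {
    issues <- rbind(issues, validation_issue(
      "error", "invalid_relation",
      sprintf("unknown relation token '%s'", df$rel[i]),
      file = "relations.csv", row = parsed$rownum[i]
    ))
  }
  raise_issues(issues, strict)
  structure(df[!seq_len(nrow(df)) %in% bad, , drop = FALSE], issues = issues)
}

#' Load the grounding map
#'
#' @param path path to `grounding_map.csv`
#' @inheritParams load_entities
#' @return data.frame with columns text, target_ns, target_id; text keys are
#'   verbatim (case preserved) and unique
#' @export
load_grounding_map <- function(path, strict = TRUE) {
  parsed <- read_csv_rows(path, 3L, 3L, "grounding_map.csv")
  df <- rows_to_frame(parsed$rows, names(empty_grounding_map()))
  issues <- parsed$issues
  dup <- which(duplicated(df$text))
  for (i in dup) {
    issues <- rbind(issues, validation_issue(
      "error", "duplicate_synonym",
      sprintf("grounding-map text '%s' has multiple targets", df$text[i]),
      file = "grounding_map.csv", row = parsed$rownum[i]
    ))
  }
  raise_issues(issues, strict)
  structure(df[!seq_len(nrow(df)) %in% dup, , drop = FALSE], issues = issues)
}

#' Load the equivalence table
#'
#' @param path path to `equivalences.csv`
#' @inheritParams load_entities
#' @return data.frame with columns external_ns, external_id, famplex_id
#' @export
load_equivalences <- function(path, strict = TRUE) {
  parsed <- read_csv_rows(path, 3L, 3L, "equivalences.csv")
  df <- rows_to_frame(parsed$rows, names(empty_equivalences()))
  raise_issues(parsed$issues, strict)
  structure(df, issues = parsed$issues)
}

#' Load the affix table
#'
#' @param path path to `gene_prefixes.csv` (3 or 4 fields per row; the
#'   fourth field is the species tag, only meaningful for species affixes)
#' @inheritParams load_entities
#' @return data.frame with columns pattern, position, category, species_tag
#' @export
load_affixes <- function(path, strict = TRUE) {
  parsed <- read_csv_rows(path, 3L, 4L, "gene_prefixes.csv")
  df <- rows_to_frame(parsed$rows, names(empty_affixes()), pad = TRUE)
  issues <- parsed$issues
  for (i in seq_len(nrow(df))) {
    hits <- gregexpr(AFFIX_PLACEHOLDER, df$pattern[i], fixed = TRUE)[[1]]
    if (length(hits[hits > 0]) != 1L) {
      issues <- rbind(issues, validation_issue(
        "error", "malformed_affix",
        sprintf("affix pattern '%s' must contain exactly one '%s' placeholder",
                df$pattern[i], AFFIX_PLACEHOLDER),
        file = "gene_prefixes.csv", row = parsed$rownum[i]
      ))
    }
  }
  raise_issues(issues, strict)
  structure(df, issues = issues)
}

#' Load a full ontology from a resource directory
#'
#' Reads the five resource files (see [resource_files]) and validates the
#' assembled ontology.
#'
#' @param dir directory containing the five CSV files
#' @param namespace the resource's own namespace token
#' @param namespaces controlled namespace vocabulary
#' @param strict stop if validation finds errors
#' @return a validated [ontology()]
#' @export
load_ontology <- function(dir, namespace = "FPLX",
                          namespaces = default_namespaces(), strict = TRUE) {
  fn <- resource_file_names()
  parts <- list(
    entities = load_entities(file.path(dir, fn[["entities"]]), strict = strict),
    relations = load_relations(file.path(dir, fn[["relations"]]), strict = strict),
    grounding_map = load_grounding_map(file.path(dir, fn[["grounding_map"]]), strict = strict),
    equivalences = load_equivalences(file.path(dir, fn[["equivalences"]]), strict = strict),
    affixes = load_affixes(file.path(dir, fn[["affixes"]]), strict = strict)
  )
  load_issues <- do.call(rbind, c(list(no_issues()),
                                  lapply(parts, attr, "issues")))
  rownames(load_issues) <- NULL
  ont <- ontology(
    entities = parts$entities, relations = parts$relations,
    grounding_map = parts$grounding_map, equivalences = parts$equivalences,
    affixes = parts$affixes, namespace = namespace, namespaces = namespaces
  )
  issues <- validate(ont)
  raise_issues(issues[issues$severity == "error", , drop = FALSE], strict)
  # loader-level findings (duplicates removed during parsing, malformed rows)
  # are preserved for non-strict callers such as the CLI validator
  attr(ont, "load_issues") <- load_issues
  ont
}

write_resource_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df) > 0L) {
    quoted <- vapply(seq_len(nrow(df)), function(i) {
      fields <- as.character(unlist(df[i, , drop = TRUE]))
      needs <- grepl('[",]', fields)
      fields[needs] <- paste0('"', gsub('"', '""', fields[needs]), '"')
      paste(fields, collapse = ",")
    }, character(1))
    writeLines(quoted, con, useBytes = TRUE)
  }
}

#' Write an ontology to the five-file resource format
#'
#' Output is deterministic: every table is sorted with C-locale (radix)
#' ordering so repeated writes of equal ontologies are byte-identical.
#' Affix rows without a species tag are written with three fields.
#'
#' @param ont an [ontology()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory path
#' @export
write_ontology <- function(ont, dir) {
  stopifnot(inherits(ont, "famground_ontology"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- resource_file_names()
  sort_rows <- function(df) {
    if (nrow(df) == 0L) return(df)
    df[do.call(order, c(unname(as.list(df)), list(method = "radix"))), , drop = FALSE]
  }
  ents <- data.frame(id = sort(ont$entities, method = "radix"),
                     stringsAsFactors = FALSE)
  write_resource_csv(ents, file.path(dir, fn[["entities"]]))
  write_resource_csv(sort_rows(ont$relations), file.path(dir, fn[["relations"]]))
  write_resource_csv(sort_rows(ont$grounding_map), file.path(dir, fn[["grounding_map"]]))
  write_resource_csv(sort_rows(ont$equivalences), file.path(dir, fn[["equivalences"]]))
  af <- sort_rows(ont$affixes)
  if (nrow(af) > 0L) {
    lines <- vapply(seq_len(nrow(af)), function(i) {
      fields <- as.character(unlist(af[i, , drop = TRUE]))
      if (!nzchar(fields[[4L]])) fields <- fields[1:3]
      needs <- grepl('[",]', fields)
      fields[needs] <- paste0('"', gsub('"', '""', fields[needs]), '"')
      paste(fields, collapse = ",")
    }, character(1))
    con <- file(file.path(dir, fn[["affixes"]]), open = "wb")
    writeLines(lines, con, useBytes = TRUE)
    close(con)
  } else {
    file.create(file.path(dir, fn[["affixes"]]))
  }
  invisible(dir)
}
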