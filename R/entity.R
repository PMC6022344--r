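#' Namespaced entity references
#'
#' An entity reference pairs a namespace token (the resource's own namespace
#' for families/complexes, a gene-symbol namespace such as `"HGNC"` for
#' gene-level leaves, or an external database namespace) with a local
#' identifier.  References are represented throughout the package as
#' `"NAMESPACE:identifier"` strings so they can live in plain character
#' vectors and be compared with set operations.
#'
#' @param ns namespace token (no colon, no surrounding whitespace)
#' @param id local identifier (non-empty, no surrounding whitespace)
#' @return character vector of `"ns:id"` references
#' @export
#' @examples
#' entity_ref("FPLX", "AMPK")
#' ref_ns("HGNC:PLCG1")
#' ref_id("HGNC:PLCG1")
entity_ref <- function(ns, id) {
  ns <- as.character(ns)
  id <- as.character(id)
  if (length(ns) == 0L || length(id) == 0L) return(character())
  if (any(ns != trimws(ns)) || any(id != trimws(id))) {
    stop("namespace and identifier must not have surrounding whitespace", call. = FALSE)
  }
  if (any(!nzchar(id))) stop("identifier must be non-empty", call. = FALSE)
  if (any(grepl(":", ns, fixed = TRUE))) {
    stop("namespace must not contain ':'", call. = FALSE)
  }
  paste0(ns, ":", id)
}

#' @rdname entity_ref
#' @param ref character vector of `"ns:id"` references
#' @export
ref_ns <- function(ref) sub(":.*$", "", ref)

#' @rdname entity_ref
#' @export
ref_id <- function(ref) sub("^[^:]*:", "", ref)

#' Default namespace vocabulary
#'
#' The controlled vocabulary of namespace tokens accepted by [validate()].
#' Contains the resource's own namespace (`FPLX`), the gene-symbol namespace
#' (`HGNC`), protein (`UP`), family databases (`IP`, `PF`, `NXP`, `RE`,
#' `BEL`), and ontology/vocabulary namespaces (`GO`, `MESH`, `NCIT`).
#'
#' @return character vector of namespace tokens
#' @export
default_namespaces <- function() {
  c("FPLX", "HGNC", "UP", "IP", "PF", "NXP", "RE", "BEL", "GO", "MESH", "NCIT")
}

# Affix semantic categories (fixed enumeration).
affix_categories <- function() {
  c("experimental_context", "protein_state", "inhibition",
    "generic_descriptor", "species", "mrna_grounding")
}

# Placeholder token inside affix patterns.
AFFIX_PLACEHOLDER <- "{Gene name}"

#' Construct a validation issue table
#'
#' Issues are plain data frames with one row per finding.  `severity` is
#' `"error"` for invariant violations and `"warning"` for suspicious but
#' non-fatal content.  `code` is drawn from a documented enumeration (see
#' [issue_codes()]).
#'
#' @param severity `"error"` or `"warning"`
#' @param code issue code token
#' @param message human-readable description
#' @param file source file (or `NA`)
#' @param row 1-based row number in `file` (or `NA`)
#' @return data.frame with columns severity, code, message, file, row
#' @export
validation_issue <- function(severity, code, message, file = NA_character_, row = NA_integer_) {
  stopifnot(severity %in% c("error", "warning"))
  data.frame(
    severity = severity, code = code, message = message,
    file = as.character(file), row = as.integer(row),
    stringsAsFactors = FALSE
  )
}

no_issues <- function() {
  validation_issue("error", "x", "x")[0L, , drop = FALSE]
}

#' Documented validation issue codes
#'
#' @return named character vector mapping code to description
#' @export
issue_codes <- function() {
  c(
    duplicate_entity     = "an identifier appears more than once in the entity list",
    duplicate_synonym    = "a grounding-map text key appears more than once",
    malformed_row        = "a CSV row has the wrong number of fields",
    invalid_relation     = "a relation token is not 'isa' or 'partof'",
    self_relation        = "a relation has identical subject and object",
    malformed_affix      = "an affix pattern lacks exactly one gene-name placeholder",
    invalid_affix        = "an affix category or position is outside its enumeration",
    dangling_relation    = "a relation endpoint in the resource namespace is not in the entity list",
    dangling_equivalence = "an equivalence refers to an identifier not in the entity list",
    dangling_grounding   = "a grounding-map target in the resource namespace is not in the entity list",
    invalid_namespace    = "a namespace token is outside the controlled vocabulary",
    cycle                = "the relation graph contains a directed cycle",
    empty_file           = "a resource file contains no rows"
  )
}

issues_condition <- function(issues) {
  msg <- paste0(
    "ontology validation failed:\n",
    paste0("  [", issues$severity, "] ", issues$code, ": ", issues$message,
           ifelse(is.na(issues$file), "", paste0(" (", issues$file,
                  ifelse(is.na(issues$row), "", paste0(":", issues$row)), ")")),
           collapse = "\n")
  )
  structure(
    class = c("famground_validation_error", "error", "condition"),
    list(message = msg, call = NULL, issues = issues)
  )
}

# Stop with a classed condition if any error-severity issue is present;
# surface warnings as R warnings.
raise_issues <- function(issues, strict = TRUE) {
  if (nrow(issues) == 0L) return(invisible(issues))
  warn <- issues[issues$severity == "warning", , drop = FALSE]
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(warn) > 0L) {
    for (i in seq_len(nrow(warn))) {
      warning(sprintf("[%s] %s", warn$code[i], warn$message[i]), call. = FALSE)
    }
  }
  if (strict && nrow(errs) > 0L) stop(issues_condition(errs))
  invisible(issues)
}
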