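#' Export an ontology to OBO format
#'
#' Emits one `[Term]` stanza per entity in the resource namespace and one per
#' external (gene-level) node appearing in the relation table or as a
#' grounding-map target.  Family membership (`isa`) becomes an OBO `is_a`
#' line; complex membership (`partof`) becomes a
#' `relationship: part_of` line, with a closing `[Typedef]` stanza defining
#' `part_of`.  Grounding-map synonyms become `synonym: "..." EXACT []`
#' lines and equivalences become `xref:` lines.  Output is deterministic:
#' stanzas and lines are sorted (C locale).
#'
#' @param ont a validated [ontology()]; refused (with the validation issues
#'   in the condition) if validation reports errors
#' @return a single string of OBO 1.2 text
#' @seealso [parse_obo()] for the inverse on entities, relations, synonyms
#'   and equivalences (affixes are not represented in OBO)
#' @export
export_obo <- function(ont) {
  issues <- validate(ont)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) stop(issues_condition(errs))

  own <- ont$namespace
  rel <- ont$relations
  gm <- ont$grounding_map
  eq <- ont$equivalences

  subj_ref <- if (nrow(rel)) entity_ref(rel$subject_ns, rel$subject_id) else character()
  obj_ref <- if (nrow(rel)) entity_ref(rel$object_ns, rel$object_id) else character()
  gm_ref <- if (nrow(gm)) entity_ref(gm$target_ns, gm$target_id) else character()

  own_refs <- sort(entity_ref(own, ont$entities), method = "radix")
  ext_refs <- sort(setdiff(unique(c(subj_ref, obj_ref, gm_ref)),
                           entity_ref(own, ont$entities)), method = "radix")

  stanza <- function(ref) {
    lines <- c("[Term]", paste0("id: ", ref), paste0("name: ", ref_id(ref)))
    syn <- sort(gm$text[gm_ref == ref], method = "radix")
    lines <- c(lines, sprintf('synonym: "%s" EXACT []', gsub('"', '\\\\"', syn)))
    if (ref_ns(ref) == own && nrow(eq) > 0L) {
      xr <- eq[eq$famplex_id == ref_id(ref), , drop = FALSE]
      if (nrow(xr) > 0L) {
        lines <- c(lines, sort(sprintf("xref: %s", entity_ref(xr$external_ns, xr$external_id)),
                               method = "radix"))
      }
    }
    isa_parents <- sort(obj_ref[subj_ref == ref & rel$rel == "isa"], method = "radix")
    po_parents <- sort(obj_ref[subj_ref == ref & rel$rel == "partof"], method = "radix")
    lines <- c(lines, sprintf("is_a: %s", isa_parents),
               sprintf("relationship: part_of %s", po_parents))
    lines
  }

  blocks <- lapply(c(own_refs, ext_refs), stanza)
  header <- c("format-version: 1.2", paste0("ontology: ", tolower(own)))
  typedef <- c("[Typedef]", "id: part_of", "name: part of")
  paste(
    c(header, "", unlist(lapply(blocks, function(b) c(b, ""))), typedef, ""),
    collapse = "\n"
  )
}

#' Parse OBO text into an ontology
#'
#' The inverse of [export_obo()] on its image: reconstructs the entity list
#' (term ids in the resource namespace), relations (`is_a` and
#' `relationship: part_of` lines), grounding-map synonyms and equivalences
#' (`xref` lines).  Affix tables are not represented in OBO and come back
#' empty.
#'
#' @param text OBO text, as a single string or a character vector of lines
#' @param namespace the resource's own namespace token
#' @param namespaces controlled namespace vocabulary
#' @return an [ontology()]
#' @export
parse_obo <- function(text, namespace = "FPLX", namespaces = default_namespaces()) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  entities <- character()
  relations <- list()
  grounding <- list()
  equivalences <- list()
  in_term <- FALSE
  cur_id <- NULL

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "!")) next
    if (line == "[Term]") {
      in_term <- TRUE
      cur_id <- NULL
      next
    }
    if (startsWith(line, "[")) {  # e.g. [Typedef]
      in_term <- FALSE
      next
    }
    if (!grepl("^[A-Za-z_-]+:", line)) {
      stop(sprintf("malformed OBO line %d: '%s'", i, line), call. = FALSE)
    }
    if (!in_term) next
    key <- sub(":.*$", "", line)
    val <- trimws(sub("^[A-Za-z_-]+:", "", line))
    if (key == "id") {
      if (!grepl(":", val, fixed = TRUE)) {
        stop(sprintf("malformed term id at line %d: '%s'", i, val), call. = FALSE)
      }
      cur_id <- val
      if (ref_ns(val) == namespace) entities <- c(entities, ref_id(val))
      next
    }
    if (is.null(cur_id)) {
      stop(sprintf("stanza field before id at line %d", i), call. = FALSE)
    }
    if (key == "synonym") {
      m <- regmatches(val, regexec('^"((?:[^"\\\\]|\\\\.)*)"', val))[[1]]
      if (length(m) < 2L) {
        stop(sprintf("malformed synonym at line %d: '%s'", i, val), call. = FALSE)
      }
      grounding[[length(grounding) + 1L]] <- c(
        text = gsub('\\\\"', '"', m[[2]]), target_ns = ref_ns(cur_id),
        target_id = ref_id(cur_id)
      )
    } else if (key == "is_a") {
      relations[[length(relations) + 1L]] <- c(
        subject_ns = ref_ns(cur_id), subject_id = ref_id(cur_id), rel = "isa",
        object_ns = ref_ns(val), object_id = ref_id(val)
      )
    } else if (key == "relationship") {
      parts <- strsplit(val, "[[:space:]]+")[[1]]
      if (length(parts) < 2L || parts[[1]] != "part_of") {
        stop(sprintf("malformed relationship at line %d: '%s'", i, val), call. = FALSE)
      }
      relations[[length(relations) + 1L]] <- c(
        subject_ns = ref_ns(cur_id), subject_id = ref_id(cur_id), rel = "partof",
        object_ns = ref_ns(parts[[2]]), object_id = ref_id(parts[[2]])
      )
    } else if (key == "xref") {
      equivalences[[length(equivalences) + 1L]] <- c(
        external_ns = ref_ns(val), external_id = ref_id(val),
        famplex_id = ref_id(cur_id)
      )
    }
    # name and other tags carry no extra information in this profile
  }

  to_df <- function(lst, empty) {
    if (length(lst) == 0L) return(empty)
    as.data.frame(do.call(rbind, lst), stringsAsFactors = FALSE)
  }
  ontology(
    entities = unique(entities),
    relations = to_df(relations, empty_relations()),
    grounding_map = to_df(grounding, empty_grounding_map()),
    equivalences = to_df(equivalences, empty_equivalences()),
    namespace = namespace, namespaces = namespaces
  )
}
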