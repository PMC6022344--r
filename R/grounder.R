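#' Strip case-sensitive gene/protein affixes from an entity string
#'
#' Gene and protein mentions in text are frequently decorated with affixes
#' describing experimental context ("eGFP-AKT1"), modification state
#' ("pAKT1"), inhibition ("BRAF siRNA"), generic descriptors, species
#' ("mmu-AKT1") or transcript reference ("AKT1 mRNA").  This function
#' removes such affixes iteratively (longest matching pattern first,
#' prefixes before suffixes on ties, repeated to a fixed point so stacked
#' decorations like "phospho-mmu-AKT1" resolve) and aggregates their
#' semantics:
#' \itemize{
#'   \item inhibition affixes set `polarity_inverted` — a positive
#'     regulation event mediated by a gene's siRNA is a negative regulation
#'     by the gene itself;
#'   \item species affixes record the species tag;
#'   \item protein-state affixes accumulate as state modifiers;
#'   \item the mRNA affix sets `is_mrna` while still exposing the core gene.
#' }
#' Matching is case-sensitive.  Input whitespace is trimmed and internal
#' runs collapsed to a single space before matching.
#'
#' @param text a single entity string
#' @param affixes affix table (columns pattern, position, category,
#'   species_tag), e.g. `inpaper_ontology()$affixes`
#' @return list with `core_text`, `matches` (data.frame pattern, position,
#'   category, species_tag, matched_span), `polarity_inverted`, `species`
#'   (`NA` if none), `state_modifiers`, `is_mrna`
#' @export
#' @examples
#' af <- inpaper_ontology()$affixes
#' strip_affixes("mmu-AKT1", af)$core_text       # "AKT1"
#' strip_affixes("BRAF siRNA", af)$polarity_inverted
strip_affixes <- function(text, affixes) {
  stopifnot_scalar_chr(text, "text")
  core <- normalize_whitespace(text)
  af <- as_chr_df(affixes, names(empty_affixes()))
  matches <- cbind(empty_affixes(), data.frame(matched_span = character()))

  if (nrow(af) > 0L) {
    parts <- lapply(af$pattern, function(p) {
      sp <- strsplit(p, AFFIX_PLACEHOLDER, fixed = TRUE)[[1]]
      c(if (length(sp) >= 1L) sp[[1L]] else "",
        if (length(sp) >= 2L) sp[[2L]] else "")
    })
    pre <- vapply(parts, `[[`, character(1), 1L)
    post <- vapply(parts, `[[`, character(1), 2L)
    lit_len <- nchar(pre) + nchar(post)
    # longest literal first; prefixes win ties
    ord <- order(-lit_len, af$position != "prefix", af$pattern, method = "radix")
    repeat {
      applied <- FALSE
      for (i in ord) {
        p <- pre[[i]]
        s <- post[[i]]
        if (!nzchar(p) && !nzchar(s)) next
        if (nchar(core) <= lit_len[[i]]) next
        if (startsWith(core, p) && endsWith(core, s)) {
          inner <- substr(core, nchar(p) + 1L, nchar(core) - nchar(s))
          if (!nzchar(trimws(inner))) next
          matches <- rbind(matches, cbind(
            af[i, , drop = FALSE],
            data.frame(matched_span = paste0(p, s), stringsAsFactors = FALSE)
          ))
          core <- trimws(inner)
          applied <- TRUE
          break
        }
      }
      if (!applied) break
    }
  }
  rownames(matches) <- NULL
  species <- matches$species_tag[matches$category == "species" & nzchar(matches$species_tag)]
  list(
    core_text = core,
    matches = matches,
    polarity_inverted = any(matches$category == "inhibition"),
    species = if (length(species) > 0L) species[[1L]] else NA_character_,
    state_modifiers = matches$matched_span[matches$category == "protein_state"],
    is_mrna = any(matches$category == "mrna_grounding")
  )
}

#' Ground an entity string to a namespaced identifier
#'
#' Normalizes the string, strips affixes (see [strip_affixes()]), and looks
#' the core string up in the ontology's grounding map.  The default policy
#' is an exact, case-sensitive lookup (the high-precision behaviour expected
#' of a curated synonym dictionary); `"case_insensitive_fallback"` retries a
#' case-folded match when the exact one misses, the behaviour used when
#' evaluating recall against externally curated corpora.
#'
#' @param text a single entity string (NER output)
#' @param ont a validated [ontology()]
#' @param policy `"exact"` or `"case_insensitive_fallback"`
#' @return object of class `famground_grounding`: list with `input_text`,
#'   `core_text`, `entity` (full `"NS:ID"` reference, or `NA` if the core
#'   string is absent from the grounding map), `affix_matches`,
#'   `polarity_inverted`, `species`, `state_modifiers`, `is_mrna`
#' @export
#' @examples
#' ont <- inpaper_ontology()
#' ground("NF-kB", ont)$entity            # "FPLX:NFkappaB"
#' ground("shRNA-ERK 1/2", ont)$polarity_inverted
ground <- function(text, ont, policy = c("exact", "case_insensitive_fallback")) {
  policy <- match.arg(policy)
  stopifnot(inherits(ont, "famground_ontology"))
  stripped <- strip_affixes(text, ont$affixes)
  gm <- ont$grounding_map
  hit <- which(gm$text == stripped$core_text)
  if (length(hit) == 0L && policy == "case_insensitive_fallback") {
    hit <- which(tolower(gm$text) == tolower(stripped$core_text))
  }
  entity <- if (length(hit) > 0L) {
    entity_ref(gm$target_ns[hit[[1L]]], gm$target_id[hit[[1L]]])
  } else {
    NA_character_
  }
  structure(
    list(
      input_text = text,
      core_text = stripped$core_text,
      entity = entity,
      affix_matches = stripped$matches,
      polarity_inverted = stripped$polarity_inverted,
      species = stripped$species,
      state_modifiers = stripped$state_modifiers,
      is_mrna = stripped$is_mrna
    ),
    class = "famground_grounding"
  )
}

#' @export
print.famground_grounding <- function(x, ...) {
  cat(sprintf("'%s' -> core '%s' -> %s%s%s\n",
              x$input_text, x$core_text,
              if (is.na(x$entity)) "(ungrounded)" else x$entity,
              if (x$polarity_inverted) " [polarity inverted]" else "",
              if (!is.na(x$species)) paste0(" [species ", x$species, "]") else ""))
  invisible(x)
}

#' Ground a string and expand it to gene-level members
#'
#' Combines [ground()] with [gene_members()]: the second element is the set
#' of gene-level leaves of the grounded entity, empty when the string is
#' ungrounded, grounded outside the hierarchy, or grounded to a placeholder.
#'
#' @inheritParams ground
#' @param graph optional pre-built [hierarchy_graph()] (rebuilt from `ont`
#'   when omitted)
#' @return list with elements `grounding` (a `famground_grounding`) and
#'   `genes` (character vector of gene-level references)
#' @export
ground_and_expand <- function(text, ont,
                              policy = c("exact", "case_insensitive_fallback"),
                              graph = NULL) {
  res <- ground(text, ont, policy)
  genes <- character()
  if (!is.na(res$entity)) {
    graph <- graph %||% hierarchy_graph(ont)
    if (res$entity %in% graph$nodes) genes <- gene_members(graph, res$entity)
  }
  list(grounding = res, genes = genes)
}
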