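#' The worked-example ontology
#'
#' A small, deterministic ontology assembling the canonical worked examples
#' of the resource format into one validated object:
#' \itemize{
#'   \item NFkappaB — a transcription-factor complex with gene-level members
#'     RELA, RELB, REL, NFKB1, NFKB2 and synonyms "NF-kB", "NF-kappaB",
#'     "NF-kappaB TFs";
#'   \item ERK — with synonyms "ERK 1/2", "ERKs", "Extracellular Signal
#'     Regulated Kinase" and members MAPK1/MAPK3;
#'   \item AMPK — a heterotrimeric kinase: alpha and beta subunit families
#'     with two isoforms each and a gamma family with three, linked with
#'     `isa` (gene -> subunit family) and `partof` (family -> complex);
#'   \item PLC — a two-level family: subfamilies PLCB (4 genes), PLCG
#'     (PLCG1, PLCG2) and PLCD (3 genes) plus the direct gene members PLCE1
#'     and PLCZ1, a 15-node sub-hierarchy subsuming 9 genes through
#'     subfamilies.  The PLCB/PLCD memberships (4 and 3 genes) are a fixture
#'     convention chosen to reach the printed subfamily total of nine;
#'   \item RAS (KRAS, NRAS, HRAS) and RAF (ARAF, BRAF, RAF1) — single-level
#'     families;
#'   \item GTPase, Phosphatase, Protease — placeholder entries with no
#'     relations;
#'   \item seven representative affixes covering all six semantic categories
#'     (including both "shRNA-\{Gene name\}" and "\{Gene name\} siRNA" for
#'     inhibition).
#' }
#' Every entity and gene also carries its own symbol as a grounding-map
#' synonym, plus "PLCgamma" for PLCG and "AKT1" as an off-hierarchy gene
#' entry.
#'
#' @return a validated [ontology()]
#' @export
#' @examples
#' ont <- inpaper_ontology()
#' g <- hierarchy_graph(ont)
#' length(gene_members(g, "NFkappaB"))  # 5
#' subsumed_depth(g, "PLC")            # 2
inpaper_ontology <- function() {
  entities <- c(
    "AMPK", "AMPK_alpha", "AMPK_beta", "AMPK_gamma", "ERK", "GTPase",
    "NFkappaB", "PLC", "PLCB", "PLCD", "PLCG", "Phosphatase", "Protease",
    "RAF", "RAS"
  )

  rel <- function(sns, sid, r, ons, oid) {
    data.frame(subject_ns = sns, subject_id = sid, rel = r,
               object_ns = ons, object_id = oid, stringsAsFactors = FALSE)
  }
  isa_genes <- function(genes, parent) rel("HGNC", genes, "isa", "FPLX", parent)
  relations <- rbind(
    rel("FPLX", c("AMPK_alpha", "AMPK_beta", "AMPK_gamma"), "partof", "FPLX", "AMPK"),
    isa_genes(c("PRKAA1", "PRKAA2"), "AMPK_alpha"),
    isa_genes(c("PRKAB1", "PRKAB2"), "AMPK_beta"),
    isa_genes(c("PRKAG1", "PRKAG2", "PRKAG3"), "AMPK_gamma"),
    rel("HGNC", c("RELA", "RELB", "REL", "NFKB1", "NFKB2"), "partof", "FPLX", "NFkappaB"),
    isa_genes(c("MAPK1", "MAPK3"), "ERK"),
    rel("FPLX", c("PLCB", "PLCG", "PLCD"), "isa", "FPLX", "PLC"),
    isa_genes(c("PLCB1", "PLCB2", "PLCB3", "PLCB4"), "PLCB"),
    isa_genes(c("PLCG1", "PLCG2"), "PLCG"),
    isa_genes(c("PLCD1", "PLCD3", "PLCD4"), "PLCD"),
    isa_genes(c("PLCE1", "PLCZ1"), "PLC"),
    isa_genes(c("KRAS", "NRAS", "HRAS"), "RAS"),
    isa_genes(c("ARAF", "BRAF", "RAF1"), "RAF")
  )

  genes <- unique(relations$subject_id[relations$subject_ns == "HGNC"])
  gm <- function(text, ns, id) {
    data.frame(text = text, target_ns = ns, target_id = id, stringsAsFactors = FALSE)
  }
  grounding_map <- rbind(
    gm(entities, "FPLX", entities),
    gm(genes, "HGNC", genes),
    gm(c("NF-kB", "NF-kappaB", "NF-kappaB TFs"), "FPLX", "NFkappaB"),
    gm(c("ERK 1/2", "ERKs", "Extracellular Signal Regulated Kinase"), "FPLX", "ERK"),
    gm("PLCgamma", "FPLX", "PLCG"),
    gm("AKT1", "HGNC", "AKT1")
  )

  equivalences <- data.frame(
    external_ns = c("NCIT", "MESH", "MESH"),
    external_id = c("C94701", "D055372", "D016328"),
    famplex_id = c("AMPK", "AMPK", "NFkappaB"),
    stringsAsFactors = FALSE
  )

  ontology(
    entities = entities,
    relations = relations,
    grounding_map = grounding_map,
    equivalences = equivalences,
    affixes = inpaper_affixes(),
    namespace = "FPLX"
  )
}

#' Representative affix table
#'
#' One example affix per semantic category (with a second inhibition entry
#' for the suffix form), matching the published category examples.
#'
#' @return data.frame with columns pattern, position, category, species_tag
#' @export
inpaper_affixes <- function() {
  data.frame(
    pattern = c("eGFP-{Gene name}", "phospho-{Gene name}", "shRNA-{Gene name}",
                "proto-oncogene {Gene name}", "mmu-{Gene name}",
                "{Gene name} mRNA", "{Gene name} siRNA"),
    position = c("prefix", "prefix", "prefix", "prefix", "prefix",
                 "suffix", "suffix"),
    category = c("experimental_context", "protein_state", "inhibition",
                 "generic_descriptor", "species", "mrna_grounding",
                 "inhibition"),
    species_tag = c("", "", "", "", "mouse", "", ""),
    stringsAsFactors = FALSE
  )
}

#' Generate a random valid ontology
#'
#' Builds a seeded random family/complex hierarchy obeying every structural
#' invariant: a forest of top-level entries whose subsumed depth is drawn
#' from `1:max_depth` (each entry realises its drawn depth on at least one
#' branch), gene-level leaves in the `HGNC` namespace unique to the
#' ontology, a mix of `isa` and `partof` edges, optional placeholder
#' entries, and at least one grounding-map synonym per entity.  The same
#' seed yields a byte-identical serialization via [write_ontology()].
#'
#' @param seed integer RNG seed
#' @param n_families number of top-level entries (>= 1)
#' @param max_depth maximum subsumed depth (>= 1)
#' @param branching maximum children per node (>= 1)
#' @param n_placeholders number of placeholder entries
#' @param p_extra_synonym probability an entity receives a second synonym
#' @return a validated [ontology()]
#' @export
generate_ontology <- function(seed, n_families = 10L, max_depth = 2L,
                              branching = 3L, n_placeholders = 2L,
                              p_extra_synonym = 0.5) {
  if (n_families < 1L || max_depth < 1L || branching < 1L || n_placeholders < 0L) {
    stop("infeasible generator parameters", call. = FALSE)
  }
  with_seed(seed, {
    env <- new.env(parent = emptyenv())
    env$gene_n <- 0L
    env$relations <- list()
    env$entities <- character()

    new_gene <- function() {
      env$gene_n <- env$gene_n + 1L
      sprintf("G%05d", env$gene_n)
    }
    add_rel <- function(sns, sid, ons, oid) {
      env$relations[[length(env$relations) + 1L]] <- data.frame(
        subject_ns = sns, subject_id = sid,
        rel = sample(c("isa", "partof"), 1L),
        object_ns = ons, object_id = oid, stringsAsFactors = FALSE
      )
    }
    build <- function(name, depth) {
      env$entities <- c(env$entities, name)
      if (depth == 1L) {
        for (g in replicate(sample.int(branching, 1L), new_gene())) {
          add_rel("HGNC", g, "FPLX", name)
        }
      } else {
        n_children <- sample.int(branching, 1L)
        for (j in seq_len(n_children)) {
          d <- if (j == 1L) depth - 1L else sample.int(depth - 1L, 1L)
          child <- sprintf("%s_S%d", name, j)
          add_rel("FPLX", child, "FPLX", name)
          build(child, d)
        }
      }
    }

    for (i in seq_len(n_families)) {
      build(sprintf("FAM%03d", i), sample.int(max_depth, 1L))
    }
    placeholders <- if (n_placeholders > 0L) sprintf("PH%02d", seq_len(n_placeholders)) else character()
    env$entities <- c(env$entities, placeholders)

    relations <- do.call(rbind, env$relations)
    genes <- unique(relations$subject_id[relations$subject_ns == "HGNC"])

    syn_rows <- list(
      data.frame(text = env$entities, target_ns = "FPLX", target_id = env$entities,
                 stringsAsFactors = FALSE),
      data.frame(text = genes, target_ns = "HGNC", target_id = genes,
                 stringsAsFactors = FALSE)
    )
    extra <- env$entities[stats::runif(length(env$entities)) < p_extra_synonym]
    if (length(extra) > 0L) {
      variant <- paste(extra, sample(c("protein", "complex", "family"),
                                     length(extra), replace = TRUE))
      syn_rows[[3L]] <- data.frame(text = variant, target_ns = "FPLX",
                                   target_id = extra, stringsAsFactors = FALSE)
    }
    grounding_map <- do.call(rbind, syn_rows)

    eq_for <- env$entities[stats::runif(length(env$entities)) < 0.3]
    equivalences <- if (length(eq_for) > 0L) {
      data.frame(external_ns = "BEL", external_id = paste0("BE_", eq_for),
                 famplex_id = eq_for, stringsAsFactors = FALSE)
    } else {
      empty_equivalences()
    }

    ontology(
      entities = env$entities,
      relations = relations,
      grounding_map = grounding_map,
      equivalences = equivalences,
      affixes = inpaper_affixes(),
      namespace = "FPLX"
    )
  })
}

#' Specification for a synthetic mention corpus
#'
#' Describes a corpus of synthetic named-entity mentions standing in for
#' reader (NER) output: each mention is a grounding-map synonym, optionally
#' decorated with a random affix and optionally corrupted by one random
#' character edit, together with its gold-standard target.
#'
#' @param seed integer RNG seed
#' @param n_mentions number of mentions to generate
#' @param affix_probability probability a mention is decorated with one
#'   affix, in `[0, 1]`
#' @param noise_probability probability a mention receives one random
#'   character substitution/deletion/insertion, in `[0, 1]`
#' @param category_mix named probability vector over mention categories
#'   `protein_gene` (gene-level targets) and `family_complex` (resource-
#'   namespace targets)
#' @return list of class `famground_corpus_spec`
#' @export
corpus_spec <- function(seed, n_mentions = 200L, affix_probability = 0.3,
                        noise_probability = 0,
                        category_mix = c(protein_gene = 0.6, family_complex = 0.4)) {
  stopifnot(
    n_mentions >= 1L,
    affix_probability >= 0, affix_probability <= 1,
    noise_probability >= 0, noise_probability <= 1,
    all(names(category_mix) %in% c("protein_gene", "family_complex")),
    all(category_mix >= 0), sum(category_mix) > 0
  )
  structure(
    list(seed = seed, n_mentions = as.integer(n_mentions),
         affix_probability = affix_probability,
         noise_probability = noise_probability,
         category_mix = category_mix / sum(category_mix)),
    class = "famground_corpus_spec"
  )
}

# one random unit edit on a string
noise_string <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  alphabet <- c(letters, LETTERS, 0:9)
  op <- sample(c("sub", "del", "ins"), 1L)
  if (length(chars) == 0L) op <- "ins"
  if (op == "sub") {
    i <- sample.int(length(chars), 1L)
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  } else if (op == "del" && length(chars) > 1L) {
    chars <- chars[-sample.int(length(chars), 1L)]
  } else {
    i <- sample.int(length(chars) + 1L, 1L)
    chars <- append(chars, sample(alphabet, 1L), after = i - 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic gold-standard mention corpus
#'
#' Samples mentions from an ontology's grounding map per
#' [corpus_spec()]: the mention category decides whether the synonym is
#' drawn from gene-level or resource-namespace entries, affix decoration
#' substitutes the synonym into a random affix pattern, and character noise
#' applies one random edit.  With `noise_probability = 0`, [ground()]
#' recovers the gold target for every mention.
#'
#' @param ont a validated [ontology()] with a non-empty grounding map
#' @param spec a [corpus_spec()]
#' @return data.frame with one row per mention: text, true_ns, true_id,
#'   category, decorated (affix pattern or `NA`), noised (logical)
#' @export
generate_corpus <- function(ont, spec) {
  stopifnot(inherits(ont, "famground_ontology"),
            inherits(spec, "famground_corpus_spec"))
  gm <- ont$grounding_map
  if (nrow(gm) == 0L) stop("ontology has an empty grounding map", call. = FALSE)
  own <- ont$namespace
  pool <- list(
    family_complex = which(gm$target_ns == own),
    protein_gene = which(gm$target_ns != own)
  )
  mix <- spec$category_mix[vapply(names(spec$category_mix),
                                  function(c) length(pool[[c]]) > 0L, logical(1))]
  if (length(mix) == 0L) stop("no grounding-map entries to sample", call. = FALSE)
  mix <- mix / sum(mix)
  af <- ont$affixes

  with_seed(spec$seed, {
    cats <- sample(names(mix), spec$n_mentions, replace = TRUE, prob = mix)
    rows <- lapply(cats, function(cat) {
      i <- pool[[cat]][sample.int(length(pool[[cat]]), 1L)]
      text <- gm$text[i]
      decorated <- NA_character_
      if (nrow(af) > 0L && stats::runif(1L) < spec$affix_probability) {
        j <- sample.int(nrow(af), 1L)
        sp <- strsplit(af$pattern[j], AFFIX_PLACEHOLDER, fixed = TRUE)[[1]]
        pre <- if (length(sp) >= 1L) sp[[1L]] else ""
        post <- if (length(sp) >= 2L) sp[[2L]] else ""
        text <- paste0(pre, text, post)
        decorated <- af$pattern[j]
      }
      noised <- stats::runif(1L) < spec$noise_probability
      if (noised) text <- noise_string(text)
      data.frame(text = text, true_ns = gm$target_ns[i], true_id = gm$target_id[i],
                 category = cat, decorated = decorated, noised = noised,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Ground a gold corpus and score recovery
#'
#' Grounds every mention of a [generate_corpus()] corpus against the
#' ontology and scores it against the gold labels, returning per-mention
#' results suitable for [accuracy_table()].
#'
#' @param corpus data.frame from [generate_corpus()]
#' @param ont the generating [ontology()]
#' @param policy grounding policy, see [ground()]
#' @return the corpus with added columns grounded_ns, grounded_id, correct
#' @export
score_corpus <- function(corpus, ont, policy = "exact") {
  res <- lapply(corpus$text, ground, ont = ont, policy = policy)
  ref <- vapply(res, function(r) r$entity %||% NA_character_, character(1))
  corpus$grounded_ns <- ifelse(is.na(ref), NA_character_, ref_ns(ref))
  corpus$grounded_id <- ifelse(is.na(ref), NA_character_, ref_id(ref))
  corpus$correct <- !is.na(ref) &
    corpus$grounded_ns == corpus$true_ns & corpus$grounded_id == corpus$true_id
  corpus
}
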