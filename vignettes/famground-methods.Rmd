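---
title: "Methods: grounding and relationship resolution for protein families and complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grounding and relationship resolution for protein families and complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famground)
```

## The problem

Biomedical text describes molecular mechanisms at whatever level of
granularity the authors find natural: a sentence may attribute an activity to
a single gene product (*PLCG1*), to a subfamily (PLCγ), to a family (the
phospholipase C enzymes), or to a multi-subunit complex (NF-κB, AMPK).
Machine-reading pipelines must solve two problems before such statements can
be integrated with gene-level data:

1. **Grounding** (named entity linking/normalization): the surface string
   "NF-kB" must map to a unique identifier.
2. **Relationship resolution**: that identifier must resolve to the genes it
   comprises — NF-κB is not one molecule but a class of dimers over five
   genes in two Rel-family groups.

General gene-name lexicons fail disproportionately on families and complexes:
the strings either match nothing, or spuriously match obscure synonyms of
unrelated genes. famground implements a curated-resource format purpose-built
for this gap, together with the computations needed to validate such a
resource, use it for grounding, extend it by semi-automated curation, and
evaluate the result.

## The resource model

An ontology is five tables (five headerless CSV files on disk):

| component | content |
|---|---|
| entities | local identifiers for families/complexes in the resource's own namespace (default `FPLX`) |
| relations | `isa` (family membership) and `partof` (complex membership) edges, child → parent, spanning both resource entries and external gene-level identifiers |
| grounding map | verbatim, case-preserved surface strings → namespaced identifiers |
| equivalences | cross-references from resource identifiers to external databases |
| affixes | case-sensitive prefix/suffix patterns with one `{Gene name}` placeholder and a semantic category |

The two relation types carry distinct biology (a gene *is a* member of a
family; a subunit is *part of* a complex) but the resource's structural
statistics do not distinguish them, so the hierarchy functions traverse both
while preserving the type as an edge attribute. The directed graph over all
relations must be acyclic; gene-level nodes are recognised **by namespace**
(any namespace other than the resource's own), not by out-degree, so that
placeholder families with no curated children are not mistaken for genes.

Hierarchy positions follow from degree: *top-level* entries have children but
no parent, *intermediate* entries have both, *placeholders* (broad functional
categories such as GTPase) have neither. An entry with a parent but no
children has no class under these definitions and cannot occur in a
well-formed resource, where every family enumerates members; for totality
`classify_levels()` would class such a node `intermediate`, since it sits
below the top of a hierarchy. *Subsumed depth* is the **longest** chain from
an entry to a leaf, so a family with both direct gene members and subfamilies
(PLC) reports the subfamily route; this matches how multi-level entries are
counted in practice when branches have mixed depth.

## Grounding procedure

`ground()` fixes the order **strip affixes, then look up**:

1. Trim and collapse whitespace. No Greek-letter or hyphen normalization is
   applied: a curated grounding map is expected to enumerate variants
   ("NF-kB", "NF-kappaB", …) exactly, and silent normalization would
   reintroduce the spurious-match failure mode the resource exists to fix.
2. Remove affixes iteratively: at each pass the matching affix with the
   longest literal is removed (prefixes win ties), until no affix applies.
   The fixed-point iteration makes stacked decorations ("phospho-mmu-AKT1")
   deterministic without a combination rule, and is idempotent by
   construction. A match that would empty the core string is refused.
3. Look the core string up in the grounding map. The default policy is
   exact, case-sensitive matching — the high-precision behaviour appropriate
   when the map itself is case-curated. A `case_insensitive_fallback` policy
   is provided for recall-style evaluations against externally curated
   corpora, which are scored case-insensitively.

Affix semantics aggregate across matches: any inhibition-category match
inverts event polarity (a positive regulation by "BRAF siRNA" is a negative
regulation by BRAF), species affixes record their tag, protein-state affixes
accumulate as modifiers, and the mRNA affix flags transcript context while
still grounding the core gene. Ambiguity — one string with several plausible
targets across lexicons — is explicitly out of scope: within the map, key
uniqueness makes lookup unambiguous, and context-based disambiguation is a
different problem.

## Curation support

`propose_equivalences()` compares member sets between this resource and an
external one. The default `exact_set` mode proposes a mapping only when the
sets are identical: common usage of a family name (RAS = KRAS, NRAS, HRAS) is
*not* equivalent to a sequence-derived family listing 145 proteins that
happens to contain those three. `subset` mode surfaces either-direction
containments and `jaccard` mode scores all pairs by |A∩B|/|A∪B| (default
threshold 0.8). All output is a proposal table for manual curation, never an
automatic merge.

`propose_synonyms()` ranks corpus strings against known names by Levenshtein
distance. The similarity score is fixed to `1 − d/max(|a|,|b|)`; the
literature's "ratio"-style scores vary in detail, and any monotone variant
induces the same ranking, so the simplest normalization is used and
documented. Distance is case-sensitive by default because gene symbols are
case-meaningful (`ERK` vs `erk`); a case-folding option exists.

## Evaluation statistics

`accuracy_table()` summarises a manually scored entity sample per category;
the standard error of each category's accuracy is the binomial
`sqrt((k/n)(1−k/n)/n)` with `k` correct of `n` in the category. Displayed
percentages round half-up to one decimal (banker's rounding would flip
boundary values). `cumulative_curve()`/`top_share()` quantify how heavily
ungrounded occurrences concentrate in few distinct strings — ties in the
frequency ordering are broken lexicographically purely for determinism.
`event_coverage()` reports the fraction of events with any/all entities
ungrounded, and `level_distribution()` reports where in a multi-level
sub-hierarchy groundings land (gene / intermediate / top). No significance
test is implemented: the evaluation tables this package models annotate
p-values without naming the test, and guessing one would be worse than
omitting it.

## The worked-example fixture and the synthetic generator

`inpaper_ontology()` is a deterministic 15-entity ontology assembling the
format's canonical worked examples: the AMPK complex (α/β subunit families
with two isoforms each, γ with three), NF-κB with five gene-level members,
ERK and its synonym set, the depth-2 PLC hierarchy, single-level RAS/RAF,
and three placeholders. Two conventions are documented rather than sourced:
the five NF-κB genes attach directly to the complex (their two-family
substructure is not named in the material the fixture encodes), and PLCB/PLCD
carry 4 and 3 genes so that the subfamilies subsume nine genes inside a
15-node sub-hierarchy (with PLCE1 and PLCZ1 as direct members). The affix
table carries one example per semantic category plus the suffix form
"{Gene name} siRNA", so both inhibition positions are exercised.

`generate_ontology(seed, …)` produces random ontologies that satisfy every
structural invariant by construction (layered tree growth, globally unique
gene symbols, at least one synonym per entity), and `generate_corpus()`
emulates reader output: each mention is a grounding-map synonym, decorated
with one random affix with probability `affix_probability` (default 0.3 — a
minority of mentions in text carry affixes) and corrupted with probability
`noise_probability` by a single random character substitution, deletion or
insertion. The defaults `n_mentions = 200` and the single-edit noise model
mirror the scale of a manually scorable evaluation sample and the simplest
corruption sufficient to exercise failure paths. All generation is seeded
with save/restore of the caller's RNG state, so equal seeds give
byte-identical CSV serializations.

**What a green test establishes — and what it does not.** Synthetic corpora
contain no real NER errors: no tokenization damage, no abbreviation
ambiguity, no cross-lexicon shadowing, and noise is a uniform single edit
rather than the highly skewed error distribution of real readers. A 100%
recovery on noise-free corpora verifies the strip-then-lookup pipeline is
lossless on its own lexicon; it says nothing about coverage of real text.
Corpus-scale published statistics (cumulative curves over hundreds of
thousands of articles, identifier-usage counts) are similarly not
reproducible at the desk and are exercised here only as properties of the
operations on synthetic inputs.

## Numerical and degenerate-input choices

* Percent display rounding: half away from zero at one decimal
  (`round_half_up()`), matching the printed evaluation tables.
* File output is sorted with C-locale radix ordering everywhere, so exports
  are diff-stable across platforms and locales.
* Empty resource files parse to empty collections with an `empty_file`
  warning; duplicate entities/synonyms are error-severity issues carrying
  the offending row.
* Self-loop relations are reported as `self_relation` and excluded from
  cycle search, which otherwise reports one concrete cycle as a node list.
* `standard_error()` refuses `n = 0`; `cumulative_curve()` refuses empty
  input; `grounding_level()` refuses entities outside the anchoring
  sub-hierarchy.
* Affix matching refuses to strip a pattern whose removal would leave an
  empty or all-whitespace core.

## Known limitations

* No OWL export; OBO output is the 1.2 flat-file profile with a single
  `part_of` typedef, and affix tables do not survive an OBO round-trip
  (they have no OBO representation).
* The grounding map is one-target-per-string by design; competing targets
  across lexicons require an external disambiguation layer.
* `adist`-backed edit distance operates on characters, not graphemes;
  combining-character synonyms would need pre-normalization upstream.
* The CSV dialect (column orders, headerless files) is a documented
  convention of this package, isolated behind the readers.
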