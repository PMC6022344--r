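test_that("exact_set mode proposes only identical member sets", {
  fam <- list(F = c("a", "b", "c"))
  ext <- list(E1 = c("c", "b", "a"), E2 = c("a", "b"))
  props <- propose_equivalences(fam, ext, mode = "exact_set")
  expect_equal(nrow(props), 1L)
  expect_equal(props$external_id, "E1")
  expect_equal(props$score, 1)

  # a small family is not equated with a large external family containing it
  ras <- list(RAS = c("KRAS", "NRAS", "HRAS"))
  big <- list(IPR020849 = c("KRAS", "NRAS", "HRAS", sprintf("OTHER%03d", 1:142)))
  expect_equal(nrow(propose_equivalences(ras, big, mode = "exact_set")), 0L)
  # but subset mode surfaces the containment as a scored proposal
  sub <- propose_equivalences(ras, big, mode = "subset")
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$score, 3 / 145)
})

test_that("jaccard mode reproduces the brute-force all-pairs ranking", {
  for (s in 1:3) {
    fam <- ext <- list()
    set.seed(s)
    genes <- sprintf("g%02d", 1:20)
    for (i in 1:6) fam[[paste0("F", i)]] <- sample(genes, sample(2:6, 1))
    for (i in 1:8) ext[[paste0("E", i)]] <- sample(genes, sample(2:6, 1))
    props <- propose_equivalences(fam, ext, mode = "jaccard", threshold = 0)
    oracle <- oracle_jaccard_pairs(fam, ext)
    key <- function(df) paste(df$famplex_id, df$external_id)
    expect_setequal(key(props), key(oracle))
    m <- match(key(oracle), key(props))
    expect_equal(props$score[m], oracle$score)
    # ranking within each famplex id is score-descending
    for (f in unique(props$famplex_id)) {
      sc <- props$score[props$famplex_id == f]
      expect_true(all(diff(sc) <= 0))
    }
  }
})

test_that("equivalence proposals are invariant to row order and modes nest", {
  fam_df <- data.frame(group = c("F1", "F1", "F2"), gene = c("a", "b", "c"))
  ext_df <- data.frame(group = c("E1", "E1", "E2"), gene = c("b", "a", "c"))
  p1 <- propose_equivalences(fam_df, ext_df)
  p2 <- propose_equivalences(fam_df[c(3, 1, 2), ], ext_df[c(2, 3, 1), ])
  expect_identical(p1[, c("famplex_id", "external_id", "score")],
                   p2[, c("famplex_id", "external_id", "score")])
  expect_equal(nrow(p1), 2L)

  # every exact_set proposal appears in jaccard mode with score 1
  jac <- propose_equivalences(fam_df, ext_df, mode = "jaccard", threshold = 1)
  expect_setequal(paste(p1$famplex_id, p1$external_id),
                  paste(jac$famplex_id, jac$external_id))
  expect_true(all(jac$score == 1))

  expect_warning(
    propose_equivalences(list(F = "a", G = character()), list(E = "a")),
    "empty member sets"
  )
})

test_that("levenshtein matches a naive recursive oracle and known values", {
  expect_equal(levenshtein("ERK1/2", "ERK 1/2"), 1L)
  expect_equal(string_similarity("ERK1/2", "ERK 1/2"), 1 - 1 / 7)
  expect_equal(levenshtein("AKT", "AKT"), 0L)
  expect_equal(string_similarity("AKT", "AKT"), 1)
  expect_equal(levenshtein("", "AKT"), 3L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)

  set.seed(42)
  alphabet <- c("a", "b", "c")
  for (i in 1:40) {
    a <- paste(sample(alphabet, sample(0:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(0:6, 1), replace = TRUE), collapse = "")
    expect_equal(levenshtein(a, b), oracle_lev(a, b))
  }
})

test_that("levenshtein is a metric on random strings", {
  set.seed(7)
  alphabet <- c("x", "y", "z")
  rand_str <- function() paste(sample(alphabet, sample(0:5, 1), replace = TRUE),
                               collapse = "")
  for (i in 1:30) {
    a <- rand_str(); b <- rand_str(); c <- rand_str()
    expect_equal(levenshtein(a, b), levenshtein(b, a))
    expect_equal(levenshtein(a, a), 0L)
    expect_true((levenshtein(a, b) == 0L) == (a == b))
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
})

test_that("propose_synonyms returns sorted candidates above threshold", {
  cand <- propose_synonyms(c("ERK 1/2", "AMPK"),
                           c("ERK1/2", "AMPKalpha", "unrelated string"),
                           threshold = 0.5)
  expect_true(all(cand$similarity >= 0.5))
  expect_true(all(diff(cand$similarity) <= 0))
  expect_equal(cand$corpus_string[[1L]], "ERK1/2")
  expect_false("unrelated string" %in% cand$corpus_string)
  # identical strings score exactly 1
  self <- propose_synonyms("AMPK", "AMPK", threshold = 1)
  expect_equal(self$similarity, 1)
  expect_equal(self$distance, 0L)
  # case folding option
  expect_equal(nrow(propose_synonyms("erks", "ERKs", threshold = 1)), 0L)
  expect_equal(propose_synonyms("erks", "ERKs", threshold = 1,
                                case_sensitive = FALSE)$similarity, 1)
})

test_that("member_table derives comparable sets from an ontology", {
  ont <- inpaper_ontology()
  mt <- member_table(ont)
  expect_setequal(mt$RAS, paste0("HGNC:", c("KRAS", "NRAS", "HRAS")))
  expect_length(mt$GTPase, 0L)
  props <- propose_equivalences(
    mt[lengths(mt) > 0],
    list(REACTOME_RAS = paste0("HGNC:", c("KRAS", "NRAS", "HRAS")))
  )
  expect_equal(props$famplex_id, "RAS")
})
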