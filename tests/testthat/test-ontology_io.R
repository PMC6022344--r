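test_that("load_entities parses identifiers and flags duplicates and empties", {
  p <- write_fixture_csv(c("AKT", "AMPK", "RAS"), "entities.csv")
  expect_setequal(load_entities(p), c("AKT", "AMPK", "RAS"))

  p <- write_fixture_csv(character(), "empty.csv")
  expect_warning(ids <- load_entities(p), "empty_file")
  expect_length(ids, 0L)

  p <- write_fixture_csv(c("AKT", "AKT"), "dup.csv")
  err <- tryCatch(load_entities(p), error = identity)
  expect_s3_class(err, "famground_validation_error")
  expect_equal(err$issues$code, "duplicate_entity")
  expect_equal(err$issues$row, 2L)
})

test_that("load_relations parses five-field rows into typed relations", {
  p <- write_fixture_csv(c(
    "HGNC,PLCG1,isa,FPLX,PLCG",
    "FPLX,AMPK_gamma,partof,FPLX,AMPK"
  ), "relations.csv")
  rel <- load_relations(p)
  expect_equal(rel$subject_id, c("PLCG1", "AMPK_gamma"))
  expect_equal(rel$rel, c("isa", "partof"))
  expect_equal(rel$object_id, c("PLCG", "AMPK"))

  p <- write_fixture_csv("HGNC,PLCG1,memberof,FPLX,PLCG", "bad_rel.csv")
  err <- tryCatch(load_relations(p), error = identity)
  expect_equal(err$issues$code, "invalid_relation")

  p <- write_fixture_csv("HGNC,PLCG1,isa,FPLX", "short.csv")
  err <- tryCatch(load_relations(p), error = identity)
  expect_equal(err$issues$code, "malformed_row")
})

test_that("grounding map, equivalences and affixes load with their checks", {
  p <- write_fixture_csv('NF-kB,FPLX,NFkappaB', "gm.csv")
  gm <- load_grounding_map(p)
  expect_equal(gm$text, "NF-kB")
  expect_equal(gm$target_id, "NFkappaB")

  p <- write_fixture_csv(c("ERKs,FPLX,ERK", "ERKs,FPLX,MAPK"), "gm_dup.csv")
  err <- tryCatch(load_grounding_map(p), error = identity)
  expect_equal(err$issues$code, "duplicate_synonym")

  p <- write_fixture_csv("mmu-{Gene name},prefix,species,mouse", "af.csv")
  af <- load_affixes(p)
  expect_equal(af$species_tag, "mouse")
  expect_equal(af$category, "species")

  p <- write_fixture_csv("mmu-,prefix,species,mouse", "af_bad.csv")
  err <- tryCatch(load_affixes(p), error = identity)
  expect_equal(err$issues$code, "malformed_affix")

  p <- write_fixture_csv("BEL,akt-family,AKT", "eq.csv")
  eq <- load_equivalences(p)
  expect_equal(eq$famplex_id, "AKT")
})

test_that("load_ontology assembles and validates a resource directory", {
  dir <- make_resource_dir()
  ont <- load_ontology(dir)
  expect_s3_class(ont, "famground_ontology")
  expect_setequal(ont$entities, c("AKT", "AMPK", "RAS"))
  # quoted comma field preserved verbatim
  expect_true("RAS, wild-type" %in% ont$grounding_map$text)
  expect_equal(nrow(validate(ont)), 0L)
})

test_that("validate flags each seeded defect with exactly the matching code", {
  base <- inpaper_ontology()
  expect_equal(nrow(validate(base)), 0L)

  mutate_and_code <- function(mutate) {
    ont <- mutate(base)
    validate(ont)$code
  }

  expect_equal(mutate_and_code(function(o) {
    o$entities <- c(o$entities, o$entities[[1L]])
    o
  }), "duplicate_entity")

  expect_equal(mutate_and_code(function(o) {
    o$relations$rel[1L] <- "memberof"
    o
  }), "invalid_relation")

  expect_equal(mutate_and_code(function(o) {
    o$relations[1L, ] <- list("FPLX", "AMPK", "isa", "FPLX", "AMPK")
    o
  }), "self_relation")

  expect_equal(mutate_and_code(function(o) {
    o$relations$object_id[1L] <- "FOO"
    o
  }), "dangling_relation")

  expect_equal(mutate_and_code(function(o) {
    o$equivalences$famplex_id[1L] <- "FOO"
    o
  }), "dangling_equivalence")

  expect_equal(mutate_and_code(function(o) {
    o$grounding_map$target_id[1L] <- "FOO"
    o
  }), "dangling_grounding")

  expect_equal(mutate_and_code(function(o) {
    o$grounding_map <- rbind(o$grounding_map, o$grounding_map[1L, ])
    o
  }), "duplicate_synonym")

  expect_equal(mutate_and_code(function(o) {
    o$affixes$pattern[1L] <- "eGFP-"
    o
  }), "malformed_affix")

  issues <- mutate_and_code(function(o) {
    o$relations <- rbind(o$relations, data.frame(
      subject_ns = "FPLX", subject_id = c("PLC", "RAS"), rel = "isa",
      object_ns = "FPLX", object_id = c("RAS", "PLC"), stringsAsFactors = FALSE
    ))
    o
  })
  expect_equal(issues, "cycle")

  # cycle message names the offending nodes
  ont <- base
  ont$relations <- rbind(ont$relations, data.frame(
    subject_ns = "FPLX", subject_id = c("PLC", "RAS"), rel = "isa",
    object_ns = "FPLX", object_id = c("RAS", "PLC"), stringsAsFactors = FALSE
  ))
  msg <- validate(ont)$message
  expect_match(msg, "FPLX:PLC")
  expect_match(msg, "FPLX:RAS")

  # unknown namespace is a warning, not an error
  ont <- base
  ont$relations$subject_ns[4L] <- "MYDB"
  iss <- validate(ont)
  expect_equal(iss$code, "invalid_namespace")
  expect_equal(iss$severity, "warning")
})

test_that("CSV write/load round-trip preserves the ontology", {
  for (ont in list(inpaper_ontology(), generate_ontology(11, n_families = 6, max_depth = 3))) {
    dir <- withr::local_tempdir()
    write_ontology(ont, dir)
    back <- load_ontology(dir)
    expect_true(ontology_equal(ont, back))
    # re-serialization is byte-identical (deterministic sorted output)
    dir2 <- withr::local_tempdir()
    write_ontology(back, dir2)
    for (f in list.files(dir)) {
      expect_identical(readLines(file.path(dir2, f)), readLines(file.path(dir, f)))
    }
  }
})

test_that("export_obo emits the contracted stanza structure", {
  ont <- ontology(
    entities = "NFkappaB",
    grounding_map = data.frame(text = "NF-kB", target_ns = "FPLX",
                               target_id = "NFkappaB", stringsAsFactors = FALSE)
  )
  obo <- export_obo(ont)
  lines <- strsplit(obo, "\n")[[1]]
  i <- which(lines == "[Term]")
  expect_length(i, 1L)
  expect_equal(lines[i + 1L], "id: FPLX:NFkappaB")
  expect_equal(lines[i + 2L], "name: NFkappaB")
  expect_equal(lines[i + 3L], 'synonym: "NF-kB" EXACT []')

  obo <- export_obo(inpaper_ontology())
  x <- oracle_obo_extract(obo)
  expect_true("FPLX:PLC" %in% x$isa)         # PLCG isa PLC somewhere
  expect_true("FPLX:AMPK" %in% x$partof)     # subunit families partof AMPK
  expect_true("ERK 1/2" %in% x$synonyms)

  # invalid ontology is refused with the validation issues attached
  bad <- inpaper_ontology()
  bad$relations$object_id[1L] <- "FOO"
  err <- tryCatch(export_obo(bad), error = identity)
  expect_s3_class(err, "famground_validation_error")
  expect_true("dangling_relation" %in% err$issues$code)
})

test_that("OBO export/parse round-trip is lossless for entities, relations, synonyms", {
  for (seed in c(1, 2)) {
    ont <- generate_ontology(seed, n_families = 5, max_depth = 3)
    obo <- export_obo(ont)
    # independent reader agrees on the inventory
    x <- oracle_obo_extract(obo)
    expect_setequal(x$ids[startsWith(x$ids, "FPLX:")],
                    paste0("FPLX:", ont$entities))
    expect_setequal(x$synonyms, ont$grounding_map$text)
    expect_equal(length(x$isa) + length(x$partof), nrow(ont$relations))
    # package parser inverts the export
    expect_true(ontology_equal(ont, parse_obo(obo), affixes = FALSE))
  }
  # malformed stanza reports a line number
  err <- tryCatch(parse_obo(c("[Term]", "id: FPLX:A", "not a field")),
                  error = identity)
  expect_match(conditionMessage(err), "line 3")
})
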