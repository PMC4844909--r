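test_that("an empty set serializes to a document with zero annotations and round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  set <- annotation_set("empty", "human")
  write_annotations(set, path)
  doc <- jsonlite::read_json(path)
  expect_equal(length(doc$annotations), 0)
  expect_equal(doc$format, "pddikit-annotation/v1")
  expect_identical(read_annotations(path), set)
})

test_that("a PDDI annotation body carries the typed fields of the data model", {
  path <- withr::local_tempfile(fileext = ".json")
  corpus <- property_corpus()
  set <- as_set(pm_row("sec1", 0:1, "D1", "D2", statement = "quantitative"))
  write_annotations(set, path, corpus)
  body <- jsonlite::read_json(path)$annotations[[1]]$body
  expect_true(all(c("precipitant", "object", "statement", "modality") %in% names(body)))
  expect_equal(body$precipitant$id, "D1")
  sel <- jsonlite::read_json(path)$annotations[[1]]$target$selector
  expect_equal(sel$exact, substr(corpus$sections$sec1$text, sel$start + 1, sel$end))
})

test_that("write-then-read is the identity for generated many-mention sets", {
  withr::with_seed(11, {
    corpus <- property_corpus()
    for (rep in 1:5) {
      pm <- random_pddi_set(50)
      set <- as_set(pm, source_id = sprintf("annotator-%d", rep))
      path <- withr::local_tempfile(fileext = ".json")
      write_annotations(set, path, corpus)
      expect_identical(read_annotations(path, corpus), set)
    }
  })
  # including drug mentions and pass-through payload
  st <- generate_corpus(generator_config(n_sections = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(st$reference, path, st$corpus)
  expect_identical(read_annotations(path, st$corpus), st$reference)
})

test_that("unknown body keys survive in the pass-through slot", {
  path <- withr::local_tempfile(fileext = ".json")
  pm <- pm_row("sec1", 0, "D1", "D2")
  pm$extra <- list(list(reviewer_note = "check", confidence = 0.9))
  set <- as_set(pm)
  write_annotations(set, path)
  back <- read_annotations(path)
  expect_equal(back$pddi_mentions$extra[[1]]$reviewer_note, "check")
  expect_equal(back$pddi_mentions$extra[[1]]$confidence, 0.9)
})

test_that("a selector quote that disagrees with the section text is rejected by id", {
  corpus <- property_corpus()
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(as_set(pm_row("sec1", 0, "D1", "D2")), path, corpus)
  txt <- sub("Sentence number 1", "Tampered sentence 1", readLines(path))
  writeLines(txt, path)
  expect_error(read_annotations(path, corpus), "p1")
})

test_that("a hand-written minimal document with one drug mention loads", {
  corpus <- make_test_corpus(c(s1 = "Ketoconazole was given."))
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "format": "pddikit-annotation/v1",
    "source": {"id": "annotator-9", "kind": "human"},
    "annotations": [{
      "id": "d1",
      "target": {"section": "s1",
                 "selector": {"type": "TextPositionSelector", "start": 0, "end": 12,
                              "exact": "Ketoconazole"}},
      "body": {"type": "DrugMention", "entity_type": "active_ingredient",
               "concept_id": "ING_KETO"}
    }]
  }', path)
  set <- read_annotations(path, corpus)
  expect_equal(nrow(set$drug_mentions), 1)
  expect_equal(set$drug_mentions$normalized_ingredient_id, "ING_KETO")
})

test_that("validation rejects malformed mention sets", {
  expect_error(
    validate_annotation_set(as_set(pm_row("sec1", 0, "D1", "D1"))),
    "precipitant and object"
  )
  pm <- rbind(pm_row("sec1", 0, "D1", "D2"), pm_row("sec1", 0, "D1", "D2"))
  expect_error(validate_annotation_set(as_set(pm)), "duplicate")
  corpus <- property_corpus()
  expect_error(
    validate_annotation_set(as_set(pm_row("nope", 0, "D1", "D2")), corpus),
    "unknown section"
  )
  expect_error(
    validate_annotation_set(as_set(pm_row("sec1", 99, "D1", "D2")), corpus),
    "out of range"
  )
})
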