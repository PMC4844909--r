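lex <- make_test_lexicon()

extract_one <- function(text, rules = rule_config()) {
  sec <- label_section("s1", "L1", text)
  extract_pddi_mentions(sec, annotate_drug_mentions(sec, lex), rules)
}

test_that("a causative quantitative sentence yields one correctly typed mention", {
  res <- extract_one("Ketoconazole increased midazolam AUC by 5-fold.")
  expect_equal(nrow(res$mentions), 1)
  m <- res$mentions
  expect_equal(m$precipitant_id, "ING_KETO")
  expect_equal(m$object_id, "ING_MIDA")
  expect_equal(m$statement, "quantitative")
  expect_equal(m$modality, "positive")
  expect_equal(m$sentence_indices[[1]], 0L)
  expect_true(res$classifications$is_pddi[1])
})

test_that("negation cues flip modality and absent magnitudes give qualitative statements", {
  res <- extract_one("Coadministration of ketoconazole had no effect on the pharmacokinetics of midazolam.")
  expect_equal(res$mentions$modality, "negative")
  expect_equal(res$mentions$statement, "qualitative")
  expect_equal(res$classifications$modality[1], "negative")
})

test_that("passive frames assign the agent as precipitant", {
  res <- extract_one("The AUC of midazolam was increased 2.5-fold by ketoconazole.")
  expect_equal(res$mentions$precipitant_id, "ING_KETO")
  expect_equal(res$mentions$object_id, "ING_MIDA")
  expect_equal(res$mentions$statement, "quantitative")
})

test_that("cue-only sentences fall back to first-drug-precipitant and are flagged", {
  res <- extract_one("Ketoconazole and midazolam showed altered AUC values together.")
  expect_equal(res$mentions$precipitant_id, "ING_KETO")
  expect_true(isTRUE(res$mentions$extra[[1]]$role_fallback))
})

test_that("windows without two distinct drugs or without a cue emit nothing", {
  expect_equal(nrow(extract_one("Ketoconazole increased the AUC substantially.")$mentions), 0)
  expect_equal(nrow(extract_one("Ketoconazole and midazolam were both given.")$mentions), 0)
  # normalized identity: product + its own ingredient is one drug, not two
  expect_equal(nrow(extract_one("Warfarin sodium increased warfarin AUC.")$mentions), 0)
  cls <- extract_one("Ketoconazole and midazolam were both given.")$classifications
  expect_false(cls$is_pddi[1])
  expect_true(is.na(cls$modality[1]))
})

test_that("a size-2 window joins adjacent sentences", {
  text <- "Ketoconazole was studied. Midazolam AUC increased markedly."
  expect_equal(nrow(extract_one(text)$mentions), 0) # size-1 windows: one drug each
  res2 <- extract_one(text, rule_config(window_size = 2))
  expect_equal(nrow(res2$mentions), 1)
  expect_equal(res2$mentions$sentence_indices[[1]], c(0L, 1L))
})

test_that("every extracted mention's window contains both of its drugs", {
  st <- generate_corpus(generator_config(n_sections = 8, seed = 31))
  for (sec in st$corpus$sections) {
    dm <- annotate_drug_mentions(sec, st$lexicon)
    res <- extract_pddi_mentions(sec, dm, rule_config())
    for (i in seq_len(nrow(res$mentions))) {
      m <- res$mentions[i, ]
      sp <- sec$sentence_spans[m$sentence_indices[[1]] + 1, , drop = FALSE]
      inside <- dm$char_start >= min(sp$start) & dm$char_end <= max(sp$end)
      ids <- dm$normalized_ingredient_id[inside]
      expect_true(all(c(m$precipitant_id, m$object_id) %in% ids))
    }
  }
})

test_that("the pipeline is deterministic and composes over a corpus", {
  expect_equal(nrow(run_pipeline(pddi_corpus(list()), lex)$pddi_mentions), 0)
  st <- generate_corpus(generator_config(n_sections = 6, seed = 13))
  a <- run_pipeline(st$corpus, st$lexicon)
  b <- run_pipeline(st$corpus, st$lexicon)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_annotations(a, p1, st$corpus)
  write_annotations(b, p2, st$corpus)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical output
})

test_that("planted negative-modality statements are recovered as negative", {
  st <- generate_corpus(generator_config(n_sections = 12, p_negative_modality = 0.5, seed = 17))
  nlp <- run_pipeline(st$corpus, st$lexicon)
  ref <- st$reference$pddi_mentions
  neg <- ref[ref$modality == "negative", ]
  expect_gt(nrow(neg), 1)
  got <- nlp$pddi_mentions
  for (i in seq_len(nrow(neg))) {
    hit <- got$section_id == neg$section_id[i] &
      vapply(seq_len(nrow(got)), function(j) is_match(got[j, ], neg[i, ]), logical(1))
    expect_equal(sum(hit), 1)
  }
})
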