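test_that("degenerate configurations are honored exactly", {
  empty <- generate_corpus(generator_config(n_sections = 0, seed = 1))
  expect_equal(corpus_size(empty$corpus), 0)
  expect_equal(nrow(empty$reference$pddi_mentions), 0)
  no_neg <- generate_corpus(generator_config(n_sections = 15, p_negative_modality = 0, seed = 2))
  expect_true(all(no_neg$reference$pddi_mentions$modality == "positive"))
  all_neg <- generate_corpus(generator_config(n_sections = 15, p_negative_modality = 1, seed = 2))
  expect_true(all(all_neg$reference$pddi_mentions$modality == "negative"))
})

test_that("the same seed reproduces the study byte for byte", {
  cfg <- generator_config(n_sections = 10, seed = 41)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  sa <- simulate_nlp(a$reference, a$ledger, cfg)
  sb <- simulate_nlp(b$reference, b$ledger, cfg)
  expect_identical(sa, sb)
  ua <- simulate_annotator(a$reference, sa$nlp, sa$ledger, seed = 9)
  ub <- simulate_annotator(b$reference, sb$nlp, sb$ledger, seed = 9)
  expect_identical(ua, ub)
})

test_that("planted mention totals track the reference-standard composition", {
  st <- generate_corpus(generator_config(n_sections = 208, seed = 6))
  # published totals are per 205 annotated sections; scale to 208
  scale <- 208 / 205
  target_pddi <- 607 * scale
  expect_lt(abs(nrow(st$reference$pddi_mentions) - target_pddi), 0.10 * target_pddi)
  mix <- table(st$reference$drug_mentions$entity_type)
  expect_lt(abs(mix[["active_ingredient"]] - 3351 * scale) / (3351 * scale), 0.15)
  expect_lt(abs(mix[["drug_product"]] - 234 * scale) / (234 * scale), 0.25)
  expect_lt(abs(mix[["metabolite"]] - 201 * scale) / (201 * scale), 0.25)
})

test_that("every planted reference mention is internally consistent", {
  st <- generate_corpus(generator_config(n_sections = 10, seed = 8))
  expect_silent(validate_annotation_set(st$reference, st$corpus))
  led <- st$ledger$records
  expect_equal(sum(led$kind == "planted"), nrow(st$reference$pddi_mentions))
  expect_equal(sum(led$kind == "fp_pool"), nrow(st$ledger$fp_pool_mentions))
})

test_that("a perfect NLP operating point copies the reference", {
  cfg <- generator_config(n_sections = 10, nlp_sentence_recall = 1,
                          nlp_sentence_precision = 1, seed = 10)
  st <- generate_corpus(cfg)
  sim <- simulate_nlp(st$reference, st$ledger, cfg)
  expect_identical(sim$nlp$pddi_mentions, st$reference$pddi_mentions)
})

test_that("precision 0.5 at recall 1 adds about as many false positives as references", {
  cfg <- generator_config(n_sections = 300, pddis_per_section = c(1L, 1L),
                          nlp_sentence_recall = 1, nlp_sentence_precision = 0.5,
                          seed = 12)
  st <- generate_corpus(cfg)
  sim <- simulate_nlp(st$reference, st$ledger, cfg)
  n_ref <- nrow(st$reference$pddi_mentions)
  n_fp <- sum(sim$ledger$records$nlp == "FP", na.rm = TRUE)
  expect_lt(abs(n_fp - n_ref), 3 * sqrt(n_ref * 0.5)) # binomial sampling slack
})

test_that("a perfectly corrective annotator reproduces the reference", {
  cfg <- generator_config(n_sections = 10, seed = 14)
  st <- generate_corpus(cfg)
  sim <- simulate_nlp(st$reference, st$ledger, cfg)
  perfect <- annotator_profile(p_fix_nlp_fn = 1, p_drop_nlp_tp = 0,
                               p_accept_nlp_fp = 0, p_spontaneous_fp_per_section = 0)
  res <- simulate_annotator(st$reference, sim$nlp, sim$ledger, perfect, seed = 15)
  got <- res$user$pddi_mentions
  expect_setequal(got$uid, st$reference$pddi_mentions$uid)
})

test_that("unassisted annotation uses the base sensitivity and no NLP information", {
  cfg <- generator_config(n_sections = 60, seed = 16)
  st <- generate_corpus(cfg)
  prof <- annotator_profile(p_fix_nlp_fn = 0.7, p_spontaneous_fp_per_section = 0)
  res <- simulate_annotator(st$reference, NULL, st$ledger, prof,
                            assisted = FALSE, source_id = "solo", seed = 17)
  n_ref <- nrow(st$reference$pddi_mentions)
  found <- nrow(res$user$pddi_mentions)
  expect_lt(abs(found / n_ref - 0.7), 3 * sqrt(0.7 * 0.3 / n_ref))
})

test_that("pipeline precision and recall degrade monotonically with planted noise", {
  recalls <- vapply(c(0, 0.3, 0.6), function(pp) {
    st <- generate_corpus(generator_config(n_sections = 25, p_paraphrase = pp, seed = 18))
    met <- evaluate_annotations(run_pipeline(st$corpus, st$lexicon), st$reference, st$corpus)
    met$overall[["recall"]]
  }, numeric(1))
  expect_true(all(diff(recalls) < 0))
  precisions <- vapply(c(0, 0.7, 1.5), function(cd) {
    st <- generate_corpus(generator_config(n_sections = 25, cue_distractor_rate = cd, seed = 18))
    met <- evaluate_annotations(run_pipeline(st$corpus, st$lexicon), st$reference, st$corpus)
    met$overall[["precision"]]
  }, numeric(1))
  expect_true(all(diff(precisions) < 0))
})

test_that("write_study materializes a loadable, consistent study directory", {
  dir <- withr::local_tempdir()
  write_study(generator_config(n_sections = 6, seed = 20), dir, annotators = 1)
  corpus <- load_corpus(file.path(dir, "corpus", "manifest.json"))
  lexicon <- read_lexicon(file.path(dir, "lexicon.tsv"), file.path(dir, "relations.tsv"))
  reference <- read_annotations(file.path(dir, "reference.json"), corpus)
  nlp <- read_annotations(file.path(dir, "nlp.json"), corpus)
  user <- read_annotations(file.path(dir, "annotator-1.json"), corpus)
  expect_s3_class(lexicon, "pddi_lexicon")
  expect_gt(nrow(reference$pddi_mentions), 0)
  expect_equal(nlp$source_kind, "nlp")
  expect_equal(user$source_kind, "human")
  ledger <- utils::read.delim(file.path(dir, "ledger.tsv"), stringsAsFactors = FALSE)
  expect_true(all(c("uid", "nlp", "annotator.1") %in% make.names(names(ledger))))
})
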