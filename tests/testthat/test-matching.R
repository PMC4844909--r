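corpus <- property_corpus()

test_that("the TP criterion compares drugs, modality, and sentence overlap only", {
  a <- pm_row("sec1", c(1, 2), "D1", "D2")
  expect_true(is_match(a, a))
  expect_true(is_match(pm_row("sec1", c(1, 2), "D1", "D2"), pm_row("sec1", 2, "D1", "D2")))
  expect_false(is_match(pm_row("sec1", 1, "D1", "D2"), pm_row("sec1", 3, "D1", "D2")))
  expect_false(is_match(pm_row("sec1", 1, "D1", "D2"),
                        pm_row("sec1", 1, "D1", "D2", modality = "negative")))
  # roles are directional
  expect_false(is_match(pm_row("sec1", 1, "D1", "D2"), pm_row("sec1", 1, "D2", "D1")))
  # statement type deliberately ignored
  expect_true(is_match(pm_row("sec1", 1, "D1", "D2", statement = "quantitative"),
                       pm_row("sec1", 1, "D1", "D2", statement = "qualitative")))
  # different sections: false by contract
  expect_false(is_match(pm_row("sec1", 1, "D1", "D2"),
                        pm_row("sec2", 1, "D1", "D2")))
})

test_that("match bookkeeping conserves mention counts", {
  ref <- bind_pm(pm_row("sec1", 0, "D1", "D2"), pm_row("sec1", 2, "D2", "D3"))
  cand <- bind_pm(pm_row("sec1", 0, "D1", "D2"), pm_row("sec1", 4, "D1", "D3"))
  m <- match_sets(as_set(cand), as_set(ref, "ref", "reference"), corpus)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(length(m$candidate_fp), 1)
  expect_equal(length(m$reference_fn), 1)
  expect_equal(nrow(m$pairs) + length(m$reference_fn), nrow(ref))
  expect_equal(nrow(m$pairs) + length(m$candidate_fp), nrow(cand))
})

test_that("two duplicate candidates against one reference give one TP and one FP", {
  ref <- pm_row("sec1", 1, "D1", "D2")
  cand <- bind_pm(pm_row("sec1", 1, "D1", "D2"), pm_row("sec1", c(1, 2), "D1", "D2"))
  m <- match_sets(as_set(cand), as_set(ref, "ref", "reference"), corpus)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(length(m$candidate_fp), 1)
})

test_that("pairing is not starved by processing order on interleaved sentence sets", {
  # a first-come pairing that gave the {1,2} candidate the {2} reference
  # would strand the {1}-only candidate; the matcher must find both pairs
  ref <- bind_pm(pm_row("sec1", 2, "D1", "D2"), pm_row("sec1", c(1, 3), "D1", "D2"))
  cand <- bind_pm(pm_row("sec1", c(1, 2), "D1", "D2"), pm_row("sec1", 3, "D1", "D2"))
  m <- match_sets(as_set(cand), as_set(ref, "ref", "reference"), corpus)
  expect_equal(nrow(m$pairs), 2)
})

test_that("the matcher attains brute-force maximum matching on random instances", {
  withr::with_seed(101, {
    for (rep in 1:60) {
      nc <- sample(0:8, 1)
      nr <- sample(0:8, 1)
      cand <- random_pddi_set(nc)
      ref <- random_pddi_set(nr)
      m <- match_sets(as_set(cand), as_set(ref, "ref", "reference"), corpus)
      expect_equal(nrow(m$pairs), bf_max_matching_size(cand, ref))
    }
  })
})

test_that("adding candidates moves recall in the right direction only", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      ref <- random_pddi_set(5)
      cand <- random_pddi_set(4)
      base <- match_sets(as_set(cand), as_set(ref, "ref", "reference"), corpus)
      base_tp <- nrow(base$pairs)
      # a candidate matching nothing (unique drug pair) never raises recall
      noise <- pm_row("sec1", 0, "D8", "D9")
      with_noise <- match_sets(as_set(rbind(cand, noise)),
                               as_set(ref, "ref", "reference"), corpus)
      expect_equal(nrow(with_noise$pairs), base_tp)
      # a copy of an unmatched reference mention never lowers recall
      if (length(base$reference_fn)) {
        extra <- ref[base$reference_fn[1], ]
        extra$statement <- "quantitative" # identity modulo statement
        more <- rbind(cand, extra)
        more <- more[!duplicated(pddikit:::pddi_keys(more)), ]
        with_fix <- match_sets(as_set(more), as_set(ref, "ref", "reference"), corpus)
        expect_gte(nrow(with_fix$pairs), base_tp)
      }
    }
  })
})
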