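test_that("the canonical 208-section design reproduces the published split", {
  st <- generate_corpus(generator_config(n_sections = 208, seed = 3))
  plan <- assign_scenarios(st$corpus, seed = 5)
  tab <- table(plan$assignment)
  expect_equal(tab[["training"]], 3)
  expect_equal(tab[["1"]], 52)
  expect_equal(tab[["2"]], 52)
  expect_equal(tab[["3"]], 53)
  expect_equal(tab[["4"]], 48)
  expect_equal(sum(tab) - tab[["training"]], 205)
  expect_identical(plan$assignment, assign_scenarios(st$corpus, seed = 5)$assignment)
  expect_false(identical(plan$assignment, assign_scenarios(st$corpus, seed = 6)$assignment))
})

test_that("a perfectly balanced corpus splits its strata exactly", {
  texts <- stats::setNames(
    c(rep(strrep("Long sentence here. ", 30), 4), rep("Short one.", 4)),
    sprintf("s%d", 1:8)
  )
  corpus <- make_test_corpus(texts)
  plan <- assign_scenarios(corpus, c(`1` = 4L, `2` = 4L), seed = 1)
  for (s in c("1", "2")) {
    ids <- names(plan$assignment)[plan$assignment == s]
    cls <- vapply(corpus$sections[ids], function(x) x$length_class, character(1))
    expect_equal(sum(cls == "long"), 2)
    expect_equal(sum(cls == "short"), 2)
  }
})

test_that("scenario sizes must sum to the corpus size", {
  corpus <- make_test_corpus(c(a = "One.", b = "Two."))
  expect_error(assign_scenarios(corpus, c(`1` = 5L)), "sum")
})

test_that("per-scenario length composition stays near the corpus median", {
  withr::with_seed(91, {
    for (rep in 1:50) {
      n <- 40
      lens <- sample(80:2000, n)
      texts <- stats::setNames(vapply(lens, function(l) strrep("a", l), character(1)),
                               sprintf("s%02d", 1:n))
      corpus <- make_test_corpus(texts)
      plan <- assign_scenarios(corpus, c(`1` = 10L, `2` = 10L, `3` = 10L, `4` = 10L),
                               seed = rep)
      cls <- vapply(corpus$sections, function(x) x$length_class, character(1))
      n_long <- sum(cls == "long")
      for (s in c("1", "2", "3", "4")) {
        ids <- names(plan$assignment)[plan$assignment == s]
        # long/short composition within one of a perfectly balanced split
        expect_lte(abs(sum(cls[ids] == "long") - 10 * n_long / n), 1)
      }
    }
  })
})

test_that("usability margins are reproduced from the packaged ratings", {
  ratings <- utils::read.delim(pddikit_extdata("table3_usability.tsv"),
                               stringsAsFactors = FALSE)
  s <- summarize_usability(ratings)
  expect_equal(s$per_participant$mean, c(2.67, 3.67, 3.67, 2.67))
  expect_equal(s$per_scenario$mean, c(3.25, 4.25, 2))
  expect_equal(s$group_means$mean[s$group_means$group == "expert"], 2.67)
  expect_equal(s$group_means$mean[s$group_means$group == "nonexpert"], 3.33)
  # all-equal ratings give flat means
  flat <- ratings
  flat$rating <- 5L
  sf <- summarize_usability(flat)
  expect_true(all(sf$per_participant$mean == 5))
  expect_true(all(sf$per_scenario$mean == 5))
})

test_that("incomplete or invalid rating grids are rejected by cell", {
  ratings <- utils::read.delim(pddikit_extdata("table3_usability.tsv"),
                               stringsAsFactors = FALSE)
  expect_error(summarize_usability(ratings[-2, ]), "Expert.*scenario 2")
  bad <- ratings
  bad$rating[1] <- 9L
  expect_error(summarize_usability(bad), "\\[1, 5\\]")
})

test_that("time-category tallies reproduce the packaged reports and conserve rows", {
  reports <- utils::read.delim(pddikit_extdata("table2_times.tsv"),
                               stringsAsFactors = FALSE)
  tab <- tally_time_categories(reports)
  expect_equal(unname(rowSums(tab)), rep(3, 4))
  expect_equal(tab["Expert", "<1h"], 3)
  expect_equal(tab["Nonexpert 2", "1-3h"], 1)
  expect_equal(tab["Nonexpert 3", ">5h"], 1)
  expect_equal(sum(tally_time_categories(reports[0, ])), 0)
  bad <- reports
  bad$category[1] <- "2-4h"
  expect_error(tally_time_categories(bad), "2-4h")
})
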