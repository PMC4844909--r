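#' Default scenario sizes for a corpus of n sections
#'
#' The canonical study design reserves 3 of 208 sections for training
#' and distributes the remaining 205 as 52/52/53/48 across four
#' scenarios.  For other corpus sizes the same proportions are scaled
#' by largest-remainder apportionment.
#'
#' @param n Corpus size.
#' @return Named integer vector with elements `training`, `1`..`4`.
#' @export
default_scenario_sizes <- function(n = 208L) {
  base <- c(training = 3L, `1` = 52L, `2` = 52L, `3` = 53L, `4` = 48L)
  if (n == sum(base)) {
    return(base)
  }
  stats::setNames(apportion(n, base), names(base))
}

#' Assign sections to scenarios, balanced by section length
#'
#' Sections are stratified into short and long (the corpus's length
#' class), each stratum's sections are allocated across scenarios by
#' largest-remainder apportionment proportional to the target sizes,
#' and within a stratum sections are ordered by length (seeded random
#' tie-break) and dealt round-robin into scenarios with remaining
#' stratum quota.  Output sizes are exact and each scenario's
#' long/short composition is within one section of a perfectly
#' balanced split.  Deterministic given the seed.
#'
#' @param corpus A [pddi_corpus].
#' @param target_sizes Named counts per scenario (default
#'   [default_scenario_sizes()] for the corpus size); must sum to the
#'   corpus size.
#' @param seed Integer seed for the tie-break shuffle.
#' @return An object of class `scenario_plan`: list with `assignment`
#'   (named character vector section id -> scenario) and `target_sizes`.
#' @export
assign_scenarios <- function(corpus, target_sizes = NULL, seed = 1L) {
  target_sizes <- target_sizes %||% default_scenario_sizes(corpus_size(corpus))
  if (sum(target_sizes) != corpus_size(corpus)) {
    stop_pddi("target_sizes sum to %d but the corpus has %d sections",
              sum(target_sizes), corpus_size(corpus))
  }
  scen <- names(target_sizes)
  ids <- names(corpus$sections)
  lens <- vapply(corpus$sections, function(s) nchar(s$text), numeric(1))
  cls <- vapply(corpus$sections, function(s) s$length_class, character(1))
  assignment <- stats::setNames(rep(NA_character_, length(ids)), ids)
  withr::with_seed(as.integer(seed), {
    quota_short <- apportion(sum(cls == "short"), target_sizes)
    quota_long <- as.integer(target_sizes) - quota_short
    for (stratum in c("long", "short")) {
      in_str <- ids[cls == stratum]
      quota <- if (stratum == "long") quota_long else quota_short
      names(quota) <- scen
      # order by length descending; seeded shuffle breaks ties
      in_str <- in_str[sample(length(in_str))]
      in_str <- in_str[order(-lens[in_str])]
      k <- 1L
      for (id in in_str) {
        while (quota[[k]] == 0L) k <- if (k == length(quota)) 1L else k + 1L
        assignment[[id]] <- scen[[k]]
        quota[[k]] <- quota[[k]] - 1L
        k <- if (k == length(quota)) 1L else k + 1L
      }
    }
  })
  structure(
    list(assignment = assignment, target_sizes = target_sizes),
    class = "scenario_plan"
  )
}

#' @export
print.scenario_plan <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = names(x$target_sizes)))
  cat("<scenario_plan>\n  ")
  cat(paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a scenario plan to a corpus
#'
#' @param corpus A [pddi_corpus].
#' @param plan A [assign_scenarios()] result.
#' @return The corpus with its `scenario_assignment` replaced.
#' @export
apply_scenario_plan <- function(corpus, plan) {
  if (!setequal(names(plan$assignment), names(corpus$sections))) {
    stop_pddi("plan does not cover the corpus sections")
  }
  corpus$scenario_assignment <- plan$assignment[names(corpus$sections)]
  corpus
}

#' Summarize usability ratings
#'
#' Computes the margin values of a participants-by-scenario grid of
#' 5-point usability ratings: per-participant means (across scenarios),
#' per-scenario means (across participants), and per-group means taken
#' over all of a group's ratings.  Means are rounded half-up to two
#' decimals, the printed convention.
#'
#' @param ratings A data.frame with columns `participant`, `group`
#'   (e.g. `"expert"`/`"nonexpert"`), `scenario`, and `rating`
#'   (integers 1-5).  The participant-by-scenario grid must be
#'   complete; a missing cell fails with its name.
#' @return List with data.frames `per_participant`, `per_scenario`,
#'   and `group_means`.
#' @export
summarize_usability <- function(ratings) {
  stopifnot(all(c("participant", "group", "scenario", "rating") %in% names(ratings)))
  if (any(is.na(ratings$rating)) || any(ratings$rating < 1 | ratings$rating > 5)) {
    stop_pddi("ratings must be integers in [1, 5]")
  }
  participants <- unique(ratings$participant)
  scenarios <- sort(unique(as.character(ratings$scenario)))
  key <- paste(ratings$participant, ratings$scenario)
  for (p in participants) {
    for (s in scenarios) {
      if (!(paste(p, s) %in% key)) {
        stop_pddi("missing rating for participant '%s', scenario %s", p, s)
      }
    }
  }
  if (anyDuplicated(key)) {
    stop_pddi("duplicate rating for '%s'", key[duplicated(key)][1])
  }
  per_participant <- do.call(rbind, lapply(participants, function(p) {
    rows <- ratings[ratings$participant == p, ]
    data.frame(
      participant = p,
      group = rows$group[1],
      mean = round_half_up(mean(rows$rating), 2),
      stringsAsFactors = FALSE
    )
  }))
  per_scenario <- do.call(rbind, lapply(scenarios, function(s) {
    rows <- ratings[as.character(ratings$scenario) == s, ]
    data.frame(scenario = s, mean = round_half_up(mean(rows$rating), 2),
               stringsAsFactors = FALSE)
  }))
  group_means <- do.call(rbind, lapply(unique(ratings$group), function(g) {
    rows <- ratings[ratings$group == g, ]
    data.frame(group = g, mean = round_half_up(mean(rows$rating), 2),
               n_ratings = nrow(rows), stringsAsFactors = FALSE)
  }))
  list(
    per_participant = per_participant,
    per_scenario = per_scenario,
    group_means = group_means
  )
}

TIME_CATEGORIES <- c("<1h", "1-3h", "3-5h", ">5h")

#' Tally self-reported task completion times
#'
#' Cross-tabulates participants against the closed set of time
#' categories (`<1h`, `1-3h`, `3-5h`, `>5h`).
#'
#' @param reports A data.frame with columns `participant`, `scenario`,
#'   and `category` (from the closed set; anything else fails).
#' @return A participant-by-category contingency table; row sums equal
#'   each participant's number of reports.
#' @export
tally_time_categories <- function(reports) {
  if (nrow(reports) == 0) {
    return(table(participant = character(0), category = factor(character(0), TIME_CATEGORIES)))
  }
  bad <- which(!reports$category %in% TIME_CATEGORIES)
  if (length(bad)) {
    stop_pddi("unknown time category '%s' (participant '%s')",
              reports$category[bad[1]], reports$participant[bad[1]])
  }
  table(
    participant = reports$participant,
    category = factor(reports$category, levels = TIME_CATEGORIES)
  )
}
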