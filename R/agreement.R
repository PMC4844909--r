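#' Percentage of a count, rounded half-up to one decimal
#'
#' @param cell Count in the cell.
#' @param denominator Total the percentage is taken over.
#' @return `100 * cell / denominator` rounded half-up to one decimal;
#'   `NA` (an explicit undefined marker, never 0) when the denominator
#'   is zero.
#' @examples
#' format_percent(59, 151) # 39.1
#' format_percent(93, 93)  # 100
#' @export
format_percent <- function(cell, denominator) {
  if (denominator == 0) {
    return(NA_real_)
  }
  round_half_up(100 * cell / denominator, 1)
}

#' Render a count with its parenthesized percentage
#'
#' Integral percentages print without a trailing ".0" (`"93 (100)"`);
#' an undefined percentage prints as the bare count.
#'
#' @inheritParams format_percent
#' @return A string such as `"59 (39.1)"`.
#' @export
format_count_percent <- function(cell, denominator) {
  pct <- format_percent(cell, denominator)
  if (is.na(pct)) {
    return(sprintf("%d", cell))
  }
  if (pct == trunc(pct)) {
    sprintf("%d (%d)", cell, as.integer(pct))
  } else {
    sprintf("%d (%.1f)", cell, pct)
  }
}

#' Three-way user/NLP/reference agreement cross-tabulation
#'
#' For every reference PDDI mention, classifies whether the NLP
#' preannotation and the user each found it (via [match_sets()]),
#' yielding the four reference-side cells (NLP FN & user FN, NLP FN &
#' user TP — the user corrected an NLP miss, NLP TP & user FN — the NLP
#' was right and the user dropped it, NLP TP & user TP).  NLP mentions
#' unmatched by the reference form the NLP false-positive pool, split
#' by whether the user's set contains a mention matching them (user
#' accepted the false positive) or not (user rejected it).  User
#' mentions matching neither the reference nor the NLP FP pool are
#' user-invented false positives.
#'
#' @param user,nlp,reference [annotation_set] objects over `corpus`.
#' @param corpus A [pddi_corpus].
#' @param scenario_filter Optional character vector of scenario labels;
#'   only sections assigned to them are analyzed (the study design
#'   restricts this table to the scenario with full preannotation).
#' @return An object of class `pddi_agreement`: `n_reference`,
#'   `tp_cells` (named counts), `n_nlp_fp`, `fp_cells`, and `percents`
#'   (same shape, half-up to one decimal; the user-invented cell has no
#'   defined denominator and is reported as a bare count).
#' @export
build_agreement <- function(user, nlp, reference, corpus, scenario_filter = NULL) {
  if (!is.null(scenario_filter)) {
    keep <- names(corpus$scenario_assignment)[
      corpus$scenario_assignment %in% as.character(scenario_filter)
    ]
    user <- filter_set_sections(user, keep)
    nlp <- filter_set_sections(nlp, keep)
    reference <- filter_set_sections(reference, keep)
  }
  m_nlp <- match_sets(nlp, reference, corpus)
  m_user <- match_sets(user, reference, corpus)
  nref <- nrow(reference$pddi_mentions)
  nlp_found <- rep(FALSE, nref)
  nlp_found[m_nlp$pairs$reference] <- TRUE
  user_found <- rep(FALSE, nref)
  user_found[m_user$pairs$reference] <- TRUE
  tp_cells <- c(
    nlpFN_userFN = sum(!nlp_found & !user_found),
    nlpFN_userTP = sum(!nlp_found & user_found),
    nlpTP_userFN = sum(nlp_found & !user_found),
    nlpTP_userTP = sum(nlp_found & user_found)
  )

  # NLP false positives: match the user's leftover mentions against them
  nlp_fp_set <- subset_pddi(nlp, m_nlp$candidate_fp)
  user_left_set <- subset_pddi(user, m_user$candidate_fp)
  m_fp <- match_sets(user_left_set, nlp_fp_set, corpus)
  n_nlp_fp <- nrow(nlp_fp_set$pddi_mentions)
  fp_cells <- c(
    nlpTN_userFP = length(m_fp$candidate_fp),
    nlpFP_userTN = length(m_fp$reference_fn),
    nlpFP_userFP = nrow(m_fp$pairs)
  )

  percents <- list(
    tp_cells = vapply(tp_cells, format_percent, numeric(1), denominator = nref),
    fp_cells = c(
      nlpTN_userFP = NA_real_, # no defined denominator; reported as bare count
      nlpFP_userTN = format_percent(fp_cells[["nlpFP_userTN"]], n_nlp_fp),
      nlpFP_userFP = format_percent(fp_cells[["nlpFP_userFP"]], n_nlp_fp)
    )
  )
  structure(
    list(
      n_reference = nref,
      tp_cells = tp_cells,
      n_nlp_fp = n_nlp_fp,
      fp_cells = fp_cells,
      percents = percents,
      user_id = user$source_id
    ),
    class = "pddi_agreement"
  )
}

# keep only mentions in the given sections
filter_set_sections <- function(set, section_ids) {
  set$drug_mentions <- set$drug_mentions[set$drug_mentions$section_id %in% section_ids, , drop = FALSE]
  set$pddi_mentions <- set$pddi_mentions[set$pddi_mentions$section_id %in% section_ids, , drop = FALSE]
  set
}

# annotation set containing only the given PDDI mention rows
subset_pddi <- function(set, rows) {
  set$drug_mentions <- drug_mentions()
  set$pddi_mentions <- set$pddi_mentions[rows, , drop = FALSE]
  set
}

#' @export
print.pddi_agreement <- function(x, ...) {
  cat(sprintf("Agreement vs reference standard (user '%s')\n", x$user_id))
  cat(sprintf("Reference mentions (N=%d):\n", x$n_reference))
  cells <- x$tp_cells
  cat(sprintf(
    "  NLP FN/User FN %s | NLP FN/User TP %s | NLP TP/User FN %s | NLP TP/User TP %s\n",
    format_count_percent(cells[["nlpFN_userFN"]], x$n_reference),
    format_count_percent(cells[["nlpFN_userTP"]], x$n_reference),
    format_count_percent(cells[["nlpTP_userFN"]], x$n_reference),
    format_count_percent(cells[["nlpTP_userTP"]], x$n_reference)
  ))
  cat(sprintf("False positives (NLP FP pool n=%d):\n", x$n_nlp_fp))
  cat(sprintf(
    "  NLP TN/User FP %d | NLP FP/User TN %s | NLP FP/User FP %s\n",
    x$fp_cells[["nlpTN_userFP"]],
    format_count_percent(x$fp_cells[["nlpFP_userTN"]], x$n_nlp_fp),
    format_count_percent(x$fp_cells[["nlpFP_userFP"]], x$n_nlp_fp)
  ))
  invisible(x)
}

#' Write one or more agreement tables as TSV
#'
#' Rows mirror the published layout: one row per user with counts and
#' parenthesized percentages for the reference-side and FP-side cells.
#'
#' @param tables A list of `pddi_agreement` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_tsv <- function(tables, path) {
  if (inherits(tables, "pddi_agreement")) tables <- list(tables)
  rows <- lapply(tables, function(x) {
    data.frame(
      user = x$user_id,
      n_reference = x$n_reference,
      nlpFN_userFN = format_count_percent(x$tp_cells[["nlpFN_userFN"]], x$n_reference),
      nlpFN_userTP = format_count_percent(x$tp_cells[["nlpFN_userTP"]], x$n_reference),
      nlpTP_userFN = format_count_percent(x$tp_cells[["nlpTP_userFN"]], x$n_reference),
      nlpTP_userTP = format_count_percent(x$tp_cells[["nlpTP_userTP"]], x$n_reference),
      n_nlp_fp = x$n_nlp_fp,
      nlpTN_userFP = sprintf("%d", x$fp_cells[["nlpTN_userFP"]]),
      nlpFP_userTN = format_count_percent(x$fp_cells[["nlpFP_userTN"]], x$n_nlp_fp),
      nlpFP_userFP = format_count_percent(x$fp_cells[["nlpFP_userFP"]], x$n_nlp_fp),
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
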