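#' Rule configuration for the sentence-level PDDI extractor
#'
#' The extractor is a transparent, auditable rule system: a sentence
#' window is classified as containing a pharmacokinetic PDDI when at
#' least two distinct normalized ingredients co-occur with at least one
#' pharmacokinetic cue term.  Cue and negation lexicons ship as editable
#' TSV files under `extdata/` and can be overridden here.
#'
#' @param window_size Sentences per window, 1 (default) or 2; size-2
#'   windows slide over adjacent sentence pairs.
#' @param cues Character vector of cue stems, each matched
#'   case-insensitively at a token start (so `"inhibit"` covers
#'   "inhibited", "inhibitor").  Default: packaged `pddi-cues.tsv`.
#' @param negations Character vector of negation phrases matched
#'   case-insensitively as substrings of the window.  Default: packaged
#'   `negation-cues.tsv`.
#' @param quantitative_pattern Perl regex deciding the
#'   quantitative/qualitative statement split (numeric magnitude:
#'   percent, fold, or ratio).
#' @param fallback_policy Role-assignment fallback when no causative or
#'   passive frame matches; only `"first_drug_precipitant"` is defined.
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(window_size = 1L,
                        cues = NULL,
                        negations = NULL,
                        quantitative_pattern = NULL,
                        fallback_policy = "first_drug_precipitant") {
  if (!window_size %in% c(1L, 2L)) stop_pddi("window_size must be 1 or 2")
  if (!identical(fallback_policy, "first_drug_precipitant")) {
    stop_pddi("unknown fallback_policy '%s'", fallback_policy)
  }
  cues <- cues %||% utils::read.delim(pddikit_extdata("pddi-cues.tsv"),
                                      stringsAsFactors = FALSE)$cue
  negations <- negations %||% utils::read.delim(pddikit_extdata("negation-cues.tsv"),
                                                stringsAsFactors = FALSE)$cue
  quantitative_pattern <- quantitative_pattern %||%
    "\\d+(\\.\\d+)?\\s*(%|percent\\b)|\\d+(\\.\\d+)?\\s*-?\\s*fold\\b|\\bratio\\s+of\\s+\\d"
  structure(
    list(
      window_size = as.integer(window_size),
      cues = cues,
      negations = negations,
      cue_pattern = paste0("\\b(?:", paste(regex_escape(cues), collapse = "|"), ")"),
      quantitative_pattern = quantitative_pattern,
      # "Y ... was increased by X": auxiliary then a trailing agentive "by"
      # in the text between the two drugs
      passive_pattern = "\\b(?:was|were|is|are)\\b.*\\bby\\s*$",
      # "X increased/inhibited ... Y": causative verb between the drugs
      causative_pattern = "\\b(?:increas|decreas|inhibit|induc|elevat|reduc|rais|lower|prolong|alter|affect)\\w*\\b",
      fallback_policy = fallback_policy
    ),
    class = "rule_config"
  )
}

has_cue <- function(text, rules) {
  grepl(rules$cue_pattern, text, perl = TRUE, ignore.case = TRUE)
}

has_negation <- function(text, rules) {
  lc <- tolower(text)
  any(vapply(tolower(rules$negations), function(neg) grepl(neg, lc, fixed = TRUE), logical(1)))
}

is_quantitative <- function(text, rules) {
  grepl(rules$quantitative_pattern, text, perl = TRUE, ignore.case = TRUE)
}

# role assignment for one ordered-by-occurrence drug pair; returns TRUE
# if the first-occurring drug is the precipitant
first_is_precipitant <- function(between, rules) {
  if (grepl(rules$passive_pattern, between, perl = TRUE, ignore.case = TRUE)) {
    return(FALSE) # "Y ... was increased by X" => X (second) precipitates
  }
  if (grepl(rules$causative_pattern, between, perl = TRUE, ignore.case = TRUE)) {
    return(TRUE) # "X increased ... Y"
  }
  TRUE # documented fallback: first drug = precipitant
}

#' Extract PDDI mentions from one section with the rule system
#'
#' For each sentence window: the window is a PDDI candidate iff at least
#' two distinct normalized ingredients co-occur and at least one
#' pharmacokinetic cue term occurs; modality is negative iff a negation
#' phrase scopes the window, else positive; statement is quantitative
#' iff a numeric magnitude (percent/fold/ratio) occurs, else
#' qualitative.  Roles: for each unordered drug pair (ordered by first
#' occurrence), a passive frame between the drugs ("... was increased by
#' X") makes the second drug the precipitant; otherwise a causative verb
#' between them ("X increased ... Y") makes the first the precipitant;
#' otherwise the first drug is the precipitant (explicit fallback,
#' flagged in the mention's `extra` slot).  One mention is emitted per
#' distinct normalized ingredient pair per positive window.
#'
#' @param section A [label_section].
#' @param drugs A [drug_mentions()] table for the section (from
#'   [annotate_drug_mentions()]).
#' @param rules A [rule_config()].
#' @return A list with `classifications` (data.frame: one row per
#'   window with `section_id`, `sentences` list column, `is_pddi`,
#'   `modality`) and `mentions` (a [pddi_mentions()] table).
#' @export
extract_pddi_mentions <- function(section, drugs, rules = rule_config()) {
  ns <- n_sentences(section)
  w <- min(rules$window_size, max(ns, 1L))
  windows <- if (ns >= w) lapply(seq_len(ns - w + 1L) - 1L, function(i) i + seq_len(w) - 1L) else list()

  cls <- list()
  men <- list()
  for (win in windows) {
    sp <- section$sentence_spans[win + 1L, , drop = FALSE]
    wstart <- min(sp$start)
    wend <- max(sp$end)
    wtext <- slice_text(section$text, wstart, wend)
    ind <- which(drugs$char_start >= wstart & drugs$char_end <= wend)
    ind <- ind[order(drugs$char_start[ind])]
    first_pos <- ind[!duplicated(drugs$normalized_ingredient_id[ind])]
    pddi <- length(first_pos) >= 2L && has_cue(wtext, rules)
    modality <- NA_character_
    if (pddi) {
      modality <- if (has_negation(wtext, rules)) "negative" else "positive"
      statement <- if (is_quantitative(wtext, rules)) "quantitative" else "qualitative"
      for (a in seq_len(length(first_pos) - 1L)) {
        for (b in seq((a + 1L), length(first_pos))) {
          i <- first_pos[a]
          j <- first_pos[b]
          between <- slice_text(section$text, drugs$char_end[i], drugs$char_start[j])
          forward <- first_is_precipitant(between, rules)
          framed <- grepl(rules$passive_pattern, between, perl = TRUE, ignore.case = TRUE) ||
            grepl(rules$causative_pattern, between, perl = TRUE, ignore.case = TRUE)
          prec <- if (forward) i else j
          obj <- if (forward) j else i
          men[[length(men) + 1L]] <- list(
            sentence_indices = win,
            precipitant_id = drugs$normalized_ingredient_id[prec],
            precipitant_type = drugs$entity_type[prec],
            object_id = drugs$normalized_ingredient_id[obj],
            object_type = drugs$entity_type[obj],
            statement = statement,
            modality = modality,
            role_fallback = !framed
          )
        }
      }
    }
    cls[[length(cls) + 1L]] <- list(sentences = win, is_pddi = pddi, modality = modality)
  }

  classifications <- data.frame(
    section_id = rep(section$section_id, length(cls)),
    is_pddi = vapply(cls, function(x) x$is_pddi, logical(1)),
    modality = vapply(cls, function(x) x$modality, character(1)),
    stringsAsFactors = FALSE
  )
  classifications$sentences <- lapply(cls, function(x) x$sentences)

  mentions <- pddi_mentions(
    section_id = rep(section$section_id, length(men)),
    sentence_indices = lapply(men, function(x) x$sentence_indices),
    precipitant_id = vapply(men, function(x) x$precipitant_id, character(1)),
    precipitant_type = vapply(men, function(x) x$precipitant_type, character(1)),
    object_id = vapply(men, function(x) x$object_id, character(1)),
    object_type = vapply(men, function(x) x$object_type, character(1)),
    statement = vapply(men, function(x) x$statement, character(1)),
    modality = vapply(men, function(x) x$modality, character(1)),
    extra = lapply(men, function(x) if (x$role_fallback) list(role_fallback = TRUE) else NULL)
  )
  list(classifications = classifications, mentions = mentions)
}

#' Run the full preannotation pipeline over a corpus
#'
#' Composes dictionary NER ([annotate_drug_mentions()]) and the rule-
#' based PDDI extractor ([extract_pddi_mentions()]) over every section,
#' in section order.  Deterministic given inputs and configuration.
#'
#' @param corpus A [pddi_corpus].
#' @param lexicon A [pddi_lexicon].
#' @param rules A [rule_config()].
#' @param source_id Source id for the resulting set (default `"nlp"`).
#' @return An [annotation_set] with `source_kind = "nlp"`.
#' @export
run_pipeline <- function(corpus, lexicon, rules = rule_config(), source_id = "nlp") {
  dms <- list()
  pms <- list()
  for (sec in corpus$sections) {
    dm <- annotate_drug_mentions(sec, lexicon)
    res <- extract_pddi_mentions(sec, dm, rules)
    dms[[length(dms) + 1L]] <- dm
    pms[[length(pms) + 1L]] <- res$mentions
  }
  set <- annotation_set(
    source_id = source_id,
    source_kind = "nlp",
    drug_mentions = do.call(rbind, c(dms, list(drug_mentions()))),
    pddi_mentions = do.call(rbind, c(pms, list(pddi_mentions())))
  )
  validate_annotation_set(set, corpus)
  set
}
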