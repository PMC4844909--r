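DRUG_ENTITY_TYPES <- c("active_ingredient", "metabolite", "drug_product")
LEXICON_ENTITY_TYPES <- c(DRUG_ENTITY_TYPES, "non_drug")
STATEMENT_TYPES <- c("quantitative", "qualitative")
MODALITY_TYPES <- c("positive", "negative")
SOURCE_KINDS <- c("reference", "nlp", "human")

#' Build a drug-mention table
#'
#' One row per typed, normalized drug span.  Offsets are 0-based,
#' half-open into the section text; `surface` must equal the text slice.
#' `normalized_ingredient_id` equals `concept_id` except for drug
#' products with a sole-active-ingredient mapping.
#'
#' @param section_id,char_start,char_end,surface,entity_type,concept_id,
#'   normalized_ingredient_id Parallel vectors (recycled if length 1).
#' @param unmapped_product Logical flag: a drug product with no
#'   sole-ingredient mapping (kept under its own concept id).
#' @param extra List of named lists with pass-through payload.
#' @return A data.frame with one row per mention.
#' @export
drug_mentions <- function(section_id = character(0), char_start = integer(0),
                          char_end = integer(0), surface = character(0),
                          entity_type = character(0), concept_id = character(0),
                          normalized_ingredient_id = concept_id,
                          unmapped_product = FALSE, extra = NULL) {
  n <- max(length(section_id), length(char_start))
  out <- data.frame(
    section_id = as.character(section_id),
    char_start = as.integer(char_start),
    char_end = as.integer(char_end),
    surface = as.character(surface),
    entity_type = as.character(entity_type),
    concept_id = as.character(concept_id),
    normalized_ingredient_id = as.character(normalized_ingredient_id),
    unmapped_product = rep_len(as.logical(unmapped_product), n),
    stringsAsFactors = FALSE
  )
  out$extra <- extra %||% rep(list(NULL), nrow(out))
  out
}

#' Build a PDDI-mention table
#'
#' One row per PDDI claim: a precipitant and an object drug (normalized
#' ingredient id plus entity type), anchored to a non-empty set of
#' sentence indices (0-based, into the section's canonical
#' segmentation; contiguity is not required), with a statement type
#' (quantitative/qualitative) and modality (positive/negative).
#'
#' @param section_id Character vector of section ids.
#' @param sentence_indices List of integer vectors (one per mention).
#' @param precipitant_id,precipitant_type,object_id,object_type Drug
#'   references for the two roles.
#' @param statement `"quantitative"` or `"qualitative"`.
#' @param modality `"positive"` or `"negative"`.
#' @param uid Optional stable mention identifier (used by the simulator's
#'   ground-truth ledger); `NA` otherwise.
#' @param extra List of named lists with pass-through payload.
#' @return A data.frame with one row per mention and a list column
#'   `sentence_indices`.
#' @export
pddi_mentions <- function(section_id = character(0), sentence_indices = list(),
                          precipitant_id = character(0), precipitant_type = character(0),
                          object_id = character(0), object_type = character(0),
                          statement = character(0), modality = character(0),
                          uid = NA_character_, extra = NULL) {
  n <- length(section_id)
  out <- data.frame(
    section_id = as.character(section_id),
    precipitant_id = as.character(precipitant_id),
    precipitant_type = as.character(precipitant_type),
    object_id = as.character(object_id),
    object_type = as.character(object_type),
    statement = as.character(statement),
    modality = as.character(modality),
    uid = rep_len(as.character(uid), n),
    stringsAsFactors = FALSE
  )
  out$sentence_indices <- lapply(sentence_indices, function(x) sort(unique(as.integer(x))))
  out$extra <- extra %||% rep(list(NULL), nrow(out))
  out[, c(
    "section_id", "sentence_indices", "precipitant_id", "precipitant_type",
    "object_id", "object_type", "statement", "modality", "uid", "extra"
  )]
}

# identity key used for the duplicate-mention invariant
pddi_keys <- function(pm) {
  if (nrow(pm) == 0) return(character(0))
  sentences <- vapply(pm$sentence_indices, function(x) paste(x, collapse = ","), character(1))
  paste(pm$section_id, pm$precipitant_id, pm$object_id, pm$modality, pm$statement, sentences,
        sep = "|")
}

#' Construct an annotation set
#'
#' All mentions produced by one source (the reference standard, an NLP
#' run, or one human annotator) over a corpus.
#'
#' @param source_id Opaque source identifier (e.g. `"reference"`,
#'   `"nlp"`, `"annotator-3"`).
#' @param source_kind One of `"reference"`, `"nlp"`, `"human"`.
#' @param drug_mentions A [drug_mentions()] table.
#' @param pddi_mentions A [pddi_mentions()] table.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(source_id, source_kind,
                           drug_mentions = pddikit::drug_mentions(),
                           pddi_mentions = pddikit::pddi_mentions()) {
  if (!is_string(source_id)) stop_pddi("source_id must be a single string")
  if (!source_kind %in% SOURCE_KINDS) {
    stop_pddi("source_kind must be one of %s", paste(SOURCE_KINDS, collapse = ", "))
  }
  structure(
    list(
      source_id = source_id,
      source_kind = source_kind,
      drug_mentions = drug_mentions,
      pddi_mentions = pddi_mentions
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set '%s' (%s): %d drug mentions, %d PDDI mentions>\n",
    x$source_id, x$source_kind, nrow(x$drug_mentions), nrow(x$pddi_mentions)
  ))
  invisible(x)
}

#' Validate an annotation set against its invariants
#'
#' Checks field enumerations, offset sanity, surface/text agreement and
#' sentence-index validity (against `corpus` when supplied), distinct
#' precipitant/object ids, and the no-duplicate-PDDI rule.  Failures
#' name the offending mention.
#'
#' @param set An [annotation_set].
#' @param corpus Optional [pddi_corpus] for text-level checks.
#' @return `set`, invisibly, if valid; otherwise an error.
#' @export
validate_annotation_set <- function(set, corpus = NULL) {
  dm <- set$drug_mentions
  pm <- set$pddi_mentions
  bad <- which(!dm$entity_type %in% DRUG_ENTITY_TYPES)
  if (length(bad)) {
    stop_pddi("drug mention %d: invalid entity_type '%s'", bad[1], dm$entity_type[bad[1]])
  }
  bad <- which(!(dm$char_start >= 0 & dm$char_start < dm$char_end))
  if (length(bad)) {
    stop_pddi("drug mention %d (section '%s'): invalid offsets [%d, %d)",
              bad[1], dm$section_id[bad[1]], dm$char_start[bad[1]], dm$char_end[bad[1]])
  }
  bad <- which(!pm$statement %in% STATEMENT_TYPES)
  if (length(bad)) stop_pddi("PDDI mention %d: invalid statement '%s'", bad[1], pm$statement[bad[1]])
  bad <- which(!pm$modality %in% MODALITY_TYPES)
  if (length(bad)) stop_pddi("PDDI mention %d: invalid modality '%s'", bad[1], pm$modality[bad[1]])
  bad <- which(pm$precipitant_id == pm$object_id)
  if (length(bad)) {
    stop_pddi("PDDI mention %d (section '%s'): precipitant and object ids are both '%s'",
              bad[1], pm$section_id[bad[1]], pm$precipitant_id[bad[1]])
  }
  bad <- which(vapply(pm$sentence_indices, length, integer(1)) == 0L)
  if (length(bad)) stop_pddi("PDDI mention %d: empty sentence_indices", bad[1])
  dup <- duplicated(pddi_keys(pm))
  if (any(dup)) {
    stop_pddi("duplicate PDDI mention at row %d (section '%s')",
              which(dup)[1], pm$section_id[which(dup)[1]])
  }
  if (!is.null(corpus)) {
    for (id in unique(c(dm$section_id, pm$section_id))) {
      if (is.null(corpus$sections[[id]])) {
        stop_pddi("mention references unknown section '%s'", id)
      }
    }
    for (i in seq_len(nrow(dm))) {
      sec <- corpus$sections[[dm$section_id[i]]]
      if (dm$char_end[i] > nchar(sec$text)) {
        stop_pddi("drug mention %d: offsets exceed section '%s' length", i, sec$section_id)
      }
      got <- slice_text(sec$text, dm$char_start[i], dm$char_end[i])
      if (!identical(got, dm$surface[i])) {
        stop_pddi("drug mention %d (section '%s'): surface '%s' != text slice '%s'",
                  i, sec$section_id, dm$surface[i], got)
      }
    }
    for (i in seq_len(nrow(pm))) {
      sec <- corpus$sections[[pm$section_id[i]]]
      idx <- pm$sentence_indices[[i]]
      if (any(idx < 0L) || any(idx >= n_sentences(sec))) {
        stop_pddi("PDDI mention %d (section '%s'): sentence index out of range", i, sec$section_id)
      }
    }
  }
  invisible(set)
}
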