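ANNOTATION_FORMAT <- "pddikit-annotation/v1"

DRUG_BODY_KEYS <- c("type", "entity_type", "concept_id", "normalized_ingredient_id",
                    "unmapped_product", "uid")
PDDI_BODY_KEYS <- c("type", "precipitant", "object", "statement", "modality", "uid")

#' Write an annotation set as Open-Annotation-style JSON
#'
#' Each mention becomes an annotation with a `target` (section id plus a
#' text-position selector carrying the exact quoted text) and a `body`
#' carrying the typed fields of the data model.  PDDI mentions anchor to
#' sentence indices; their selector (covering span plus quote) is
#' embedded when `corpus` is supplied, since only the corpus holds the
#' sentence text.  Pass-through payload in the `extra` column is written
#' as additional body keys, so [read_annotations()] round-trips
#' losslessly.  The document layout is described by the packaged schema
#' (`pddikit_extdata("annotation-schema.json")`).
#'
#' @param set An [annotation_set]; validated before writing.
#' @param path Output file path.
#' @param corpus Optional [pddi_corpus] used to embed and verify quotes.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path, corpus = NULL) {
  validate_annotation_set(set, corpus)
  dm <- set$drug_mentions
  pm <- set$pddi_mentions
  anns <- vector("list", nrow(dm) + nrow(pm))
  k <- 0L
  for (i in seq_len(nrow(dm))) {
    body <- list(
      type = "DrugMention",
      entity_type = dm$entity_type[i],
      concept_id = dm$concept_id[i],
      normalized_ingredient_id = dm$normalized_ingredient_id[i],
      unmapped_product = dm$unmapped_product[i]
    )
    body <- c(body, dm$extra[[i]])
    k <- k + 1L
    anns[[k]] <- list(
      id = sprintf("d%d", i),
      target = list(
        section = dm$section_id[i],
        selector = list(
          type = "TextPositionSelector",
          start = dm$char_start[i],
          end = dm$char_end[i],
          exact = dm$surface[i]
        )
      ),
      body = body
    )
  }
  for (i in seq_len(nrow(pm))) {
    body <- list(
      type = "PDDIMention",
      precipitant = list(id = pm$precipitant_id[i], entity_type = pm$precipitant_type[i]),
      object = list(id = pm$object_id[i], entity_type = pm$object_type[i]),
      statement = pm$statement[i],
      modality = pm$modality[i]
    )
    if (!is.na(pm$uid[i])) body$uid <- pm$uid[i]
    body <- c(body, pm$extra[[i]])
    target <- list(
      section = pm$section_id[i],
      sentences = as.list(pm$sentence_indices[[i]])
    )
    if (!is.null(corpus)) {
      sec <- corpus_section(corpus, pm$section_id[i])
      sp <- sec$sentence_spans[pm$sentence_indices[[i]] + 1L, , drop = FALSE]
      target$selector <- list(
        type = "TextPositionSelector",
        start = min(sp$start),
        end = max(sp$end),
        exact = slice_text(sec$text, min(sp$start), max(sp$end))
      )
    }
    k <- k + 1L
    anns[[k]] <- list(id = sprintf("p%d", i), target = target, body = body)
  }
  doc <- list(
    format = ANNOTATION_FORMAT,
    source = list(id = set$source_id, kind = set$source_kind),
    annotations = anns
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an annotation set from Open-Annotation-style JSON
#'
#' Inverse of [write_annotations()].  Unknown body keys are preserved in
#' the mentions' `extra` pass-through column.  When `corpus` is given,
#' every selector's exact quote is checked against the section text and
#' a mismatch fails with the offending annotation id.
#'
#' @param path Path to a JSON document written by [write_annotations()]
#'   (or hand-written to the same schema).
#' @param corpus Optional [pddi_corpus] for quote verification.
#' @return An [annotation_set].
#' @export
read_annotations <- function(path, corpus = NULL) {
  if (!file.exists(path)) stop_pddi("annotation file '%s' does not exist", path)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop_pddi("malformed annotation JSON '%s': %s", path, conditionMessage(e))
  )
  src <- doc$source %||% list()
  dm_rows <- list()
  pm_rows <- list()
  for (ann in doc$annotations %||% list()) {
    id <- ann$id %||% "<unnamed>"
    body <- ann$body %||% list()
    target <- ann$target %||% list()
    type <- body$type %||% stop_pddi("annotation '%s' has no body type", id)
    sel <- target$selector
    if (!is.null(sel) && !is.null(corpus)) {
      sec <- corpus_section(corpus, target$section)
      got <- slice_text(sec$text, as.integer(sel$start), as.integer(sel$end))
      if (!identical(got, sel$exact)) {
        stop_pddi("annotation '%s': exact quote disagrees with section '%s' text",
                  id, target$section)
      }
    }
    if (identical(type, "DrugMention")) {
      extra <- body[setdiff(names(body), DRUG_BODY_KEYS)]
      dm_rows[[length(dm_rows) + 1L]] <- list(
        section_id = target$section,
        char_start = as.integer(sel$start),
        char_end = as.integer(sel$end),
        surface = sel$exact,
        entity_type = body$entity_type,
        concept_id = body$concept_id,
        normalized_ingredient_id = body$normalized_ingredient_id %||% body$concept_id,
        unmapped_product = isTRUE(body$unmapped_product),
        extra = if (length(extra)) extra else NULL
      )
    } else if (identical(type, "PDDIMention")) {
      extra <- body[setdiff(names(body), PDDI_BODY_KEYS)]
      pm_rows[[length(pm_rows) + 1L]] <- list(
        section_id = target$section,
        sentence_indices = vapply(target$sentences, as.integer, integer(1)),
        precipitant_id = body$precipitant$id,
        precipitant_type = body$precipitant$entity_type,
        object_id = body$object$id,
        object_type = body$object$entity_type,
        statement = body$statement,
        modality = body$modality,
        uid = body$uid %||% NA_character_,
        extra = if (length(extra)) extra else NULL
      )
    } else {
      stop_pddi("annotation '%s': unknown body type '%s'", id, type)
    }
  }
  field <- function(rows, name) vapply(rows, function(r) r[[name]], character(1))
  dm <- drug_mentions(
    section_id = field(dm_rows, "section_id"),
    char_start = vapply(dm_rows, function(r) r$char_start, integer(1)),
    char_end = vapply(dm_rows, function(r) r$char_end, integer(1)),
    surface = field(dm_rows, "surface"),
    entity_type = field(dm_rows, "entity_type"),
    concept_id = field(dm_rows, "concept_id"),
    normalized_ingredient_id = field(dm_rows, "normalized_ingredient_id"),
    unmapped_product = vapply(dm_rows, function(r) r$unmapped_product, logical(1)),
    extra = lapply(dm_rows, function(r) r$extra)
  )
  pm <- pddi_mentions(
    section_id = field(pm_rows, "section_id"),
    sentence_indices = lapply(pm_rows, function(r) r$sentence_indices),
    precipitant_id = field(pm_rows, "precipitant_id"),
    precipitant_type = field(pm_rows, "precipitant_type"),
    object_id = field(pm_rows, "object_id"),
    object_type = field(pm_rows, "object_type"),
    statement = field(pm_rows, "statement"),
    modality = field(pm_rows, "modality"),
    uid = field(pm_rows, "uid"),
    extra = lapply(pm_rows, function(r) r$extra)
  )
  set <- annotation_set(
    source_id = src$id %||% "unknown",
    source_kind = src$kind %||% "human",
    drug_mentions = dm,
    pddi_mentions = pm
  )
  validate_annotation_set(set, corpus)
  set
}
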