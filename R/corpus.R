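#' Construct a label section
#'
#' A `label_section` is one text section of a drug product label, the
#' unit of annotation and of per-label metrics.  Sentence segmentation
#' is computed once here so that every annotation source anchors PDDI
#' mentions to the same canonical sentence indices.
#'
#' @param section_id Opaque section identifier.
#' @param label_id Identifier of the product label the section belongs to.
#' @param text Section text (UTF-8).
#' @param length_class `"short"` or `"long"` (usually set by the corpus
#'   loader from the corpus-wide median length); `NA` if not yet classed.
#' @param abbreviations Abbreviation list for [segment_sentences()].
#' @return An object of class `label_section`.
#' @export
label_section <- function(section_id, label_id, text, length_class = NA_character_,
                          abbreviations = default_abbreviations()) {
  if (!is_string(section_id)) stop_pddi("section_id must be a single string")
  if (!is_string(label_id)) stop_pddi("label_id must be a single string")
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_pddi("text must be a single string (section '%s')", section_id)
  }
  spans <- segment_sentences(text, abbreviations)
  structure(
    list(
      section_id = section_id,
      label_id = label_id,
      text = text,
      sentence_spans = spans,
      length_class = length_class
    ),
    class = "label_section"
  )
}

#' @export
print.label_section <- function(x, ...) {
  cat(sprintf(
    "<label_section %s (label %s): %d chars, %d sentences, %s>\n",
    x$section_id, x$label_id, nchar(x$text), nrow(x$sentence_spans),
    if (is.na(x$length_class)) "unclassed" else x$length_class
  ))
  invisible(x)
}

n_sentences <- function(section) nrow(section$sentence_spans)

sentence_text <- function(section, index) {
  sp <- section$sentence_spans[index + 1L, , drop = FALSE]
  slice_text(section$text, min(sp$start), max(sp$end))
}

classify_length <- function(nchars, threshold) {
  ifelse(nchars > threshold, "long", "short")
}

#' Construct a corpus of label sections
#'
#' @param sections A list of [label_section] objects.
#' @param scenario_assignment Named character vector mapping section id to
#'   a scenario label (`"training"`, `"1"`..`"4"`, or `"unassigned"`);
#'   defaults to `"unassigned"` for every section.
#' @param length_threshold Character-count threshold for the short/long
#'   split; defaults to the median section length.  Sections strictly
#'   longer than the threshold are `"long"`.
#' @return An object of class `pddi_corpus`.
#' @export
pddi_corpus <- function(sections, scenario_assignment = NULL, length_threshold = NULL) {
  ids <- vapply(sections, function(s) s$section_id, character(1))
  if (anyDuplicated(ids)) {
    stop_pddi("duplicate section_id '%s'", ids[duplicated(ids)][1])
  }
  names(sections) <- ids
  if (is.null(scenario_assignment)) {
    scenario_assignment <- stats::setNames(rep("unassigned", length(ids)), ids)
  }
  if (!setequal(names(scenario_assignment), ids)) {
    stop_pddi("scenario_assignment keys must equal section ids")
  }
  scenario_assignment <- scenario_assignment[ids]
  lens <- vapply(sections, function(s) nchar(s$text), numeric(1))
  if (length(sections)) {
    threshold <- length_threshold %||% stats::median(lens)
    for (i in seq_along(sections)) {
      sections[[i]]$length_class <- classify_length(lens[i], threshold)
    }
  } else {
    threshold <- length_threshold %||% 0
  }
  structure(
    list(
      sections = sections,
      scenario_assignment = scenario_assignment,
      length_threshold = threshold
    ),
    class = "pddi_corpus"
  )
}

#' @export
print.pddi_corpus <- function(x, ...) {
  tab <- table(x$scenario_assignment)
  cat(sprintf("<pddi_corpus: %d sections>\n", length(x$sections)))
  if (length(tab)) {
    cat("  scenarios:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of sections in a corpus
#' @param corpus A [pddi_corpus] object.
#' @return Integer count.
#' @export
corpus_size <- function(corpus) length(corpus$sections)

corpus_section <- function(corpus, section_id) {
  sec <- corpus$sections[[section_id]]
  if (is.null(sec)) stop_pddi("unknown section_id '%s'", section_id)
  sec
}

#' Load a corpus from a manifest file
#'
#' The manifest is a JSON document `{"sections": [{"section_id": ...,
#' "label_id": ..., "file": ..., "scenario": ...}, ...]}` with section
#' text files resolved relative to the manifest's directory.  Sentence
#' segmentation and the short/long length class are computed at load
#' time; the load fails atomically (no partial corpus) on a missing
#' file, duplicate id, or malformed record, naming the offending record.
#'
#' @param manifest_path Path to the manifest JSON.
#' @param length_threshold Optional short/long character threshold
#'   (default: median section length).
#' @return A [pddi_corpus].
#' @export
load_corpus <- function(manifest_path, length_threshold = NULL) {
  if (!file.exists(manifest_path)) stop_pddi("manifest '%s' does not exist", manifest_path)
  manifest <- tryCatch(
    jsonlite::read_json(manifest_path),
    error = function(e) stop_pddi("malformed manifest JSON '%s': %s", manifest_path, conditionMessage(e))
  )
  recs <- manifest$sections
  if (is.null(recs)) stop_pddi("manifest '%s' has no 'sections' array", manifest_path)
  base <- dirname(manifest_path)
  seen <- character(0)
  sections <- vector("list", length(recs))
  scenario <- character(length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    for (field in c("section_id", "file")) {
      if (!is_string(rec[[field]] %||% NA_character_)) {
        stop_pddi("manifest record %d is missing field '%s'", i, field)
      }
    }
    if (rec$section_id %in% seen) {
      stop_pddi("duplicate section_id '%s' in manifest", rec$section_id)
    }
    seen <- c(seen, rec$section_id)
    path <- file.path(base, rec$file)
    if (!file.exists(path)) {
      stop_pddi("section '%s': file '%s' does not exist", rec$section_id, path)
    }
    text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    sections[[i]] <- label_section(
      rec$section_id,
      rec$label_id %||% rec$section_id,
      text
    )
    scenario[i] <- as.character(rec$scenario %||% "unassigned")
  }
  names(scenario) <- seen
  pddi_corpus(sections, scenario, length_threshold)
}

#' Write a corpus to a directory as manifest plus text files
#'
#' Inverse of [load_corpus()]: writes one UTF-8 text file per section and
#' a `manifest.json` referencing them.
#'
#' @param corpus A [pddi_corpus].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(corpus$sections, function(sec) {
    file <- paste0(sec$section_id, ".txt")
    writeLines(sec$text, file.path(dir, file), useBytes = TRUE)
    list(
      section_id = sec$section_id,
      label_id = sec$label_id,
      file = file,
      scenario = unname(corpus$scenario_assignment[[sec$section_id]])
    )
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(sections = unname(recs)), manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
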