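#' Construct a drug lexicon
#'
#' The lexicon emulates the terminology resources behind dictionary NER:
#' each entry is a concept with a preferred name, optional synonyms, and
#' an entity type (`active_ingredient`, `metabolite`, `drug_product`, or
#' `non_drug`, the last being matched then filtered out).  The
#' product-to-ingredient map carries sole-active-ingredient
#' relationships used to normalize drug product mentions.
#'
#' @param entries A data.frame with columns `concept_id`, `name`,
#'   `entity_type`, and `synonyms` (a list column of character vectors,
#'   or a character column with pipe-separated synonyms).
#' @param product_to_ingredient Named character vector mapping product
#'   concept ids to active-ingredient concept ids.
#' @return An object of class `pddi_lexicon`.
#' @export
pddi_lexicon <- function(entries, product_to_ingredient = character(0)) {
  stopifnot(all(c("concept_id", "name", "entity_type") %in% names(entries)))
  entries$concept_id <- as.character(entries$concept_id)
  entries$name <- as.character(entries$name)
  entries$entity_type <- as.character(entries$entity_type)
  if (is.null(entries$synonyms)) {
    entries$synonyms <- rep(list(character(0)), nrow(entries))
  } else if (is.character(entries$synonyms)) {
    entries$synonyms <- lapply(entries$synonyms, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
    })
  }
  if (anyDuplicated(entries$concept_id)) {
    stop_pddi("duplicate concept_id '%s'", entries$concept_id[duplicated(entries$concept_id)][1])
  }
  bad <- which(!entries$entity_type %in% LEXICON_ENTITY_TYPES)
  if (length(bad)) {
    stop_pddi("entry '%s': invalid entity_type '%s'",
              entries$concept_id[bad[1]], entries$entity_type[bad[1]])
  }
  p2i <- product_to_ingredient
  if (length(p2i)) {
    type_of <- stats::setNames(entries$entity_type, entries$concept_id)
    bad <- names(p2i)[is.na(type_of[names(p2i)]) | type_of[names(p2i)] != "drug_product"]
    if (length(bad)) stop_pddi("relationship key '%s' is not a drug_product concept", bad[1])
    bad <- unname(p2i)[is.na(type_of[p2i]) | type_of[p2i] != "active_ingredient"]
    if (length(bad)) stop_pddi("relationship value '%s' is not an active_ingredient concept", bad[1])
    if (anyDuplicated(names(p2i))) {
      stop_pddi("product '%s' maps to more than one ingredient",
                names(p2i)[duplicated(names(p2i))][1])
    }
  }
  structure(
    list(entries = entries, product_to_ingredient = p2i),
    class = "pddi_lexicon"
  )
}

#' @export
print.pddi_lexicon <- function(x, ...) {
  tab <- table(x$entries$entity_type)
  cat(sprintf("<pddi_lexicon: %d concepts (%s); %d product->ingredient relations>\n",
              nrow(x$entries),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$product_to_ingredient)))
  invisible(x)
}

#' Read a lexicon from TSV files
#'
#' The lexicon TSV has columns `concept_id`, `name`, `type`, `synonyms`
#' (pipe-separated, possibly empty); the optional relationship TSV has
#' columns `product_id`, `ingredient_id` and emulates sole-active-
#' ingredient relations.
#'
#' @param lexicon_path Path to the lexicon TSV.
#' @param relations_path Optional path to the relationship TSV.
#' @return A [pddi_lexicon].
#' @export
read_lexicon <- function(lexicon_path, relations_path = NULL) {
  lex <- utils::read.delim(lexicon_path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  entries <- data.frame(
    concept_id = lex$concept_id,
    name = lex$name,
    entity_type = lex$type,
    stringsAsFactors = FALSE
  )
  entries$synonyms <- lex$synonyms %||% rep("", nrow(lex))
  p2i <- character(0)
  if (!is.null(relations_path)) {
    rel <- utils::read.delim(relations_path, stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = NULL)
    p2i <- stats::setNames(rel$ingredient_id, rel$product_id)
  }
  pddi_lexicon(entries, p2i)
}

#' Write a lexicon to TSV files
#'
#' @param lexicon A [pddi_lexicon].
#' @param lexicon_path Output path for the concept TSV.
#' @param relations_path Optional output path for the relationship TSV.
#' @return `lexicon_path`, invisibly.
#' @export
write_lexicon <- function(lexicon, lexicon_path, relations_path = NULL) {
  out <- data.frame(
    concept_id = lexicon$entries$concept_id,
    name = lexicon$entries$name,
    type = lexicon$entries$entity_type,
    synonyms = vapply(lexicon$entries$synonyms, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, lexicon_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(relations_path)) {
    rel <- data.frame(
      product_id = names(lexicon$product_to_ingredient),
      ingredient_id = unname(lexicon$product_to_ingredient),
      stringsAsFactors = FALSE
    )
    utils::write.table(rel, relations_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(lexicon_path)
}

# expanded name table for dictionary matching: one row per surface name
# (preferred names and synonyms); duplicate surfaces keep the first
# entry in lexicon order
lexicon_lookup <- function(lexicon) {
  e <- lexicon$entries
  reps <- lengths(e$synonyms) + 1L
  names_all <- unlist(Map(function(n, s) c(n, s), e$name, e$synonyms), use.names = FALSE)
  lk <- data.frame(
    name = names_all,
    name_lc = tolower(names_all),
    concept_id = rep(e$concept_id, reps),
    entity_type = rep(e$entity_type, reps),
    stringsAsFactors = FALSE
  )
  lk[!duplicated(lk$name_lc), , drop = FALSE]
}
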