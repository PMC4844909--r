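regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Dictionary NER for drug mentions
#'
#' Case-insensitive, token-boundary-anchored, longest-leftmost matching
#' of lexicon names (preferred names and synonyms) over the section
#' text.  A token boundary is a transition between word characters
#' (letters, digits, underscore, hyphen) and anything else, so hyphens
#' and digits inside drug names never split a match.  Overlapping
#' candidates are resolved longest-leftmost, making the output spans
#' non-overlapping.  Matches typed `non_drug` in the lexicon are matched
#' first (so they can shadow shorter drug names) and then filtered out,
#' mirroring a broad terminology annotator followed by an entity-type
#' filter.  Drug-product mentions are normalized to their sole active
#' ingredient via the lexicon's relationship map; products without a
#' mapping keep their own concept id and are flagged `unmapped_product`.
#'
#' @param section A [label_section].
#' @param lexicon A [pddi_lexicon].
#' @return A [drug_mentions()] table sorted by `char_start`.
#' @export
annotate_drug_mentions <- function(section, lexicon) {
  lk <- lexicon_lookup(lexicon)
  if (nrow(lk) == 0 || !nzchar(section$text)) {
    return(drug_mentions())
  }
  # longest alternative first => regex alternation returns the longest
  # match at each leftmost position
  ord <- order(-nchar(lk$name), lk$name_lc)
  pattern <- paste0(
    "(?<![\\w-])(?:",
    paste(regex_escape(lk$name[ord]), collapse = "|"),
    ")(?![\\w-])"
  )
  m <- gregexpr(pattern, section$text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) {
    return(drug_mentions())
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surface <- substring(section$text, starts, starts + lens - 1L)
  hit <- lk[match(tolower(surface), lk$name_lc), , drop = FALSE]
  keep <- hit$entity_type %in% DRUG_ENTITY_TYPES
  if (!any(keep)) {
    return(drug_mentions())
  }
  starts <- starts[keep]
  lens <- lens[keep]
  surface <- surface[keep]
  hit <- hit[keep, , drop = FALSE]
  mapped <- lexicon$product_to_ingredient[hit$concept_id]
  is_product <- hit$entity_type == "drug_product"
  norm <- ifelse(is_product & !is.na(mapped), mapped, hit$concept_id)
  out <- drug_mentions(
    section_id = rep(section$section_id, length(starts)),
    char_start = starts - 1L,
    char_end = starts - 1L + lens,
    surface = surface,
    entity_type = hit$entity_type,
    concept_id = hit$concept_id,
    normalized_ingredient_id = norm,
    unmapped_product = is_product & is.na(mapped)
  )
  out[order(out$char_start), , drop = FALSE]
}
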