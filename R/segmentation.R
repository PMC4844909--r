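#' Abbreviations protected from sentence splitting
#'
#' Reads the packaged abbreviation list (one token per line, each ending
#' in a period).  A period closing one of these tokens is never treated
#' as a sentence boundary.
#'
#' @return Character vector of abbreviations such as `"e.g."`.
#' @export
default_abbreviations <- function() {
  readLines(pddikit_extdata("abbreviations.txt"), warn = FALSE)
}

#' Segment text into sentence spans
#'
#' Deterministic rule-based segmentation: a sentence ends at `.`, `!` or
#' `?` followed by whitespace or end of text, unless the period closes a
#' token on the abbreviation list (compared case-insensitively, e.g.
#' "e.g." or "i.v.").  Periods inside tokens (decimal numbers,
#' "2.5-fold") are never boundaries because they are not followed by
#' whitespace.  Spans are 0-based, half-open character intervals; leading
#' and trailing whitespace of each sentence is left unassigned, so spans
#' are non-overlapping and sorted but need not tile the text.
#'
#' @param text A single character string.
#' @param abbreviations Character vector of protected abbreviations.
#' @return A data.frame with integer columns `start` and `end` (0-based,
#'   half-open), one row per sentence, in document order.
#' @examples
#' segment_sentences("Ketoconazole increased midazolam AUC. No dose change is needed.")
#' @export
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (is.na(text) || !nzchar(text)) {
    return(empty)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  abbr <- tolower(abbreviations)
  token_chars <- grepl("[A-Za-z0-9.'-]", chars)

  terminators <- which(chars %in% c(".", "!", "?"))
  boundaries <- integer(0)
  for (t in terminators) {
    nxt <- if (t < n) chars[t + 1L] else ""
    if (nzchar(nxt) && !grepl("\\s", nxt)) next
    if (chars[t] == ".") {
      # walk back over the token that the period closes
      s <- t
      while (s > 1L && token_chars[s - 1L]) s <- s - 1L
      token <- tolower(paste(chars[s:t], collapse = ""))
      if (token %in% abbr) next
    }
    boundaries <- c(boundaries, t)
  }

  starts <- integer(0)
  ends <- integer(0)
  cursor <- 1L
  emit <- function(from, to) {
    while (from <= to && grepl("\\s", chars[from])) from <- from + 1L
    while (to >= from && grepl("\\s", chars[to])) to <- to - 1L
    if (from <= to) {
      starts <<- c(starts, from - 1L) # to 0-based
      ends <<- c(ends, to)            # half-open
    }
  }
  for (b in boundaries) {
    emit(cursor, b)
    cursor <- b + 1L
  }
  if (cursor <= n) emit(cursor, n)
  data.frame(start = starts, end = ends)
}

# slice of `text` for a 0-based half-open interval
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}
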