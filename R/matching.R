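#' True-positive criterion for a candidate PDDI mention
#'
#' A candidate matches a reference mention iff (a) the normalized
#' precipitant ids, normalized object ids, and modality are all equal
#' and (b) the selected sentences partially or exactly overlap (their
#' index sets intersect).  The statement type
#' (quantitative/qualitative) is deliberately not part of the
#' criterion.  Mentions in different sections never match (false, not
#' an error).  Because ids are normalized, a drug-product candidate
#' matches an active-ingredient reference of its sole ingredient.
#'
#' @param candidate,reference One-row slices of a [pddi_mentions()]
#'   table (or lists with the same fields).
#' @return Logical scalar.
#' @export
is_match <- function(candidate, reference) {
  cs <- candidate$sentence_indices
  rs <- reference$sentence_indices
  if (is.list(cs)) cs <- cs[[1]]
  if (is.list(rs)) rs <- rs[[1]]
  identical(as.character(candidate$section_id), as.character(reference$section_id)) &&
    identical(as.character(candidate$precipitant_id), as.character(reference$precipitant_id)) &&
    identical(as.character(candidate$object_id), as.character(reference$object_id)) &&
    identical(as.character(candidate$modality), as.character(reference$modality)) &&
    length(intersect(cs, rs)) > 0L
}

# deterministic processing order: (first sentence index, precipitant id,
# object id) within a section
mention_order <- function(pm, rows) {
  first_sent <- vapply(pm$sentence_indices[rows], min, integer(1))
  rows[order(first_sent, pm$precipitant_id[rows], pm$object_id[rows])]
}

#' Match a candidate annotation set against a reference set
#'
#' Produces a one-to-one pairing of candidate and reference PDDI
#' mentions per section under the [is_match()] criterion.  Candidates
#' and references are processed in (first sentence index, precipitant
#' id) order and paired by augmenting paths, which yields the greedy
#' first-come pairing whenever that pairing is maximal and a maximum
#' one-to-one matching always, so no candidate double-counts and no
#' attainable true positive is lost to processing order.  Unpaired
#' candidates are false positives; unpaired references are false
#' negatives.
#'
#' @param candidate,reference [annotation_set] objects over `corpus`.
#' @param corpus A [pddi_corpus].
#' @return An object of class `pddi_match`: list with data.frames
#'   `pairs` (`section_id`, `candidate`, `reference` row indices),
#'   `candidate_fp`, and `reference_fn`, plus the two sets.
#' @export
match_sets <- function(candidate, reference, corpus) {
  validate_annotation_set(candidate, corpus)
  validate_annotation_set(reference, corpus)
  cm <- candidate$pddi_mentions
  rm_ <- reference$pddi_mentions
  pairs <- list()
  cand_fp <- integer(0)
  ref_fn <- integer(0)
  for (sid in unique(c(cm$section_id, rm_$section_id))) {
    ci <- mention_order(cm, which(cm$section_id == sid))
    ri <- mention_order(rm_, which(rm_$section_id == sid))
    nref <- length(ri)
    # adjacency in reference processing order
    adj <- lapply(ci, function(i) {
      which(vapply(ri, function(j) is_match(cm[i, ], rm_[j, ]), logical(1)))
    })
    match_ref <- rep(NA_integer_, nref) # ref slot -> candidate slot
    augment <- function(a, state) {
      for (b in adj[[a]]) {
        if (!state$visited[b]) {
          state$visited[b] <- TRUE
          if (is.na(match_ref[b]) || augment(match_ref[b], state)) {
            match_ref[b] <<- a
            return(TRUE)
          }
        }
      }
      FALSE
    }
    for (a in seq_along(ci)) {
      state <- new.env(parent = emptyenv())
      state$visited <- rep(FALSE, nref)
      augment(a, state)
    }
    matched_c <- integer(0)
    for (b in seq_len(nref)) {
      if (!is.na(match_ref[b])) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          section_id = sid,
          candidate = ci[match_ref[b]],
          reference = ri[b],
          stringsAsFactors = FALSE
        )
        matched_c <- c(matched_c, match_ref[b])
      }
    }
    cand_fp <- c(cand_fp, ci[setdiff(seq_along(ci), matched_c)])
    ref_fn <- c(ref_fn, ri[which(is.na(match_ref))])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(section_id = character(0), candidate = integer(0), reference = integer(0))
  structure(
    list(
      pairs = pairs,
      candidate_fp = sort(cand_fp),
      reference_fn = sort(ref_fn),
      candidate_set = candidate,
      reference_set = reference
    ),
    class = "pddi_match"
  )
}

#' @export
print.pddi_match <- function(x, ...) {
  cat(sprintf("<pddi_match: %d pairs (TP), %d candidate FP, %d reference FN>\n",
              nrow(x$pairs), length(x$candidate_fp), length(x$reference_fn)))
  invisible(x)
}
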