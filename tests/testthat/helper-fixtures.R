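# Shared fixtures and independent oracles, all built in code.

# small hand-checkable lexicon: three ingredients, a two-token product
# name that shadows one of them, and a non-drug confounder
make_test_lexicon <- function() {
  entries <- data.frame(
    concept_id = c("ING_KETO", "ING_MIDA", "ING_WARF", "PRD_WSOD", "PRD_ORPH", "MET_NORK", "NDG_ASA"),
    name = c("ketoconazole", "midazolam", "warfarin", "warfarin sodium",
             "Orphatex", "norketoconazole", "aspirin"),
    entity_type = c("active_ingredient", "active_ingredient", "active_ingredient",
                    "drug_product", "drug_product", "metabolite", "non_drug"),
    stringsAsFactors = FALSE
  )
  entries$synonyms <- list(character(0), "midazolam hydrochloride", character(0),
                           character(0), character(0), character(0), character(0))
  pddi_lexicon(entries, c(PRD_WSOD = "ING_WARF"))
}

make_test_corpus <- function(texts) {
  sections <- Map(function(id, text) label_section(id, paste0("L_", id), text),
                  names(texts), texts)
  pddi_corpus(unname(sections))
}

# quick constructor for one PDDI mention row
pm_row <- function(section, sents, prec, obj, modality = "positive",
                   statement = "qualitative", uid = NA_character_) {
  pddi_mentions(
    section_id = section, sentence_indices = list(as.integer(sents)),
    precipitant_id = prec, precipitant_type = "active_ingredient",
    object_id = obj, object_type = "active_ingredient",
    statement = statement, modality = modality, uid = uid
  )
}

bind_pm <- function(...) do.call(rbind, list(...))

# a multi-sentence corpus section for random-mention property tests
property_corpus <- function(n_sentences = 5) {
  text <- paste(sprintf("Sentence number %d is here.", seq_len(n_sentences)), collapse = " ")
  make_test_corpus(c(sec1 = text))
}

# random valid PDDI-mention table over one section; caller seeds RNG
random_pddi_set <- function(n, n_sentences = 5, drugs = c("D1", "D2", "D3"),
                            section = "sec1") {
  if (n == 0) return(pddi_mentions())
  rows <- lapply(seq_len(n), function(i) {
    pair <- sample(drugs, 2)
    k <- sample(seq_len(min(3, n_sentences)), 1)
    pm_row(section, sort(sample(0:(n_sentences - 1), k)), pair[1], pair[2],
           modality = sample(c("positive", "negative"), 1),
           statement = sample(c("quantitative", "qualitative"), 1))
  })
  pm <- do.call(rbind, rows)
  pm <- pm[!duplicated(pddikit:::pddi_keys(pm)), , drop = FALSE]
  rownames(pm) <- NULL
  pm
}

as_set <- function(pm, source_id = "x", kind = "human") {
  annotation_set(source_id, kind, pddi_mentions = pm)
}

# independent oracle: maximum one-to-one matching size by bitmask DP
# over reference subsets (exact for <= ~16 references)
bf_max_matching_size <- function(cand_pm, ref_pm) {
  nc <- nrow(cand_pm)
  nref <- nrow(ref_pm)
  adj <- lapply(seq_len(nc), function(i) {
    which(vapply(seq_len(nref), function(j) is_match(cand_pm[i, ], ref_pm[j, ]), logical(1)))
  })
  memo <- new.env(parent = emptyenv())
  rec <- function(i, mask) {
    if (i > nc) return(0L)
    key <- paste(i, mask)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- rec(i + 1L, mask)
    for (j in adj[[i]]) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) {
        best <- max(best, 1L + rec(i + 1L, bitwOr(mask, bit)))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 0L)
}

# build candidate/reference sets realizing planted per-label TP/FP/FN
# counts: TP mentions are shared, FN mentions are reference-only, FP
# mentions use drug pairs absent from the reference
planted_sets <- function(counts) {
  texts <- stats::setNames(
    rep(paste(sprintf("Filler sentence %d here.", 1:20), collapse = " "), nrow(counts)),
    counts$section_id
  )
  corpus <- make_test_corpus(texts)
  ref <- list()
  cand <- list()
  for (i in seq_len(nrow(counts))) {
    sid <- counts$section_id[i]
    s <- 0L
    for (k in seq_len(counts$tp[i])) {
      m <- pm_row(sid, s, sprintf("T%d", k), "OBJ")
      ref[[length(ref) + 1L]] <- m
      cand[[length(cand) + 1L]] <- m
      s <- s + 1L
    }
    for (k in seq_len(counts$fn[i])) {
      ref[[length(ref) + 1L]] <- pm_row(sid, s, sprintf("N%d", k), "OBJ")
      s <- s + 1L
    }
    for (k in seq_len(counts$fp[i])) {
      cand[[length(cand) + 1L]] <- pm_row(sid, s, sprintf("P%d", k), "OBJ")
      s <- s + 1L
    }
  }
  list(
    corpus = corpus,
    candidate = as_set(do.call(rbind, c(cand, list(pddi_mentions()))), "cand"),
    reference = as_set(do.call(rbind, c(ref, list(pddi_mentions()))), "ref", "reference"),
    assignment = stats::setNames(counts$scenario, counts$section_id)
  )
}

# write a tiny three-section corpus to disk and return the manifest path
write_demo_manifest <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  texts <- c(
    s1 = "Ketoconazole increased midazolam AUC by 5-fold. Midazolam is administered orally.",
    s2 = "Warfarin sodium was well tolerated. Aspirin was given to controls.",
    s3 = "No dosage adjustment is necessary."
  )
  for (id in names(texts)) writeLines(texts[[id]], file.path(dir, paste0(id, ".txt")))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(sections = lapply(names(texts), function(id) {
    list(section_id = id, label_id = paste0("L_", id), file = paste0(id, ".txt"), scenario = "1")
  })), manifest, auto_unbox = TRUE)
  manifest
}
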