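#' Annotator behaviour profile
#'
#' Four rates formalizing how a simulated annotator interacts with
#' preannotation: the probability of adding a mention the NLP missed
#' (`p_fix_nlp_fn`), of deleting a correct NLP mention
#' (`p_drop_nlp_tp`), of keeping an NLP false positive
#' (`p_accept_nlp_fp`), and the per-section rate of user-invented
#' mentions (`p_spontaneous_fp_per_section`).  The expectations of this
#' model are exactly the cells of the agreement cross-tabulation.
#' Defaults are calibrated to the published behaviour of the strongest
#' nonexpert annotator (corrected 63 of 109 NLP misses, dropped 11 of
#' 42 NLP hits, kept 5 of 93 NLP false positives, ~0.3 invented
#' mentions per section).  In unassisted mode `p_fix_nlp_fn` doubles as
#' the base sensitivity for finding reference mentions.
#'
#' @param p_fix_nlp_fn,p_drop_nlp_tp,p_accept_nlp_fp Probabilities.
#' @param p_spontaneous_fp_per_section Non-negative rate.
#' @return An object of class `annotator_profile`.
#' @export
annotator_profile <- function(p_fix_nlp_fn = 63 / 109,
                              p_drop_nlp_tp = 11 / 42,
                              p_accept_nlp_fp = 5 / 93,
                              p_spontaneous_fp_per_section = 0.3) {
  for (p in c(p_fix_nlp_fn, p_drop_nlp_tp, p_accept_nlp_fp)) {
    if (!is_probability(p)) stop_pddi("profile probabilities must lie in [0, 1]")
  }
  if (p_spontaneous_fp_per_section < 0) stop_pddi("spontaneous rate must be >= 0")
  structure(
    list(
      p_fix_nlp_fn = p_fix_nlp_fn,
      p_drop_nlp_tp = p_drop_nlp_tp,
      p_accept_nlp_fp = p_accept_nlp_fp,
      p_spontaneous_fp_per_section = p_spontaneous_fp_per_section
    ),
    class = "annotator_profile"
  )
}

#' Configuration for the synthetic study generator
#'
#' The defaults emulate the composition of the reference-standard
#' corpus this package's evaluation design assumes: 208 label sections
#' of which 3 are reserved for training, about 607 PDDI mentions per
#' 205 annotated sections (2-4 planted per section), and drug-mention
#' rates per section derived from the reference composition of 3351
#' active-ingredient, 234 drug-product, and 201 metabolite mentions
#' over 205 sections.  The NLP operating point defaults to the
#' sentence-level recall 0.81 / precision 0.86 of the best published
#' PDDI classifier, used here as simulation parameters.
#'
#' @param n_sections Number of label sections.
#' @param pddis_per_section Integer range (length 2) of PDDI statements
#'   planted per section.
#' @param mention_rates Named per-section Poisson means controlling
#'   extra drug mentions: `drug_product`, `metabolite`, and the total
#'   `active_ingredient` target (PDDI and pool sentences count against
#'   it).
#' @param p_negative_modality Probability a planted PDDI statement
#'   explicitly denies the interaction.
#' @param p_quantitative Probability a planted positive statement
#'   carries a numeric magnitude.
#' @param nlp_sentence_recall,nlp_sentence_precision Simulated NLP
#'   operating point.
#' @param profile An [annotator_profile()].
#' @param fp_pool_per_section Two-drug non-PDDI sentences planted per
#'   section as material for plausible false positives.
#' @param p_paraphrase Probability a planted positive qualitative PDDI
#'   is phrased outside the extractor's rule grammar (recall noise).
#' @param cue_distractor_rate Per-section Poisson mean of cue-bearing
#'   two-drug non-PDDI sentences (precision noise).  Both noise rates
#'   default to 0: the default corpus is rule-perfect.
#' @param n_ingredients,n_products,n_metabolites,n_non_drug Lexicon
#'   composition.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_sections = 208L,
                             pddis_per_section = c(2L, 4L),
                             mention_rates = c(
                               active_ingredient = 3351 / 205,
                               drug_product = 234 / 205,
                               metabolite = 201 / 205
                             ),
                             p_negative_modality = 0.15,
                             p_quantitative = 0.5,
                             nlp_sentence_recall = 0.81,
                             nlp_sentence_precision = 0.86,
                             profile = annotator_profile(),
                             fp_pool_per_section = 2L,
                             p_paraphrase = 0,
                             cue_distractor_rate = 0,
                             n_ingredients = 60L,
                             n_products = 12L,
                             n_metabolites = 10L,
                             n_non_drug = 4L,
                             seed = 1L) {
  stopifnot(is_count(n_sections), length(pddis_per_section) == 2)
  for (p in c(p_negative_modality, p_quantitative, nlp_sentence_recall,
              nlp_sentence_precision, p_paraphrase)) {
    if (!is_probability(p)) stop_pddi("probabilities must lie in [0, 1]")
  }
  structure(
    list(
      n_sections = as.integer(n_sections),
      pddis_per_section = as.integer(pddis_per_section),
      mention_rates = mention_rates,
      p_negative_modality = p_negative_modality,
      p_quantitative = p_quantitative,
      nlp_sentence_recall = nlp_sentence_recall,
      nlp_sentence_precision = nlp_sentence_precision,
      profile = profile,
      fp_pool_per_section = as.integer(fp_pool_per_section),
      p_paraphrase = p_paraphrase,
      cue_distractor_rate = cue_distractor_rate,
      n_ingredients = as.integer(n_ingredients),
      n_products = as.integer(n_products),
      n_metabolites = as.integer(n_metabolites),
      n_non_drug = as.integer(n_non_drug),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# pronounceable synthetic names; RNG must be active.  Syllables avoid
# prefixes of the packaged cue stems so names can never trigger a rule.
make_names <- function(n, suffixes) {
  syl <- c("ba", "co", "da", "fe", "ga", "ke", "lo", "mi", "na", "pe",
           "ra", "so", "ta", "vo", "xa", "zu", "bri", "dal", "fen", "gor",
           "lim", "mar", "nev", "pol", "qua", "rit", "sel", "tor", "vel", "zam")
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(
      paste(sample(syl, 2, replace = TRUE), collapse = ""),
      sample(suffixes, 1)
    )
    cand <- paste0(toupper(substr(cand, 1, 1)), substr(cand, 2, nchar(cand)))
    if (!tolower(cand) %in% tolower(out)) out <- c(out, cand)
  }
  out
}

#' Build a synthetic drug lexicon
#'
#' Generates pronounceable ingredient, product, and metabolite names
#' (plus a handful of non-drug confounder terms), assigns each product
#' a sole active ingredient, and gives roughly a third of ingredients a
#' salt-form synonym.  RNG state must be seeded by the caller.
#'
#' @param n_ingredients,n_products,n_metabolites,n_non_drug Entry counts.
#' @return A [pddi_lexicon].
#' @export
make_synthetic_lexicon <- function(n_ingredients = 60L, n_products = 12L,
                                   n_metabolites = 10L, n_non_drug = 4L) {
  ing <- make_names(n_ingredients, c("azole", "mycin", "olol", "pril", "statin",
                                     "idine", "avir", "oxacin", "mab", "tinib"))
  prod <- make_names(n_products, c("ex", "on", "ax", "um", "is"))
  met_of <- sample(seq_len(n_ingredients), n_metabolites)
  met <- paste0("Nor", tolower(ing[met_of]))
  non_drug <- utils::head(c("placebo", "saline", "vehicle", "excipient"), n_non_drug)
  ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  entries <- data.frame(
    concept_id = c(ids("ING", n_ingredients), ids("PRD", n_products),
                   ids("MET", n_metabolites), ids("NDG", n_non_drug)),
    name = c(ing, prod, met, non_drug),
    entity_type = c(rep("active_ingredient", n_ingredients),
                    rep("drug_product", n_products),
                    rep("metabolite", n_metabolites),
                    rep("non_drug", n_non_drug)),
    stringsAsFactors = FALSE
  )
  syn <- rep(list(character(0)), nrow(entries))
  with_syn <- sample(seq_len(n_ingredients), max(1L, n_ingredients %/% 3))
  for (i in with_syn) syn[[i]] <- paste(ing[i], sample(c("hydrochloride", "sodium", "maleate"), 1))
  entries$synonyms <- syn
  p2i <- stats::setNames(
    ids("ING", n_ingredients)[sample(seq_len(n_ingredients), n_products)],
    ids("PRD", n_products)
  )
  pddi_lexicon(entries, p2i)
}

# instantiate "...{A}...{B}..." returning the text and 0-based slot spans
fill_template <- function(template, values) {
  m <- gregexpr("\\{[A-Za-z]+\\}", template)[[1]]
  if (m[1] == -1L) {
    return(list(text = template, spans = list()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  pieces <- character(0)
  spans <- list()
  pos <- 1L
  out_len <- 0L
  for (k in seq_along(starts)) {
    lit <- substr(template, pos, starts[k] - 1L)
    slot <- substr(template, starts[k] + 1L, starts[k] + lens[k] - 2L)
    val <- as.character(values[[slot]])
    pieces <- c(pieces, lit, val)
    out_len <- out_len + nchar(lit)
    spans[[length(spans) + 1L]] <- list(slot = slot, start = out_len, end = out_len + nchar(val))
    out_len <- out_len + nchar(val)
    pos <- starts[k] + lens[k]
  }
  pieces <- c(pieces, substr(template, pos, nchar(template)))
  list(text = paste(pieces, collapse = ""), spans = spans)
}

# template grammar: positive/negative x quantitative/qualitative PDDI
# sentences whose surface form exactly matches the extractor's rules
# (cue term, frame, magnitude, negation scope), so the planted truth is
# recoverable with P = R = 1 when noise rates are 0
PDDI_TEMPLATES <- list(
  pos_quant = c(
    "{A} increased the AUC of {B} by {X}%.",
    "{A} decreased the clearance of {B} by approximately {X}%.",
    "The AUC of {B} was increased {F}-fold by {A}."
  ),
  pos_qual = c(
    "{A} increased the plasma concentration of {B}.",
    "{A} inhibited the metabolism of {B}.",
    "The clearance of {B} was reduced by {A}."
  ),
  neg_qual = c(
    "{A} had no effect on the exposure of {B}.",
    "Coadministration of {A} did not alter the AUC of {B}."
  ),
  neg_quant = c(
    "{A} changed the AUC of {B} by less than {X}% (no significant difference)."
  ),
  # recall-noise phrasing: a true PDDI the rule grammar cannot see
  paraphrase = c(
    "{A} markedly potentiated the effects of {B}."
  )
)

SINGLE_DRUG_TEMPLATES <- c(
  "{A} is administered orally once daily.",
  "{A} was well tolerated in clinical trials.",
  "The recommended dose of {A} should be adjusted in patients with renal impairment.",
  "{A} is eliminated primarily by the kidneys."
)

FP_POOL_TEMPLATES <- c(
  "Both {A} and {B} were evaluated in the clinical development program.",
  "{A} and {B} have each been studied in patients with hepatic impairment."
)

CUE_DISTRACTOR_TEMPLATES <- c(
  "Both {A} and {B} decreased appetite in long-term studies."
)

PRODUCT_TEMPLATES <- c(
  "Patients receiving {P} should be monitored for adverse reactions.",
  "{P} may be taken with or without food."
)

METABOLITE_TEMPLATES <- c(
  "{M}, the principal circulating metabolite of {A}, is pharmacologically active.",
  "{M} is the major metabolite formed after administration of {A}."
)

FILLER_TEMPLATES <- c(
  "Patients should be advised to report unusual symptoms promptly.",
  "Safety and tolerability were assessed throughout the study.",
  "Dosage adjustment is unnecessary in elderly patients.",
  "Caution is advised when therapy is initiated or discontinued."
)

#' Generate a synthetic study corpus with ground truth
#'
#' Builds templated label-section prose mixing PDDI statements
#' (rule-grammar sentences with drug names, cue verbs, optional
#' magnitudes and negation), two-drug non-PDDI sentences (the material
#' for plausible false positives), product, metabolite, and filler
#' sentences.  Returns the corpus (with a length-balanced scenario
#' assignment), the lexicon, the reference annotation set recording
#' every planted mention, and a ground-truth ledger that downstream
#' simulators update and against which the agreement table can be
#' checked cell for cell.  Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list with elements `corpus`, `lexicon`, `reference`, and
#'   `ledger` (class `pddi_ledger`: `records` data.frame plus the
#'   hidden `fp_pool_mentions` table).
#' @export
generate_corpus <- function(config = generator_config()) {
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  lexicon <- make_synthetic_lexicon(config$n_ingredients, config$n_products,
                                    config$n_metabolites, config$n_non_drug)
  e <- lexicon$entries
  ing_idx <- which(e$entity_type == "active_ingredient")
  met_idx <- which(e$entity_type == "metabolite")
  mu_ai <- config$mention_rates[["active_ingredient"]]
  mu_prod <- config$mention_rates[["drug_product"]]
  mu_met <- config$mention_rates[["metabolite"]]
  mean_pddi <- mean(config$pddis_per_section)
  lambda_single <- max(0, mu_ai - 2 * mean_pddi - 2 * config$fp_pool_per_section - mu_met)

  sections <- vector("list", config$n_sections)
  dm_acc <- list()
  pm_acc <- list()
  fp_acc <- list()
  led_acc <- list()
  uid_n <- 0L
  next_uid <- function(prefix) {
    uid_n <<- uid_n + 1L
    sprintf("%s%06d", prefix, uid_n)
  }

  draw_pair <- function() sample(ing_idx, 2L)
  surface_of <- function(i) {
    syns <- e$synonyms[[i]]
    if (length(syns) && stats::runif(1) < 0.1) sample(syns, 1) else e$name[i]
  }

  for (si in seq_len(config$n_sections)) {
    sid <- sprintf("s%04d", si)
    sent <- list() # each: text, drugs (slot -> lexicon row), kind, pddi fields

    n_pddi <- sample(seq(config$pddis_per_section[1], config$pddis_per_section[2]), 1L)
    for (k in seq_len(n_pddi)) {
      pair <- draw_pair()
      paraphrase <- stats::runif(1) < config$p_paraphrase
      negative <- !paraphrase && stats::runif(1) < config$p_negative_modality
      quant <- stats::runif(1) < config$p_quantitative
      group <- if (paraphrase) "paraphrase"
        else if (negative && quant) "neg_quant"
        else if (negative) "neg_qual"
        else if (quant) "pos_quant"
        else "pos_qual"
      template <- sample(PDDI_TEMPLATES[[group]], 1L)
      filled <- fill_template(template, list(
        A = e$name[pair[1]], B = e$name[pair[2]],
        X = sample(15:95, 1), F = sample(c("2", "2.5", "3", "3.5", "4", "5"), 1)
      ))
      sent[[length(sent) + 1L]] <- list(
        text = filled$text,
        drugs = lapply(filled$spans, function(sp) {
          if (sp$slot %in% c("A", "B")) {
            c(sp, list(row = pair[match(sp$slot, c("A", "B"))]))
          }
        }),
        kind = "pddi",
        pddi = list(
          precipitant = pair[1], object = pair[2],
          statement = if (group %in% c("pos_quant", "neg_quant")) "quantitative" else "qualitative",
          modality = if (startsWith(group, "neg")) "negative" else "positive"
        )
      )
    }

    n_pool <- config$fp_pool_per_section
    for (k in seq_len(n_pool)) {
      pair <- draw_pair()
      filled <- fill_template(sample(FP_POOL_TEMPLATES, 1L),
                              list(A = e$name[pair[1]], B = e$name[pair[2]]))
      sent[[length(sent) + 1L]] <- list(
        text = filled$text,
        drugs = lapply(filled$spans, function(sp) c(sp, list(row = pair[match(sp$slot, c("A", "B"))]))),
        kind = "fp_pool",
        pddi = list(precipitant = pair[1], object = pair[2],
                    statement = "qualitative", modality = "positive")
      )
    }

    n_cue <- stats::rpois(1, config$cue_distractor_rate)
    for (k in seq_len(n_cue)) {
      pair <- draw_pair()
      filled <- fill_template(sample(CUE_DISTRACTOR_TEMPLATES, 1L),
                              list(A = e$name[pair[1]], B = e$name[pair[2]]))
      sent[[length(sent) + 1L]] <- list(
        text = filled$text,
        drugs = lapply(filled$spans, function(sp) c(sp, list(row = pair[match(sp$slot, c("A", "B"))]))),
        kind = "cue_distractor",
        pddi = NULL
      )
    }

    n_prod <- stats::rpois(1, mu_prod)
    for (k in seq_len(n_prod)) {
      row <- which(e$concept_id == sample(names(lexicon$product_to_ingredient), 1))
      filled <- fill_template(sample(PRODUCT_TEMPLATES, 1L), list(P = e$name[row]))
      sent[[length(sent) + 1L]] <- list(
        text = filled$text,
        drugs = lapply(filled$spans, function(sp) c(sp, list(row = row))),
        kind = "distractor", pddi = NULL
      )
    }

    n_met <- stats::rpois(1, mu_met)
    for (k in seq_len(n_met)) {
      mrow <- sample(met_idx, 1)
      arow <- sample(ing_idx, 1)
      filled <- fill_template(sample(METABOLITE_TEMPLATES, 1L),
                              list(M = e$name[mrow], A = e$name[arow]))
      sent[[length(sent) + 1L]] <- list(
        text = filled$text,
        drugs = lapply(filled$spans, function(sp) {
          c(sp, list(row = if (sp$slot == "M") mrow else arow))
        }),
        kind = "distractor", pddi = NULL
      )
    }

    n_single <- stats::rpois(1, lambda_single)
    for (k in seq_len(n_single)) {
      arow <- sample(ing_idx, 1)
      surf <- surface_of(arow)
      filled <- fill_template(sample(SINGLE_DRUG_TEMPLATES, 1L), list(A = surf))
      sent[[length(sent) + 1L]] <- list(
        text = filled$text,
        drugs = lapply(filled$spans, function(sp) c(sp, list(row = arow))),
        kind = "distractor", pddi = NULL
      )
    }

    n_fill <- stats::rpois(1, 2)
    for (k in seq_len(n_fill)) {
      sent[[length(sent) + 1L]] <- list(
        text = sample(FILLER_TEMPLATES, 1L),
        drugs = list(), kind = "filler", pddi = NULL
      )
    }

    sent <- sent[sample(length(sent))]

    texts <- vapply(sent, function(x) x$text, character(1))
    offsets <- c(0L, cumsum(nchar(texts) + 1L))[seq_along(texts)]
    section_text <- paste(texts, collapse = " ")

    for (j in seq_along(sent)) {
      s <- sent[[j]]
      for (d in s$drugs) {
        if (is.null(d)) next
        dm_acc[[length(dm_acc) + 1L]] <- list(
          section_id = sid,
          char_start = as.integer(offsets[j] + d$start),
          char_end = as.integer(offsets[j] + d$end),
          surface = slice_text(section_text, offsets[j] + d$start, offsets[j] + d$end),
          entity_type = e$entity_type[d$row],
          concept_id = e$concept_id[d$row]
        )
      }
      if (s$kind == "pddi") {
        uid <- next_uid("m")
        pm_acc[[length(pm_acc) + 1L]] <- list(
          section_id = sid, sentence = j - 1L, uid = uid,
          precipitant = s$pddi$precipitant, object = s$pddi$object,
          statement = s$pddi$statement, modality = s$pddi$modality
        )
        led_acc[[length(led_acc) + 1L]] <- list(
          uid = uid, section_id = sid, sentence_index = j - 1L, kind = "planted"
        )
      } else if (s$kind == "fp_pool") {
        uid <- next_uid("f")
        fp_acc[[length(fp_acc) + 1L]] <- list(
          section_id = sid, sentence = j - 1L, uid = uid,
          precipitant = s$pddi$precipitant, object = s$pddi$object,
          statement = s$pddi$statement, modality = s$pddi$modality
        )
        led_acc[[length(led_acc) + 1L]] <- list(
          uid = uid, section_id = sid, sentence_index = j - 1L, kind = "fp_pool"
        )
      }
    }
    sections[[si]] <- label_section(sid, sprintf("L%04d", (si + 1L) %/% 2L), section_text)
    if (n_sentences(sections[[si]]) != length(sent)) {
      stop_pddi("internal: segmentation of generated section '%s' disagrees with its template plan", sid)
    }
  }

  corpus <- pddi_corpus(sections)
  plan <- assign_scenarios(corpus, seed = config$seed)
  corpus <- apply_scenario_plan(corpus, plan)

  chr <- function(acc, f) vapply(acc, function(x) as.character(x[[f]]), character(1))
  int <- function(acc, f) vapply(acc, function(x) as.integer(x[[f]]), integer(1))
  dm_concept <- chr(dm_acc, "concept_id")
  dm_type <- chr(dm_acc, "entity_type")
  mapped <- lexicon$product_to_ingredient[dm_concept]
  ref_dm <- drug_mentions(
    section_id = chr(dm_acc, "section_id"),
    char_start = int(dm_acc, "char_start"),
    char_end = int(dm_acc, "char_end"),
    surface = chr(dm_acc, "surface"),
    entity_type = dm_type,
    concept_id = dm_concept,
    normalized_ingredient_id = ifelse(dm_type == "drug_product" & !is.na(mapped),
                                      mapped, dm_concept)
  )
  build_pm <- function(acc) {
    pddi_mentions(
      section_id = chr(acc, "section_id"),
      sentence_indices = lapply(acc, `[[`, "sentence"),
      precipitant_id = e$concept_id[int(acc, "precipitant")],
      precipitant_type = rep("active_ingredient", length(acc)),
      object_id = e$concept_id[int(acc, "object")],
      object_type = rep("active_ingredient", length(acc)),
      statement = chr(acc, "statement"),
      modality = chr(acc, "modality"),
      uid = chr(acc, "uid")
    )
  }
  reference <- annotation_set("reference", "reference",
                              drug_mentions = ref_dm,
                              pddi_mentions = build_pm(pm_acc))
  validate_annotation_set(reference, corpus)
  ledger <- structure(
    list(
      records = data.frame(
        uid = chr(led_acc, "uid"),
        section_id = chr(led_acc, "section_id"),
        sentence_index = int(led_acc, "sentence_index"),
        kind = chr(led_acc, "kind"),
        stringsAsFactors = FALSE
      ),
      fp_pool_mentions = build_pm(fp_acc)
    ),
    class = "pddi_ledger"
  )
  list(corpus = corpus, lexicon = lexicon, reference = reference, ledger = ledger)
}

#' Simulate NLP preannotation output
#'
#' Each reference PDDI mention is emitted with probability
#' `nlp_sentence_recall`; plausible false positives (two co-mentioned
#' drugs from a planted non-PDDI sentence) are added so that the
#' expected precision equals `nlp_sentence_precision`.  Drug mentions
#' are carried over from the reference (the dictionary NER step is not
#' the error source being modelled).  The ledger is updated with each
#' mention's NLP outcome.
#'
#' @param reference The reference [annotation_set].
#' @param ledger The `pddi_ledger` from [generate_corpus()].
#' @param config A [generator_config()] (rates and seed).
#' @param seed Seed for this simulation step (default derived from the
#'   config seed).
#' @return List with `nlp` (an [annotation_set], `source_kind = "nlp"`)
#'   and the updated `ledger`.
#' @export
simulate_nlp <- function(reference, ledger, config, seed = config$seed + 1L) {
  withr::with_seed(as.integer(seed), {
    rec <- ledger$records
    planted <- which(rec$kind == "planted")
    pool <- which(rec$kind == "fp_pool")
    keep <- stats::runif(length(planted)) < config$nlp_sentence_recall
    n_tp <- sum(keep)
    prec <- config$nlp_sentence_precision
    target_fp <- n_tp * (1 - prec) / prec
    p_use <- if (length(pool)) target_fp / length(pool) else 0
    if (p_use > 1) {
      warning("false-positive pool too small to reach the requested precision; using all of it")
      p_use <- 1
    }
    use <- stats::runif(length(pool)) < p_use
    rec$nlp <- NA_character_
    rec$nlp[planted] <- ifelse(keep, "TP", "FN")
    rec$nlp[pool] <- ifelse(use, "FP", "unused")
    ledger$records <- rec

    pm_ref <- reference$pddi_mentions
    kept_pm <- pm_ref[pm_ref$uid %in% rec$uid[planted][keep], , drop = FALSE]
    fp_pm <- ledger$fp_pool_mentions
    fp_pm <- fp_pm[fp_pm$uid %in% rec$uid[pool][use], , drop = FALSE]
    nlp <- annotation_set("nlp", "nlp",
                          drug_mentions = reference$drug_mentions,
                          pddi_mentions = rbind(kept_pm, fp_pm))
    list(nlp = nlp, ledger = ledger)
  })
}

#' Simulate one annotator
#'
#' In assisted mode (preannotation shown): keeps each NLP true positive
#' with probability `1 - p_drop_nlp_tp`, adds each NLP-missed reference
#' mention with probability `p_fix_nlp_fn`, keeps each NLP false
#' positive with probability `p_accept_nlp_fp`, and invents false
#' positives from unused pool sentences at
#' `p_spontaneous_fp_per_section`.  In unassisted mode, each reference
#' mention is found with probability `p_fix_nlp_fn` (reused as base
#' sensitivity) and spontaneous false positives are added the same
#' way.  The ledger gains a column named after `source_id` recording
#' every mention's outcome.
#'
#' @param reference The reference [annotation_set].
#' @param nlp The simulated NLP [annotation_set] (ignored when
#'   `assisted = FALSE`).
#' @param ledger The `pddi_ledger`, already updated by [simulate_nlp()]
#'   when `assisted = TRUE`.
#' @param profile An [annotator_profile()].
#' @param assisted Whether the annotator saw the NLP preannotations.
#' @param source_id Annotator id (also the ledger column name).
#' @param seed Seed for this simulation step.
#' @return List with `user` (an [annotation_set], `source_kind =
#'   "human"`) and the updated `ledger`.
#' @export
simulate_annotator <- function(reference, nlp, ledger, profile = annotator_profile(),
                               assisted = TRUE, source_id = "annotator-1",
                               seed = 1L) {
  rec <- ledger$records
  if (assisted && is.null(rec$nlp)) {
    stop_pddi("assisted simulation requires a ledger updated by simulate_nlp()")
  }
  withr::with_seed(as.integer(seed), {
    outcome <- rep(NA_character_, nrow(rec))
    planted <- rec$kind == "planted"
    if (assisted) {
      tp_rows <- planted & rec$nlp == "TP"
      fn_rows <- planted & rec$nlp == "FN"
      outcome[tp_rows] <- ifelse(stats::runif(sum(tp_rows)) < profile$p_drop_nlp_tp, "FN", "TP")
      outcome[fn_rows] <- ifelse(stats::runif(sum(fn_rows)) < profile$p_fix_nlp_fn, "TP", "FN")
      fp_rows <- rec$kind == "fp_pool" & rec$nlp == "FP"
      outcome[fp_rows] <- ifelse(stats::runif(sum(fp_rows)) < profile$p_accept_nlp_fp,
                                 "accepted_fp", "rejected_fp")
      spont_eligible <- rec$kind == "fp_pool" & rec$nlp != "FP"
    } else {
      outcome[planted] <- ifelse(stats::runif(sum(planted)) < profile$p_fix_nlp_fn, "TP", "FN")
      spont_eligible <- rec$kind == "fp_pool" &
        (if (is.null(rec$nlp)) TRUE else rec$nlp != "FP")
    }
    rate <- profile$p_spontaneous_fp_per_section
    outcome[spont_eligible] <- "unused"
    if (rate > 0 && any(spont_eligible)) {
      for (sid in unique(rec$section_id[spont_eligible])) {
        rows <- which(spont_eligible & rec$section_id == sid)
        p <- min(1, rate / length(rows))
        pick <- stats::runif(length(rows)) < p
        outcome[rows[pick]] <- "spont_fp"
      }
    }
    rec[[source_id]] <- outcome
    ledger$records <- rec

    pm_ref <- reference$pddi_mentions
    user_pm <- rbind(
      pm_ref[pm_ref$uid %in% rec$uid[planted][outcome[planted] == "TP"], , drop = FALSE],
      ledger$fp_pool_mentions[
        ledger$fp_pool_mentions$uid %in% rec$uid[outcome %in% c("accepted_fp", "spont_fp")], ,
        drop = FALSE
      ]
    )
    user <- annotation_set(source_id, "human",
                           drug_mentions = reference$drug_mentions,
                           pddi_mentions = user_pm)
    list(user = user, ledger = ledger)
  })
}

#' Aggregate the ground-truth ledger into agreement cells
#'
#' The ledger records every mention's planted truth, NLP outcome, and
#' per-annotator outcome, so the agreement cross-tabulation can be
#' computed by pure bookkeeping; [build_agreement()] must reproduce it
#' exactly on every run.
#'
#' @param ledger A `pddi_ledger` updated by [simulate_nlp()] and
#'   [simulate_annotator()].
#' @param user_id The annotator's `source_id` (ledger column).
#' @param sections Optional section ids to restrict to.
#' @return List with `n_reference`, `tp_cells`, `n_nlp_fp`, `fp_cells`
#'   in the same shape as a `pddi_agreement`.
#' @export
ledger_agreement_cells <- function(ledger, user_id, sections = NULL) {
  rec <- ledger$records
  if (!is.null(sections)) rec <- rec[rec$section_id %in% sections, , drop = FALSE]
  u <- rec[[user_id]]
  if (is.null(u)) stop_pddi("ledger has no outcomes for user '%s'", user_id)
  planted <- rec$kind == "planted"
  pool <- rec$kind == "fp_pool"
  list(
    n_reference = sum(planted),
    tp_cells = c(
      nlpFN_userFN = sum(planted & rec$nlp == "FN" & u == "FN"),
      nlpFN_userTP = sum(planted & rec$nlp == "FN" & u == "TP"),
      nlpTP_userFN = sum(planted & rec$nlp == "TP" & u == "FN"),
      nlpTP_userTP = sum(planted & rec$nlp == "TP" & u == "TP")
    ),
    n_nlp_fp = sum(pool & rec$nlp == "FP"),
    fp_cells = c(
      nlpTN_userFP = sum(pool & u == "spont_fp"),
      nlpFP_userTN = sum(pool & rec$nlp == "FP" & u == "rejected_fp"),
      nlpFP_userFP = sum(pool & rec$nlp == "FP" & u == "accepted_fp")
    )
  )
}

#' Write a complete synthetic study to a directory
#'
#' Writes the corpus (manifest plus section texts), lexicon and
#' relationship TSVs, reference, NLP, and annotator annotation JSON,
#' and the ground-truth ledger TSV.
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @param annotators Number of simulated assisted annotators.
#' @return `dir`, invisibly.
#' @export
write_study <- function(config, dir, annotators = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_corpus(config)
  write_corpus(study$corpus, file.path(dir, "corpus"))
  write_lexicon(study$lexicon, file.path(dir, "lexicon.tsv"), file.path(dir, "relations.tsv"))
  write_annotations(study$reference, file.path(dir, "reference.json"), study$corpus)
  sim <- simulate_nlp(study$reference, study$ledger, config)
  write_annotations(sim$nlp, file.path(dir, "nlp.json"), study$corpus)
  ledger <- sim$ledger
  for (k in seq_len(annotators)) {
    id <- sprintf("annotator-%d", k)
    res <- simulate_annotator(study$reference, sim$nlp, ledger, config$profile,
                              assisted = TRUE, source_id = id, seed = config$seed + 100L + k)
    ledger <- res$ledger
    write_annotations(res$user, file.path(dir, paste0(id, ".json")), study$corpus)
  }
  utils::write.table(ledger$records, file.path(dir, "ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
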