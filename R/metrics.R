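f1_score <- function(p, r) {
  if (is.na(p) || is.na(r) || (p + r) == 0) NA_real_ else 2 * p * r / (p + r)
}

#' Per-label metrics macro-averaged by scenario
#'
#' Computes TP/FP/FN counts and precision, recall, and F1 per product
#' label section ("by label"), then unweighted means per scenario and
#' over all included labels.  Undefined metrics are excluded rather
#' than forced to a 0/0 convention: a label with no reference and no
#' candidate mentions is excluded entirely; a label with reference
#' mentions but no candidates has its precision excluded and recall 0
#' (and symmetrically for candidates without references); F1 is defined
#' only when both precision and recall are defined and P + R > 0.
#' Scenario and overall means are taken per metric over the labels for
#' which that metric is defined.
#'
#' @param match A [pddi_match] from [match_sets()].
#' @param corpus The [pddi_corpus] the sets annotate.
#' @param scenario_assignment Named scenario labels per section id;
#'   defaults to the corpus assignment.
#' @return An object of class `pddi_metrics`: list with data.frames
#'   `per_label` (section_id, scenario, tp, fp, fn, precision, recall,
#'   f1), `per_scenario`, and named numeric `overall`.
#' @export
compute_metrics <- function(match, corpus, scenario_assignment = NULL) {
  scenario_assignment <- scenario_assignment %||% corpus$scenario_assignment
  cm <- match$candidate_set$pddi_mentions
  rm_ <- match$reference_set$pddi_mentions
  ids <- unique(c(cm$section_id, rm_$section_id))
  unknown <- setdiff(ids, names(corpus$sections))
  if (length(unknown)) stop_pddi("match references unknown section '%s'", unknown[1])
  ids <- ids[order(match(ids, names(corpus$sections)))]
  tp <- table(factor(match$pairs$section_id, levels = ids))
  fp <- table(factor(cm$section_id[match$candidate_fp], levels = ids))
  fn <- table(factor(rm_$section_id[match$reference_fn], levels = ids))
  per <- data.frame(
    section_id = ids,
    scenario = unname(scenario_assignment[ids]),
    tp = as.integer(tp),
    fp = as.integer(fp),
    fn = as.integer(fn),
    stringsAsFactors = FALSE
  )
  per$precision <- ifelse(per$tp + per$fp > 0, per$tp / (per$tp + per$fp), NA_real_)
  per$recall <- ifelse(per$tp + per$fn > 0, per$tp / (per$tp + per$fn), NA_real_)
  per$f1 <- mapply(f1_score, per$precision, per$recall)

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  scen_levels <- unique(per$scenario)
  per_scenario <- do.call(rbind, lapply(scen_levels, function(s) {
    rows <- per[per$scenario == s, , drop = FALSE]
    data.frame(
      scenario = s,
      n_labels = nrow(rows),
      precision = mean_or_na(rows$precision),
      recall = mean_or_na(rows$recall),
      f1 = mean_or_na(rows$f1),
      stringsAsFactors = FALSE
    )
  })) %||% data.frame()
  overall <- c(
    precision = mean_or_na(per$precision),
    recall = mean_or_na(per$recall),
    f1 = mean_or_na(per$f1)
  )
  structure(
    list(per_label = per, per_scenario = per_scenario, overall = overall),
    class = "pddi_metrics"
  )
}

#' @export
print.pddi_metrics <- function(x, ...) {
  cat("Per-scenario means (unweighted over labels):\n")
  ps <- x$per_scenario
  for (col in c("precision", "recall", "f1")) ps[[col]] <- round_half_up(ps[[col]], 2)
  print(ps, row.names = FALSE)
  cat(sprintf(
    "Overall (%d labels): P=%.2f R=%.2f F1=%.2f\n",
    nrow(x$per_label),
    round_half_up(x$overall[["precision"]], 2),
    round_half_up(x$overall[["recall"]], 2),
    round_half_up(x$overall[["f1"]], 2)
  ))
  invisible(x)
}

#' Evaluate a candidate annotation set against a reference
#'
#' Convenience wrapper: [match_sets()] then [compute_metrics()].
#'
#' @inheritParams match_sets
#' @inheritParams compute_metrics
#' @return A `pddi_metrics` object.
#' @export
evaluate_annotations <- function(candidate, reference, corpus, scenario_assignment = NULL) {
  compute_metrics(match_sets(candidate, reference, corpus), corpus, scenario_assignment)
}

#' Write a metrics report as TSV blocks
#'
#' Writes the per-label, per-scenario, and overall blocks of a
#' `pddi_metrics` object into one TSV file, separated by block labels.
#'
#' @param metrics A `pddi_metrics`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per_label", con)
  utils::write.table(metrics$per_label, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# per_scenario", con)
  utils::write.table(metrics$per_scenario, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# overall", con)
  ov <- as.data.frame(as.list(metrics$overall))
  utils::write.table(ov, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
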