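# Matching-similarity scoring for Lives_In events. A predicted event counts
# as a true positive when some still-unmatched gold event has the same (or
# Equiv-equivalent) Bacterium AND the same (or Equiv-equivalent) Location.
# Matching is 1-to-1; duplicate predictions of one canonical pair are
# deduplicated before scoring. Gold relations whose arguments lie in
# different sentences can never be predicted by an intra-sentence system
# and therefore count as false negatives.

#' Match predicted against gold Lives_In events
#'
#' @param gold Tibble of gold relations (`bacterium`, `location` entity id
#'   columns).
#' @param pred Tibble of predicted relations, same layout.
#' @param equiv List of Equiv groups (character vectors of entity ids);
#'   arguments in the same group are interchangeable.
#' @return A one-row tibble with `TP`, `FP`, `FN`, `P`, `R`, `F`.
#' @export
match_events <- function(gold, pred, equiv = list()) {
  if (!is.null(pred[["id"]]) && anyDuplicated(pred[["id"]])) {
    abort("duplicate prediction ids")
  }
  canon <- equiv_canon(close_equiv(equiv))
  gold_keys <- if (nrow(gold)) paste(canon(gold$bacterium),
                                     canon(gold$location)) else character(0)
  pred_keys <- if (nrow(pred)) paste(canon(pred$bacterium),
                                     canon(pred$location)) else character(0)
  pred_keys <- unique(pred_keys)

  matched <- logical(length(gold_keys))
  tp <- 0L
  for (k in pred_keys) {
    hit <- which(!matched & gold_keys == k)
    if (length(hit)) {
      matched[hit[[1]]] <- TRUE
      tp <- tp + 1L
    }
  }
  prf(TP = tp, FP = length(pred_keys) - tp, FN = sum(!matched))
}

#' Precision, recall and F-score from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`, with the convention
#' that an empty denominator yields 0.
#'
#' @param TP,FP,FN Nonnegative integer counts.
#' @return A one-row tibble with `TP`, `FP`, `FN`, `P`, `R`, `F`.
#' @export
prf <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F <- if (P + R > 0) 2 * P * R / (P + R) else 0
  tibble(TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN),
         P = P, R = R, F = F)
}

#' Score a predicted corpus against a gold corpus
#'
#' Matches per document (entity ids are document-scoped) and aggregates the
#' counts into corpus-level precision/recall/F.
#'
#' @param gold_docs Named list of gold `bb_document`s (see [read_corpus()]).
#' @param pred_docs Named list of predicted documents, or a tibble of
#'   predicted relations with a `doc_id` column.
#' @return List with `per_doc` (tibble `doc_id`, `TP`, `FP`, `FN`) and
#'   `overall` (one-row tibble with the aggregated counts and `P`, `R`,
#'   `F`).
#' @export
evaluate_corpus <- function(gold_docs, pred_docs) {
  per_doc <- lapply(names(gold_docs), function(id) {
    g <- gold_docs[[id]]
    p <- if (is.data.frame(pred_docs)) {
      filter(pred_docs, .data$doc_id == .env$id)
    } else if (id %in% names(pred_docs)) {
      pred_docs[[id]]$relations
    } else {
      empty_relations()
    }
    counts <- match_events(g$relations, p, g$equiv)
    mutate(counts, doc_id = id, .before = 1)
  })
  per_doc <- bind_rows(per_doc)
  overall <- prf(sum(per_doc$TP), sum(per_doc$FP), sum(per_doc$FN))
  list(per_doc = select(per_doc, "doc_id", "TP", "FP", "FN"),
       overall = overall)
}

#' Format an evaluation as a TSV report
#'
#' One line per document with its counts, then a global line with
#' percentages printed to two decimals.
#'
#' @param ev Result of [evaluate_corpus()].
#' @return Character vector of report lines.
#' @export
format_report <- function(ev) {
  lines <- c("doc_id\tTP\tFP\tFN",
             sprintf("%s\t%d\t%d\t%d", ev$per_doc$doc_id, ev$per_doc$TP,
                     ev$per_doc$FP, ev$per_doc$FN),
             sprintf("overall\tP=%.2f%%\tR=%.2f%%\tF=%.2f%%",
                     100 * ev$overall$P, 100 * ev$overall$R,
                     100 * ev$overall$F))
  lines
}
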