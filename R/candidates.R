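# Intra-sentence candidate generation: every (Bacteria) x (Habitat or
# Geographical) mention pair inside one sentence is a classification
# instance. The two argument mentions are replaced by the placeholders
# "entity_1" (bacterium) and "entity_2" (location) so the classifier
# generalizes over mention strings.

#' Enumerate intra-sentence bacterium-location candidate pairs
#'
#' Pairs every Bacteria mention with every Habitat or Geographical mention
#' co-occurring in a sentence. A candidate's gold label is 1 when a gold
#' `Lives_In` relation links the two mentions directly or through
#' Equiv-equivalent mentions. Gold relations whose arguments lie in
#' different sentences cannot produce a candidate; their ids are attached as
#' attribute `"cross_sentence"` so the scorer can count them as false
#' negatives.
#'
#' @param doc A `bb_document`.
#' @param sentences List of sentence parse tibbles for the document, in
#'   document order (see [read_parses()]); token character offsets are
#'   aligned internally against `doc$text`.
#' @return A tibble with one row per candidate: `doc_id`, `sentence`
#'   (index), `e1`, `e2` (entity ids), `e2_type`, `e1_tokens`, `e2_tokens`
#'   (list-columns of token indices within the sentence) and `label`
#'   (0/1). Entities that cross sentence boundaries, and pairs whose token
#'   runs overlap, are skipped with a warning.
#' @export
enumerate_candidates <- function(doc, sentences) {
  aligned <- align_parses(doc$text, sentences, doc$doc_id)
  ent <- doc$entities
  loc_sent <- integer(nrow(ent))
  runs <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    hit <- entity_sentence(ent$start[[i]], ent$end[[i]], aligned)
    if (is.na(hit$sentence)) {
      warn(sprintf("entity %s in %s crosses a sentence boundary; skipped",
                   ent$id[[i]], doc$doc_id))
      loc_sent[[i]] <- NA_integer_
    } else {
      loc_sent[[i]] <- hit$sentence
      runs[[i]] <- hit$tokens
    }
  }
  canon <- equiv_canon(doc$equiv)
  gold_pairs <- character(0)
  if (nrow(doc$relations)) {
    gold_pairs <- paste(canon(doc$relations$bacterium),
                        canon(doc$relations$location))
  }

  out <- list()
  for (s in seq_along(aligned)) {
    here <- which(loc_sent == s)
    b_idx <- here[ent$type[here] == "Bacteria"]
    l_idx <- here[ent$type[here] %in% LOCATION_TYPES]
    for (bi in b_idx) {
      for (li in l_idx) {
        if (length(intersect(runs[[bi]], runs[[li]]))) {
          warn(sprintf("entities %s and %s overlap in %s; candidate skipped",
                       ent$id[[bi]], ent$id[[li]], doc$doc_id))
          next
        }
        lab <- as.integer(
          paste(canon(ent$id[[bi]]), canon(ent$id[[li]])) %in% gold_pairs)
        out[[length(out) + 1L]] <- tibble(
          doc_id = doc$doc_id, sentence = s,
          e1 = ent$id[[bi]], e2 = ent$id[[li]], e2_type = ent$type[[li]],
          e1_tokens = list(runs[[bi]]), e2_tokens = list(runs[[li]]),
          label = lab)
      }
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(doc_id = character(), sentence = integer(), e1 = character(),
           e2 = character(), e2_type = character(), e1_tokens = list(),
           e2_tokens = list(), label = integer())

  # gold relations not reachable by any intra-sentence candidate
  unreachable <- character(0)
  if (nrow(doc$relations)) {
    covered <- paste(res$e1, res$e2)[res$label == 1]
    covered_canon <- if (length(covered)) {
      ids <- strsplit(covered, " ")
      vapply(ids, function(p) paste(canon(p[1]), canon(p[2])), character(1))
    } else character(0)
    unreachable <- doc$relations$id[!gold_pairs %in% covered_canon]
  }
  attr(res, "cross_sentence") <- unreachable
  res
}

# sentence whose aligned token span contains the entity; NA if none
entity_sentence <- function(start, end, aligned) {
  for (s in seq_along(aligned)) {
    g <- aligned[[s]]
    if (start >= min(g$start) && end <= max(g$end)) {
      toks <- which(g$start < end & g$end > start)
      if (!length(toks)) break
      return(list(sentence = s, tokens = toks))
    }
  }
  list(sentence = NA_integer_, tokens = integer(0))
}

#' Replace the two argument mentions with placeholder tokens
#'
#' Rewrites a sentence parse graph so the bacterium mention becomes the
#' single token `entity_1` and the location mention `entity_2`. In
#' `mode = "span"` (default) the entity's full token run is collapsed to one
#' placeholder node: the run's internal head keeps its attachment, tokens
#' pointing into the run are re-attached to the placeholder, and all other
#' tokens keep their sentence order. `mode = "head"` renames only the run's
#' syntactic head token, preserving sentence length, which mirrors systems
#' that substitute just the mention head word.
#'
#' @param graph Sentence parse tibble (see [read_parses()]).
#' @param e1_tokens,e2_tokens Integer token indices of the two mentions;
#'   must be non-empty, disjoint runs inside the sentence.
#' @param mode `"span"` or `"head"`.
#' @return The rewritten parse tibble with attributes `e1_pos` and `e2_pos`,
#'   the (1-based) token positions of `entity_1` and `entity_2`.
#' @export
replace_entities <- function(graph, e1_tokens, e2_tokens,
                             mode = c("span", "head")) {
  mode <- match.arg(mode)
  n <- nrow(graph)
  if (!length(e1_tokens) || !length(e2_tokens) ||
      any(c(e1_tokens, e2_tokens) < 1L) || any(c(e1_tokens, e2_tokens) > n)) {
    abort("entity token runs must be non-empty and lie inside the sentence")
  }
  if (length(intersect(e1_tokens, e2_tokens))) {
    abort("entity token runs overlap; candidate is ill-formed")
  }
  if (mode == "head") {
    g <- graph
    h1 <- run_head(g, e1_tokens)
    h2 <- run_head(g, e2_tokens)
    g$surface[[h1]] <- "entity_1"; g$stem[[h1]] <- "entity_1"
    g$surface[[h2]] <- "entity_2"; g$stem[[h2]] <- "entity_2"
    attr(g, "e1_pos") <- h1
    attr(g, "e2_pos") <- h2
    return(g)
  }
  collapse_spans(graph, e1_tokens, e2_tokens)
}

# token of the run whose head lies outside the run (first such, else first)
run_head <- function(graph, run) {
  outside <- run[!(graph$head[run] %in% run)]
  if (length(outside)) outside[[1]] else run[[1]]
}

collapse_spans <- function(graph, e1_tokens, e2_tokens) {
  n <- nrow(graph)
  group <- seq_len(n)
  group[e1_tokens] <- min(e1_tokens)
  group[e2_tokens] <- min(e2_tokens)
  keep <- sort(unique(group))
  new_id <- match(group, keep)        # old idx -> new idx
  rep1 <- run_head(graph, e1_tokens)
  rep2 <- run_head(graph, e2_tokens)
  rep_of <- keep                       # representative old token per new node
  rep_of[new_id[rep1]] <- rep1
  rep_of[new_id[rep2]] <- rep2

  m <- length(keep)
  g <- graph[rep_of, ]
  g$idx <- seq_len(m)
  g$head <- vapply(rep_of, function(old) {
    h <- graph$head[[old]]
    if (h == 0L) 0L else new_id[[h]]
  }, integer(1))
  p1 <- new_id[[rep1]]
  p2 <- new_id[[rep2]]
  g$surface[[p1]] <- "entity_1"; g$stem[[p1]] <- "entity_1"
  g$surface[[p2]] <- "entity_2"; g$stem[[p2]] <- "entity_2"
  # a collapsed node must not point into itself
  g$head[[p1]] <- if (g$head[[p1]] == p1) 0L else g$head[[p1]]
  g$head[[p2]] <- if (g$head[[p2]] == p2) 0L else g$head[[p2]]
  attr(g, "e1_pos") <- p1
  attr(g, "e2_pos") <- p2
  g
}
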