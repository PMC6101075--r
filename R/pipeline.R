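# End-to-end glue: standoff corpus + parses -> classifier-ready instances,
# and model predictions -> standoff relations.

#' Build classifier instances from a standoff corpus directory
#'
#' For every document (`doc_id.{txt,a1,a2}` plus `doc_id.parse`) the
#' intra-sentence bacterium-location pairs are enumerated, the two mentions
#' replaced by placeholders, and the dependency-path token subsequence
#' extracted and linearized. Documents without a `.parse` file fall back to
#' the whitespace tokenizer with a flat parse (path features then degrade
#' to the whole sentence).
#'
#' @param dir Corpus directory.
#' @param input Which token subsequence feeds the model: the shortest
#'   dependency path extended by the nearest governing verb (`"det"`,
#'   default), the bare shortest path (`"spt"`), or the whole sentence
#'   (`"sentence"`).
#' @param replace Placeholder granularity, `"span"` (whole mention) or
#'   `"head"` (syntactic head token only); see [replace_entities()].
#' @return Tibble with columns `doc_id`, `sentence`, `e1`, `e2`, `e2_type`,
#'   `label` and list-column `input` of [linearized_input()]s. Attribute
#'   `"cross_sentence"` collects ids of gold relations unreachable by any
#'   intra-sentence candidate; attribute `"docs"` carries the parsed
#'   documents.
#' @export
build_instances <- function(dir, input = c("det", "spt", "sentence"),
                            replace = c("span", "head")) {
  input <- match.arg(input)
  replace <- match.arg(replace)
  docs <- read_corpus(dir)
  rows <- list()
  cross <- list()
  for (doc in docs) {
    ppath <- file.path(dir, paste0(doc$doc_id, ".parse"))
    sentences <- if (file.exists(ppath)) read_parses(ppath)
                 else fallback_parse(doc$text)
    cands <- enumerate_candidates(doc, sentences)
    cross[[doc$doc_id]] <- attr(cands, "cross_sentence")
    if (!nrow(cands)) next
    cands$input <- lapply(seq_len(nrow(cands)), function(i) {
      g <- replace_entities(sentences[[cands$sentence[[i]]]],
                            cands$e1_tokens[[i]], cands$e2_tokens[[i]],
                            mode = replace)
      if (input == "sentence") {
        return(linearized_input(g$surface, g$pos,
                                attr(g, "e1_pos"), attr(g, "e2_pos")))
      }
      spt <- shortest_path_tokens(g)
      if (input == "spt") spt else dynamic_extended_tokens(g, spt)
    })
    rows[[doc$doc_id]] <- select(cands, -"e1_tokens", -"e2_tokens")
  }
  res <- if (length(rows)) bind_rows(rows) else
    tibble(doc_id = character(), sentence = integer(), e1 = character(),
           e2 = character(), e2_type = character(), label = integer(),
           input = list())
  attr(res, "cross_sentence") <- cross
  attr(res, "docs") <- docs
  res
}

#' Turn classifier predictions into Lives_In relations
#'
#' @param predictions Output of [predict.bgru_fit()]: instance tibble with a
#'   `pred` column.
#' @return Tibble of predicted relations (`doc_id`, `bacterium`,
#'   `location`), duplicates removed.
#' @export
extract_relations <- function(predictions) {
  pos <- filter(predictions, .data$pred == 1L)
  unique(tibble(doc_id = pos$doc_id, bacterium = pos$e1,
                location = pos$e2))
}

#' Write predicted relations as .a2 files
#'
#' @param relations Tibble from [extract_relations()].
#' @param docs Named list of `bb_document`s the predictions refer to (for
#'   argument-type validation).
#' @param dir Output directory; one `doc_id.a2` per document in `docs`
#'   (empty when nothing was predicted for it).
#' @return The written paths, invisibly.
#' @export
write_predictions <- function(relations, docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(docs), function(id) {
    rel <- filter(relations, .data$doc_id == .env$id)
    path <- file.path(dir, paste0(id, ".a2"))
    txt <- write_a2(rel, docs[[id]]$entities)
    writeLines(if (nzchar(txt)) strsplit(txt, "\n")[[1]] else character(0),
               path, useBytes = TRUE)
    path
  }, character(1))
  invisible(paths)
}
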