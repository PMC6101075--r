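# Per-sentence dependency parses in a GDep-compatible CoNLL-style dialect:
# one token per line, TAB-separated columns
#   index  surface  stem  POS  chunk  entity  head  deplabel
# with a blank line between sentences. head = 0 denotes the artificial root.

PARSE_COLS <- c("idx", "surface", "stem", "pos", "chunk", "entity",
                "head", "dep")

#' Read a CoNLL-style dependency parse file
#'
#' Each blank-line-separated block is one sentence; columns are token index
#' (1-based), surface form, stem, POS tag, chunk tag, entity tag, head index
#' (0 = root) and dependency label.
#'
#' @param path Parse file path.
#' @return A list of sentence tibbles with columns
#'   `idx, surface, stem, pos, chunk, entity, head, dep`.
#' @export
read_parses <- function(path) {
  if (!file.exists(path)) abort(paste0("parse file not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  breaks <- cumsum(!nzchar(lines))
  blocks <- split(lines[nzchar(lines)], breaks[nzchar(lines)])
  sentences <- lapply(seq_along(blocks), function(b) {
    block <- blocks[[b]]
    fields <- strsplit(block, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != length(PARSE_COLS))
    if (length(bad)) {
      abort(sprintf("malformed parse line in %s, sentence %d, token %d",
                    path, b, bad[[1]]))
    }
    m <- do.call(rbind, fields)
    g <- tibble(
      idx = as.integer(m[, 1]), surface = m[, 2], stem = m[, 3],
      pos = m[, 4], chunk = m[, 5], entity = m[, 6],
      head = as.integer(m[, 7]), dep = m[, 8]
    )
    validate_parse_graph(g, where = sprintf("%s sentence %d", path, b))
    g
  })
  unname(sentences)
}

validate_parse_graph <- function(g, where = "parse graph") {
  n <- nrow(g)
  if (!identical(g$idx, seq_len(n))) {
    abort(paste0(where, ": token indices must be 1..n"))
  }
  if (anyNA(g$head) || any(g$head < 0L) || any(g$head > n)) {
    abort(paste0(where, ": head indices must lie in [0, n]"))
  }
  invisible(g)
}

#' Write sentence parse graphs to a CoNLL-style file
#'
#' @param sentences List of sentence tibbles as returned by [read_parses()].
#' @param path Output path.
#' @export
write_parses <- function(sentences, path) {
  blocks <- vapply(sentences, function(g) {
    paste(sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%d\t%s",
                  g$idx, g$surface, g$stem, g$pos, g$chunk, g$entity,
                  g$head, g$dep),
          collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

# Align parse tokens with the raw document text: each token is searched for
# left-to-right; returns per-sentence tibbles with 0-based half-open
# character offsets added. Token text must occur verbatim in the document.
align_parses <- function(text, sentences, doc_id = "?") {
  pos <- 0L
  lapply(seq_along(sentences), function(s) {
    g <- sentences[[s]]
    start <- integer(nrow(g))
    end <- integer(nrow(g))
    for (i in seq_len(nrow(g))) {
      tok <- g$surface[[i]]
      hit <- regexpr(tok, substr(text, pos + 1L, nchar(text)), fixed = TRUE)
      if (hit == -1L) {
        abort(sprintf("token '%s' (sentence %d) not found in text of %s",
                      tok, s, doc_id))
      }
      start[[i]] <- pos + as.integer(hit) - 1L
      end[[i]] <- start[[i]] + nchar(tok)
      pos <<- end[[i]]
    }
    mutate(g, start = start, end = end)
  })
}

#' Split raw text into whitespace-tokenized sentence graphs
#'
#' A minimal fallback for documents without an external parse: sentences are
#' split on `.`, `!` or `?` followed by whitespace, tokens on whitespace with
#' trailing punctuation detached. Every token's head is the first token
#' (a flat parse); stems are lowercased surfaces, POS/chunk/entity tags are
#' placeholders. Intended only to keep the pipeline runnable without a
#' dependency parser; path-based features degenerate to the full sentence.
#'
#' @param text Document text.
#' @return A list of sentence tibbles in the [read_parses()] layout.
#' @export
fallback_parse <- function(text) {
  sents <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  sents <- sents[nzchar(trimws(sents))]
  lapply(sents, function(s) {
    toks <- unlist(strsplit(trimws(s), "\\s+"))
    # detach sentence-final punctuation as its own token
    last <- toks[[length(toks)]]
    if (grepl("[.!?]$", last) && nchar(last) > 1) {
      toks <- c(toks[-length(toks)], sub("[.!?]$", "", last),
                substr(last, nchar(last), nchar(last)))
    }
    n <- length(toks)
    tibble(idx = seq_len(n), surface = toks, stem = tolower(toks),
           pos = "UNK", chunk = "O", entity = "O",
           head = c(0L, rep(1L, n - 1L)), dep = c("ROOT", rep("dep", n - 1L)))
  })
}
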