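# Dependency-path input construction. Instead of feeding the whole sentence
# to the classifier, the token subsequence on the shortest undirected
# dependency path between the two entity placeholders (the linearized
# shortest-path-enclosed tree, SPT) is used, optionally extended by the
# nearest governing verb above the path (the dynamic extended tree, DET).
# Retained tokens keep their original sentence order.

#' Construct a linearized model input
#'
#' @param tokens Character vector of surface tokens (containing `entity_1`
#'   and `entity_2` exactly once each).
#' @param pos Character vector of POS tags, same length.
#' @param e1_pos,e2_pos Positions of the two placeholders within `tokens`.
#' @return A `linearized_input` list.
#' @export
linearized_input <- function(tokens, pos, e1_pos, e2_pos) {
  stopifnot(length(tokens) == length(pos),
            e1_pos >= 1, e1_pos <= length(tokens),
            e2_pos >= 1, e2_pos <= length(tokens), e1_pos != e2_pos)
  structure(list(tokens = tokens, pos = pos,
                 e1_pos = as.integer(e1_pos), e2_pos = as.integer(e2_pos)),
            class = "linearized_input")
}

#' @export
print.linearized_input <- function(x, ...) {
  marks <- rep("", length(x$tokens))
  marks[x$e1_pos] <- "*"
  marks[x$e2_pos] <- "*"
  cat("<linearized_input> ", paste0(x$tokens, marks, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

# undirected dependency graph of a sentence (root edges dropped)
dependency_graph <- function(g) {
  edges <- cbind(g$idx, g$head)
  edges <- edges[edges[, 2] != 0L, , drop = FALSE]
  ig <- igraph::make_empty_graph(n = nrow(g), directed = FALSE)
  if (nrow(edges)) ig <- igraph::add_edges(ig, t(edges))
  ig
}

#' Tokens on the shortest dependency path between the two entities
#'
#' Computes the shortest undirected path through the dependency graph from
#' `entity_1` to `entity_2` (both endpoints included) and returns the
#' retained tokens re-ordered by sentence position — the linearized
#' shortest-path-enclosed tree. On a disconnected parse the full sentence is
#' returned with a warning.
#'
#' @param graph Sentence parse tibble carrying `e1_pos`/`e2_pos` attributes
#'   (see [replace_entities()]), or pass positions explicitly.
#' @param e1_pos,e2_pos Placeholder token positions; default to the
#'   attributes on `graph`.
#' @return A `linearized_input`.
#' @export
shortest_path_tokens <- function(graph,
                                 e1_pos = attr(graph, "e1_pos"),
                                 e2_pos = attr(graph, "e2_pos")) {
  n <- nrow(graph)
  stopifnot(!is.null(e1_pos), !is.null(e2_pos))
  ig <- dependency_graph(graph)
  path <- suppressWarnings(
    igraph::shortest_paths(ig, from = e1_pos, to = e2_pos,
                           output = "vpath")$vpath[[1]]
  )
  if (length(path) == 0 && e1_pos != e2_pos) {
    warn("disconnected dependency graph; falling back to the full sentence")
    keep <- seq_len(n)
  } else {
    keep <- sort(as.integer(path))
  }
  out <- linearized_input(graph$surface[keep], graph$pos[keep],
                          match(e1_pos, keep), match(e2_pos, keep))
  attr(out, "sentence_idx") <- keep
  out
}

#' Extend a shortest-path input by the nearest governing verb
#'
#' Walks head links upward from the shallower of the two path endpoints
#' until a token with a verb POS tag (`VB*`) is found and adds it to the
#' retained set (the dynamic extended tree). When no verb ancestor exists
#' the input is returned unchanged. The governing-verb rule is a
#' reconstruction of the usual "extend the path by its governing predicate"
#' heuristic; only the linearized leaf sequence is produced.
#'
#' @param graph Sentence parse tibble used to build `spt`.
#' @param spt A `linearized_input` from [shortest_path_tokens()] on `graph`.
#' @return A `linearized_input` whose retained-token set is a superset of
#'   the input's, still in sentence order.
#' @export
dynamic_extended_tokens <- function(graph, spt) {
  keep <- attr(spt, "sentence_idx")
  if (is.null(keep)) abort("spt must come from shortest_path_tokens()")
  ends <- keep[c(spt$e1_pos, spt$e2_pos)]
  depths <- vapply(ends, token_depth, integer(1), graph = graph)
  start <- ends[[which.min(depths)]]
  verb <- verb_ancestor(graph, start)
  if (!is.na(verb)) keep <- sort(union(keep, verb))
  out <- linearized_input(graph$surface[keep], graph$pos[keep],
                          match(ends[[1]], keep), match(ends[[2]], keep))
  attr(out, "sentence_idx") <- keep
  out
}

token_depth <- function(graph, i) {
  d <- 1L
  seen <- integer(0)
  while (graph$head[[i]] != 0L) {
    seen <- c(seen, i)
    i <- graph$head[[i]]
    if (i %in% seen) return(d)   # defensive: cyclic head chain
    d <- d + 1L
  }
  d
}

# nearest strict ancestor with a VB* POS tag; NA when none
verb_ancestor <- function(graph, i) {
  seen <- i
  while (graph$head[[i]] != 0L) {
    i <- graph$head[[i]]
    if (i %in% seen) return(NA_integer_)
    seen <- c(seen, i)
    if (startsWith(graph$pos[[i]], "VB")) return(i)
  }
  NA_integer_
}
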