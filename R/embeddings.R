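# Input encoding: every token of a linearized input is represented by the
# concatenation of its word embedding, POS embedding and distance embedding.
# The distance embedding concatenates two vectors indexed by the signed
# token distances to entity_1 and entity_2; each component of a fresh
# distance vector is tanh(l/s), where s is the largest absolute relative
# distance seen in the training corpus (larger distances are clipped).

OOV_TOKEN <- "<oov>"

#' Create an embedding lookup table
#'
#' @param tokens Character vector of vocabulary items (duplicates dropped,
#'   order preserved). A dedicated `"<oov>"` row is always present and is
#'   itself trainable.
#' @param k Embedding width.
#' @param seed Integer seed for the uniform initialization in
#'   `(-0.5/k, 0.5/k)`.
#' @param vectors Optional pre-trained matrix (`length(vocab) x k`, rows in
#'   vocabulary order, OOV row included) overriding the random init.
#' @return An `embedding_table`: list with `vocab` (named row index) and
#'   `vectors`.
#' @export
embedding_table <- function(tokens, k, seed = 1L, vectors = NULL) {
  stopifnot(k >= 1)
  vocab_tokens <- unique(c(OOV_TOKEN, as.character(tokens)))
  if (is.null(vectors)) {
    vectors <- with_seed(seed, matrix(runif(length(vocab_tokens) * k,
                                            -0.5 / k, 0.5 / k),
                                      nrow = length(vocab_tokens), ncol = k))
  }
  stopifnot(nrow(vectors) == length(vocab_tokens), ncol(vectors) == k)
  rownames(vectors) <- NULL
  structure(list(vocab = setNames(seq_along(vocab_tokens), vocab_tokens),
                 vectors = vectors, k = as.integer(k)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", length(x$vocab), " tokens x ", x$k,
      " dims\n", sep = "")
  invisible(x)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# token -> row index, OOV row for unknowns
table_index <- function(tab, tokens) {
  idx <- tab$vocab[tokens]
  idx[is.na(idx)] <- tab$vocab[[OOV_TOKEN]]
  unname(idx)
}

#' Signed relative distances of a token to the two entities
#'
#' The distance of token `i` to an entity is the entity's token position
#' minus `i`: tokens left of the entity get positive distances. In the
#' running sequence `(contains, entity_1, at, environment, with, entity_2)`
#' the token `at` has distances (-1, 3). Distances are clipped to
#' `[-s, s]` when `s` is supplied.
#'
#' @param inp A `linearized_input`.
#' @param i Token position within the input.
#' @param s Optional maximum absolute distance (clipping bound).
#' @return Integer vector `c(l1, l2)`.
#' @export
relative_distances <- function(inp, i, s = NULL) {
  stopifnot(i >= 1, i <= length(inp$tokens))
  l <- c(inp$e1_pos - i, inp$e2_pos - i)
  if (!is.null(s)) l <- pmax(-s, pmin(s, l))
  as.integer(l)
}

#' Initialize one distance embedding vector
#'
#' Every component of the vector for signed distance `l` equals
#' `tanh(l / s)`; the value is copied `k` times. The table built from these
#' vectors is trainable afterwards.
#'
#' @param l Signed relative distance.
#' @param s Normalizer: the maximum absolute relative distance in the
#'   training corpus; must be >= 1.
#' @param k Vector width.
#' @return Numeric vector of length `k`.
#' @export
init_distance_vector <- function(l, s, k) {
  if (s < 1) abort("distance normalizer s must be >= 1")
  stopifnot(k >= 1)
  rep(tanh(l / s), k)
}

#' Build the trainable distance embedding table
#'
#' One row per signed distance in `-s..s` (row `l + s + 1` holds distance
#' `l`), each initialized with [init_distance_vector()]. The same table
#' serves both entity-distance channels; their `k`-wide lookups are
#' concatenated into the `2k`-wide distance slice of the encoding.
#'
#' @param s Maximum absolute relative distance in the training corpus.
#' @param k Width of each distance vector (half the distance-slice width).
#' @return A `distance_table`: list with `s`, `k` and `vectors`
#'   (`(2s+1) x k`).
#' @export
distance_table <- function(s, k) {
  if (s < 1) abort("distance normalizer s must be >= 1")
  ls <- seq.int(-s, s)
  vectors <- do.call(rbind, lapply(ls, init_distance_vector, s = s, k = k))
  structure(list(s = as.integer(s), k = as.integer(k), vectors = vectors),
            class = "distance_table")
}

distance_index <- function(dtab, l) {
  pmax(-dtab$s, pmin(dtab$s, l)) + dtab$s + 1L
}

#' Encode a linearized input as an embedding matrix
#'
#' Row `i` is the concatenation `[word; pos; d1; d2]` for token `i`, where
#' `d1`/`d2` are the distance embeddings to `entity_1`/`entity_2`. With the
#' default widths (50/50/25+25) each row has 150 components.
#'
#' @param inp A `linearized_input`.
#' @param word_tab,pos_tab `embedding_table`s for surfaces and POS tags.
#' @param dist_tab A `distance_table`.
#' @return Numeric matrix `n x (k_word + k_pos + 2 * k_dist)`.
#' @export
encode_sequence <- function(inp, word_tab, pos_tab, dist_tab) {
  n <- length(inp$tokens)
  if (n == 0) abort("cannot encode an empty input")
  wi <- table_index(word_tab, inp$tokens)
  pi <- table_index(pos_tab, inp$pos)
  l1 <- inp$e1_pos - seq_len(n)
  l2 <- inp$e2_pos - seq_len(n)
  cbind(word_tab$vectors[wi, , drop = FALSE],
        pos_tab$vectors[pi, , drop = FALSE],
        dist_tab$vectors[distance_index(dist_tab, l1), , drop = FALSE],
        dist_tab$vectors[distance_index(dist_tab, l2), , drop = FALSE])
}

#' Write an embedding table in word2vec text format
#'
#' Header line `"|V| k"`, then one line per vocabulary item: the token
#' followed by `k` floats.
#'
#' @param tab An `embedding_table`.
#' @param path Output path.
#' @export
write_word2vec <- function(tab, path) {
  toks <- names(tab$vocab)
  lines <- c(paste(length(toks), tab$k),
             vapply(seq_along(toks), function(i) {
               paste(toks[[i]],
                     paste(formatC(tab$vectors[i, ], format = "g",
                                   digits = 8), collapse = " "))
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an embedding table from word2vec text format
#'
#' @param path File path.
#' @return An `embedding_table`. When the file lacks an `"<oov>"` row one is
#'   appended, initialized to the mean of all vectors.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) {
    abort(paste0("malformed word2vec header in ", path))
  }
  body <- lines[-1][nzchar(lines[-1])]
  if (length(body) != hdr[[1]]) {
    abort(sprintf("word2vec file %s declares %d rows but has %d",
                  path, hdr[[1]], length(body)))
  }
  parts <- strsplit(body, "\\s+")
  toks <- vapply(parts, `[[`, character(1), 1)
  vecs <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  if (ncol(vecs) != hdr[[2]]) {
    abort(paste0("word2vec vector width mismatch in ", path))
  }
  if (!OOV_TOKEN %in% toks) {
    toks <- c(OOV_TOKEN, toks)
    vecs <- rbind(colMeans(vecs), vecs)
  } else {
    ord <- c(which(toks == OOV_TOKEN), which(toks != OOV_TOKEN))
    toks <- toks[ord]
    vecs <- vecs[ord, , drop = FALSE]
  }
  embedding_table(toks[-1], k = ncol(vecs),
                  vectors = vecs)
}
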