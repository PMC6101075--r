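# Domain-oriented embedding training. A skip-gram-with-negative-sampling
# variant in which the context of a focus token is not just the surrounding
# surface words: every neighbour inside the window contributes its surface,
# stem, chunk tag, entity tag and POS tag as five distinct context units, so
# the learned space reflects the parser's biomedical annotation layers. Both
# the surface unit and the POS unit of the focus token are trained as focus
# items; the emitted word table reads off the surface-unit input vectors and
# the POS table the POS-unit input vectors.

#' Train domain-oriented word and POS embeddings
#'
#' @param parses List of sentence parse tibbles (see [read_parses()]) — the
#'   unlabeled training corpus.
#' @param k Embedding width.
#' @param window Context window half-size (neighbours within `window`
#'   positions).
#' @param lr Starting learning rate.
#' @param epochs Passes over the corpus; `0` returns the (seeded) random
#'   initialization untouched.
#' @param negative Negative samples per positive pair, drawn from the
#'   unigram distribution over context units raised to 3/4.
#' @param min_count Drop units occurring fewer than this many times.
#' @param seed Integer seed.
#' @return List with `word` and `pos` [embedding_table()]s. The word
#'   table's vocabulary is the distinct surfaces meeting `min_count`.
#' @export
train_domain_embeddings <- function(parses, k = 50, window = 5, lr = 0.025,
                                    epochs = 1, negative = 5,
                                    min_count = 1, seed = 1L) {
  if (!length(parses)) abort("empty training corpus")
  stopifnot(window >= 1, k >= 1, epochs >= 0)

  units_of <- function(g) {
    list(w = paste0("w:", g$surface), s = paste0("s:", g$stem),
         c = paste0("c:", g$chunk), e = paste0("e:", g$entity),
         p = paste0("p:", g$pos))
  }
  sent_units <- lapply(parses, units_of)
  all_units <- unlist(lapply(sent_units, function(u) unlist(u)))
  counts <- table(all_units)
  counts <- counts[counts >= min_count]
  if (!length(counts)) abort("empty vocabulary after min_count filtering")
  vocab <- names(counts)
  vidx <- setNames(seq_along(vocab), vocab)
  noise <- as.numeric(counts)^0.75
  noise <- noise / sum(noise)

  set.seed(seed)
  V <- length(vocab)
  inp <- matrix(runif(V * k, -0.5 / k, 0.5 / k), V, k)
  out <- matrix(0, V, k)

  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      for (su in sent_units) {
        n <- length(su$w)
        f_w <- unname(vidx[su$w])
        f_p <- unname(vidx[su$p])
        ctx_units <- rbind(su$w, su$s, su$c, su$e, su$p)
        for (t in seq_len(n)) {
          lo <- max(1L, t - window)
          hi <- min(n, t + window)
          nb <- setdiff(lo:hi, t)
          if (!length(nb)) next
          ctx <- unname(vidx[ctx_units[, nb]])
          ctx <- ctx[!is.na(ctx)]
          for (f in c(f_w[[t]], f_p[[t]])) {
            if (is.na(f)) next
            for (ci in ctx) {
              neg <- sample.int(V, negative, replace = TRUE, prob = noise)
              targets <- c(ci, neg)
              labels <- c(1, numeric(negative))
              v <- inp[f, ]
              e <- numeric(k)
              for (j in seq_along(targets)) {
                u <- out[targets[[j]], ]
                g <- (labels[[j]] - sigmoid(sum(v * u))) * lr
                e <- e + g * u
                out[targets[[j]], ] <- u + g * v
              }
              inp[f, ] <- v + e
            }
          }
        }
      }
    }
  }

  extract <- function(prefix) {
    rows <- which(startsWith(vocab, prefix))
    toks <- substring(vocab[rows], nchar(prefix) + 1L)
    vecs <- inp[rows, , drop = FALSE]
    embedding_table(toks, k,
                    vectors = rbind(colMeans(vecs), vecs))
  }
  list(word = extract("w:"), pos = extract("p:"))
}
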