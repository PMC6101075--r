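# The attention-based bidirectional GRU classifier.
#
# Gate equations (no bias terms):
#   r = sigmoid(W_r x + U_r h_prev)
#   h~ = tanh(W x + U (r * h_prev))
#   z = sigmoid(W_z x + U_z h_prev)
#   h = z * h_prev + (1 - z) * h~
# The two directions are merged by averaging their states per time step,
# attention pooling turns the state matrix into one sentence vector, and a
# 2-class softmax predicts Lives_In vs none.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One gated-recurrent-unit step
#'
#' Applies the reset/update-gate equations to a single input vector.
#' All gate pre-activations are pure matrix products; there are no bias
#' terms by default (set `use_bias` in [train_config()] to add them).
#'
#' @param x Input vector (width `d_w`).
#' @param h_prev Previous state vector (width `h`).
#' @param params List with matrices `W_r`, `U_r`, `W_z`, `U_z`, `W`, `U`
#'   (and optionally bias vectors `b_r`, `b_z`, `b_h`).
#' @return List with gate activations `r`, `z`, candidate `h_tilde` and the
#'   new state `h`.
#' @export
gru_step <- function(x, h_prev, params) {
  if (ncol(params$W_r) != length(x) || ncol(params$U_r) != length(h_prev)) {
    abort("gru_step: parameter/input shape mismatch")
  }
  b_r <- params$b_r %||% 0
  b_z <- params$b_z %||% 0
  b_h <- params$b_h %||% 0
  r <- sigmoid(drop(params$W_r %*% x + params$U_r %*% h_prev) + b_r)
  z <- sigmoid(drop(params$W_z %*% x + params$U_z %*% h_prev) + b_z)
  h_tilde <- tanh(drop(params$W %*% x + params$U %*% (r * h_prev)) + b_h)
  h <- z * h_prev + (1 - z) * h_tilde
  list(r = r, z = z, h_tilde = h_tilde, h = h)
}

# run a GRU over the columns of X (d_w x n) in the given order;
# returns states H (h x n) and per-step caches for backprop
gru_run <- function(X, params) {
  n <- ncol(X)
  h_dim <- nrow(params$W_r)
  H <- matrix(0, h_dim, n)
  cache <- vector("list", n)
  h_prev <- numeric(h_dim)
  for (t in seq_len(n)) {
    st <- gru_step(X[, t], h_prev, params)
    H[, t] <- st$h
    cache[[t]] <- c(st, list(h_prev = h_prev))
    h_prev <- st$h
  }
  list(H = H, cache = cache)
}

#' Bidirectional GRU state matrix
#'
#' Runs independent forward and backward GRUs over the encoded sequence and
#' merges them by averaging the two states at every time step.
#'
#' @param seq Encoded sequence, `n x d_w` (row per token, as produced by
#'   [encode_sequence()]).
#' @param fwd,bwd Direction parameter lists (see [gru_step()]).
#' @return Matrix `D` of size `h x n`; column `t` is the averaged state for
#'   token `t`.
#' @export
bgru_forward <- function(seq, fwd, bwd) {
  if (is.null(dim(seq)) || nrow(seq) < 1) abort("empty input sequence")
  X <- t(seq)                              # d_w x n, column per token
  n <- ncol(X)
  f <- gru_run(X, fwd)
  b <- gru_run(X[, n:1, drop = FALSE], bwd)
  Hb <- b$H[, n:1, drop = FALSE]           # re-align to sentence order
  (f$H + Hb) / 2
}

#' Attention pooling of a state matrix
#'
#' Scores every column of `tanh(D)` against a learned vector `p`, softmax-
#' normalizes the scores into attention weights, and returns the weighted
#' state sum squashed through tanh as the sentence representation.
#'
#' @param D State matrix `h x n` from [bgru_forward()].
#' @param p Attention parameter vector (width `h`).
#' @return List with `H = tanh(D)`, raw scores `m_hat`, weights `alpha`
#'   (nonnegative, summing to 1), pooled state `r = D %*% alpha` and
#'   sentence vector `o = tanh(r)`.
#' @export
attention_pool <- function(D, p) {
  if (is.null(dim(D)) || ncol(D) < 1) abort("attention over empty sequence")
  H <- tanh(D)
  m_hat <- drop(crossprod(p, H))                     # p^T H, length n
  m_shift <- m_hat - max(m_hat)                      # stabilized softmax
  e <- exp(m_shift)
  alpha <- e / sum(e)
  r <- drop(D %*% alpha)
  list(H = H, m_hat = m_hat, alpha = alpha, r = r, o = tanh(r))
}

softmax2 <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

# full forward pass for one instance; dropout_mask (length h, values
# 0 or 1/(1-rate)) is applied to o during training only
model_forward <- function(state, inp, dropout_mask = NULL) {
  Xrows <- encode_sequence(inp, state$word, state$pos, state$dist)
  X <- t(Xrows)                             # d_w x n
  n <- ncol(X)
  f <- gru_run(X, state$fwd)
  b <- gru_run(X[, n:1, drop = FALSE], state$bwd)
  Hb <- b$H[, n:1, drop = FALSE]
  D <- (f$H + Hb) / 2
  att <- attention_pool(D, state$p)
  o_d <- if (is.null(dropout_mask)) att$o else att$o * dropout_mask
  logits <- drop(state$W_o %*% o_d + state$b_o)
  probs <- softmax2(logits)
  list(X = X, n = n, f = f, b = b, D = D, att = att,
       o_d = o_d, dropout_mask = dropout_mask,
       logits = logits, probs = probs)
}

#' Training configuration
#'
#' Defaults follow the reference setup: 50-dimensional word, POS and
#' distance embeddings, dropout 0.5 on the final (attention-pooled) hidden
#' state, learning rate 1e-3, mini-batches of 5, a single bidirectional
#' layer and 4 training epochs (the useful range on small corpora is 3-5).
#'
#' @param lr Adam learning rate.
#' @param dropout Dropout rate on the sentence vector during training.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training instances.
#' @param k_word,k_pos Word/POS embedding widths.
#' @param k_dist Total distance-slice width; split evenly between the two
#'   entity-distance channels.
#' @param hidden Hidden width `h`; `NULL` means the input width
#'   `k_word + k_pos + k_dist`.
#' @param use_bias Add bias vectors to the GRU gates (off by default; the
#'   gate equations carry none).
#' @param seed Integer seed driving initialization, batch shuffling and
#'   dropout masks.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, dropout = 0.5, batch_size = 5,
                         epochs = 4, k_word = 50, k_pos = 50, k_dist = 50,
                         hidden = NULL, use_bias = FALSE, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, epochs >= 0, batch_size >= 1,
            k_dist %% 2 == 0)
  structure(list(lr = lr, dropout = dropout, batch_size = batch_size,
                 epochs = epochs, k_word = k_word, k_pos = k_pos,
                 k_dist = k_dist, hidden = hidden, use_bias = use_bias,
                 seed = as.integer(seed)),
            class = "train_config")
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

init_gru_params <- function(h, d_w, use_bias = FALSE) {
  out <- list(W_r = glorot(h, d_w), U_r = glorot(h, h),
              W_z = glorot(h, d_w), U_z = glorot(h, h),
              W = glorot(h, d_w), U = glorot(h, h))
  if (use_bias) out <- c(out, list(b_r = numeric(h), b_z = numeric(h),
                                   b_h = numeric(h)))
  out
}

# assemble an untrained model state; consumes the active RNG stream
init_model_state <- function(cfg, word_tab, pos_tab, s) {
  d_w <- cfg$k_word + cfg$k_pos + cfg$k_dist
  h <- cfg$hidden %||% d_w
  structure(list(
    word = word_tab, pos = pos_tab,
    dist = distance_table(s, cfg$k_dist %/% 2L),
    fwd = init_gru_params(h, d_w, cfg$use_bias),
    bwd = init_gru_params(h, d_w, cfg$use_bias),
    p = rnorm(h, sd = 1 / sqrt(h)),
    W_o = glorot(2L, h), b_o = numeric(2L),
    h = h, d_w = d_w, cfg = cfg, version = 1L
  ), class = "bgru_state")
}
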