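# Analytic gradients for the full model: softmax cross-entropy through the
# output layer, attention pooling, both GRU directions (backprop through
# time) and the embedding lookups. Verified against central finite
# differences in the test suite.

#' Cross-entropy loss of one instance
#'
#' Deterministic (no dropout) unless an explicit `dropout_mask` is given;
#' used for inspection and for numerical gradient checks.
#'
#' @param state A `bgru_state`.
#' @param inp A `linearized_input`.
#' @param label Gold label, 0 (none) or 1 (Lives_In).
#' @param dropout_mask Optional fixed mask on the sentence vector.
#' @return Negative log-probability of the gold class.
#' @export
instance_loss <- function(state, inp, label, dropout_mask = NULL) {
  fw <- model_forward(state, inp, dropout_mask)
  -log(fw$probs[[label + 1L]])
}

# loss + gradients for one instance; grads mirror the parameter structure
instance_grads <- function(state, inp, label, dropout_mask = NULL) {
  fw <- model_forward(state, inp, dropout_mask)
  n <- fw$n
  att <- fw$att

  dlogits <- fw$probs
  dlogits[[label + 1L]] <- dlogits[[label + 1L]] - 1
  gW_o <- outer(dlogits, fw$o_d)
  gb_o <- dlogits
  do_d <- drop(crossprod(state$W_o, dlogits))
  do <- if (is.null(fw$dropout_mask)) do_d else do_d * fw$dropout_mask

  drv <- do * (1 - att$o^2)                       # through o = tanh(r)
  dD <- outer(drv, att$alpha)                     # through r = D alpha
  dalpha <- drop(crossprod(fw$D, drv))
  dm <- att$alpha * (dalpha - sum(dalpha * att$alpha))   # softmax jacobian
  gp <- drop(att$H %*% dm)
  dD <- dD + outer(state$p, dm) * (1 - att$H^2)   # through H = tanh(D)

  dHf <- dD / 2
  dHb <- dD[, n:1, drop = FALSE] / 2              # backward-direction order
  Xr <- fw$X[, n:1, drop = FALSE]
  bf <- gru_backward(fw$X, fw$f$cache, dHf, state$fwd)
  bb <- gru_backward(Xr, fw$b$cache, dHb, state$bwd)
  dX <- bf$dX + bb$dX[, n:1, drop = FALSE]

  emb <- embedding_grads(state, inp, dX)

  list(loss = -log(fw$probs[[label + 1L]]),
       probs = fw$probs,
       grads = c(emb,
                 list(fwd = bf$grads, bwd = bb$grads,
                      p = gp, W_o = gW_o, b_o = gb_o)))
}

gru_backward <- function(X, cache, dH, params) {
  n <- ncol(X)
  zero_like <- function(m) array(0, dim(m))
  g <- lapply(params[c("W_r", "U_r", "W_z", "U_z", "W", "U")], zero_like)
  use_bias <- !is.null(params$b_r)
  if (use_bias) {
    g$b_r <- numeric(length(params$b_r))
    g$b_z <- numeric(length(params$b_z))
    g$b_h <- numeric(length(params$b_h))
  }
  dX <- matrix(0, nrow(X), n)
  dh_next <- numeric(nrow(dH))
  for (t in n:1) {
    st <- cache[[t]]
    x <- X[, t]
    dh <- dH[, t] + dh_next
    dz <- dh * (st$h_prev - st$h_tilde)
    da_z <- dz * st$z * (1 - st$z)
    dht <- dh * (1 - st$z)
    da_h <- dht * (1 - st$h_tilde^2)
    u_da_h <- drop(crossprod(params$U, da_h))
    dr <- u_da_h * st$h_prev
    da_r <- dr * st$r * (1 - st$r)

    g$W_r <- g$W_r + outer(da_r, x)
    g$U_r <- g$U_r + outer(da_r, st$h_prev)
    g$W_z <- g$W_z + outer(da_z, x)
    g$U_z <- g$U_z + outer(da_z, st$h_prev)
    g$W <- g$W + outer(da_h, x)
    g$U <- g$U + outer(da_h, st$r * st$h_prev)
    if (use_bias) {
      g$b_r <- g$b_r + da_r
      g$b_z <- g$b_z + da_z
      g$b_h <- g$b_h + da_h
    }
    dX[, t] <- drop(crossprod(params$W_r, da_r) +
                    crossprod(params$W_z, da_z) +
                    crossprod(params$W, da_h))
    dh_next <- dh * st$z +
      drop(crossprod(params$U_z, da_z)) +
      drop(crossprod(params$U_r, da_r)) +
      u_da_h * st$r
  }
  list(grads = g, dX = dX)
}

# route input-feature gradients back into the three lookup tables
embedding_grads <- function(state, inp, dX) {
  kw <- state$cfg$k_word
  kp <- state$cfg$k_pos
  kd <- state$dist$k
  n <- ncol(dX)
  wi <- table_index(state$word, inp$tokens)
  pi <- table_index(state$pos, inp$pos)
  l1 <- distance_index(state$dist, inp$e1_pos - seq_len(n))
  l2 <- distance_index(state$dist, inp$e2_pos - seq_len(n))

  gw <- array(0, dim(state$word$vectors))
  gpos <- array(0, dim(state$pos$vectors))
  gd <- array(0, dim(state$dist$vectors))
  for (t in seq_len(n)) {
    gw[wi[[t]], ] <- gw[wi[[t]], ] + dX[seq_len(kw), t]
    gpos[pi[[t]], ] <- gpos[pi[[t]], ] + dX[kw + seq_len(kp), t]
    gd[l1[[t]], ] <- gd[l1[[t]], ] + dX[kw + kp + seq_len(kd), t]
    gd[l2[[t]], ] <- gd[l2[[t]], ] + dX[kw + kp + kd + seq_len(kd), t]
  }
  list(word = gw, pos = gpos, dist = gd)
}
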