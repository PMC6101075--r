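# Mini-batch training of the classifier: mean cross-entropy minimized with
# Adam, inverted dropout on the attention-pooled sentence vector, one seed
# driving initialization, shuffling and dropout masks. Mini-batches are
# processed as gradient accumulation over the individual variable-length
# sequences, which is arithmetically identical to padded batching.

# parameter bookkeeping: where each trainable tensor lives in the state
# (s) and in an instance_grads() result (g)
param_paths <- function(state) {
  gru_names <- c("W_r", "U_r", "W_z", "U_z", "W", "U")
  if (!is.null(state$fwd$b_r)) gru_names <- c(gru_names, "b_r", "b_z", "b_h")
  out <- list(
    word = list(s = c("word", "vectors"), g = "word"),
    pos = list(s = c("pos", "vectors"), g = "pos"),
    dist = list(s = c("dist", "vectors"), g = "dist"),
    p = list(s = "p", g = "p"),
    W_o = list(s = "W_o", g = "W_o"),
    b_o = list(s = "b_o", g = "b_o")
  )
  for (dir in c("fwd", "bwd")) {
    for (nm in gru_names) {
      out[[paste(dir, nm, sep = "_")]] <-
        list(s = c(dir, nm), g = c(dir, nm))
    }
  }
  out
}

get_path <- function(x, path) Reduce(`[[`, path, x)

set_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
  } else {
    x[[path[[1]]]] <- set_path(x[[path[[1]]]], path[-1], value)
  }
  x
}

adam_init <- function(state, paths) {
  list(t = 0L,
       m = lapply(paths, function(p) array(0, dim(as.array(get_path(state, p$s))))),
       v = lapply(paths, function(p) array(0, dim(as.array(get_path(state, p$s))))))
}

adam_step <- function(state, grads, opt, paths, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(paths)) {
    g <- get_path(grads, paths[[nm]]$g)
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    upd <- lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
    val <- get_path(state, paths[[nm]]$s)
    new_val <- if (is.null(dim(val))) val - as.numeric(upd)
               else val - array(upd, dim(val))
    state <- set_path(state, paths[[nm]]$s, new_val)
  }
  list(state = state, opt = opt)
}

add_grads <- function(a, b, paths) {
  for (nm in names(paths)) {
    p <- paths[[nm]]$g
    a <- set_path(a, p, get_path(a, p) + get_path(b, p))
  }
  a
}

scale_grads <- function(a, f, paths) {
  for (nm in names(paths)) {
    p <- paths[[nm]]$g
    a <- set_path(a, p, get_path(a, p) * f)
  }
  a
}

# maximum absolute entity distance over a set of inputs (the Eq-1 normalizer)
max_abs_distance <- function(inputs) {
  m <- max(vapply(inputs, function(inp) {
    n <- length(inp$tokens)
    max(inp$e1_pos - 1L, n - inp$e1_pos, inp$e2_pos - 1L, n - inp$e2_pos)
  }, integer(1)))
  max(m, 1L)
}

#' Train the attention-based BGRU classifier
#'
#' Minimizes mean cross-entropy over candidate instances with Adam at the
#' configured learning rate, in mini-batches, with inverted dropout applied
#' to the attention-pooled sentence vector during training only. A fixed
#' seed makes runs bit-identical on one platform.
#'
#' @param instances Tibble with a list-column `input` of
#'   [linearized_input()] objects and an integer column `label` (0/1), as
#'   produced by [build_instances()].
#' @param cfg A [train_config()].
#' @param word_tab,pos_tab Optional pre-trained [embedding_table()]s (e.g.
#'   from [train_domain_embeddings()]); by default tables are built from
#'   the training vocabulary with random initialization.
#' @param verbose Print per-epoch mean loss.
#' @return A `bgru_fit`: list with the trained `state`, per-epoch `history`
#'   tibble, the `cfg`, and the frozen distance normalizer `s`.
#' @export
train_model <- function(instances, cfg = train_config(),
                        word_tab = NULL, pos_tab = NULL, verbose = FALSE) {
  inputs <- instances$input
  labels <- instances$label
  if (length(inputs) < 1) abort("no training instances")
  if (length(unique(labels)) < 2) {
    warn("training set contains a single class; training anyway")
  }
  s <- max_abs_distance(inputs)
  if (is.null(word_tab)) {
    vocab <- unique(unlist(lapply(inputs, `[[`, "tokens")))
    word_tab <- embedding_table(vocab, cfg$k_word, seed = cfg$seed + 11L)
  }
  if (is.null(pos_tab)) {
    pvocab <- unique(unlist(lapply(inputs, `[[`, "pos")))
    pos_tab <- embedding_table(pvocab, cfg$k_pos, seed = cfg$seed + 13L)
  }
  if (word_tab$k != cfg$k_word || pos_tab$k != cfg$k_pos) {
    abort("embedding table widths do not match the training configuration")
  }

  set.seed(cfg$seed)
  state <- init_model_state(cfg, word_tab, pos_tab, s)
  paths <- param_paths(state)
  opt <- adam_init(state, paths)
  n_inst <- length(inputs)
  history <- tibble(epoch = integer(), loss = numeric())

  for (epoch in seq_len(cfg$epochs)) {
    order <- sample.int(n_inst)
    epoch_loss <- 0
    starts <- seq(1L, n_inst, by = cfg$batch_size)
    for (b0 in starts) {
      batch <- order[b0:min(b0 + cfg$batch_size - 1L, n_inst)]
      acc <- NULL
      for (i in batch) {
        mask <- if (cfg$dropout > 0) {
          rbinom(state$h, 1L, 1 - cfg$dropout) / (1 - cfg$dropout)
        } else NULL
        res <- instance_grads(state, inputs[[i]], labels[[i]], mask)
        epoch_loss <- epoch_loss + res$loss
        acc <- if (is.null(acc)) res$grads else
          add_grads(acc, res$grads, paths)
      }
      acc <- scale_grads(acc, 1 / length(batch), paths)
      stepped <- adam_step(state, acc, opt, paths, cfg$lr)
      state <- stepped$state
      opt <- stepped$opt
    }
    history <- bind_rows(history,
                         tibble(epoch = epoch, loss = epoch_loss / n_inst))
    if (verbose) {
      inform(sprintf("epoch %d: mean training loss %.4f",
                     epoch, epoch_loss / n_inst))
    }
  }
  structure(list(state = state, history = history, cfg = cfg, s = s),
            class = "bgru_fit")
}

#' @export
print.bgru_fit <- function(x, ...) {
  cat("<bgru_fit> h =", x$state$h, ", d_w =", x$state$d_w,
      ",", length(x$state$word$vocab), "word types,",
      nrow(x$history), "epochs trained\n")
  if (nrow(x$history)) {
    cat("  final mean training loss:",
        formatC(x$history$loss[nrow(x$history)], digits = 4, format = "f"),
        "\n")
  }
  invisible(x)
}

#' Classify one candidate instance
#'
#' Inference is deterministic: dropout is disabled.
#'
#' @param object A `bgru_fit` (or raw `bgru_state`).
#' @param inp A `linearized_input`.
#' @return List with `probs` (named probabilities over `none`/`Lives_In`,
#'   summing to 1) and the attention weights `alpha` for inspection.
#' @export
predict_instance <- function(object, inp) {
  state <- if (inherits(object, "bgru_fit")) object$state else object
  if (length(inp$tokens) == 0) abort("cannot classify an empty token sequence")
  fw <- model_forward(state, inp, dropout_mask = NULL)
  list(probs = setNames(fw$probs, c("none", "Lives_In")),
       alpha = fw$att$alpha)
}

#' Predict Lives_In probabilities for a table of instances
#'
#' @param object A `bgru_fit`.
#' @param instances Tibble with a list-column `input` (and any metadata
#'   columns, which are carried through).
#' @param threshold Probability above which a pair is predicted positive.
#' @param ... Unused.
#' @return The input tibble plus `prob` (Lives_In probability), `pred`
#'   (0/1) and a list-column `alpha` of attention weights.
#' @export
predict.bgru_fit <- function(object, instances, threshold = 0.5, ...) {
  res <- lapply(instances$input, function(inp) predict_instance(object, inp))
  mutate(instances,
         prob = vapply(res, function(r) r$probs[["Lives_In"]], numeric(1)),
         pred = as.integer(.data$prob > threshold),
         alpha = lapply(res, `[[`, "alpha"))
}

#' @method tidy bgru_fit
#' @export
tidy.bgru_fit <- function(x, ...) {
  x$history
}

#' @method glance bgru_fit
#' @export
glance.bgru_fit <- function(x, ...) {
  n_par <- sum(vapply(param_paths(x$state), function(p) {
    length(get_path(x$state, p$s))
  }, numeric(1)))
  tibble(h = x$state$h, d_w = x$state$d_w,
         vocab = length(x$state$word$vocab),
         s = x$s, epochs = nrow(x$history),
         final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)]
                      else NA_real_,
         n_parameters = n_par)
}

#' Plot the training-loss trajectory
#'
#' @param object A `bgru_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bgru_fit
#' @export
autoplot.bgru_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Epoch", y = "Mean training cross-entropy",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Plot attention weights over an input sequence
#'
#' @param inp A `linearized_input`.
#' @param alpha Attention weights for the sequence (summing to 1).
#' @return A ggplot bar chart of the per-token weights.
#' @export
plot_attention <- function(inp, alpha) {
  stopifnot(length(alpha) == length(inp$tokens))
  df <- tibble(position = seq_along(alpha),
               token = factor(paste0(seq_along(alpha), ": ", inp$tokens),
                              levels = paste0(seq_along(alpha), ": ",
                                              inp$tokens)),
               weight = as.numeric(alpha))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$token, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Attention weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
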