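# Model checkpointing: one JSON archive holding every learned tensor, the
# training configuration, the frozen distance normalizer and the
# vocabularies. Format version 1.

#' Save a fitted model to a JSON checkpoint
#'
#' @param fit A `bgru_fit` from [train_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  st <- fit$state
  payload <- list(
    format = "biotoper-checkpoint", version = 1L,
    cfg = Filter(Negate(is.null), unclass(fit$cfg)), s = fit$s,
    history = fit$history,
    word = list(vocab = names(st$word$vocab), vectors = st$word$vectors),
    pos = list(vocab = names(st$pos$vocab), vectors = st$pos$vectors),
    dist = list(s = st$dist$s, k = st$dist$k, vectors = st$dist$vectors),
    fwd = st$fwd, bwd = st$bwd,
    p = st$p, W_o = st$W_o, b_o = st$b_o,
    h = st$h, d_w = st$d_w
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a fitted model from a JSON checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A `bgru_fit`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort(paste0("checkpoint not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "biotoper-checkpoint")) {
    abort(paste0(path, " is not a biotoper checkpoint"))
  }
  if (raw$version != 1L) {
    abort(sprintf("unsupported checkpoint version %s", raw$version))
  }
  cfg_args <- Filter(function(x) length(x) > 0, raw$cfg)
  cfg <- do.call(train_config, cfg_args)
  as_mat <- function(x) if (is.matrix(x)) x else as.matrix(x)
  tab <- function(part, k) {
    embedding_table(part$vocab[-1], k, vectors = as_mat(part$vectors))
  }
  gru <- function(part) {
    setNames(lapply(names(part), function(nm) {
      if (startsWith(nm, "b_")) as.numeric(part[[nm]]) else as_mat(part[[nm]])
    }), names(part))
  }
  history <- if (length(raw$history)) as_tibble(raw$history)
             else tibble(epoch = integer(), loss = numeric())
  state <- structure(list(
    word = tab(raw$word, cfg$k_word),
    pos = tab(raw$pos, cfg$k_pos),
    dist = structure(list(s = raw$dist$s, k = raw$dist$k,
                          vectors = as_mat(raw$dist$vectors)),
                     class = "distance_table"),
    fwd = gru(raw$fwd), bwd = gru(raw$bwd),
    p = as.numeric(raw$p), W_o = as_mat(raw$W_o), b_o = as.numeric(raw$b_o),
    h = raw$h, d_w = raw$d_w, cfg = cfg, version = 1L
  ), class = "bgru_state")
  structure(list(state = state, history = history,
                 cfg = cfg, s = raw$s),
            class = "bgru_fit")
}
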