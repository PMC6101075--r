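# Independent reference implementations used as oracles. These are written
# element-by-element / by exhaustive search, deliberately sharing no code
# with the package internals.

# scalar-loop evaluation of the GRU gate equations, one component at a time
scalar_gru_step <- function(x, h_prev, par) {
  h_dim <- nrow(par$W_r)
  r <- z <- h_tilde <- h <- numeric(h_dim)
  sig <- function(v) 1 / (1 + exp(-v))
  for (j in seq_len(h_dim)) {
    ar <- 0
    az <- 0
    for (i in seq_along(x)) {
      ar <- ar + par$W_r[j, i] * x[i]
      az <- az + par$W_z[j, i] * x[i]
    }
    for (i in seq_along(h_prev)) {
      ar <- ar + par$U_r[j, i] * h_prev[i]
      az <- az + par$U_z[j, i] * h_prev[i]
    }
    r[j] <- sig(ar)
    z[j] <- sig(az)
  }
  for (j in seq_len(h_dim)) {
    ah <- 0
    for (i in seq_along(x)) ah <- ah + par$W[j, i] * x[i]
    for (i in seq_along(h_prev)) {
      ah <- ah + par$U[j, i] * (r[i] * h_prev[i])
    }
    h_tilde[j] <- tanh(ah)
    h[j] <- z[j] * h_prev[j] + (1 - z[j]) * h_tilde[j]
  }
  list(r = r, z = z, h_tilde = h_tilde, h = h)
}

random_gru_params <- function(h, d_w) {
  m <- function(nr, nc) matrix(rnorm(nr * nc), nr, nc)
  list(W_r = m(h, d_w), U_r = m(h, h), W_z = m(h, d_w), U_z = m(h, h),
       W = m(h, d_w), U = m(h, h))
}

# breadth-first shortest path on an undirected edge list; returns the
# vertex set of one shortest path between a and b (NULL if unreachable)
bfs_path <- function(n, edges, a, b) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  queue <- a
  seen[a] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    if (v == b) break
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!seen[b]) return(NULL)
  path <- b
  while (!is.na(prev[path[[1]]])) path <- c(prev[path[[1]]], path)
  path
}

# exhaustive maximum 1-to-1 matching between gold and pred relation sets
# under an equality predicate; returns the maximum number of matched pairs
max_matching <- function(n_gold, n_pred, can_match) {
  best <- 0L
  recurse <- function(p, used_gold, count) {
    best <<- max(best, count)
    if (p > n_pred) return()
    recurse(p + 1L, used_gold, count)           # leave prediction p unmatched
    for (g in seq_len(n_gold)) {
      if (!used_gold[g] && can_match(g, p)) {
        used_gold[g] <- TRUE
        recurse(p + 1L, used_gold, count + 1L)
        used_gold[g] <- FALSE
      }
    }
  }
  if (n_pred > 0) recurse(1L, rep(FALSE, max(n_gold, 1L)), 0L)
  best
}

# parse graph of the running instance: "contains entity_1 at environment
# with entity_2", a head chain so the path between the placeholders runs
# through at/environment/with and the governing verb sits above entity_1
example_graph <- function() {
  g <- tibble::tibble(
    idx = 1:6,
    surface = c("contains", "entity_1", "at", "environment", "with",
                "entity_2"),
    stem = c("contain", "entity_1", "at", "environment", "with",
             "entity_2"),
    pos = c("VBZ", "NNP", "IN", "NN", "IN", "NNP"),
    chunk = c("VP", "NP", "PP", "NP", "PP", "NP"),
    entity = "O",
    head = c(0L, 1L, 2L, 3L, 4L, 5L),
    dep = c("root", "dep", "prep", "pobj", "prep", "pobj")
  )
  attr(g, "e1_pos") <- 2L
  attr(g, "e2_pos") <- 6L
  g
}

example_input <- function() {
  linearized_input(
    c("contains", "entity_1", "at", "environment", "with", "entity_2"),
    c("VBZ", "NNP", "IN", "NN", "IN", "NNP"),
    e1_pos = 2, e2_pos = 6
  )
}

# quick instance tibble for model tests
toy_instances <- function(inputs, labels) {
  tibble::tibble(doc_id = "toy", sentence = 1L,
                 e1 = "T1", e2 = "T2", e2_type = "Habitat",
                 label = as.integer(labels), input = inputs)
}

# small separable instance set: positives carry the cue token on the path
separable_instances <- function(n, seed = 42) {
  withr_seed <- function(code) code
  set.seed(seed)
  inputs <- list()
  labels <- integer(n)
  fillers <- c("resembles", "parallels", "predates")
  for (i in seq_len(n)) {
    lab <- i %% 2L
    mid <- if (lab == 1L) "inhabits" else sample(fillers, 1)
    extra <- sample(c("soil", "gut", "milk"), 1)
    inputs[[i]] <- linearized_input(
      c("entity_1", mid, extra, "entity_2"),
      c("NNP", "VBZ", "NN", "NNP"), 1, 4)
    labels[[i]] <- lab
  }
  toy_instances(inputs, labels)
}

# numerical gradient of instance_loss by central differences at one
# coordinate of a nested parameter
numeric_grad_at <- function(state, inp, label, spath, idx, eps = 1e-5) {
  get_p <- function(st) Reduce(`[[`, spath, st)
  set_p <- function(st, v) {
    assign_rec <- function(x, path, value) {
      if (length(path) == 1L) {
        x[[path]] <- value
      } else {
        x[[path[[1]]]] <- assign_rec(x[[path[[1]]]], path[-1], value)
      }
      x
    }
    assign_rec(st, spath, v)
  }
  v <- get_p(state)
  vp <- v; vp[idx] <- vp[idx] + eps
  vm <- v; vm[idx] <- vm[idx] - eps
  lp <- instance_loss(set_p(state, vp), inp, label)
  lm <- instance_loss(set_p(state, vm), inp, label)
  (lp - lm) / (2 * eps)
}
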