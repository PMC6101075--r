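test_that("the running instance yields the expected SPT and DET leaves", {
  g <- example_graph()
  spt <- shortest_path_tokens(g)
  expect_equal(spt$tokens,
               c("entity_1", "at", "environment", "with", "entity_2"))
  expect_equal(spt$e1_pos, 1L)
  expect_equal(spt$e2_pos, 5L)
  det <- dynamic_extended_tokens(g, spt)
  expect_equal(det$tokens,
               c("contains", "entity_1", "at", "environment", "with",
                 "entity_2"))
  expect_equal(det$e1_pos, 2L)
  expect_equal(det$e2_pos, 6L)
})

test_that("adjacent entities with a direct edge give a 2-token path", {
  g <- tibble::tibble(idx = 1:2,
                      surface = c("entity_1", "entity_2"),
                      stem = c("entity_1", "entity_2"),
                      pos = c("NNP", "NNP"), chunk = "NP", entity = "O",
                      head = c(0L, 1L), dep = c("root", "dep"))
  spt <- shortest_path_tokens(g, 1L, 2L)
  expect_equal(spt$tokens, c("entity_1", "entity_2"))
})

test_that("SPT matches a breadth-first-search oracle on random trees", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(3:8, 1)
    # random tree via random parent links
    head <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1)))
    g <- tibble::tibble(idx = seq_len(n),
                        surface = paste0("w", seq_len(n)),
                        stem = paste0("w", seq_len(n)),
                        pos = "NN", chunk = "O", entity = "O",
                        head = head, dep = "dep")
    ends <- sample.int(n, 2)
    g$surface[ends] <- c("entity_1", "entity_2")
    spt <- shortest_path_tokens(g, ends[1], ends[2])
    edges <- cbind(g$idx, g$head)[g$head != 0L, , drop = FALSE]
    oracle <- bfs_path(n, edges, ends[1], ends[2])
    expect_setequal(attr(spt, "sentence_idx"), oracle)
    # retained tokens keep sentence order
    expect_equal(attr(spt, "sentence_idx"), sort(attr(spt, "sentence_idx")))
    # symmetry in the two entity arguments
    spt_rev <- shortest_path_tokens(g, ends[2], ends[1])
    expect_equal(spt_rev$tokens, spt$tokens)
  }
})

test_that("DET adds exactly the nearest verb ancestor, k links up", {
  for (k in 1:3) {
    # chain: verb <- f_1 <- ... <- f_{k-1} <- e1 ; e2 attached below e1
    n <- k + 2L
    head <- c(0L, seq_len(n - 1L))
    pos <- c("VBZ", rep("NN", k - 1), "NNP", "NNP")
    fillers <- if (k > 1) paste0("f", seq_len(k - 1)) else character(0)
    g <- tibble::tibble(idx = seq_len(n),
                        surface = c("gov", fillers,
                                    "entity_1", "entity_2"),
                        stem = "x", pos = pos, chunk = "O", entity = "O",
                        head = head, dep = "dep")
    spt <- shortest_path_tokens(g, n - 1L, n)
    expect_equal(spt$tokens, c("entity_1", "entity_2"))
    det <- dynamic_extended_tokens(g, spt)
    # hand-walked oracle: ancestors of the shallower endpoint until a VB*
    walk <- n - 1L
    repeat {
      walk <- g$head[[walk]]
      if (walk == 0L || startsWith(g$pos[[walk]], "VB")) break
    }
    expect_equal(setdiff(attr(det, "sentence_idx"),
                         attr(spt, "sentence_idx")),
                 walk)
    expect_equal(det$tokens[[1]], "gov")
  }
})

test_that("DET equals SPT when no verb ancestor exists", {
  g <- tibble::tibble(idx = 1:3,
                      surface = c("entity_1", "of", "entity_2"),
                      stem = "x", pos = c("NNP", "IN", "NNP"),
                      chunk = "O", entity = "O",
                      head = c(0L, 1L, 2L), dep = "dep")
  spt <- shortest_path_tokens(g, 1L, 3L)
  det <- dynamic_extended_tokens(g, spt)
  expect_equal(det$tokens, spt$tokens)
})

test_that("SPT and DET are nested subsets of the sentence in order", {
  dir <- withr_tempdir()
  generate_corpus(synth_config(n_docs = 4, seed = 21), dir)
  for (doc in read_corpus(dir)) {
    sentences <- read_parses(file.path(dir, paste0(doc$doc_id, ".parse")))
    cands <- enumerate_candidates(doc, sentences)
    for (i in seq_len(min(nrow(cands), 10))) {
      g <- replace_entities(sentences[[cands$sentence[[i]]]],
                            cands$e1_tokens[[i]], cands$e2_tokens[[i]])
      spt <- shortest_path_tokens(g)
      det <- dynamic_extended_tokens(g, spt)
      si <- attr(spt, "sentence_idx")
      di <- attr(det, "sentence_idx")
      expect_true(all(si %in% di))
      expect_true(all(di %in% g$idx))
      expect_equal(di, sort(di))
    }
  }
})

test_that("a disconnected parse falls back to the whole sentence", {
  g <- tibble::tibble(idx = 1:4,
                      surface = c("entity_1", "x", "entity_2", "y"),
                      stem = "x", pos = "NN", chunk = "O", entity = "O",
                      head = c(0L, 1L, 0L, 3L), dep = "dep")
  expect_warning(spt <- shortest_path_tokens(g, 1L, 3L), "disconnected")
  expect_equal(length(spt$tokens), 4L)
})
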