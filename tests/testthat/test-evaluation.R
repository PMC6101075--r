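rel_tbl <- function(...) {
  pairs <- list(...)
  tibble::tibble(bacterium = vapply(pairs, `[[`, character(1), 1),
                 location = vapply(pairs, `[[`, character(1), 2))
}

test_that("identical prediction and gold sets score perfectly", {
  gold <- rel_tbl(c("T1", "T2"), c("T3", "T4"))
  out <- match_events(gold, gold)
  expect_equal(out$TP, 2L)
  expect_equal(out$FP, 0L)
  expect_equal(out$FN, 0L)
  expect_equal(out$F, 1)
})

test_that("Equiv siblings match gold arguments", {
  gold <- rel_tbl(c("T1", "T2"))
  pred <- rel_tbl(c("T1", "T5"))
  expect_equal(match_events(gold, pred)$TP, 0L)
  out <- match_events(gold, pred, equiv = list(c("T2", "T5")))
  expect_equal(out$TP, 1L)
  expect_equal(out$F, 1)
})

test_that("greedy matching equals exhaustive maximum matching", {
  set.seed(41)
  ids <- paste0("T", 1:4)
  for (trial in 1:60) {
    ng <- sample(0:6, 1)
    np <- sample(0:6, 1)
    gold <- tibble::tibble(bacterium = sample(ids, ng, replace = TRUE),
                           location = sample(ids, ng, replace = TRUE))
    pred <- tibble::tibble(bacterium = sample(ids, np, replace = TRUE),
                           location = sample(ids, np, replace = TRUE))
    equiv <- if (runif(1) < 0.5) list(c("T1", "T2")) else list()
    out <- match_events(gold, pred, equiv)
    canon <- function(x) if (length(equiv) && x %in% equiv[[1]]) "T1" else x
    # scorer deduplicates equivalent predictions first; mirror that here
    pk <- unique(paste(vapply(pred$bacterium, canon, character(1)),
                       vapply(pred$location, canon, character(1))))
    gk <- paste(vapply(gold$bacterium, canon, character(1)),
                vapply(gold$location, canon, character(1)))
    best <- max_matching(length(gk), length(pk),
                         function(g, p) gk[g] == pk[p])
    expect_equal(out$TP, best)
    expect_equal(out$FP, length(pk) - best)
    expect_equal(out$FN, length(gk) - best)
  }
})

test_that("counts are invariant under Equiv substitution in gold", {
  equiv <- list(c("T3", "T7"), c("T2", "T9"))
  gold <- rel_tbl(c("T1", "T3"), c("T2", "T4"))
  pred <- rel_tbl(c("T1", "T7"), c("T9", "T4"), c("T1", "T4"))
  base <- match_events(gold, pred, equiv)
  gold_swapped <- rel_tbl(c("T1", "T7"), c("T9", "T4"))
  swapped <- match_events(gold_swapped, pred, equiv)
  expect_equal(base[c("TP", "FP", "FN")], swapped[c("TP", "FP", "FN")])
})

test_that("prf applies the F formula with guarded zero denominators", {
  perfect <- prf(5, 0, 0)
  expect_equal(c(perfect$P, perfect$R, perfect$F), c(1, 1, 1))
  nothing <- prf(0, 3, 4)
  expect_equal(c(nothing$P, nothing$R, nothing$F), c(0, 0, 0))
  mixed <- prf(2, 1, 3)
  expect_equal(mixed$P, 2 / 3)
  expect_equal(mixed$R, 0.4)
  expect_equal(mixed$F, 0.5)
})

test_that("F is symmetric, bounded by max(P, R), and FP never helps", {
  set.seed(51)
  for (i in 1:25) {
    tp <- sample(0:8, 1); fp <- sample(0:8, 1); fn <- sample(0:8, 1)
    a <- prf(tp, fp, fn)
    b <- prf(tp, fn, fp)          # swaps P and R
    expect_equal(a$F, b$F)
    expect_lte(a$F, max(a$P, a$R) + 1e-12)
    worse <- prf(tp, fp + 1, fn)
    expect_lte(worse$P, a$P)
  }
})

test_that("cross-sentence gold relations surface only as false negatives", {
  dir <- withr_tempdir()
  generate_corpus(synth_config(n_docs = 30, cross_rate = 1,
                               sentences_per_doc = 3, seed = 77), dir)
  docs <- read_corpus(dir)
  n_cross <- 0L
  for (doc in docs) {
    sentences <- read_parses(file.path(dir, paste0(doc$doc_id, ".parse")))
    cands <- enumerate_candidates(doc, sentences)
    cross <- attr(cands, "cross_sentence")
    n_cross <- n_cross + length(cross)
    # a perfect intra-sentence predictor still loses the cross-sentence gold
    perfect <- dplyr::filter(cands, label == 1L)
    pred <- tibble::tibble(bacterium = perfect$e1, location = perfect$e2)
    out <- match_events(doc$relations, pred, doc$equiv)
    expect_equal(out$FP, 0L)
    expect_equal(out$FN, length(cross))
  }
  expect_gt(n_cross, 0L)
})

test_that("corpus evaluation aggregates per-document counts", {
  dir <- withr_tempdir()
  generate_corpus(synth_config(n_docs = 3, seed = 15), dir)
  docs <- read_corpus(dir)
  ev <- evaluate_corpus(docs, docs)   # self-comparison
  expect_equal(ev$overall$F, 1)
  report <- format_report(ev)
  expect_match(report[length(report)], "P=100.00%")
  empty <- tibble::tibble(doc_id = character(), bacterium = character(),
                          location = character())
  ev0 <- evaluate_corpus(docs, empty)
  expect_equal(ev0$overall$TP, 0L)
  expect_equal(ev0$overall$FN, sum(vapply(docs, function(d)
    nrow(d$relations), integer(1))))
})
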