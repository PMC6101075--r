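test_that("entity annotations parse with the declared types and surfaces", {
  base <- tortoise_fixture(with_a2 = FALSE)
  doc <- read_document(paste0(base, ".txt"), paste0(base, ".a1"))
  expect_s3_class(doc$entities, "tbl_df")
  expect_setequal(doc$entities$id, c("T1", "T2", "T3", "T4"))
  types <- setNames(doc$entities$type, doc$entities$id)
  expect_equal(types[["T4"]], "Geographical")
  expect_equal(types[["T3"]], "Habitat")
  expect_equal(types[["T1"]], "Bacteria")
  # every surface equals the text slice it indexes
  for (i in seq_len(nrow(doc$entities))) {
    expect_equal(doc$entities$surface[[i]],
                 substr(doc$text, doc$entities$start[[i]] + 1L,
                        doc$entities$end[[i]]))
  }
  # absent a2 -> no relations, no equiv groups
  expect_equal(nrow(doc$relations), 0L)
  expect_length(doc$equiv, 0L)
})

test_that("relations, Equiv groups and discontinuous spans are read", {
  dir <- withr_tempdir()
  text <- "Borrelia burgdorferi was seen in ticks and in deer ."
  writeLines(text, file.path(dir, "d.txt"))
  writeLines(c(
    "T1\tBacteria 0 20\tBorrelia burgdorferi",
    sprintf("T2\tHabitat %d %d;%d %d\tin ticks in deer", 30, 38, 43, 50),
    "T3\tHabitat 33 38\tticks"
  ), file.path(dir, "d.a1"))
  writeLines(c(
    "R1\tLives_In Bacterium:T1 Location:T3",
    "*\tEquiv T2 T3"
  ), file.path(dir, "d.a2"))
  doc <- read_document(file.path(dir, "d.txt"), file.path(dir, "d.a1"),
                       file.path(dir, "d.a2"))
  expect_equal(doc$entities$surface[doc$entities$id == "T2"],
               "in ticks in deer")  # pieces joined by a single space
  expect_equal(nrow(doc$relations), 1L)
  expect_equal(doc$equiv, list(c("T2", "T3")))
})

test_that("equiv groups are closed transitively into disjoint sets", {
  closed <- biotoper:::close_equiv(list(c("T1", "T2"), c("T2", "T3"),
                                        c("T5", "T6")))
  expect_length(closed, 2L)
  expect_true(any(vapply(closed, function(g)
    setequal(g, c("T1", "T2", "T3")), logical(1))))
})

test_that("malformed and dangling annotations raise informative errors", {
  dir <- withr_tempdir()
  writeLines("Some text here.", file.path(dir, "d.txt"))
  writeLines("T1\tBacteria zero 4\tSome", file.path(dir, "bad.a1"))
  expect_error(read_document(file.path(dir, "d.txt"),
                             file.path(dir, "bad.a1")),
               "line 1")
  writeLines("T1\tBacteria 0 4\tSome", file.path(dir, "d.a1"))
  writeLines("R1\tLives_In Bacterium:T1 Location:T9", file.path(dir, "d.a2"))
  expect_error(read_document(file.path(dir, "d.txt"), file.path(dir, "d.a1"),
                             file.path(dir, "d.a2")),
               "T9")
})

test_that("unused annotation layers are skipped with a warning", {
  dir <- withr_tempdir()
  writeLines("Some text here.", file.path(dir, "d.txt"))
  writeLines("T1\tBacteria 0 4\tSome", file.path(dir, "d.a1"))
  writeLines(c("R1\tLives_In Bacterium:T1 Location:T1",
               "N1\tOntoBiotope Annotation:T1"),
             file.path(dir, "d.a2"))
  # note: the Lives_In line itself is invalid (location is Bacteria)
  expect_error(read_document(file.path(dir, "d.txt"), file.path(dir, "d.a1"),
                             file.path(dir, "d.a2")),
               "Bacteria")
  writeLines("N1\tOntoBiotope Annotation:T1", file.path(dir, "d.a2"))
  expect_warning(
    doc <- read_document(file.path(dir, "d.txt"), file.path(dir, "d.a1"),
                         file.path(dir, "d.a2")),
    "skipping")
  expect_equal(nrow(doc$relations), 0L)
})

test_that("write_a2 follows the relation grammar", {
  expect_equal(write_a2(tibble::tibble(bacterium = character(),
                                       location = character())), "")
  one <- tibble::tibble(bacterium = "T1", location = "T2")
  expect_equal(write_a2(one), "R1\tLives_In Bacterium:T1 Location:T2")
  # n relations -> n lines with strictly increasing ids
  set.seed(1)
  for (n in c(2, 5, 9)) {
    rel <- tibble::tibble(bacterium = paste0("T", sample(100, n)),
                          location = paste0("T", 100 + sample(100, n)))
    lines <- strsplit(write_a2(rel), "\n")[[1]]
    expect_length(lines, n)
    ids <- as.integer(sub("^R(\\d+)\t.*", "\\1", lines))
    expect_equal(ids, seq_len(n))
  }
  ents <- tibble::tibble(id = c("T1", "T2"),
                         type = c("Habitat", "Habitat"))
  expect_error(write_a2(one, ents), "Bacteria")
})

test_that("read-write-read is the identity on the relation set", {
  dir <- withr_tempdir()
  cfg <- synth_config(n_docs = 4, seed = 11)
  generate_corpus(cfg, dir)
  docs <- read_corpus(dir)
  for (doc in docs) {
    out <- withr_tempdir()
    write_document(doc, out)
    doc2 <- read_document(file.path(out, paste0(doc$doc_id, ".txt")),
                          file.path(out, paste0(doc$doc_id, ".a1")),
                          file.path(out, paste0(doc$doc_id, ".a2")))
    expect_equal(doc2$relations[c("bacterium", "location")],
                 doc$relations[c("bacterium", "location")])
    expect_equal(doc2$equiv, doc$equiv)
    expect_equal(doc2$entities$surface, doc$entities$surface)
  }
})
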