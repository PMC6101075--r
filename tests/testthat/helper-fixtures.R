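# In-code standoff fixtures (no files are stored in the repo).

# A document shaped like the task's canonical example: two bacteria, one
# habitat ("populations of gopher tortoises"), one geographical entity
# ("Georgia"), all in one sentence.
tortoise_fixture <- function(dir = withr_tempdir(), with_a2 = TRUE) {
  text <- paste("Mycoplasma agassizii and Mycoplasma testudineum infected",
                "populations of gopher tortoises in Georgia .")
  span <- function(str) {
    s <- regexpr(str, text, fixed = TRUE)
    c(s - 1L, s - 1L + nchar(str))
  }
  sp1 <- span("Mycoplasma agassizii")
  sp2 <- span("Mycoplasma testudineum")
  sp3 <- span("populations of gopher tortoises")
  sp4 <- span("Georgia")
  a1 <- c(
    sprintf("T1\tBacteria %d %d\tMycoplasma agassizii", sp1[1], sp1[2]),
    sprintf("T2\tBacteria %d %d\tMycoplasma testudineum", sp2[1], sp2[2]),
    sprintf("T3\tHabitat %d %d\tpopulations of gopher tortoises",
            sp3[1], sp3[2]),
    sprintf("T4\tGeographical %d %d\tGeorgia", sp4[1], sp4[2])
  )
  a2 <- c("R1\tLives_In Bacterium:T1 Location:T3",
          "R2\tLives_In Bacterium:T1 Location:T4",
          "R3\tLives_In Bacterium:T2 Location:T3")
  base <- file.path(dir, "tortoise")
  writeLines(text, paste0(base, ".txt"))
  writeLines(a1, paste0(base, ".a1"))
  if (with_a2) writeLines(a2, paste0(base, ".a2"))
  base
}

withr_tempdir <- function() {
  d <- tempfile("biotoper-test-")
  dir.create(d)
  d
}

# flat parse for the tortoise sentence: every content token hangs off the
# verb "infected"; entity-internal tokens chain to their mention head
tortoise_parses <- function() {
  toks <- c("Mycoplasma", "agassizii", "and", "Mycoplasma", "testudineum",
            "infected", "populations", "of", "gopher", "tortoises", "in",
            "Georgia", ".")
  pos <- c("NNP", "NNP", "CC", "NNP", "NNP", "VBD", "NNS", "IN", "NN",
           "NNS", "IN", "NNP", ".")
  head <- c(2L, 6L, 2L, 5L, 2L, 0L, 6L, 7L, 10L, 8L, 6L, 11L, 6L)
  list(tibble::tibble(
    idx = seq_along(toks), surface = toks, stem = tolower(toks), pos = pos,
    chunk = "O", entity = "O", head = head, dep = "dep"
  ))
}
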