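# Synthetic standoff corpus with planted dependency-path signal.
#
# Each sentence has 1-3 Bacteria mentions and 1-3 location mentions. Every
# location slot carries its own governing verb attached to the sentence
# root; all bacterium mentions attach to the root as subjects, so the
# dependency path between a bacterium and location j runs
#   bacterium -> root verb -> verb_j [-> preposition] -> location_j.
# A slot designated gold-positive gets the cue token (default "inhabits")
# as verb_j with probability p_cue, so the discriminative signal sits on
# the dependency path — exactly what shortest-path inputs are meant to
# exploit. Distractor cues appear off the path (inside a relative clause on
# a filler noun) so bag-of-words shortcuts see the cue in negative
# sentences too. Locations occasionally carry a parenthesized alias mention
# declared Equiv, and documents occasionally carry a cross-sentence gold
# relation that no intra-sentence system can reach.

GENUS <- c("Lactococcus", "Bacillus", "Mycoplasma", "Borrelia",
           "Streptococcus", "Helicobacter", "Vibrio", "Listeria")
SPECIES <- c("lactis", "subtilis", "agassizii", "burgdorferi", "pylori",
             "cholerae", "monocytogenes", "testudinis")
HABITATS <- list(c("soil"), c("gut"), c("dairy", "products"),
                 c("gopher", "tortoises"), c("human", "skin"),
                 c("marine", "sediment"), c("raw", "milk"), c("saliva"))
GEOS <- c("Georgia", "France", "Japan", "Norway", "Peru", "Ghana")
NEUTRAL_VERBS <- c("resembles", "predates", "parallels")
ROOT_VERBS <- c("appeared", "persisted", "spread")
FILLER_NOUNS <- c("cultures", "samples", "isolates", "colonies")
ALIASES <- c("GI", "SP", "NP", "CF", "BD", "MK")

#' Configuration for the synthetic corpus generator
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Sentences per document.
#' @param cue Cue token planted on the dependency path between positive
#'   pairs.
#' @param p_cue Probability that a gold-positive location slot actually
#'   receives the cue verb (at 1 the label is exactly
#'   "cue-on-dependency-path").
#' @param positive_rate Probability that a location slot is gold-positive.
#' @param p_distract Probability of an off-path distractor cue in a
#'   sentence.
#' @param geo_prop Proportion of Geographical (vs Habitat) locations.
#' @param equiv_rate Probability that a location carries a parenthesized
#'   alias mention declared Equiv.
#' @param cross_rate Probability that a document carries one cross-sentence
#'   gold relation (exercises the false-negative rule in scoring).
#' @param n_bacteria_vocab,n_location_vocab Vocabulary sizes (capped at the
#'   built-in inventories).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_docs = 20, sentences_per_doc = 5,
                         cue = "inhabits", p_cue = 0.95,
                         positive_rate = 0.4, p_distract = 0.3,
                         geo_prop = 0.25, equiv_rate = 0.15,
                         cross_rate = 0.05,
                         n_bacteria_vocab = length(GENUS),
                         n_location_vocab = length(HABITATS),
                         seed = 1L) {
  probs <- c(p_cue, positive_rate, p_distract, geo_prop, equiv_rate,
             cross_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_docs < 0 || sentences_per_doc < 1) abort("invalid corpus size")
  if (n_bacteria_vocab < 1 || n_location_vocab < 1) {
    abort("vocabulary sizes must be positive")
  }
  structure(list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                 cue = cue, p_cue = p_cue, positive_rate = positive_rate,
                 p_distract = p_distract, geo_prop = geo_prop,
                 equiv_rate = equiv_rate, cross_rate = cross_rate,
                 n_bacteria_vocab = min(n_bacteria_vocab, length(GENUS)),
                 n_location_vocab = min(n_location_vocab, length(HABITATS)),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# one sentence plan: a token template (surface/pos/entity/role/mention) plus
# mention metadata and slot labels
plan_sentence <- function(cfg) {
  n_b <- sample.int(3L, 1L)
  n_l <- sample.int(3L, 1L)
  rows <- list()
  mentions <- list()
  push <- function(surface, pos, role, entity = "O", mention = NA_integer_) {
    rows[[length(rows) + 1L]] <<- list(surface = surface, pos = pos,
                                       role = role, entity = entity,
                                       mention = mention)
  }
  new_mention <- function(type, target) {
    mentions[[length(mentions) + 1L]] <<- list(type = type, target = target)
    length(mentions)
  }

  if (runif(1) < 0.3) push("Reportedly", "RB", "FILLER")
  for (i in seq_len(n_b)) {
    if (i > 1) push("and", "CC", "CC")
    m <- new_mention("Bacteria", NA)
    genus <- GENUS[sample.int(cfg$n_bacteria_vocab, 1L)]
    species <- sample(SPECIES, 1L)
    push(genus, "NNP", "BMOD", "B-Bacteria", m)
    push(species, "NNP", "B", "I-Bacteria", m)
  }
  push(sample(ROOT_VERBS, 1L), "VBD", "ROOT")
  if (runif(1) < cfg$p_distract) {
    push(",", ",", "PUNCT")
    push("which", "WDT", "WH")
    push(sample(FILLER_NOUNS, 1L), "NNS", "DNOUN")
    push(cfg$cue, "VBZ", "DVERB")
  }

  slot_positive <- logical(n_l)
  slot_mention <- integer(n_l)
  slot_alias <- rep(NA_integer_, n_l)
  for (j in seq_len(n_l)) {
    if (j > 1) push(",", ",", "PUNCT")
    positive <- runif(1) < cfg$positive_rate
    slot_positive[[j]] <- positive
    verb <- if (positive && runif(1) < cfg$p_cue) cfg$cue
            else sample(NEUTRAL_VERBS, 1L)
    push(verb, "VBZ", "V")
    if (runif(1) < 0.5) push(sample(c("in", "near", "within"), 1L),
                             "IN", "PREP")
    geo <- runif(1) < cfg$geo_prop
    type <- if (geo) "Geographical" else "Habitat"
    toks <- if (geo) GEOS[sample.int(length(GEOS), 1L)]
            else HABITATS[[sample.int(cfg$n_location_vocab, 1L)]]
    m <- new_mention(type, NA)
    slot_mention[[j]] <- m
    for (ti in seq_along(toks)) {
      push(toks[[ti]], if (geo) "NNP" else "NN",
           if (ti == length(toks)) "L" else "LMOD",
           paste0(if (ti == 1) "B-" else "I-", type), m)
    }
    if (runif(1) < cfg$equiv_rate) {
      am <- new_mention(type, NA)
      slot_alias[[j]] <- am
      push("(", "-LRB-", "LPAR")
      push(sample(ALIASES, 1L), "NNP", "ALIAS", paste0("B-", type), am)
      push(")", "-RRB-", "RPAR")
    }
  }
  push(".", ".", "PUNCT")

  template <- bind_rows(lapply(rows, as_tibble))
  list(template = template, mentions = mentions,
       slot_positive = slot_positive, slot_mention = slot_mention,
       slot_alias = slot_alias)
}

crude_stem <- function(w) {
  s <- tolower(w)
  ifelse(nchar(s) > 3 & endsWith(s, "s"), substr(s, 1, nchar(s) - 1L), s)
}

chunk_of <- function(pos) {
  ifelse(startsWith(pos, "NN"), "NP",
         ifelse(startsWith(pos, "VB"), "VP",
                ifelse(pos == "IN", "PP", "O")))
}

#' Build a dependency parse for a sentence template
#'
#' Assigns a projective head structure in which each location's governing
#' verb attaches to the sentence root and the two entity heads of a pair
#' are governed by that verb (directly or through a preposition), so the
#' verb — the cue, for positive slots — lies on the dependency path between
#' them. Degenerate templates without a root verb (e.g. `B cue L .`) make
#' the cue verb itself the root governing both entity heads.
#'
#' @param template Tibble with columns `surface`, `pos`, `role` (one of
#'   `B`, `BMOD`, `CC`, `ROOT`, `V`, `PREP`, `L`, `LMOD`, `ALIAS`, `LPAR`,
#'   `RPAR`, `WH`, `DNOUN`, `DVERB`, `FILLER`, `PUNCT`) and optionally
#'   `entity`/`mention`.
#' @return A sentence parse tibble in the [read_parses()] layout.
#' @export
generate_parses <- function(template) {
  n <- nrow(template)
  role <- template$role
  head <- integer(n)
  dep <- character(n)
  root <- which(role == "ROOT")[1]
  if (is.na(root)) root <- which(role == "V")[1]
  if (is.na(root)) root <- 1L
  first_b <- which(role == "B")[1]
  last_before <- function(i, what) {
    hits <- which(role[seq_len(i - 1L)] %in% what)
    if (length(hits)) hits[[length(hits)]] else NA_integer_
  }
  next_after <- function(i, what) {
    hits <- which(role %in% what)
    hits <- hits[hits > i]
    if (length(hits)) hits[[1]] else NA_integer_
  }
  for (i in seq_len(n)) {
    h <- switch(role[[i]],
      ROOT = 0L,
      B = if (i == first_b) root else first_b,
      BMOD = next_after(i, "B"),
      CC = first_b,
      V = if (i == root) 0L else root,
      PREP = last_before(i, "V"),
      L = {
        g <- last_before(i, c("PREP", "V"))
        if (is.na(g)) root else g
      },
      LMOD = next_after(i, "L"),
      ALIAS = last_before(i, "L"),
      LPAR = next_after(i, "ALIAS"),
      RPAR = last_before(i, "ALIAS"),
      WH = next_after(i, "DNOUN"),
      DNOUN = root,
      DVERB = last_before(i, "DNOUN"),
      FILLER = root,
      PUNCT = root,
      root)
    if (is.na(h)) h <- root
    head[[i]] <- if (i == root) 0L else as.integer(h)
    dep[[i]] <- switch(role[[i]],
      ROOT = "root", B = "nsubj", BMOD = "nn", CC = "cc", V = "conj",
      PREP = "prep", L = "pobj", LMOD = "nn", ALIAS = "appos",
      WH = "rel", DNOUN = "npadvmod", DVERB = "rcmod", FILLER = "advmod",
      PUNCT = "punct", "dep")
  }
  tibble(idx = seq_len(n), surface = template$surface,
         stem = crude_stem(template$surface), pos = template$pos,
         chunk = chunk_of(template$pos),
         entity = template$entity %||% rep("O", n),
         head = head, dep = dep)
}

#' Generate a synthetic standoff corpus
#'
#' Writes `doc_id.{txt,a1,a2,parse}` quadruples whose gold `Lives_In`
#' relations are determined by the planted cue structure (see
#' [synth_config()]). Byte-identical across runs with the same config.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Tibble with one row per document: `doc_id` and the four file
#'   paths, invisibly returned alongside generation; zero-row for
#'   `n_docs = 0`.
#' @export
generate_corpus <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  out <- vector("list", cfg$n_docs)
  for (d in seq_len(cfg$n_docs)) {
    doc_id <- sprintf("synth-%03d", d)
    plans <- lapply(seq_len(cfg$sentences_per_doc),
                    function(i) plan_sentence(cfg))
    graphs <- lapply(plans, function(p) generate_parses(p$template))

    # text and character offsets: tokens joined by single spaces, one
    # sentence per line
    offset <- 0L
    ent_rows <- list()
    relations <- list()
    equiv <- list()
    tcount <- 0L
    sent_mention_ids <- vector("list", length(plans))
    lines <- character(length(plans))
    for (s in seq_along(plans)) {
      g <- graphs[[s]]
      starts <- offset + c(0L, cumsum(nchar(g$surface) + 1L))[seq_len(nrow(g))]
      ends <- starts + nchar(g$surface)
      lines[[s]] <- paste(g$surface, collapse = " ")
      plan <- plans[[s]]
      ids <- character(length(plan$mentions))
      for (m in seq_along(plan$mentions)) {
        toks <- which(!is.na(plan$template$mention) &
                        plan$template$mention == m)
        tcount <- tcount + 1L
        ids[[m]] <- paste0("T", tcount)
        ent_rows[[tcount]] <- tibble(
          id = ids[[m]], type = plan$mentions[[m]]$type,
          start = starts[[min(toks)]], end = ends[[max(toks)]],
          spans = list(cbind(starts[[min(toks)]], ends[[max(toks)]])),
          surface = paste(g$surface[toks], collapse = " "))
      }
      sent_mention_ids[[s]] <- ids
      b_ids <- ids[vapply(plan$mentions, function(m)
        m$type == "Bacteria", logical(1))]
      for (j in seq_along(plan$slot_positive)) {
        loc_id <- ids[[plan$slot_mention[[j]]]]
        alias_id <- if (!is.na(plan$slot_alias[[j]]))
          ids[[plan$slot_alias[[j]]]] else NA_character_
        if (!is.na(alias_id)) {
          equiv[[length(equiv) + 1L]] <- c(loc_id, alias_id)
        }
        if (plan$slot_positive[[j]]) {
          for (b in b_ids) {
            target <- if (!is.na(alias_id) && runif(1) < 0.5) alias_id
                      else loc_id
            relations[[length(relations) + 1L]] <-
              tibble(id = paste0("R", length(relations) + 1L),
                     type = "Lives_In", bacterium = b, location = target)
          }
        }
      }
      offset <- offset + nchar(lines[[s]]) + 1L   # newline separator
    }

    # occasional cross-sentence gold relation (unreachable by design)
    if (length(plans) >= 2 && runif(1) < cfg$cross_rate) {
      types <- lapply(plans, function(p)
        vapply(p$mentions, `[[`, character(1), "type"))
      bs <- which(vapply(types, function(tt) any(tt == "Bacteria"),
                         logical(1)))
      ls <- which(vapply(types, function(tt) any(tt != "Bacteria"),
                         logical(1)))
      pick <- expand.grid(b = bs, l = ls)
      pick <- pick[pick$b != pick$l, , drop = FALSE]
      if (nrow(pick)) {
        row <- pick[sample.int(nrow(pick), 1L), ]
        b_id <- sent_mention_ids[[row$b]][
          which(types[[row$b]] == "Bacteria")[1]]
        l_id <- sent_mention_ids[[row$l]][
          which(types[[row$l]] != "Bacteria")[1]]
        relations[[length(relations) + 1L]] <-
          tibble(id = paste0("R", length(relations) + 1L),
                 type = "Lives_In", bacterium = b_id, location = l_id)
      }
    }

    entities <- bind_rows(ent_rows)
    rels <- if (length(relations)) bind_rows(relations) else
      empty_relations()
    doc <- new_document(doc_id, paste(lines, collapse = "\n"),
                        entities, rels, equiv)
    write_document(doc, dir)
    write_parses(graphs, file.path(dir, paste0(doc_id, ".parse")))
    out[[d]] <- tibble(doc_id = doc_id,
                       txt = file.path(dir, paste0(doc_id, ".txt")),
                       a1 = file.path(dir, paste0(doc_id, ".a1")),
                       a2 = file.path(dir, paste0(doc_id, ".a2")),
                       parse = file.path(dir, paste0(doc_id, ".parse")))
  }
  if (cfg$n_docs == 0) {
    return(tibble(doc_id = character(), txt = character(), a1 = character(),
                  a2 = character(), parse = character()))
  }
  bind_rows(out)
}
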