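# BioNLP-ST standoff I/O: .txt / .a1 / .a2 triples.
#
# Offsets are 0-based, half-open character intervals into the document text.
# .a1 carries entities ("Tn<TAB>Type start end[;start end]*<TAB>surface"),
# .a2 carries Lives_In relations ("Rn<TAB>Lives_In Bacterium:Tx Location:Ty")
# and equivalence lines ("*<TAB>Equiv Tx Ty ...").

ENTITY_TYPES <- c("Bacteria", "Habitat", "Geographical")
LOCATION_TYPES <- c("Habitat", "Geographical")

#' Read a BioNLP-ST standoff document
#'
#' Reads the text/entity/relation annotation triple used by the Bacteria
#' Biotope task. Entities are Bacteria, Habitat or Geographical mentions with
#' (possibly discontinuous) character spans; relations are binary `Lives_In`
#' events between a Bacterium and a location; `Equiv` lines declare entity
#' mentions interchangeable for scoring and are closed transitively at load
#' time.
#'
#' @param txt_path Path to the `.txt` file (UTF-8 document text).
#' @param a1_path Path to the `.a1` entity file.
#' @param a2_path Optional path to the `.a2` relation file; `NULL` or a
#'   missing file yields a document with no relations and no Equiv groups.
#' @param doc_id Document identifier; defaults to the `.txt` basename.
#'
#' @return A `bb_document`: a list with `doc_id`, `text`, `entities` (tibble
#'   with columns `id`, `type`, `start`, `end`, `spans` list-column of
#'   two-column matrices, `surface`), `relations` (tibble `id`, `type`,
#'   `bacterium`, `location`) and `equiv` (list of character vectors of
#'   entity ids, disjoint after transitive closure).
#' @export
#' @examples
#' d <- tempfile(); writeLines("B. subtilis lives in soil.", paste0(d, ".txt"))
#' writeLines(c("T1\tBacteria 0 11\tB. subtilis", "T2\tHabitat 21 25\tsoil"),
#'            paste0(d, ".a1"))
#' doc <- read_document(paste0(d, ".txt"), paste0(d, ".a1"))
#' doc$entities
read_document <- function(txt_path, a1_path, a2_path = NULL,
                          doc_id = sub("\\.txt$", "", basename(txt_path))) {
  if (!file.exists(txt_path)) abort(paste0("text file not found: ", txt_path))
  if (!file.exists(a1_path)) abort(paste0("a1 file not found: ", a1_path))
  text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  entities <- parse_a1(a1_path, text)
  if (!is.null(a2_path) && file.exists(a2_path)) {
    a2 <- parse_a2(a2_path, entities)
  } else {
    a2 <- list(relations = empty_relations(), equiv = list())
  }
  new_document(doc_id, text, entities, a2$relations, a2$equiv)
}

new_document <- function(doc_id, text, entities, relations, equiv) {
  if (anyDuplicated(entities$id)) {
    abort(paste0("duplicate entity ids in document ", doc_id))
  }
  structure(
    list(doc_id = doc_id, text = text, entities = entities,
         relations = relations, equiv = close_equiv(equiv)),
    class = "bb_document"
  )
}

#' @export
print.bb_document <- function(x, ...) {
  cat("<bb_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$entities), " entities, ", nrow(x$relations), " relations, ",
      length(x$equiv), " equiv groups\n", sep = "")
  invisible(x)
}

empty_relations <- function() {
  tibble(id = character(), type = character(),
         bacterium = character(), location = character())
}

parse_a1 <- function(a1_path, text) {
  lines <- readLines(a1_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !grepl("^T[0-9]+$", parts[[1]])) {
      abort(sprintf("malformed a1 line %d in %s: %s", i, a1_path, lines[[i]]))
    }
    ann <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
    type <- ann[[1]]
    if (!type %in% ENTITY_TYPES) {
      warn(sprintf("skipping entity of unused type '%s' (%s line %d)",
                   type, basename(a1_path), i))
      rows[[i]] <- NULL
      next
    }
    spans <- parse_spans(paste(ann[-1], collapse = " "), a1_path, i)
    if (any(spans[, 1] < 0) || any(spans[, 2] > nchar(text)) ||
        any(spans[, 1] >= spans[, 2])) {
      abort(sprintf("span out of bounds on a1 line %d in %s", i, a1_path))
    }
    surface <- span_surface(text, spans)
    declared <- if (length(parts) >= 3) parts[[3]] else surface
    if (declared != surface) {
      warn(sprintf(
        "surface mismatch for %s in %s: annotation '%s' vs text '%s'",
        parts[[1]], basename(a1_path), declared, surface))
    }
    rows[[i]] <- tibble(id = parts[[1]], type = type,
                        start = spans[1, 1], end = spans[nrow(spans), 2],
                        spans = list(spans), surface = surface)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), type = character(), start = integer(),
                  end = integer(), spans = list(), surface = character())
  }
  out
}

parse_spans <- function(s, path, lineno) {
  pieces <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- matrix(NA_integer_, nrow = length(pieces), ncol = 2)
  for (j in seq_along(pieces)) {
    se <- suppressWarnings(as.integer(strsplit(trimws(pieces[[j]]), " ")[[1]]))
    if (length(se) != 2 || anyNA(se)) {
      abort(sprintf("malformed span on line %d in %s: '%s'", lineno, path, s))
    }
    m[j, ] <- se
  }
  m[order(m[, 1]), , drop = FALSE]
}

# discontinuous spans are joined by a single space, per the standoff standard
span_surface <- function(text, spans) {
  paste(vapply(seq_len(nrow(spans)), function(j) {
    substr(text, spans[j, 1] + 1L, spans[j, 2])
  }, character(1)), collapse = " ")
}

parse_a2 <- function(a2_path, entities) {
  lines <- readLines(a2_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  relations <- list()
  equiv <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    tag <- parts[[1]]
    if (tag == "*") {
      ann <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
      if (ann[[1]] != "Equiv" || length(ann) < 3) {
        abort(sprintf("malformed Equiv line %d in %s", i, a2_path))
      }
      members <- ann[-1]
      check_refs(members, entities, a2_path, i)
      equiv[[length(equiv) + 1L]] <- members
    } else if (grepl("^R[0-9]+$", tag)) {
      ann <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
      if (ann[[1]] != "Lives_In" || length(ann) != 3) {
        abort(sprintf("malformed relation line %d in %s: %s",
                      i, a2_path, lines[[i]]))
      }
      args <- setNames(
        sub("^[^:]+:", "", ann[2:3]),
        sub(":.*$", "", ann[2:3])
      )
      if (!all(c("Bacterium", "Location") %in% names(args))) {
        abort(sprintf("relation line %d in %s lacks Bacterium/Location roles",
                      i, a2_path))
      }
      check_refs(unname(args), entities, a2_path, i)
      btype <- entities$type[entities$id == args[["Bacterium"]]]
      ltype <- entities$type[entities$id == args[["Location"]]]
      if (btype != "Bacteria" || !ltype %in% LOCATION_TYPES) {
        abort(sprintf(
          "relation line %d in %s has argument types (%s, %s); expected (Bacteria, Habitat|Geographical)",
          i, a2_path, btype, ltype))
      }
      relations[[length(relations) + 1L]] <-
        tibble(id = tag, type = "Lives_In",
               bacterium = args[["Bacterium"]], location = args[["Location"]])
    } else {
      warn(sprintf("skipping unused annotation line %d in %s ('%s')",
                   i, basename(a2_path), tag))
    }
  }
  list(relations = if (length(relations)) bind_rows(relations)
                   else empty_relations(),
       equiv = equiv)
}

check_refs <- function(ids, entities, path, lineno) {
  missing <- setdiff(ids, entities$id)
  if (length(missing)) {
    abort(sprintf("line %d in %s references unknown entities: %s",
                  lineno, path, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# transitive closure of equivalence declarations; returns disjoint groups
close_equiv <- function(groups) {
  if (!length(groups)) return(list())
  repeat {
    merged <- FALSE
    out <- list()
    for (g in groups) {
      hit <- which(vapply(out, function(o) length(intersect(o, g)) > 0,
                          logical(1)))
      if (length(hit)) {
        out[[hit[[1]]]] <- union(out[[hit[[1]]]], g)
        merged <- TRUE
      } else {
        out[[length(out) + 1L]] <- g
      }
    }
    groups <- lapply(out, function(g) sort(unique(g)))
    if (!merged) break
  }
  groups
}

# entity id -> canonical representative under Equiv (identity outside groups)
equiv_canon <- function(equiv) {
  canon <- character(0)
  for (g in equiv) canon[g] <- g[[1]]
  function(id) {
    hit <- canon[id]
    ifelse(is.na(hit), id, hit)
  }
}

#' Serialize Lives_In relations to standoff a2 text
#'
#' @param relations Tibble with columns `bacterium` and `location` holding
#'   entity ids; ids `R1..Rn` are assigned in row order.
#' @param entities Optional entity tibble (as in [read_document()]); when
#'   supplied, argument types are validated.
#' @return A single string: one `Lives_In` relation line per row,
#'   empty string for zero rows.
#' @export
write_a2 <- function(relations, entities = NULL) {
  if (is.null(relations) || nrow(relations) == 0) return("")
  if (!is.null(entities)) {
    btype <- entities$type[match(relations$bacterium, entities$id)]
    ltype <- entities$type[match(relations$location, entities$id)]
    if (anyNA(btype) || anyNA(ltype)) {
      abort("relation references an entity id absent from the entity table")
    }
    if (any(btype != "Bacteria")) {
      abort("first (Bacterium) argument of a relation is not a Bacteria entity")
    }
    if (any(!ltype %in% LOCATION_TYPES)) {
      abort("second (Location) argument is not a Habitat or Geographical entity")
    }
  }
  paste(sprintf("R%d\tLives_In Bacterium:%s Location:%s",
                seq_len(nrow(relations)),
                relations$bacterium, relations$location),
        collapse = "\n")
}

#' Write a document's annotations back to standoff files
#'
#' @param doc A `bb_document`.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_document <- function(doc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, doc$doc_id)
  writeLines(doc$text, paste0(base, ".txt"), useBytes = TRUE)
  a1 <- vapply(seq_len(nrow(doc$entities)), function(i) {
    sp <- doc$entities$spans[[i]]
    loc <- paste(apply(sp, 1, function(r) paste(r[1], r[2])), collapse = ";")
    sprintf("%s\t%s %s\t%s", doc$entities$id[[i]], doc$entities$type[[i]],
            loc, doc$entities$surface[[i]])
  }, character(1))
  writeLines(a1, paste0(base, ".a1"), useBytes = TRUE)
  a2_lines <- character(0)
  if (nrow(doc$relations)) {
    a2_lines <- strsplit(write_a2(doc$relations, doc$entities), "\n")[[1]]
  }
  if (length(doc$equiv)) {
    a2_lines <- c(a2_lines, vapply(doc$equiv, function(g) {
      paste0("*\tEquiv ", paste(g, collapse = " "))
    }, character(1)))
  }
  writeLines(a2_lines, paste0(base, ".a2"), useBytes = TRUE)
  invisible(paste0(base, c(".txt", ".a1", ".a2")))
}

#' Read every standoff document in a directory
#'
#' @param dir Directory containing `doc_id.{txt,a1,a2}` triples.
#' @return A named list of `bb_document` objects.
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) abort(paste0("no .txt documents found in ", dir))
  docs <- lapply(txts, function(p) {
    base <- sub("\\.txt$", "", p)
    read_document(p, paste0(base, ".a1"), paste0(base, ".a2"))
  })
  setNames(docs, vapply(docs, `[[`, character(1), "doc_id"))
}
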