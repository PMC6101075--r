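Package: biotoper
Title: Attention-Based Bidirectional GRU Extraction of Bacteria-Biotope
    Lives_In Relations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts Lives_In relations between Bacteria and Habitat or
    Geographical entities from BioNLP-ST standoff annotated documents.
    Builds intra-sentence bacterium-location candidate pairs, linearizes
    the shortest dependency path between the two entities (optionally
    extended by the nearest governing verb), encodes tokens with word,
    part-of-speech and signed-distance embeddings, and classifies each
    pair with a bidirectional gated recurrent unit network pooled by a
    learned attention vector. Includes a domain-oriented skip-gram
    embedding trainer over stems, chunks, entity tags and part-of-speech
    tags, the matching-similarity precision/recall/F scorer with
    equivalent-entity handling, and a synthetic standoff-corpus generator
    with planted dependency-path signal so the full pipeline can be
    trained and verified without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
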