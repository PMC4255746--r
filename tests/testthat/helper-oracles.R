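# Independent oracles and random-case generators used across the suite.
# Oracles deliberately avoid the implementation's data paths: the matcher
# oracle enumerates every token window against the raw entry table, the
# LCA oracle intersects ancestor sets, and the filter oracle evaluates a
# per-sentence truth table through R's own parser.

word_pool <- c("the", "cells", "were", "lysed", "and", "analyzed", "under",
               "native", "conditions", "before", "imaging", "with", "buffer")

# ---- random BioC collections -------------------------------------------

random_annotation_set <- function(text, base, n, prefix) {
  toks <- tokenize(text, base)
  if (!nrow(toks) || n == 0L) return(list())
  starts <- sort(sample(nrow(toks), min(n, nrow(toks))))
  anns <- list()
  last_end <- -1L
  for (i in starts) {
    if (toks$offset[i] < last_end) next  # keep spans non-overlapping
    len <- sample(1:2, 1L)
    j <- min(i + len - 1L, nrow(toks))
    span_off <- toks$offset[i]
    span_len <- toks$offset[j] + toks$length[j] - span_off
    covered <- substr(text, span_off - base + 1L, span_off - base + span_len)
    anns[[length(anns) + 1L]] <- bioc_annotation(
      id = sprintf("%s%d", prefix, length(anns) + 1L),
      text = covered, offset = span_off, length = span_len,
      infons = list(type = sample(c("protein", "chemical", "disease"), 1L),
                    concept_id = sprintf("C:%02d", sample(20L, 1L)),
                    preferred_name = covered, score = "1"))
    last_end <- span_off + span_len
  }
  anns
}

random_sentence_text <- function() {
  paste(c(sample(word_pool, sample(4:8, 1L), replace = TRUE), "."), collapse = " ")
}

random_collection <- function(seed) {
  set.seed(seed)
  docs <- lapply(seq_len(sample(1:3, 1L)), function(d) {
    n_sent <- sample(1:4, 1L)
    offset <- sample(0:3, 1L)
    sentences <- list()
    for (k in seq_len(n_sent)) {
      text <- random_sentence_text()
      sentences[[k]] <- bioc_sentence(offset = offset, text = text)
      offset <- offset + nchar(text) + 1L
    }
    ptext <- paste(vapply(sentences, function(s) s$text, character(1)),
                   collapse = " ")
    anns <- list()
    k <- 0L
    for (s in seq_along(sentences)) {
      new <- random_annotation_set(sentences[[s]]$text, sentences[[s]]$offset,
                                   sample(0:2, 1L), sprintf("T%d_", s))
      sentences[[s]]$annotations <- new
      anns <- c(anns, new)
    }
    relations <- list()
    if (length(anns) >= 2L && sample(c(TRUE, FALSE), 1L)) {
      ij <- sample(length(anns), 2L)
      relations <- list(bioc_relation(
        "R1", nodes = data.frame(refid = c(anns[[ij[1L]]]$id, anns[[ij[2L]]]$id),
                                 role = c("arg1", "arg2")),
        infons = list(type = "interaction", score = "0.5")))
    }
    p <- bioc_passage(offset = sentences[[1L]]$offset, text = ptext,
                      infons = list(type = "abstract"),
                      sentences = sentences, relations = relations)
    bioc_document(sprintf("doc%d", d), passages = list(p),
                  infons = list(origin = "random"))
  })
  renumbered <- lapply(docs, renumber_sentences_helper)
  bioc_collection(documents = renumbered, source = "random-fixture",
                  infons = list(seed = as.character(seed)))
}

renumber_sentences_helper <- function(doc) {
  k <- 0L
  for (i in seq_along(doc$passages)) {
    ss <- doc$passages[[i]]$sentences
    if (is.null(ss)) next
    for (j in seq_along(ss)) {
      ss[[j]]$index <- k
      k <- k + 1L
    }
    doc$passages[[i]]$sentences <- ss
  }
  doc
}

# ---- matcher oracle -----------------------------------------------------

oracle_annotate <- function(text, base_offset, entries, types,
                            max_span = 8L, enforce_case = TRUE) {
  toks <- tokenize(text, 0L)
  n <- nrow(toks)
  entry_keys <- normalize_surface(entries$surface)
  window_hits <- function(i, len) {
    j <- i + len - 1L
    span_len <- toks$offset[j] + toks$length[j] - toks$offset[i]
    window <- substr(text, toks$offset[i] + 1L, toks$offset[i] + span_len)
    rows <- which(entry_keys == normalize_surface(window))
    if (enforce_case) {
      rows <- rows[!entries$case_sensitive[rows] | entries$surface[rows] == window]
    }
    list(rows = rows, window = window, span_len = span_len)
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    advanced <- FALSE
    for (len in rev(seq_len(min(max_span, n - i + 1L)))) {
      hit <- window_hits(i, len)
      if (!length(hit$rows)) next
      for (r in hit$rows[entries$entity_type[hit$rows] %in% types]) {
        out[[length(out) + 1L]] <- data.frame(
          offset = base_offset + toks$offset[i], length = hit$span_len,
          concept_id = entries$concept_id[r], type = entries$entity_type[r],
          stringsAsFactors = FALSE)
      }
      i <- i + len
      advanced <- TRUE
      break
    }
    if (!advanced) i <- i + 1L
  }
  if (!length(out)) {
    data.frame(offset = integer(0), length = integer(0),
               concept_id = character(0), type = character(0))
  } else {
    do.call(rbind, out)
  }
}

annotation_key_set <- function(anns) {
  sort(vapply(anns, function(a)
    paste(ann_offset_helper(a), a$locations$length[1L],
          infon(a, "concept_id"), infon(a, "type")), character(1)))
}

ann_offset_helper <- function(a) a$locations$offset[1L]

random_lexicon_table <- function(seed) {
  set.seed(seed)
  n <- sample(5:12, 1L)
  surfaces <- unique(c(
    replicate(n, paste0(paste(sample(letters, sample(3:8, 1L), replace = TRUE),
                              collapse = ""))),
    sample(word_pool, 2L),            # collide with running text
    "IL-2", "folD"))
  tibble::tibble(
    surface = surfaces,
    concept_id = sprintf("K:%03d", seq_along(surfaces)),
    entity_type = sample(c("protein", "chemical", "gene"), length(surfaces),
                         replace = TRUE),
    preferred_name = surfaces,
    source_db = "synthetic")
}

# ---- LCA oracle ---------------------------------------------------------

oracle_lca <- function(nodes, a, b) {
  anc <- function(i) {
    chain <- i
    while (nodes$head[i] != 0L) {
      i <- nodes$head[i]
      chain <- c(chain, i)
    }
    chain
  }
  depth <- function(i) length(anc(i))
  common <- intersect(anc(a), anc(b))
  common[which.max(vapply(common, depth, integer(1)))]
}

random_tree_nodes <- function(n, labels = c("subj", "obj", "pobj", "modpp",
                                            "conj", "det", "nn")) {
  perm <- sample(n)
  head <- integer(n)
  head[perm[1L]] <- 0L
  for (k in seq_len(n)[-1L]) {
    head[perm[k]] <- perm[sample.int(k - 1L, 1L)]
  }
  tibble::tibble(
    index = seq_len(n),
    surface = sprintf("w%d", seq_len(n)),
    lemma = sprintf("l%d", seq_len(n)),
    pos = "NN", head = head,
    label = ifelse(head == 0L, "root", sample(labels, n, replace = TRUE)))
}

as_tree <- function(nodes, sentence_index = 0L) {
  structure(list(sentence_index = as.integer(sentence_index), nodes = nodes,
                 alignment = tibble::tibble(offset = integer(nrow(nodes)),
                                            length = integer(nrow(nodes)))),
            class = "dependency_tree")
}

# ---- filter oracle ------------------------------------------------------

random_filter_ast <- function(depth, types, concepts, terms) {
  if (depth <= 0L || runif(1) < 0.4) {
    atom <- sample(c("has_type", "has_concept", "has_term"), 1L)
    arg <- switch(atom,
                  has_type = sample(types, 1L),
                  has_concept = sample(concepts, 1L),
                  has_term = sample(terms, 1L))
    return(sprintf("%s(%s)", atom, arg))
  }
  op <- sample(c("AND", "OR", "NOT"), 1L)
  if (op == "NOT") {
    sprintf("NOT (%s)", random_filter_ast(depth - 1L, types, concepts, terms))
  } else {
    sprintf("(%s) %s (%s)",
            random_filter_ast(depth - 1L, types, concepts, terms), op,
            random_filter_ast(depth - 1L, types, concepts, terms))
  }
}

# evaluates a filter AST for one sentence via R's own parser, from atom
# truths computed with straight-line code
oracle_filter_sentence <- function(ast, sentence) {
  anns <- sentence$annotations
  types <- vapply(anns, function(a) infon(a, "type", ""), character(1))
  concepts <- vapply(anns, function(a) infon(a, "concept_id", ""), character(1))
  terms <- normalize_surface(vapply(anns, function(a) a$text, character(1)))
  to_r <- function(node) {
    if (node$op == "atom") {
      val <- switch(node$atom,
                    has_type = node$atom_args[[1L]] %in% types,
                    has_concept = node$atom_args[[1L]] %in% concepts,
                    has_term = normalize_surface(node$atom_args[[1L]]) %in% terms,
                    has_relation = FALSE)
      if (val) "TRUE" else "FALSE"
    } else if (node$op == "not") {
      sprintf("(!%s)", to_r(node$args[[1L]]))
    } else {
      sprintf("(%s %s %s)", to_r(node$args[[1L]]),
              if (node$op == "and") "&&" else "||", to_r(node$args[[2L]]))
    }
  }
  eval(parse(text = to_r(ast)))
}

# ---- tiny worked-example fixtures --------------------------------------

figure1_document <- function() {
  text <- "Tim18p coimmunoprecipitated with Tim12p ."
  doc <- bioc_document("pmid1", passages = list(
    bioc_passage(0L, text = text,
                 sentences = list(bioc_sentence(0L, text, index = 0L)))))
  doc
}

figure1_conll <- function() {
  paste(
    "1\tTim18p\ttim18p\tNN\t2\tsubj",
    "2\tcoimmunoprecipitated\tcoimmunoprecipitate\tVBD\t0\troot",
    "3\twith\twith\tIN\t2\tmodpp",
    "4\tTim12p\ttim12p\tNN\t2\tpobj",
    "5\t.\t.\tPUNCT\t2\tpunct",
    sep = "\n")
}

tiny_protein_lexicon <- function() {
  lexicon(tibble::tibble(
    surface = c("Tim18p", "Tim12p"),
    concept_id = c("P1", "P2"),
    entity_type = "protein",
    preferred_name = c("TIM18", "TIM12"),
    source_db = "uniprot-synthetic"),
    stoplist = character(0))
}

mk_rel_ann <- function(id, text, offset, type, concept) {
  bioc_annotation(id, text, offset = offset, length = nchar(text),
                  infons = list(type = type, concept_id = concept,
                                preferred_name = text, score = "1"))
}
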