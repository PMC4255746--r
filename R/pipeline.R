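#' Pipeline configuration
#'
#' Collects the tunable parameters of the mining pipeline in one place.
#'
#' @param max_span maximum dictionary match length in tokens.
#' @param gamma weight of uniquely-resolving gene/protein mentions in
#'   focus-organism ranking.
#' @param theta minimum positive fraction for a `yes` pattern decision.
#' @param beta backoff syntactic factor for unseen paths / unparsed
#'   sentences.
#' @param term_weights exponents of the three term-confidence factors.
#' @param interaction_weights named exponents (`term`, `syntax`, `concept`)
#'   of the interaction confidence.
#' @param bg_table named background-frequency vector (see
#'   [load_background()]); `NULL` means no background penalty.
#' @param segment split unsegmented passages into sentences before
#'   annotation.
#' @param allow_self keep candidate pairs with identical concept ids.
#' @param max_chars request payload limit (total characters of document
#'   text) for the service layer.
#' @return a list of class `mine_config`.
#' @export
mine_config <- function(max_span = 8L, gamma = 0.5, theta = 0.5, beta = 0.25,
                        term_weights = c(1, 1, 1),
                        interaction_weights = c(term = 1, syntax = 1, concept = 1),
                        bg_table = NULL, segment = TRUE, allow_self = FALSE,
                        max_chars = 1e6) {
  structure(list(max_span = as.integer(max_span), gamma = gamma, theta = theta,
                 beta = beta, term_weights = term_weights,
                 interaction_weights = interaction_weights, bg_table = bg_table,
                 segment = segment, allow_self = allow_self,
                 max_chars = max_chars),
            class = "mine_config")
}

#' Segment a passage into sentences
#'
#' Deterministic splitting at `.`, `!` or `?` followed by whitespace (or end
#' of text); offsets are preserved so downstream annotation anchors remain
#' valid. Passages that already carry sentences are returned unchanged —
#' input segmentation is always preserved.
#'
#' @param p a `bioc_passage`.
#' @return the passage with a `sentences` list.
#' @export
segment_passage <- function(p) {
  if (!is.null(p$sentences) || is.null(p$text) || !nchar(p$text)) return(p)
  text <- p$text
  ends <- stringi::stri_locate_all_regex(text, "[.!?](?=\\s|$)")[[1L]][, 1L]
  ends <- ends[!is.na(ends)]
  if (!length(ends) || ends[length(ends)] < nchar(text)) ends <- c(ends, nchar(text))
  start <- 1L
  sentences <- list()
  for (e in ends) {
    chunk <- substr(text, start, e)
    lead <- nchar(chunk) - nchar(sub("^\\s+", "", chunk))
    chunk <- trimws(chunk)
    if (nchar(chunk)) {
      sentences[[length(sentences) + 1L]] <- bioc_sentence(
        offset = p$offset + start - 1L + lead, text = chunk)
    }
    start <- as.integer(e + 1L)
  }
  p$sentences <- sentences
  p
}

assign_annotation_ids <- function(doc) {
  k <- 0L
  doc <- map_annotation_units(doc, function(anns, text, offset) {
    lapply(anns, function(a) {
      k <<- k + 1L
      a$id <- sprintf("T%d", k)
      a
    })
  })
  doc
}

#' Run the full mining pipeline over a collection
#'
#' For every document: sentence segmentation (when needed), dictionary
#' annotation, the disambiguation sequence (case filter, type rules,
#' focus-organism ranking, identifier pruning), term-confidence scoring,
#' candidate-interaction generation by sentence co-occurrence, syntactic
#' scoring against a learned pattern table, interaction-confidence
#' combination and ranking. Annotations and relations are attached to the
#' returned collection with their scores and ranks as infons.
#'
#' @param collection input `bioc_collection`.
#' @param lex a [lexicon()].
#' @param entity_types entity types to emit (default all).
#' @param relation_type_pairs list of unordered type pairs to pair up, e.g.
#'   `list(c("protein", "protein"))`; empty/`NULL` disables relation
#'   extraction.
#' @param parses optional named list (document id) of `dependency_tree`
#'   lists.
#' @param patterns optional pattern table from [learn_patterns()].
#' @param rules optional [type_rules()] table.
#' @param gold optional gold table; enables concept weighting.
#' @param config a [mine_config()].
#' @return list with `collection` (enriched), `entities` (ranked tibble),
#'   `interactions` (ranked tibble) and `organisms` (named list of per-
#'   document focus-organism tibbles).
#' @export
mine_collection <- function(collection, lex, entity_types = NULL,
                            relation_type_pairs = NULL, parses = NULL,
                            patterns = NULL, rules = NULL, gold = NULL,
                            config = mine_config()) {
  entity_rows <- list()
  pair_rows <- list()
  organisms <- list()
  docs <- collection$documents
  for (di in seq_along(docs)) {
    doc <- docs[[di]]
    if (config$segment) {
      doc$passages <- lapply(doc$passages, segment_passage)
      doc <- renumber_sentences(doc)
    }
    for (pi in seq_along(doc$passages)) {
      p <- doc$passages[[pi]]
      if (!is.null(p$sentences)) {
        for (si in seq_along(p$sentences)) {
          s <- p$sentences[[si]]
          anns <- annotate_text(s$text, s$offset, lex, entity_types,
                                config$max_span)
          anns <- lapply(anns, set_infon, "sentence_index", s$index)
          doc$passages[[pi]]$sentences[[si]]$annotations <- anns
        }
      } else if (!is.null(p$text)) {
        doc$passages[[pi]]$annotations <-
          annotate_text(p$text, p$offset, lex, entity_types, config$max_span)
      }
    }
    doc <- assign_annotation_ids(doc)
    dis <- disambiguate_document(doc, rules = rules, gamma = config$gamma)
    doc <- dis$document
    organisms[[doc$id]] <- dis$organisms

    term_tab <- score_terms(doc, config)
    doc <- set_annotation_scores(doc, term_tab)
    if (nrow(term_tab)) {
      term_tab$document_id <- doc$id
      entity_rows[[length(entity_rows) + 1L]] <- term_tab
    }

    if (length(relation_type_pairs)) {
      trees <- if (!is.null(parses)) parses[[doc$id]] else NULL
      for (s in document_sentences(doc)) {
        pairs <- candidate_pairs(s$annotations, s$index, relation_type_pairs,
                                 allow_self = config$allow_self)
        if (!nrow(pairs)) next
        pairs$document_id <- doc$id
        pairs$syntactic <- NA_real_
        if (!is.null(trees) && !is.null(patterns)) {
          tree <- tree_for_sentence(trees, s$index)
          if (!is.null(tree)) {
            for (r in seq_len(nrow(pairs))) {
              ha <- entity_head(tree, pairs$offset_a[r], pairs$length_a[r])
              hb <- entity_head(tree, pairs$offset_b[r], pairs$length_b[r])
              if (is.na(ha) || is.na(hb) || ha == hb) next
              path <- extract_path(tree, ha, hb)
              pairs$syntactic[r] <- score_syntax(path, patterns, config$beta)$score
            }
          }
        }
        pair_rows[[length(pair_rows) + 1L]] <- pairs
      }
    }
    docs[[di]] <- doc
  }

  entities <- rank_entities(entity_rows)
  all_pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  interactions <- score_interactions(all_pairs, entities, gold, config)
  docs <- attach_relations(docs, interactions)
  out_coll <- bioc_collection(documents = docs, source = collection$source,
                              date = collection$date, key = collection$key,
                              infons = collection$infons)
  list(collection = out_coll, entities = entities,
       interactions = interactions, organisms = organisms)
}

# per-document term confidence factors for each annotation
score_terms <- function(doc, config) {
  anns <- document_annotations(doc)
  if (!length(anns)) {
    return(tibble::tibble(
      id = character(0), type = character(0), concept_id = character(0),
      preferred_name = character(0), text = character(0),
      first_offset = integer(0), sentence_index = integer(0),
      rel_freq = numeric(0), bg_freq = numeric(0), context_factor = numeric(0),
      term_confidence = numeric(0)))
  }
  cid <- vapply(anns, ann_concept, character(1))
  n_total <- length(anns)
  counts <- table(cid)
  keys <- normalize_surface(vapply(anns, function(a) a$text, character(1)))
  bg <- if (is.null(config$bg_table)) rep(0, n_total) else {
    b <- unname(config$bg_table[keys]); b[is.na(b)] <- 0; b
  }
  ctx <- vapply(anns, function(a)
    if (identical(infon(a, "ambiguous"), "true")) 0.5 else 1, numeric(1))
  rel <- as.numeric(counts[cid]) / n_total
  tibble::tibble(
    id = vapply(anns, function(a) a$id, character(1)),
    type = vapply(anns, ann_type, character(1)),
    concept_id = cid,
    preferred_name = vapply(anns, function(a)
      infon(a, "preferred_name", NA_character_), character(1)),
    text = vapply(anns, function(a) a$text, character(1)),
    first_offset = vapply(anns, ann_offset, integer(1)),
    sentence_index = vapply(anns, function(a)
      as.integer(infon(a, "sentence_index", NA_integer_)), integer(1)),
    rel_freq = rel, bg_freq = bg, context_factor = ctx,
    term_confidence = term_confidence(rel, bg, ctx, config$term_weights))
}

set_annotation_scores <- function(doc, term_tab) {
  lookup <- stats::setNames(term_tab$term_confidence, term_tab$id)
  map_annotation_units(doc, function(anns, text, offset) {
    lapply(anns, function(a) {
      sc <- lookup[[a$id]]
      if (!is.null(sc)) a <- set_infon(a, "score", format_score(sc))
      a
    })
  })
}

rank_entities <- function(entity_rows) {
  empty <- tibble::tibble(
    document_id = character(0), concept_id = character(0), type = character(0),
    preferred_name = character(0), mentions = integer(0),
    first_offset = integer(0), sentence_index = integer(0), score = numeric(0),
    concept_key = character(0), rank = integer(0), curation_state = character(0))
  if (!length(entity_rows)) return(empty)
  tab <- do.call(rbind, entity_rows)
  grp <- paste(tab$document_id, tab$concept_id, tab$type, sep = "\r")
  rows <- lapply(split(seq_len(nrow(tab)), grp), function(ix) {
    sub <- tab[ix, ]
    best <- which.max(sub$term_confidence)
    tibble::tibble(
      document_id = sub$document_id[1L], concept_id = sub$concept_id[1L],
      type = sub$type[1L], preferred_name = sub$preferred_name[best],
      mentions = nrow(sub), first_offset = min(sub$first_offset),
      sentence_index = sub$sentence_index[which.min(sub$first_offset)],
      score = sub$term_confidence[best],
      concept_key = sub$concept_id[1L])
  })
  rank_candidates(do.call(rbind, rows))
}

score_interactions <- function(pairs, entities, gold, config) {
  empty <- tibble::tibble(
    document_id = character(0), sentence_index = integer(0),
    ann_a = character(0), ann_b = character(0), type_a = character(0),
    type_b = character(0), concept_a = character(0), concept_b = character(0),
    pair = character(0), term_a = numeric(0), term_b = numeric(0),
    syntactic = numeric(0), concept_wa = numeric(0), concept_wb = numeric(0),
    first_offset = integer(0), concept_key = character(0), score = numeric(0),
    rank = integer(0), curation_state = character(0))
  if (is.null(pairs) || !nrow(pairs)) return(empty)
  ent_key <- paste(entities$document_id, entities$concept_id, entities$type, sep = "\r")
  ent_score <- stats::setNames(entities$score, ent_key)
  pairs$term_a <- unname(ent_score[paste(pairs$document_id, pairs$concept_a,
                                         pairs$type_a, sep = "\r")])
  pairs$term_b <- unname(ent_score[paste(pairs$document_id, pairs$concept_b,
                                         pairs$type_b, sep = "\r")])
  pairs$term_a[is.na(pairs$term_a)] <- 0
  pairs$term_b[is.na(pairs$term_b)] <- 0
  weights <- if (!is.null(gold)) concept_weights(gold, pairs) else NULL
  pairs$concept_wa <- weight_of(weights, pairs$concept_a)
  pairs$concept_wb <- weight_of(weights, pairs$concept_b)
  pairs$pair <- unordered_pair(pairs$concept_a, pairs$concept_b)
  pairs$first_offset <- pmin(pairs$offset_a, pairs$offset_b)
  pairs$concept_key <- pairs$pair
  pairs$score <- interaction_confidence(
    pairs$term_a, pairs$term_b, pairs$syntactic, pairs$concept_wa,
    pairs$concept_wb, weights = config$interaction_weights, beta = config$beta)
  rank_candidates(pairs)
}

attach_relations <- function(docs, interactions) {
  if (!nrow(interactions)) return(docs)
  for (di in seq_along(docs)) {
    doc <- docs[[di]]
    sub <- interactions[interactions$document_id == doc$id, ]
    if (!nrow(sub)) next
    k <- 0L
    sent_passage <- sentence_passage_map(doc)
    for (r in seq_len(nrow(sub))) {
      k <- k + 1L
      rel <- bioc_relation(
        id = sprintf("R%d", k),
        nodes = data.frame(refid = c(sub$ann_a[r], sub$ann_b[r]),
                           role = c("arg1", "arg2")),
        infons = list(type = "interaction",
                      score = format_score(sub$score[r]),
                      rank = as.character(sub$rank[r])))
      pi <- sent_passage[[as.character(sub$sentence_index[r])]] %||% 1L
      doc$passages[[pi]]$relations <-
        c(doc$passages[[pi]]$relations, list(rel))
    }
    docs[[di]] <- doc
  }
  docs
}

sentence_passage_map <- function(doc) {
  out <- list()
  for (pi in seq_along(doc$passages)) {
    for (s in doc$passages[[pi]]$sentences %||% list()) {
      out[[as.character(s$index)]] <- pi
    }
  }
  out
}
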