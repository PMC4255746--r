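#' Read dependency parses in CoNLL-style tabular format
#'
#' One blank-line-separated block per sentence; six tab-separated columns:
#' token index (1-based), surface, lemma, part-of-speech tag, head index
#' (0 for the root) and dependency edge label. Lines starting with `#` are
#' ignored. Blocks are aligned to the document's sentences by order, and
#' each token surface is located in the sentence text (left to right) to
#' recover document-relative character offsets.
#'
#' @param x path to a CoNLL file, or a character scalar containing its
#'   contents (anything with a newline or tab is treated as contents).
#' @param document the `bioc_document` whose sentences the blocks parse.
#' @return list of `dependency_tree` objects: each has `sentence_index`,
#'   `nodes` (tibble `index`, `surface`, `lemma`, `pos`, `head`, `label`)
#'   and `alignment` (tibble `offset`, `length` per token).
#' @export
load_parses <- function(x, document) {
  if (length(x) == 1L && !grepl("[\n\t]", x) && file.exists(x)) {
    x <- paste(readLines(x, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(x, "\n", fixed = TRUE)[[1L]]
  lines <- lines[!startsWith(lines, "#")]
  blocks <- split_blocks(lines)
  sentences <- document_sentences(document)
  if (length(blocks) != length(sentences)) {
    stop(sprintf("document '%s' has %d sentences but parse input has %d blocks",
                 document$id, length(sentences), length(blocks)), call. = FALSE)
  }
  mapply(function(block, sent) {
    nodes <- parse_conll_block(block, sent$index)
    validate_tree(nodes, sent$index)
    alignment <- align_tokens(nodes$surface, sent)
    structure(list(sentence_index = sent$index, nodes = nodes,
                   alignment = alignment),
              class = "dependency_tree")
  }, blocks, sentences, SIMPLIFY = FALSE)
}

split_blocks <- function(lines) {
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  keep <- split(lines[!blank], grp[!blank])
  unname(keep[lengths(keep) > 0L])
}

parse_conll_block <- function(block, sentence_index) {
  fields <- strsplit(block, "\t", fixed = TRUE)
  if (any(lengths(fields) != 6L)) {
    stop("sentence ", sentence_index,
         ": expected 6 tab-separated columns per token line", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  tibble::tibble(
    index = as.integer(m[, 1L]), surface = m[, 2L], lemma = m[, 3L],
    pos = m[, 4L], head = as.integer(m[, 5L]), label = m[, 6L]
  )
}

validate_tree <- function(nodes, sentence_index) {
  n <- nrow(nodes)
  if (!identical(nodes$index, seq_len(n))) {
    stop("sentence ", sentence_index, ": token indices must be 1..n", call. = FALSE)
  }
  if (sum(nodes$head == 0L) != 1L) {
    stop("sentence ", sentence_index, ": dependency tree must have exactly one root",
         call. = FALSE)
  }
  if (any(nodes$head < 0L | nodes$head > n)) {
    stop("sentence ", sentence_index, ": head index out of range", call. = FALSE)
  }
  # every node must reach the root; a cycle exhausts the step budget
  for (i in seq_len(n)) {
    cur <- i
    for (step in seq_len(n + 1L)) {
      cur <- nodes$head[cur]
      if (cur == 0L) break
      if (step > n) {
        stop("sentence ", sentence_index, ": cyclic head links", call. = FALSE)
      }
    }
  }
  invisible(nodes)
}

align_tokens <- function(surfaces, sent) {
  pos <- 1L  # 1-based cursor within sentence text
  offs <- integer(length(surfaces))
  lens <- integer(length(surfaces))
  for (i in seq_along(surfaces)) {
    hit <- stringi::stri_locate_first_fixed(
      stringi::stri_sub(sent$text, pos), surfaces[i])
    if (is.na(hit[1L, 1L])) {
      stop(sprintf("sentence %d: token '%s' not found in sentence text",
                   sent$index, surfaces[i]), call. = FALSE)
    }
    offs[i] <- sent$offset + pos + hit[1L, 1L] - 2L  # to 0-based document offset
    lens[i] <- nchar(surfaces[i])
    pos <- pos + hit[1L, 2L]
  }
  tibble::tibble(offset = offs, length = lens)
}

tree_root <- function(tree) which(tree$nodes$head == 0L)

ancestor_chain <- function(nodes, i) {
  chain <- i
  while (nodes$head[i] != 0L) {
    i <- nodes$head[i]
    chain <- c(chain, i)
  }
  chain
}

#' Extract the syntactic path pattern connecting two entity heads
#'
#' Computes the lowest common ancestor (LCA) of the two head tokens over the
#' dependency tree's head links; the pattern is the LCA's lemma (the top
#' node) plus the two downward edge-label sequences from the LCA to each
#' head. Sides are assigned by surface order: the left path leads to the
#' entity mentioned first. In the sentence "Tim18p coimmunoprecipitated with
#' Tim12p", with Tim18p attached to the verb as subject and Tim12p as
#' prepositional object, the pattern is top node `coimmunoprecipitate`, left
#' path `[subj]`, right path `[pobj]`.
#'
#' @param tree a `dependency_tree`.
#' @param head_a,head_b 1-based token indices of the two entity heads.
#' @return list with `top_lemma`, `left_path`, `right_path` (character
#'   vectors of edge labels, possibly empty when an entity head is the LCA
#'   itself).
#' @export
extract_path <- function(tree, head_a, head_b) {
  nodes <- tree$nodes
  n <- nrow(nodes)
  if (head_a < 1L || head_a > n || head_b < 1L || head_b > n) {
    stop("entity head index outside the tree", call. = FALSE)
  }
  if (head_a == head_b) {
    stop("degenerate path: both entities share head token ", head_a, call. = FALSE)
  }
  left <- min(head_a, head_b)
  right <- max(head_a, head_b)
  chain_l <- ancestor_chain(nodes, left)
  chain_r <- ancestor_chain(nodes, right)
  lca <- chain_r[match(TRUE, chain_r %in% chain_l)]
  down_path <- function(chain, lca) {
    upto <- chain[seq_len(match(lca, chain) - 1L)]
    rev(nodes$label[upto])
  }
  list(top_lemma = nodes$lemma[lca],
       left_path = down_path(chain_l, lca),
       right_path = down_path(chain_r, lca))
}

#' Locate the syntactic head token of an entity span
#'
#' Tokens of the tree overlapping the span are collected; the entity head is
#' the last of them (head-final compounds dominate English biomedical
#' names), unless one of the overlapped tokens governs the others within the
#' span, in which case the parse wins.
#'
#' @param tree a `dependency_tree` (with alignment).
#' @param offset,length document-relative span of the entity mention.
#' @return 1-based token index, or `NA_integer_` when no token overlaps.
#' @export
entity_head <- function(tree, offset, length) {
  al <- tree$alignment
  inside <- which(al$offset < offset + length & al$offset + al$length > offset)
  if (!length(inside)) return(NA_integer_)
  if (length(inside) == 1L) return(inside)
  governing <- inside[tree$nodes$head[inside] %in% c(0L, setdiff(seq_len(nrow(al)), inside))]
  if (length(governing) == 1L) governing else inside[length(inside)]
}

path_key <- function(path) {
  c(top_lemma = path$top_lemma,
    left_path = paste(path$left_path, collapse = ">"),
    right_path = paste(path$right_path, collapse = ">"))
}

#' Generate candidate interaction pairs by sentence co-occurrence
#'
#' One candidate per unordered pair of distinct annotations in the same
#' sentence whose entity types match one of the requested (unordered) type
#' pairs. Pairs whose two mentions resolve to the same concept identifier
#' are suppressed by default (self-interactions).
#'
#' @param annotations disambiguated annotations of one sentence.
#' @param sentence_index the sentence ordinal.
#' @param type_pairs list of length-2 character vectors of entity types,
#'   e.g. `list(c("protein", "protein"), c("chemical", "disease"))`.
#' @param allow_self keep pairs with identical concept ids.
#' @return tibble with one row per candidate: annotation ids, types,
#'   concepts, offsets (`a` is the leftmost mention).
#' @export
candidate_pairs <- function(annotations, sentence_index, type_pairs,
                            allow_self = FALSE) {
  empty <- tibble::tibble(
    sentence_index = integer(0), ann_a = character(0), ann_b = character(0),
    type_a = character(0), type_b = character(0),
    concept_a = character(0), concept_b = character(0),
    offset_a = integer(0), offset_b = integer(0),
    length_a = integer(0), length_b = integer(0))
  if (length(annotations) < 2L || !length(type_pairs)) return(empty)
  ord <- order(vapply(annotations, ann_offset, integer(1)),
               vapply(annotations, function(a) a$id, character(1)))
  annotations <- annotations[ord]
  wanted <- vapply(type_pairs, function(p) paste(sort(p), collapse = "|"), character(1))
  rows <- list()
  n <- length(annotations)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- annotations[[i]]; b <- annotations[[j]]
      if (identical(a$id, b$id)) next
      if (!paste(sort(c(ann_type(a), ann_type(b))), collapse = "|") %in% wanted) next
      if (!allow_self && identical(ann_concept(a), ann_concept(b))) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sentence_index = as.integer(sentence_index),
        ann_a = a$id, ann_b = b$id,
        type_a = ann_type(a), type_b = ann_type(b),
        concept_a = ann_concept(a), concept_b = ann_concept(b),
        offset_a = ann_offset(a), offset_b = ann_offset(b),
        length_a = ann_length(a), length_b = ann_length(b))
    }
  }
  if (!length(rows)) empty else do.call(rbind, rows)
}

#' Load a gold interaction database
#'
#' @param x path to (or contents of) a 3-column TSV with header
#'   `document_id`, `id1`, `id2` — one curated interaction per row.
#' @return tibble with an additional `pair` column (unordered key).
#' @export
load_gold <- function(x) {
  if (length(x) == 1L && !grepl("[\n\t]", x) && file.exists(x)) {
    tab <- utils::read.delim(x, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character", fileEncoding = "UTF-8")
  } else {
    tab <- utils::read.delim(text = x, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  gold_table(tab)
}

gold_table <- function(tab) {
  stopifnot(all(c("document_id", "id1", "id2") %in% names(tab)))
  tab <- tibble::as_tibble(tab)
  tab$pair <- unordered_pair(tab$id1, tab$id2)
  tab
}

unordered_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

gold_pairs_for <- function(gold, doc_id) {
  unique(gold$pair[gold$document_id == doc_id])
}

#' Label sentences by distant supervision
#'
#' A sentence is positive when it contains at least one pair of annotations
#' whose (unordered) concept-identifier pair belongs to one of the gold
#' standard interactions recorded for the document; otherwise negative.
#'
#' @param doc a `bioc_document` with resolved annotations on its sentences.
#' @param gold a [gold_table()] / [load_gold()] result.
#' @return tibble with columns `sentence_index`, `label`
#'   (`"positive"`/`"negative"`).
#' @export
distant_label <- function(doc, gold) {
  doc_gold <- gold_pairs_for(gold, doc$id)
  sentences <- document_sentences(doc)
  lab <- vapply(sentences, function(s) {
    cids <- unique(vapply(s$annotations, ann_concept, character(1)))
    cids <- cids[!is.na(cids)]
    if (length(cids) >= 2L && length(doc_gold)) {
      pairs <- utils::combn(sort(cids), 2L)
      if (any(unordered_pair(pairs[1L, ], pairs[2L, ]) %in% doc_gold)) {
        return("positive")
      }
    }
    "negative"
  }, character(1))
  tibble::tibble(
    sentence_index = vapply(sentences, function(s) s$index, integer(1)),
    label = lab)
}

#' Learn syntactic path patterns by distant supervision
#'
#' For every co-occurring entity pair of the requested types, the connecting
#' dependency path is extracted and counted as positive when the pair is a
#' gold interaction for its document (`mode = "pair"`), or when the whole
#' sentence is positive under [distant_label()] (`mode = "sentence"`).
#' A pattern's decision is `yes` when its positive fraction reaches `theta`
#' and its support reaches `min_support`. Counting is order-independent, so
#' the table is deterministic for a given corpus.
#'
#' @param collection an annotated, disambiguated `bioc_collection`.
#' @param parses named list (by document id) of `dependency_tree` lists, as
#'   from [load_parses()].
#' @param gold a gold interaction table.
#' @param type_pairs see [candidate_pairs()].
#' @param mode `"pair"` (default) or `"sentence"` supervision.
#' @param theta minimum positive fraction for a `yes` decision.
#' @param min_support minimum number of observations for a `yes` decision.
#' @return tibble with columns `top_lemma`, `left_path`, `right_path`
#'   (edge labels joined by `>`), `n_pos`, `n_neg`, `decision`.
#' @export
learn_patterns <- function(collection, parses, gold,
                           type_pairs = list(c("protein", "protein")),
                           mode = c("pair", "sentence"),
                           theta = 0.5, min_support = 1L) {
  mode <- match.arg(mode)
  counts <- new.env(parent = emptyenv())
  for (doc in collection$documents) {
    trees <- parses[[doc$id]]
    if (is.null(trees)) next
    doc_gold <- gold_pairs_for(gold, doc$id)
    labels <- if (mode == "sentence") distant_label(doc, gold) else NULL
    for (s in document_sentences(doc)) {
      tree <- tree_for_sentence(trees, s$index)
      if (is.null(tree)) next
      pairs <- candidate_pairs(s$annotations, s$index, type_pairs)
      if (!nrow(pairs)) next
      for (r in seq_len(nrow(pairs))) {
        ha <- entity_head(tree, pairs$offset_a[r], pairs$length_a[r])
        hb <- entity_head(tree, pairs$offset_b[r], pairs$length_b[r])
        if (is.na(ha) || is.na(hb) || ha == hb) next
        key <- path_key(extract_path(tree, ha, hb))
        positive <- if (mode == "pair") {
          unordered_pair(pairs$concept_a[r], pairs$concept_b[r]) %in% doc_gold
        } else {
          labels$label[labels$sentence_index == s$index] == "positive"
        }
        k <- paste(key, collapse = "\r")
        cur <- get0(k, envir = counts, ifnotfound = c(0L, 0L))
        cur[if (positive) 1L else 2L] <- cur[if (positive) 1L else 2L] + 1L
        assign(k, cur, envir = counts)
      }
    }
  }
  keys <- sort(ls(counts))
  if (!length(keys)) {
    return(tibble::tibble(top_lemma = character(0), left_path = character(0),
                          right_path = character(0), n_pos = integer(0),
                          n_neg = integer(0), decision = character(0)))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  cnt <- do.call(rbind, lapply(keys, get, envir = counts))
  out <- tibble::tibble(
    top_lemma = parts[, 1L], left_path = parts[, 2L], right_path = parts[, 3L],
    n_pos = as.integer(cnt[, 1L]), n_neg = as.integer(cnt[, 2L]))
  out$decision <- pattern_decision(out$n_pos, out$n_neg, theta, min_support)
  out
}

pattern_decision <- function(n_pos, n_neg, theta = 0.5, min_support = 1L) {
  total <- n_pos + n_neg
  ifelse(total >= min_support & n_pos / total >= theta, "yes", "no")
}

tree_for_sentence <- function(trees, index) {
  for (t in trees) if (identical(t$sentence_index, as.integer(index))) return(t)
  NULL
}

#' Score a candidate pair by its syntactic path
#'
#' An exact pattern hit with decision `yes` scores the pattern's positive
#' fraction `n_pos / (n_pos + n_neg)`; a hit with decision `no` scores 0; an
#' unseen path backs off to `beta`. Candidates in unparsed sentences get
#' `NA` (the candidate is retained — high recall — and the backoff is
#' applied at confidence-combination time).
#'
#' @param path result of [extract_path()], or `NULL` when no tree is
#'   available.
#' @param patterns a pattern table from [learn_patterns()] or
#'   [read_patterns()].
#' @param beta backoff score for unseen paths.
#' @return list with `score` (numeric or `NA`) and `pattern` (matching row
#'   of the table, or `NULL`).
#' @export
score_syntax <- function(path, patterns, beta = 0.25) {
  if (is.null(path)) return(list(score = NA_real_, pattern = NULL))
  key <- path_key(path)
  hit <- which(patterns$top_lemma == key[["top_lemma"]] &
                 patterns$left_path == key[["left_path"]] &
                 patterns$right_path == key[["right_path"]])
  if (!length(hit)) return(list(score = beta, pattern = NULL))
  row <- patterns[hit[1L], ]
  score <- if (row$decision == "yes") row$n_pos / (row$n_pos + row$n_neg) else 0
  list(score = score, pattern = row)
}

#' Read / write pattern tables
#'
#' TSV with columns `top_lemma`, `left_path`, `right_path`, `n_pos`,
#' `n_neg`, `decision`; paths are edge labels joined by `>` (empty string
#' for a zero-length path).
#'
#' @param path file path.
#' @return [write_patterns()] returns `path` invisibly; [read_patterns()]
#'   returns the pattern tibble.
#' @export
read_patterns <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(rep("character", 3L),
                                          rep("integer", 2L), "character"),
                           na.strings = NULL, fileEncoding = "UTF-8")
  tibble::as_tibble(tab)
}

#' @rdname read_patterns
#' @param patterns a pattern tibble.
#' @export
write_patterns <- function(patterns, path) {
  utils::write.table(patterns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
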