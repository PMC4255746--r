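#' Weight concepts by their likeliness to appear in a correct relation
#'
#' A high-recall recognizer introduces noisy concepts that co-occur with
#' everything yet almost never participate in curated interactions. The
#' weight of a concept is `(1 + gold relations involving it) /
#' (1 + candidate pairs involving it)`, clipped to `(0, 1]`; a concept never
#' seen in any candidate pair gets weight 1 (no penalty).
#'
#' @param gold a gold interaction table ([load_gold()]).
#' @param pairs a candidate-pair tibble (rows from [candidate_pairs()],
#'   with `concept_a`/`concept_b` columns; typically pooled over a corpus).
#' @return named numeric vector, concept id to weight.
#' @export
concept_weights <- function(gold, pairs) {
  cand <- table(c(pairs$concept_a, pairs$concept_b))
  gold_n <- table(c(gold$id1, gold$id2))
  ids <- union(names(cand), names(gold_n))
  if (!length(ids)) return(stats::setNames(numeric(0), character(0)))
  nc <- as.numeric(cand[ids]); nc[is.na(nc)] <- 0
  ng <- as.numeric(gold_n[ids]); ng[is.na(ng)] <- 0
  w <- pmin(1, (1 + ng) / (1 + nc))
  stats::setNames(w, ids)
}

weight_of <- function(weights, concept) {
  if (is.null(weights) || !length(weights)) return(rep(1, length(concept)))
  w <- unname(weights[concept])
  w[is.na(w)] <- 1
  w
}

#' Term-level confidence score
#'
#' A weighted product (log-linear combination) of the mention-level factors:
#' the relative frequency of the term in the article, one minus its general
#' background frequency, and the context factor reflecting the ambiguity
#' state after type resolution (1 when unambiguous, 0.5 when flagged
#' ambiguous). All factors live in `[0, 1]`, so the score does too, and it
#' is monotone non-decreasing in every factor.
#'
#' @param rel_freq mentions of the concept in the document divided by total
#'   entity mentions in the document.
#' @param bg_freq background corpus frequency in `[0, 1]` (0 when no
#'   background table is supplied: without corpus statistics no term is
#'   penalized).
#' @param context_factor 1 unambiguous, 0.5 flagged ambiguous.
#' @param weights exponents for the three factors.
#' @return numeric score in `[0, 1]`; vectorized.
#' @export
term_confidence <- function(rel_freq, bg_freq = 0, context_factor = 1,
                            weights = c(1, 1, 1)) {
  factors <- cbind(rel_freq, 1 - bg_freq, context_factor)
  if (any(factors < -1e-12 | factors > 1 + 1e-12)) {
    stop("internal invariant violated: confidence factor outside [0, 1]",
         call. = FALSE)
  }
  factors <- pmin(pmax(factors, 0), 1)
  exp_w <- function(f, w) if (w == 0) rep(1, length(f)) else f^w
  unname(exp_w(factors[, 1L], weights[1L]) *
           exp_w(factors[, 2L], weights[2L]) *
           exp_w(factors[, 3L], weights[3L]))
}

#' Interaction-level confidence score
#'
#' Combines the term confidences of the two participants, the syntactic
#' factor from the path-pattern match, and the two concept weights into a
#' weighted product: `(ta * tb)^w_t * syn^w_s * (ca * cb)^w_c`. A missing
#' syntactic factor (unparsed sentence) backs off to `beta`. The score is
#' in `[0, 1]` and monotone non-decreasing in every factor.
#'
#' @param term_a,term_b term confidences of the two mentions.
#' @param syntactic syntactic factor from [score_syntax()]; `NA` when no
#'   parse was available.
#' @param concept_a,concept_b concept weights (default 1).
#' @param weights named exponents `term`, `syntax`, `concept`.
#' @param beta backoff for a missing syntactic factor.
#' @return numeric score in `[0, 1]`; vectorized.
#' @export
interaction_confidence <- function(term_a, term_b, syntactic,
                                   concept_a = 1, concept_b = 1,
                                   weights = c(term = 1, syntax = 1, concept = 1),
                                   beta = 0.25) {
  syntactic[is.na(syntactic)] <- beta
  exp_w <- function(f, w) if (w == 0) rep(1, length(f)) else f^w
  unname(exp_w(term_a * term_b, weights[["term"]]) *
           exp_w(syntactic, weights[["syntax"]]) *
           exp_w(concept_a * concept_b, weights[["concept"]]))
}

#' Rank scored candidates
#'
#' Stable sort by descending score; ties are broken by ascending first
#' mention offset, then lexicographic concept identifier (and document id
#' when ranking across documents). Ranks are dense 1-based; curation state
#' is initialized to `"unset"`.
#'
#' @param candidates tibble with a `score` column; tie-break columns
#'   `first_offset`, `concept_key` and optionally `document_id` are used
#'   when present.
#' @return the same tibble, sorted, with `rank` and `curation_state`
#'   columns.
#' @export
rank_candidates <- function(candidates) {
  if (!nrow(candidates)) {
    candidates$rank <- integer(0)
    candidates$curation_state <- character(0)
    return(candidates)
  }
  keys <- list(-candidates$score)
  if ("document_id" %in% names(candidates)) keys <- c(keys, list(candidates$document_id))
  if ("first_offset" %in% names(candidates)) keys <- c(keys, list(candidates$first_offset))
  if ("concept_key" %in% names(candidates)) keys <- c(keys, list(candidates$concept_key))
  ord <- do.call(order, keys)
  out <- candidates[ord, ]
  out$rank <- seq_len(nrow(out))
  out$curation_state <- "unset"
  out
}

#' Load a background frequency table
#'
#' @param path TSV with columns `key` (normalized term key) and `frequency`
#'   in `[0, 1]`.
#' @return named numeric vector.
#' @export
load_background <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  stopifnot(all(c("key", "frequency") %in% names(tab)))
  stats::setNames(as.numeric(tab$frequency), tab$key)
}

#' Export a ranked candidate list as CSV
#'
#' Standard curation export: one row per ranked candidate with its score,
#' entity type(s), concept identifier(s), preferred name(s), sentence index
#' and curation state (`unset`, `confirmed`, `rejected` or `undecided`).
#'
#' @param ranked a tibble from [rank_candidates()] (entity or interaction
#'   flavour of the pipeline result).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_ranked_csv <- function(ranked, path) {
  pick <- function(nm, alt) {
    if (nm %in% names(ranked)) ranked[[nm]]
    else if (alt %in% names(ranked)) ranked[[alt]]
    else rep(NA, nrow(ranked))
  }
  out <- data.frame(
    rank = ranked$rank,
    score = ranked$score,
    document_id = pick("document_id", "document_id"),
    types = pick("types", "type"),
    concept_ids = pick("concept_ids", "concept_id"),
    preferred_names = pick("preferred_names", "preferred_name"),
    sentence_index = pick("sentence_index", "sentence_index"),
    curation_state = ranked$curation_state,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Grid-search scoring exponents against a gold standard
#'
#' Ranks the supplied interaction candidates under each combination of
#' exponents and returns the grid ordered by recovery of gold pairs within
#' the top `|gold|` ranks. A pragmatic alternative to learned re-ranking:
#' the combination function stays a transparent weighted product and the
#' exponents become tunable data.
#'
#' @param candidates interaction tibble with columns `term_a`, `term_b`,
#'   `syntactic`, `concept_wa`, `concept_wb`, `pair`, `document_id`,
#'   `first_offset`, `concept_key`.
#' @param gold gold table.
#' @param grid data frame of exponent combinations (columns `term`,
#'   `syntax`, `concept`).
#' @param beta backoff for missing syntactic factors.
#' @return the grid with a `recovery` column, best first.
#' @export
tune_weights <- function(candidates, gold,
                         grid = expand.grid(term = c(0.5, 1), syntax = c(0.5, 1, 2),
                                            concept = c(0.5, 1)),
                         beta = 0.25) {
  gold_keys <- unique(paste(gold$document_id, gold$pair))
  recovery <- vapply(seq_len(nrow(grid)), function(i) {
    w <- c(term = grid$term[i], syntax = grid$syntax[i], concept = grid$concept[i])
    sc <- interaction_confidence(candidates$term_a, candidates$term_b,
                                 candidates$syntactic, candidates$concept_wa,
                                 candidates$concept_wb, weights = w, beta = beta)
    tab <- candidates
    tab$score <- sc
    ranked <- rank_candidates(tab)
    top <- utils::head(ranked, length(gold_keys))
    if (!length(gold_keys)) return(0)
    mean(gold_keys %in% paste(top$document_id, top$pair))
  }, numeric(1))
  grid$recovery <- recovery
  grid[order(-grid$recovery), ]
}
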