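#' Drop wrong-case matches of common-word terms
#'
#' A term that is also a word of the common language (or a very short
#' symbol) is kept only when the document spells it exactly as the lexicon
#' does: "folD" in text matches the gene folD, but "fold" does not; "sex" in
#' running text does not match the chemical SEX. Annotations of entries that
#' are not case-sensitive pass through unchanged.
#'
#' @param annotations list of [bioc_annotation()] produced by the matcher
#'   (each carries `case_sensitive` and `lexicon_surface` infons).
#' @param lex optional [lexicon()] used to recover the flags when the infons
#'   are absent (e.g. for annotations read back from XML).
#' @return the filtered annotation list.
#' @export
apply_common_word_filter <- function(annotations, lex = NULL) {
  keep <- vapply(annotations, function(a) {
    cs <- infon(a, "case_sensitive")
    surf <- infon(a, "lexicon_surface")
    if (is.null(cs) && !is.null(lex)) {
      hits <- lexicon_lookup(lex, normalize_surface(a$text))
      hits <- hits[hits$concept_id == ann_concept(a) & hits$entity_type == ann_type(a), ]
      if (is.null(hits) || !nrow(hits)) return(TRUE)
      cs <- if (hits$case_sensitive[1L]) "true" else "false"
      surf <- hits$surface[1L]
    }
    if (is.null(cs) || cs != "true") return(TRUE)
    identical(a$text, surf)
  }, logical(1))
  annotations[keep]
}

#' Context rules for entity-type conflicts
#'
#' A rule states that a term (by normalized key) should be read as a given
#' entity type when a cue word occurs within a token window around the
#' mention — the classic example being GFP, which in most papers is part of
#' an experimental method (fluorescence microscopy) rather than a protein of
#' biological interest.
#'
#' @param rules data frame with columns `pattern` (normalized key),
#'   `preferred_type`, `cues` (comma-separated cue words) and `window`
#'   (token count).
#' @param types_available optional character vector; when given, a rule
#'   naming an unknown type raises a configuration error.
#' @return a tibble with a list-column `cues`.
#' @export
type_rules <- function(rules, types_available = NULL) {
  required <- c("pattern", "preferred_type", "cues", "window")
  missing <- setdiff(required, names(rules))
  if (length(missing)) {
    stop("type rule table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rules <- tibble::as_tibble(rules)
  if (!is.null(types_available)) {
    bad <- setdiff(unique(rules$preferred_type), types_available)
    if (length(bad)) {
      stop("type rule references unknown entity type(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.list(rules$cues)) {
    rules$cues <- lapply(strsplit(as.character(rules$cues), ","), trimws)
  }
  rules$cues <- lapply(rules$cues, tolower)
  rules$pattern <- as.character(rules$pattern)
  rules$window <- as.integer(rules$window)
  rules
}

#' @rdname type_rules
#' @param path TSV file with the four rule columns.
#' @export
load_type_rules <- function(path, types_available = NULL) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  type_rules(tab, types_available)
}

#' Resolve cross-type conflicts over identical spans
#'
#' Annotations covering exactly the same span with different entity types are
#' resolved by the first context rule whose pattern matches the span and
#' whose cue occurs within the rule's token window: the preferred type is
#' kept, the competing types dropped. When no rule fires, all candidate
#' types are kept and flagged with an `ambiguous` infon (which later halves
#' the context factor in confidence scoring).
#'
#' @param annotations annotations of one sentence (or passage).
#' @param rules a [type_rules()] table, or `NULL` for no rules.
#' @param tokens tokenization of the same unit (document-relative offsets),
#'   from [tokenize()].
#' @return the resolved annotation list, ordered by offset, type, concept.
#' @export
resolve_type_conflicts <- function(annotations, rules = NULL, tokens = NULL) {
  if (!length(annotations)) return(annotations)
  span <- vapply(annotations, function(a) paste(ann_offset(a), ann_length(a)), character(1))
  out <- list()
  for (sp in unique(span)) {
    grp <- annotations[span == sp]
    types <- unique(vapply(grp, ann_type, character(1)))
    if (length(types) > 1L) {
      fired <- NULL
      if (!is.null(rules) && nrow(rules) && !is.null(tokens) && nrow(tokens)) {
        key <- normalize_surface(grp[[1L]]$text)
        a0 <- ann_offset(grp[[1L]])
        a1 <- a0 + ann_length(grp[[1L]])
        inside <- which(tokens$offset < a1 & tokens$offset + tokens$length > a0)
        for (r in seq_len(nrow(rules))) {
          if (rules$pattern[r] != key) next
          if (!rules$preferred_type[r] %in% types) next
          lo <- max(1L, min(inside) - rules$window[r])
          hi <- min(nrow(tokens), max(inside) + rules$window[r])
          ctx <- tolower(tokens$text[setdiff(lo:hi, inside)])
          if (any(ctx %in% rules$cues[[r]])) {
            fired <- rules$preferred_type[r]
            break
          }
        }
      }
      if (!is.null(fired)) {
        grp <- grp[vapply(grp, ann_type, character(1)) == fired]
      } else {
        grp <- lapply(grp, set_infon, "ambiguous", "true")
      }
    }
    out <- c(out, grp)
  }
  ord <- order(vapply(out, ann_offset, integer(1)),
               vapply(out, ann_type, character(1)),
               vapply(out, ann_concept, character(1)))
  out[ord]
}

# candidate organism set of a mention group (possibly already collapsed)
group_organisms <- function(grp) {
  orgs <- unlist(lapply(grp, function(a) {
    extra <- infon(a, "candidate_organisms")
    c(infon(a, "organism_id"),
      if (!is.null(extra) && nzchar(extra)) strsplit(extra, ",")[[1L]])
  }))
  orgs <- orgs[!is.na(orgs)]
  unique(orgs[nzchar(orgs)])
}

#' Rank the focus organisms of a document
#'
#' Builds a ranked list of the organisms an article is chiefly about, used to
#' prune cross-organism gene/protein identifier ambiguity. An organism's raw
#' score is its number of species mentions plus `gamma` times the number of
#' gene/protein mentions whose candidate identifier set is compatible with
#' that organism alone; scores are normalized to sum to one. Ties are broken
#' by ascending organism identifier.
#'
#' @param annotations all annotations of one document.
#' @param gamma weight of uniquely-resolving gene/protein mentions relative
#'   to explicit species mentions.
#' @param organism_types entity types subject to organism-based
#'   disambiguation.
#' @return tibble with columns `organism_id`, `score`, sorted by descending
#'   score; zero rows when nothing is informative.
#' @export
rank_organisms <- function(annotations, gamma = 0.5,
                           organism_types = c("gene", "protein")) {
  counts <- new.env(parent = emptyenv())
  bump <- function(org, by) {
    assign(org, (get0(org, envir = counts, ifnotfound = 0)) + by, envir = counts)
  }
  species <- Filter(function(a) identical(ann_type(a), "species"), annotations)
  for (a in species) {
    org <- infon(a, "organism_id") %||% ann_concept(a)
    if (!is.na(org)) bump(org, 1)
  }
  gp <- Filter(function(a) ann_type(a) %in% organism_types, annotations)
  if (length(gp)) {
    span <- vapply(gp, function(a)
      paste(ann_offset(a), ann_length(a), ann_type(a)), character(1))
    for (sp in unique(span)) {
      orgs <- group_organisms(gp[span == sp])
      if (length(orgs) == 1L) bump(orgs, gamma)
    }
  }
  ids <- ls(counts)
  if (!length(ids)) {
    return(tibble::tibble(organism_id = character(0), score = numeric(0)))
  }
  raw <- unname(vapply(ids, get, numeric(1), envir = counts))
  tbl <- tibble::tibble(organism_id = ids, score = raw / sum(raw))
  tbl[order(-tbl$score, tbl$organism_id), ]
}

#' Prune and rank candidate identifiers by focus organism
#'
#' Given the candidate annotations of one mention (same span, same type,
#' several concept identifiers), candidates whose organism is absent from
#' the document's ranked focus-organism list are removed and the survivors
#' are sorted by their organism's score (descending; ties by organism then
#' concept identifier). If pruning would remove every candidate, the full
#' list is retained with absent organisms scored 0 — the recognizer aims at
#' high recall, and silently dropping the last reading of a mention would
#' contradict that. The winning candidate populates the `concept_id` infon
#' of the returned single annotation; the remaining readings ride in
#' `candidate_ids` / `candidate_organisms` infons so a curator can overrule
#' the choice.
#'
#' @param group list of candidate `bioc_annotation`s for one mention.
#' @param organisms ranked organism table from [rank_organisms()] (may have
#'   zero rows, in which case all candidates are kept, ordered by concept
#'   identifier).
#' @return a single collapsed `bioc_annotation`.
#' @export
disambiguate_ids <- function(group, organisms) {
  orgs <- vapply(group, function(a) infon(a, "organism_id") %||% NA_character_,
                 character(1))
  score <- organisms$score[match(orgs, organisms$organism_id)]
  score[is.na(score)] <- 0
  keep <- if (nrow(organisms) && any(orgs %in% organisms$organism_id)) {
    which(orgs %in% organisms$organism_id)
  } else {
    seq_along(group)  # fail-safe: never empty the candidate list
  }
  cid <- vapply(group, ann_concept, character(1))
  ord <- keep[order(-score[keep], orgs[keep], cid[keep])]
  top <- group[[ord[1L]]]
  rest <- ord[-1L]
  top <- set_infon(top, "candidate_ids", paste(cid[rest], collapse = ","))
  top <- set_infon(top, "candidate_organisms",
                   paste(ifelse(is.na(orgs[rest]), "", orgs[rest]), collapse = ","))
  set_infon(top, "disambiguated", "true")
}

#' Run the full disambiguation sequence on a document
#'
#' Applies, in fixed order: the common-word case filter, context-rule type
#' resolution, focus-organism ranking over the whole document, and
#' identifier pruning for gene/protein mentions (organism-independent types
#' such as chemicals and diseases keep all identifiers but are still
#' collapsed to one annotation per mention, deterministically ordered by
#' concept identifier). The ranked organism list is stored in the document
#' infon `focus_organisms`. A document already carrying the
#' `disambiguated` infon is returned unchanged, making the sequence
#' idempotent.
#'
#' @param doc a `bioc_document` with matcher annotations on its sentences or
#'   passages.
#' @param rules optional [type_rules()] table.
#' @param gamma see [rank_organisms()].
#' @param organism_types entity types subject to identifier pruning.
#' @return list with elements `document` (annotations replaced) and
#'   `organisms` (the ranked focus-organism tibble).
#' @export
disambiguate_document <- function(doc, rules = NULL, gamma = 0.5,
                                  organism_types = c("gene", "protein")) {
  if (identical(infon(doc, "disambiguated"), "true")) {
    orgs <- parse_organism_infon(infon(doc, "focus_organisms", ""))
    return(list(document = doc, organisms = orgs))
  }
  doc <- map_annotation_units(doc, function(anns, text, offset) {
    anns <- apply_common_word_filter(anns)
    resolve_type_conflicts(anns, rules, tokenize(text, offset))
  })
  organisms <- rank_organisms(document_annotations(doc), gamma, organism_types)
  doc <- map_annotation_units(doc, function(anns, text, offset) {
    collapse_mentions(anns, organisms, organism_types)
  })
  doc <- set_infon(doc, "focus_organisms", format_organism_infon(organisms))
  doc <- set_infon(doc, "disambiguated", "true")
  list(document = doc, organisms = organisms)
}

# apply f(annotations, unit_text, unit_offset) to every annotated unit
map_annotation_units <- function(doc, f) {
  for (i in seq_along(doc$passages)) {
    p <- doc$passages[[i]]
    if (!is.null(p$sentences)) {
      for (j in seq_along(p$sentences)) {
        s <- p$sentences[[j]]
        if (length(s$annotations)) {
          doc$passages[[i]]$sentences[[j]]$annotations <-
            f(s$annotations, s$text, s$offset)
        }
      }
    }
    if (length(p$annotations) && !is.null(p$text)) {
      doc$passages[[i]]$annotations <- f(p$annotations, p$text, p$offset)
    }
  }
  doc
}

collapse_mentions <- function(anns, organisms, organism_types) {
  if (!length(anns)) return(anns)
  span <- vapply(anns, function(a)
    paste(ann_offset(a), ann_length(a), ann_type(a)), character(1))
  out <- list()
  for (sp in unique(span)) {
    grp <- anns[span == sp]
    if (length(grp) == 1L) {
      out <- c(out, list(set_infon(grp[[1L]], "disambiguated", "true")))
    } else if (ann_type(grp[[1L]]) %in% organism_types) {
      out <- c(out, list(disambiguate_ids(grp, organisms)))
    } else {
      # organism-independent type: keep all ids, deterministic order
      empty <- tibble::tibble(organism_id = character(0), score = numeric(0))
      out <- c(out, list(disambiguate_ids(grp, empty)))
    }
  }
  ord <- order(vapply(out, ann_offset, integer(1)),
               vapply(out, ann_type, character(1)),
               vapply(out, ann_concept, character(1)))
  out[ord]
}

format_organism_infon <- function(organisms) {
  if (!nrow(organisms)) return("")
  paste(sprintf("%s:%s", organisms$organism_id, format_score(organisms$score)),
        collapse = ";")
}

parse_organism_infon <- function(x) {
  if (is.null(x) || !nzchar(x)) {
    return(tibble::tibble(organism_id = character(0), score = numeric(0)))
  }
  parts <- strsplit(strsplit(x, ";")[[1L]], ":")
  tibble::tibble(
    organism_id = vapply(parts, function(p) paste(utils::head(p, -1L), collapse = ":"),
                         character(1)),
    score = vapply(parts, function(p) as.numeric(utils::tail(p, 1L)), numeric(1))
  )
}
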