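#' Parse a sentence-filter expression
#'
#' The filter language is a small boolean query over a sentence's
#' annotations, used to triage the sentences shown to a curator. Atoms:
#' `has_type(T)`, `has_concept(ID)`, `has_term(KEY)` (normalized surface
#' key) and `has_relation(T1, T2)`; combined with `AND`, `OR`, `NOT` and
#' parentheses, keywords case-insensitive, precedence `NOT > AND > OR`.
#'
#' @param expression character scalar, e.g.
#'   `"has_type(chemical) AND has_type(disease)"`.
#' @param known_types optional character vector; a `has_type`/`has_relation`
#'   argument outside it raises a validation error.
#' @return a `filter_expr` abstract syntax tree; round-trips through
#'   [format_filter()].
#' @export
parse_filter <- function(expression, known_types = NULL) {
  toks <- filter_lex(expression)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  ast <- parse_or(state)
  if (state$pos <= nrow(state$toks)) {
    stop(sprintf("filter syntax error at column %d: unexpected '%s'",
                 state$toks$col[state$pos], state$toks$text[state$pos]),
         call. = FALSE)
  }
  validate_filter(ast, known_types)
  ast
}

filter_lex <- function(expression) {
  pattern <- "[A-Za-z_][A-Za-z0-9_:.|-]*|\\(|\\)|,"
  m <- stringi::stri_locate_all_regex(expression, pattern)[[1L]]
  if (is.na(m[1L, 1L])) {
    stop("filter syntax error at column 1: empty expression", call. = FALSE)
  }
  covered <- sum(m[, 2L] - m[, 1L] + 1L)
  residue <- stringi::stri_replace_all_regex(expression, paste0(pattern, "|\\s"), "")
  if (nzchar(residue)) {
    bad <- stringi::stri_locate_first_fixed(expression, substr(residue, 1L, 1L))[1L, 1L]
    stop(sprintf("filter syntax error at column %d: unexpected character '%s'",
                 bad, substr(residue, 1L, 1L)), call. = FALSE)
  }
  tibble::tibble(
    text = stringi::stri_sub(expression, m[, 1L], m[, 2L]),
    col = as.integer(m[, 1L]),
    end = as.integer(m[, 2L])
  )
}

peek <- function(state) {
  if (state$pos > nrow(state$toks)) NULL else state$toks$text[state$pos]
}

advance <- function(state) {
  state$pos <- state$pos + 1L
}

expect_tok <- function(state, what) {
  tk <- peek(state)
  if (is.null(tk)) {
    last <- state$toks$end[nrow(state$toks)]
    stop(sprintf("filter syntax error at column %d: expected '%s' but input ended",
                 last + 1L, what), call. = FALSE)
  }
  if (!identical(tk, what)) {
    stop(sprintf("filter syntax error at column %d: expected '%s', found '%s'",
                 state$toks$col[state$pos], what, tk), call. = FALSE)
  }
  advance(state)
}

is_kw <- function(tk, kw) !is.null(tk) && toupper(tk) == kw

parse_or <- function(state) {
  left <- parse_and(state)
  while (is_kw(peek(state), "OR")) {
    advance(state)
    left <- filter_node("or", list(left, parse_and(state)))
  }
  left
}

parse_and <- function(state) {
  left <- parse_not(state)
  while (is_kw(peek(state), "AND")) {
    advance(state)
    left <- filter_node("and", list(left, parse_not(state)))
  }
  left
}

parse_not <- function(state) {
  if (is_kw(peek(state), "NOT")) {
    advance(state)
    return(filter_node("not", list(parse_not(state))))
  }
  parse_primary(state)
}

parse_primary <- function(state) {
  tk <- peek(state)
  if (is.null(tk)) {
    last <- if (nrow(state$toks)) state$toks$end[nrow(state$toks)] else 0L
    stop(sprintf("filter syntax error at column %d: expression ended unexpectedly",
                 last + 1L), call. = FALSE)
  }
  if (tk == "(") {
    advance(state)
    inner <- parse_or(state)
    expect_tok(state, ")")
    return(inner)
  }
  name <- tolower(tk)
  if (!name %in% names(.filter_atoms)) {
    stop(sprintf("filter syntax error at column %d: unknown atom '%s'",
                 state$toks$col[state$pos], tk), call. = FALSE)
  }
  advance(state)
  expect_tok(state, "(")
  args <- character(0)
  repeat {
    tk <- peek(state)
    if (is.null(tk) || tk %in% c("(", ")", ",")) {
      col <- state$toks$col[min(state$pos, nrow(state$toks))]
      stop(sprintf("filter syntax error at column %d: expected an argument", col),
           call. = FALSE)
    }
    args <- c(args, tk)
    advance(state)
    if (identical(peek(state), ",")) { advance(state); next }
    break
  }
  expect_tok(state, ")")
  if (length(args) != .filter_atoms[[name]]) {
    stop(sprintf("filter atom '%s' takes %d argument(s), got %d",
                 name, .filter_atoms[[name]], length(args)), call. = FALSE)
  }
  filter_node("atom", list(), atom = name, atom_args = args)
}

.filter_atoms <- list(has_type = 1L, has_concept = 1L, has_term = 1L,
                      has_relation = 2L)

filter_node <- function(op, args, atom = NULL, atom_args = NULL) {
  structure(list(op = op, args = args, atom = atom, atom_args = atom_args),
            class = "filter_expr")
}

validate_filter <- function(ast, known_types) {
  if (is.null(known_types)) return(invisible(ast))
  walk <- function(node) {
    if (node$op == "atom") {
      if (node$atom %in% c("has_type", "has_relation")) {
        bad <- setdiff(node$atom_args, known_types)
        if (length(bad)) {
          stop("filter references unknown entity type(s): ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
      }
    } else {
      lapply(node$args, walk)
    }
  }
  walk(ast)
  invisible(ast)
}

#' Print a filter expression
#'
#' Fully parenthesized rendering; `parse_filter(format_filter(ast))` yields
#' a structurally identical AST.
#'
#' @param ast a `filter_expr`.
#' @return character scalar.
#' @export
format_filter <- function(ast) {
  switch(ast$op,
    atom = sprintf("%s(%s)", ast$atom, paste(ast$atom_args, collapse = ", ")),
    not = sprintf("NOT %s", wrap_operand(ast$args[[1L]])),
    and = sprintf("(%s AND %s)", format_filter(ast$args[[1L]]),
                  format_filter(ast$args[[2L]])),
    or = sprintf("(%s OR %s)", format_filter(ast$args[[1L]]),
                 format_filter(ast$args[[2L]]))
  )
}

wrap_operand <- function(node) {
  if (node$op %in% c("atom", "not")) format_filter(node)
  else sprintf("(%s)", format_filter(node))
}

#' @export
print.filter_expr <- function(x, ...) {
  cat("<filter_expr>", format_filter(x), "\n")
  invisible(x)
}

# truth of the four atoms over one sentence's annotation/relation context
sentence_atoms <- function(sentence, doc_relations, doc_ann_index) {
  anns <- sentence$annotations
  types <- unique(vapply(anns, ann_type, character(1)))
  concepts <- unique(unlist(lapply(anns, function(a) {
    extra <- infon(a, "candidate_ids")
    c(ann_concept(a), if (!is.null(extra) && nzchar(extra)) strsplit(extra, ",")[[1L]])
  })))
  terms <- unique(normalize_surface(vapply(anns, function(a) a$text, character(1))))
  ids <- vapply(anns, function(a) a$id, character(1))
  rel_types <- character(0)
  for (r in doc_relations) {
    if (all(r$nodes$refid %in% ids)) {
      tt <- sort(doc_ann_index[r$nodes$refid])
      rel_types <- c(rel_types, paste(tt, collapse = "|"))
    }
  }
  list(types = types[!is.na(types)], concepts = concepts[!is.na(concepts)],
       terms = terms, rel_types = unique(rel_types))
}

eval_filter_atoms <- function(ast, atoms) {
  switch(ast$op,
    atom = switch(ast$atom,
      has_type = ast$atom_args[[1L]] %in% atoms$types,
      has_concept = ast$atom_args[[1L]] %in% atoms$concepts,
      has_term = normalize_surface(ast$atom_args[[1L]]) %in% atoms$terms,
      has_relation = paste(sort(ast$atom_args), collapse = "|") %in% atoms$rel_types
    ),
    not = !eval_filter_atoms(ast$args[[1L]], atoms),
    and = eval_filter_atoms(ast$args[[1L]], atoms) &&
      eval_filter_atoms(ast$args[[2L]], atoms),
    or = eval_filter_atoms(ast$args[[1L]], atoms) ||
      eval_filter_atoms(ast$args[[2L]], atoms)
  )
}

#' Apply a sentence filter to a document
#'
#' Evaluates the filter over every sentence's annotation set and reports the
#' selected sentence indices together with how much of the document the
#' selection represents. The headline `reduction_ratio` counts characters
#' (the fraction of article *size* a curator still has to read); word and
#' sentence ratios are reported alongside.
#'
#' @param doc a sentence-segmented, annotated `bioc_document`.
#' @param expr a `filter_expr` from [parse_filter()], or a string (parsed on
#'   the fly).
#' @return list with `selected` (integer sentence indices),
#'   `reduction_ratio` (characters), `word_ratio`, `sentence_ratio`.
#' @export
apply_filter <- function(doc, expr) {
  if (is.character(expr)) expr <- parse_filter(expr)
  sentences <- document_sentences(doc)
  if (!length(sentences)) {
    return(list(selected = integer(0), reduction_ratio = NA_real_,
                word_ratio = NA_real_, sentence_ratio = NA_real_))
  }
  doc_rel <- document_relations(doc)
  all_anns <- document_annotations(doc)
  ann_index <- stats::setNames(vapply(all_anns, ann_type, character(1)),
                               vapply(all_anns, function(a) a$id, character(1)))
  sel <- vapply(sentences, function(s) {
    eval_filter_atoms(expr, sentence_atoms(s, doc_rel, ann_index))
  }, logical(1))
  chars <- vapply(sentences, function(s) nchar(s$text), numeric(1))
  words <- vapply(sentences, function(s) nrow(tokenize(s$text)), numeric(1))
  list(
    selected = vapply(sentences[sel], function(s) s$index, integer(1)),
    reduction_ratio = sum(chars[sel]) / sum(chars),
    word_ratio = if (sum(words) > 0) sum(words[sel]) / sum(words) else NA_real_,
    sentence_ratio = mean(sel)
  )
}
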