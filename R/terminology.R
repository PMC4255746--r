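#' Tokenize text into offset-anchored word and punctuation tokens
#'
#' Deterministic, locale-independent tokenization: maximal runs of Unicode
#' letters/digits form word tokens; every other non-space character (hyphens,
#' slashes, punctuation) is a single-character token. Concatenating the token
#' texts with their original gaps reconstructs the input, so offsets can be
#' trusted for annotation anchoring. `"IL-2-dependent"` yields the tokens
#' `IL`, `-`, `2`, `-`, `dependent`.
#'
#' @param text character scalar.
#' @param base_offset document offset of the first character of `text`
#'   (0-based); token offsets are document-relative.
#' @return tibble with columns `text`, `offset`, `length`.
#' @export
tokenize <- function(text, base_offset = 0L) {
  empty <- tibble::tibble(text = character(0), offset = integer(0), length = integer(0))
  if (!nchar(text)) return(empty)
  m <- stringi::stri_locate_all_regex(text, "[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]")[[1L]]
  if (is.na(m[1L, 1L])) return(empty)
  tibble::tibble(
    text = stringi::stri_sub(text, m[, 1L], m[, 2L]),
    offset = as.integer(base_offset + m[, 1L] - 1L),
    length = as.integer(m[, 2L] - m[, 1L] + 1L)
  )
}

.greek_names <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma", "δ" = "delta",
  "ε" = "epsilon", "ζ" = "zeta", "η" = "eta", "θ" = "theta",
  "ι" = "iota", "κ" = "kappa", "λ" = "lambda", "μ" = "mu",
  "ν" = "nu", "ξ" = "xi", "ο" = "omicron", "π" = "pi",
  "ρ" = "rho", "ς" = "sigma", "σ" = "sigma", "τ" = "tau",
  "υ" = "upsilon", "φ" = "phi", "χ" = "chi", "ψ" = "psi",
  "ω" = "omega"
)

#' Normalize a term surface form to its canonical lookup key
#'
#' Applies, in order: Unicode compatibility folding (NFKC), lowercasing,
#' Greek letter symbol-to-name unification (`α` and `alpha` collapse),
#' removal of hyphens/dashes, slashes and whitespace, and stripping of a
#' single trailing plural `s` from keys longer than 3 characters (a key
#' ending in `ss` is left alone, which also makes the rule idempotent).
#' `IL-2`, `Il 2` and `il2` all map to `il2`; `α-synuclein` and
#' `alpha-synuclein` both map to `alphasynuclein`.
#'
#' The function is deterministic and idempotent: applying it to its own
#' output is a no-op.
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized keys.
#' @export
normalize_surface <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- stringi::stri_trans_tolower(x, locale = "en")
  x <- stringi::stri_replace_all_fixed(x, names(.greek_names), .greek_names,
                                       vectorize_all = FALSE)
  x <- stringi::stri_replace_all_regex(x, "[\\p{Pd}/\\s]+", "")
  strip <- nchar(x) > 3L &
    stringi::stri_endswith_fixed(x, "s") &
    !stringi::stri_endswith_fixed(x, "ss")
  x[strip] <- stringi::stri_sub(x[strip], 1L, -2L)
  x
}

#' Default common-word stoplist
#'
#' A frequency-ordered list of common English words shipped with the package,
#' used to flag lexicon surfaces that collide with ordinary language (and
#' therefore require exact-case matching). Users can supply their own list to
#' [lexicon()]; the file format is one word per line.
#'
#' @param n keep the first `n` words (the shipped list is ordered by
#'   decreasing frequency).
#' @return character vector of lowercase words.
#' @export
default_stoplist <- function(n = 5000L) {
  path <- system.file("extdata", "stoplist-en.txt", package = "biocmine")
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- words[nzchar(words) & !startsWith(words, "#")]
  utils::head(words, n)
}

#' Build a terminology lexicon
#'
#' A lexicon maps term surface forms to database concepts. Each entry carries
#' the original surface, a concept identifier, an entity type, a preferred
#' name, the source database and (optionally) an organism identifier, and is
#' indexed under the normalized key produced by [normalize_surface()], which
#' makes lookup tolerant to case, hyphenation, Greek-letter and plural
#' variants. A surface may map to several concepts of the same type (e.g.
#' the same gene name in several organisms) or to concepts of different
#' types; both ambiguities are preserved for the disambiguation stage.
#'
#' An entry is flagged `case_sensitive` when its surface is at most
#' `case_length` characters long or its lowercase form occurs in the
#' stoplist: short symbols and common-language collisions (a gene named after
#' a lowercase word, a chemical whose acronym spells an English word) are
#' only matched when the document spells them exactly as the database does.
#'
#' @param entries data frame with columns `surface`, `concept_id`,
#'   `entity_type`, `preferred_name`, `source_db` and optionally
#'   `organism_id`.
#' @param stoplist character vector of common words (see
#'   [default_stoplist()]).
#' @param case_length surfaces of at most this many characters are matched
#'   case-sensitively.
#' @return an object of class `lexicon`.
#' @seealso [load_lexicon()] to read the 5-column TSV format.
#' @export
lexicon <- function(entries, stoplist = default_stoplist(), case_length = 5L) {
  required <- c("surface", "concept_id", "entity_type", "preferred_name", "source_db")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    stop("lexicon table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  entries <- tibble::as_tibble(entries)
  if (!"organism_id" %in% names(entries)) entries$organism_id <- NA_character_
  entries <- entries[, c(required, "organism_id")]
  for (col in names(entries)) entries[[col]] <- as.character(entries[[col]])
  blank <- is.na(entries$surface) | !nzchar(entries$surface)
  if (any(blank)) {
    warning(sum(blank), " lexicon row(s) with empty surface rejected", call. = FALSE)
    entries <- entries[!blank, ]
  }
  entries <- entries[!duplicated(entries[, c("surface", "concept_id", "entity_type")]), ]
  entries$key <- normalize_surface(entries$surface)
  entries$case_sensitive <- nchar(entries$surface) <= case_length |
    stringi::stri_trans_tolower(entries$surface, locale = "en") %in% stoplist
  index <- new.env(parent = emptyenv())
  for (k in unique(entries$key)) {
    assign(k, which(entries$key == k), envir = index)
  }
  structure(
    list(entries = entries, index = index,
         types_available = sort(unique(entries$entity_type)),
         stoplist = stoplist),
    class = "lexicon"
  )
}

#' Load a lexicon from a tab-separated table
#'
#' @param path path to a UTF-8 TSV file with a header row and columns
#'   `surface`, `concept_id`, `entity_type`, `preferred_name`, `source_db`
#'   and optionally `organism_id`.
#' @inheritParams lexicon
#' @return a `lexicon` object.
#' @export
load_lexicon <- function(path, stoplist = default_stoplist(), case_length = 5L) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8", check.names = FALSE)
  lexicon(tab, stoplist = stoplist, case_length = case_length)
}

#' Write a lexicon table as TSV
#'
#' @param entries a lexicon entry table (as produced by [gen_lexicon()]) or a
#'   `lexicon` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(entries, path) {
  if (inherits(entries, "lexicon")) {
    entries <- entries$entries[, c("surface", "concept_id", "entity_type",
                                   "preferred_name", "source_db", "organism_id")]
  }
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> entries=%d keys=%d types={%s}\n",
              nrow(x$entries), length(ls(x$index)),
              paste(x$types_available, collapse = ", ")))
  invisible(x)
}

lexicon_lookup <- function(lex, key) {
  if (is.na(key) || !nzchar(key)) return(NULL)
  rows <- get0(key, envir = lex$index, inherits = FALSE)
  if (is.null(rows)) NULL else lex$entries[rows, ]
}

#' Annotate text by greedy longest-match dictionary lookup
#'
#' Scans the token sequence left to right; at each position the longest
#' window (up to `max_span` tokens) whose normalized surface hits the lexicon
#' index is annotated, shorter and overlapping matches are suppressed, and
#' scanning resumes after the match. A window hit yields one annotation per
#' candidate concept (ambiguity is preserved for the disambiguation stage).
#' Entries flagged case-sensitive only match when the document spells the
#' surface exactly as the lexicon does ("fold" in running text does not match
#' a gene named "folD").
#'
#' Greedy matching is only over windows that survive the case check; type
#' filtering happens after matching, so annotating with a restricted type set
#' is exactly the restriction of the full annotation set.
#'
#' @param text character scalar to annotate.
#' @param base_offset document offset of `text` (0-based).
#' @param lex a [lexicon()].
#' @param types entity types to emit (default: all types in the lexicon).
#' @param max_span maximum match length in tokens.
#' @param enforce_case apply the exact-case rule for case-sensitive entries.
#' @return list of [bioc_annotation()] objects with empty ids (callers assign
#'   document-unique ids); infons: `type`, `concept_id`, `preferred_name`,
#'   `source_db`, `organism_id` (when present), `lexicon_surface`,
#'   `case_sensitive`, `score`.
#' @export
annotate_text <- function(text, base_offset, lex, types = NULL,
                          max_span = 8L, enforce_case = TRUE) {
  if (is.null(types)) types <- lex$types_available
  toks <- tokenize(text, 0L)
  n <- nrow(toks)
  anns <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(max_span, n - i + 1L), 1L)) {
      j <- i + len - 1L
      window <- substr0(text, toks$offset[i], toks$offset[j] + toks$length[j] - toks$offset[i])
      hits <- lexicon_lookup(lex, normalize_surface(window))
      if (is.null(hits)) next
      if (enforce_case) {
        hits <- hits[!hits$case_sensitive | hits$surface == window, ]
      }
      if (!nrow(hits)) next
      emit <- hits[hits$entity_type %in% types, ]
      if (nrow(emit)) {
        for (r in seq_len(nrow(emit))) {
          infons <- list(
            type = emit$entity_type[r],
            concept_id = emit$concept_id[r],
            preferred_name = emit$preferred_name[r],
            source_db = emit$source_db[r],
            lexicon_surface = emit$surface[r],
            case_sensitive = if (emit$case_sensitive[r]) "true" else "false",
            score = "1"
          )
          if (!is.na(emit$organism_id[r])) infons$organism_id <- emit$organism_id[r]
          anns[[length(anns) + 1L]] <- bioc_annotation(
            id = "", text = window,
            offset = base_offset + toks$offset[i],
            length = nchar(window), infons = infons)
        }
      }
      i <- j + 1L
      matched <- TRUE
      break
    }
    if (!matched) i <- i + 1L
  }
  anns
}

#' Annotate a BioC passage
#'
#' Applies [annotate_text()] to each sentence of the passage (so no
#' annotation ever crosses a sentence boundary), or to the passage text when
#' no sentence segmentation is present. Sentence-level matches carry a
#' `sentence_index` infon.
#'
#' @param passage a [bioc_passage()].
#' @inheritParams annotate_text
#' @return list of `bioc_annotation` objects.
#' @export
annotate_passage <- function(passage, lex, types = NULL, max_span = 8L,
                             enforce_case = TRUE) {
  if (!is.null(passage$sentences)) {
    out <- list()
    for (s in passage$sentences) {
      anns <- annotate_text(s$text, s$offset, lex, types, max_span, enforce_case)
      anns <- lapply(anns, set_infon, "sentence_index", s$index)
      out <- c(out, anns)
    }
    out
  } else if (!is.null(passage$text)) {
    annotate_text(passage$text, passage$offset, lex, types, max_span, enforce_case)
  } else {
    list()
  }
}
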