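#' BioC data model
#'
#' Plain S3 containers mirroring the BioC interchange model: a collection of
#' documents, each a sequence of passages, optionally segmented into
#' sentences, with offset-anchored annotations and binary relations. Every
#' element carries an open `infons` key-value map; unknown infons are
#' preserved verbatim through read/write. All offsets are 0-based character
#' counts relative to the start of the document text.
#'
#' @param source free-text label of the producing system.
#' @param date ISO-8601 date string (kept verbatim; defaults to empty so that
#'   serialization is deterministic).
#' @param key free-text key (e.g. a DTD file name).
#' @param infons named list of character values.
#' @param documents list of [bioc_document()] objects.
#' @return an object of class `bioc_collection`.
#' @examples
#' p <- bioc_passage(0L, "aspirin reduces inflammation")
#' d <- bioc_document("doc1", passages = list(p))
#' coll <- bioc_collection(documents = list(d))
#' @export
bioc_collection <- function(documents = list(), source = "biocmine", date = "",
                            key = "", infons = list()) {
  ids <- vapply(documents, function(d) d$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate document ids in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(source = as.character(source), date = as.character(date),
         key = as.character(key), infons = infons, documents = documents),
    class = "bioc_collection"
  )
}

#' @rdname bioc_collection
#' @param id document identifier (e.g. a PMID).
#' @param passages ordered list of [bioc_passage()] objects.
#' @export
bioc_document <- function(id, passages = list(), infons = list()) {
  offs <- vapply(passages, function(p) p$offset, integer(1))
  if (length(offs) > 1L && any(diff(offs) <= 0L)) {
    stop("passage offsets must be strictly increasing in document ", id, call. = FALSE)
  }
  structure(list(id = as.character(id), infons = infons, passages = passages),
            class = "bioc_document")
}

#' @rdname bioc_collection
#' @param offset 0-based character offset of the passage from document start.
#' @param text passage text, or `NULL` when only sentences carry text.
#' @param sentences optional ordered list of [bioc_sentence()] objects.
#' @param annotations list of [bioc_annotation()] objects.
#' @param relations list of [bioc_relation()] objects.
#' @export
bioc_passage <- function(offset, text = NULL, infons = list(), sentences = NULL,
                         annotations = list(), relations = list()) {
  structure(
    list(offset = as.integer(offset), text = text, infons = infons,
         sentences = sentences, annotations = annotations, relations = relations),
    class = "bioc_passage"
  )
}

#' @rdname bioc_collection
#' @param index 0-based sentence ordinal within the document (dense, gap-free;
#'   recomputed on read from document order).
#' @export
bioc_sentence <- function(offset, text, infons = list(), annotations = list(),
                          index = NA_integer_) {
  structure(
    list(index = as.integer(index), offset = as.integer(offset),
         text = as.character(text), infons = infons, annotations = annotations),
    class = "bioc_sentence"
  )
}

#' @rdname bioc_collection
#' @param locations data frame with integer columns `offset` and `length`;
#'   usually a single row. When omitted, built from `offset`/`length`.
#' @param length character count covered by the annotation.
#' @export
bioc_annotation <- function(id, text, offset = NULL, length = NULL,
                            infons = list(), locations = NULL) {
  if (is.null(locations)) {
    locations <- data.frame(offset = as.integer(offset),
                            length = as.integer(length))
  }
  structure(
    list(id = as.character(id), infons = infons,
         locations = locations, text = as.character(text)),
    class = "bioc_annotation"
  )
}

#' @rdname bioc_collection
#' @param nodes data frame with character columns `refid` (annotation ids)
#'   and `role` (`arg1`, `arg2`).
#' @export
bioc_relation <- function(id, nodes, infons = list()) {
  stopifnot(is.data.frame(nodes), all(c("refid", "role") %in% names(nodes)))
  structure(list(id = as.character(id), infons = infons, nodes = nodes),
            class = "bioc_relation")
}

ann_offset <- function(a) a$locations$offset[[1L]]
ann_length <- function(a) a$locations$length[[1L]]
ann_end <- function(a) ann_offset(a) + ann_length(a)
ann_type <- function(a) infon(a, "type", NA_character_)
ann_concept <- function(a) infon(a, "concept_id", NA_character_)

passage_end <- function(p) {
  if (!is.null(p$text)) return(p$offset + nchar(p$text))
  if (length(p$sentences)) {
    max(vapply(p$sentences, function(s) s$offset + nchar(s$text), numeric(1)))
  } else {
    p$offset
  }
}

#' Reconstruct the full text of a document
#'
#' Passage (or sentence) texts are placed at their recorded offsets; gaps
#' between units are filled with spaces, so that any annotation location can
#' be sliced out of the result.
#'
#' @param doc a `bioc_document`.
#' @return character scalar (empty for a document without text).
#' @export
document_text <- function(doc) {
  if (!length(doc$passages)) return("")
  total <- max(vapply(doc$passages, passage_end, numeric(1)))
  buf <- strrep(" ", total)
  for (p in doc$passages) {
    if (!is.null(p$text) && nchar(p$text)) {
      substr(buf, p$offset + 1L, p$offset + nchar(p$text)) <- p$text
    }
    for (s in p$sentences %||% list()) {
      if (nchar(s$text)) {
        substr(buf, s$offset + 1L, s$offset + nchar(s$text)) <- s$text
      }
    }
  }
  buf
}

#' Collect all annotations of a document
#'
#' @param doc a `bioc_document`.
#' @return flat list of `bioc_annotation` objects in document order
#'   (passage-level first within each passage, then per sentence).
#' @export
document_annotations <- function(doc) {
  out <- list()
  for (p in doc$passages) {
    out <- c(out, p$annotations)
    for (s in p$sentences %||% list()) out <- c(out, s$annotations)
  }
  out
}

#' Collect all sentences of a document
#'
#' @param doc a `bioc_document`.
#' @return flat list of `bioc_sentence` objects in document order.
#' @export
document_sentences <- function(doc) {
  out <- list()
  for (p in doc$passages) out <- c(out, p$sentences %||% list())
  out
}

document_relations <- function(doc) {
  out <- list()
  for (p in doc$passages) out <- c(out, p$relations)
  out
}

# re-number sentence indices densely (0-based) across the document
renumber_sentences <- function(doc) {
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

#' @export
print.bioc_collection <- function(x, ...) {
  nann <- sum(vapply(x$documents, function(d) length(document_annotations(d)), integer(1)))
  cat(sprintf("<bioc_collection> source='%s' documents=%d annotations=%d\n",
              x$source, length(x$documents), nann))
  invisible(x)
}

#' @export
print.bioc_document <- function(x, ...) {
  cat(sprintf("<bioc_document> id='%s' passages=%d sentences=%d annotations=%d\n",
              x$id, length(x$passages), length(document_sentences(x)),
              length(document_annotations(x))))
  invisible(x)
}

#' @export
print.bioc_annotation <- function(x, ...) {
  cat(sprintf("<bioc_annotation> id=%s [%d+%d] '%s' type=%s concept=%s\n",
              x$id, ann_offset(x), ann_length(x), x$text,
              ann_type(x), ann_concept(x)))
  invisible(x)
}
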