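xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  gsub("\"", "&quot;", xml_escape(x), fixed = TRUE)
}

#' Read a BioC XML collection
#'
#' Parses a BioC XML stream into the [bioc_collection()] data model. Both
#' stand-off annotations (`<annotation>` elements with `<location>` children)
#' and the in-line dialect written by [write_bioc()] (`<mark>` elements
#' embedded in `<text>`) are understood; in-line marks are converted back to
#' offset-anchored annotations, so the two serializations of a collection
#' re-parse to identical annotation sets. All infons, known or not, are
#' preserved verbatim.
#'
#' @param x a file path or a character scalar containing XML.
#' @return a `bioc_collection`.
#' @details Structural validation is performed on read: offsets must be
#'   non-negative integers and every relation node must reference an
#'   annotation of the same document; violations raise an error naming the
#'   offending element. Content-level checks (does each location slice equal
#'   the annotation text?) are left to [validate_offsets()], which reports
#'   violations as data.
#' @seealso [write_bioc()], [validate_offsets()]
#' @export
read_bioc <- function(x) {
  doc <- xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "collection") {
    stop("expected <collection> root element, found <", xml2::xml_name(root), ">",
         call. = FALSE)
  }
  coll <- bioc_collection(
    documents = lapply(xml2::xml_find_all(root, "./document"), read_document_node),
    source = first_child_text(root, "source"),
    date = first_child_text(root, "date"),
    key = first_child_text(root, "key"),
    infons = read_infons(root)
  )
  check_structure(coll)
  coll
}

first_child_text <- function(node, name) {
  n <- xml2::xml_find_first(node, paste0("./", name))
  if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
}

read_infons <- function(node) {
  ns <- xml2::xml_find_all(node, "./infon")
  if (!length(ns)) return(list())
  stats::setNames(as.list(xml2::xml_text(ns)), xml2::xml_attr(ns, "key"))
}

read_document_node <- function(node) {
  doc <- bioc_document(
    id = first_child_text(node, "id"),
    infons = read_infons(node),
    passages = lapply(xml2::xml_find_all(node, "./passage"), read_passage_node)
  )
  renumber_sentences(doc)
}

read_passage_node <- function(node) {
  offset <- as_integer_strict(first_child_text(node, "offset"), "passage offset")
  txt <- read_text_node(node, offset)
  sent_nodes <- xml2::xml_find_all(node, "./sentence")
  sentences <- if (length(sent_nodes)) lapply(sent_nodes, read_sentence_node) else NULL
  bioc_passage(
    offset = offset,
    text = txt$text,
    infons = read_infons(node),
    sentences = sentences,
    annotations = c(txt$annotations,
                    lapply(xml2::xml_find_all(node, "./annotation"), read_annotation_node)),
    relations = lapply(xml2::xml_find_all(node, "./relation"), read_relation_node)
  )
}

read_sentence_node <- function(node) {
  offset <- as_integer_strict(first_child_text(node, "offset"), "sentence offset")
  txt <- read_text_node(node, offset)
  bioc_sentence(
    offset = offset,
    text = txt$text %||% "",
    infons = read_infons(node),
    annotations = c(txt$annotations,
                    lapply(xml2::xml_find_all(node, "./annotation"), read_annotation_node))
  )
}

# Reads a <text> child that may carry in-line <mark> elements; returns the
# plain text plus any annotations reconstructed from marks (offsets are
# base-relative document offsets).
read_text_node <- function(node, base) {
  tn <- xml2::xml_find_first(node, "./text")
  if (inherits(tn, "xml_missing")) return(list(text = NULL, annotations = list()))
  kids <- xml2::xml_contents(tn)
  if (!length(kids) || all(xml2::xml_type(kids) == "text")) {
    return(list(text = xml2::xml_text(tn), annotations = list()))
  }
  pos <- 0L
  parts <- character(0)
  anns <- list()
  for (k in seq_along(kids)) {
    kid <- kids[[k]]
    chunk <- xml2::xml_text(kid)
    if (xml2::xml_type(kid) == "element") {
      if (xml2::xml_name(kid) != "mark") {
        stop("unexpected element <", xml2::xml_name(kid), "> inside <text>", call. = FALSE)
      }
      at <- as.list(xml2::xml_attrs(kid))
      id <- at[["id"]] %||% ""
      at[["id"]] <- NULL
      anns[[length(anns) + 1L]] <- bioc_annotation(
        id = id, text = chunk, offset = base + pos, length = nchar(chunk),
        infons = at
      )
    }
    parts <- c(parts, chunk)
    pos <- pos + nchar(chunk)
  }
  list(text = paste(parts, collapse = ""), annotations = anns)
}

read_annotation_node <- function(node) {
  locs <- xml2::xml_find_all(node, "./location")
  locations <- data.frame(
    offset = vapply(xml2::xml_attr(locs, "offset"), as_integer_strict, integer(1),
                    what = "annotation location offset", USE.NAMES = FALSE),
    length = vapply(xml2::xml_attr(locs, "length"), as_integer_strict, integer(1),
                    what = "annotation location length", USE.NAMES = FALSE)
  )
  id <- xml2::xml_attr(node, "id")
  bioc_annotation(
    id = if (is.na(id)) "" else id,
    text = first_child_text(node, "text"),
    infons = read_infons(node),
    locations = locations
  )
}

read_relation_node <- function(node) {
  ns <- xml2::xml_find_all(node, "./node")
  id <- xml2::xml_attr(node, "id")
  bioc_relation(
    id = if (is.na(id)) "" else id,
    infons = read_infons(node),
    nodes = data.frame(refid = xml2::xml_attr(ns, "refid"),
                       role = xml2::xml_attr(ns, "role"))
  )
}

# structural validation shared by read_bioc and handle_annotate
check_structure <- function(coll) {
  for (doc in coll$documents) {
    ids <- vapply(document_annotations(doc), function(a) a$id, character(1))
    for (a in document_annotations(doc)) {
      if (any(a$locations$offset < 0L) || any(a$locations$length < 0L)) {
        stop("negative offset in annotation '", a$id, "' of document '",
             doc$id, "'", call. = FALSE)
      }
    }
    for (r in document_relations(doc)) {
      missing <- setdiff(r$nodes$refid, ids)
      if (length(missing)) {
        stop("relation '", r$id, "' of document '", doc$id,
             "' references unknown annotation(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(coll)
}

#' Write a BioC XML collection
#'
#' Serializes a [bioc_collection()] to BioC XML. In `standoff` mode (the
#' default) annotations are written as sibling `<annotation>` elements with
#' `<location offset length>` anchors. In `inline` mode annotations are
#' embedded in the text as `<mark>` elements carrying their infons as
#' attributes; overlapping spans are an error unless
#' `overlap_policy = "longest-wins"`, in which case only the longest span of
#' each overlapping group is marked (ties broken by earlier offset).
#'
#' @param collection a `bioc_collection`.
#' @param mode `"standoff"` or `"inline"`.
#' @param overlap_policy `"error"` or `"longest-wins"` (inline mode only).
#' @param include_offsets emit `<location>` elements in standoff mode
#'   (disabling this yields annotations without anchors, mirroring services
#'   that return offsets only on request).
#' @return character scalar containing the XML document.
#' @export
write_bioc <- function(collection, mode = c("standoff", "inline"),
                       overlap_policy = c("error", "longest-wins"),
                       include_offsets = TRUE) {
  mode <- match.arg(mode)
  overlap_policy <- match.arg(overlap_policy)
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<collection>")
  out <- c(out,
           sprintf("  <source>%s</source>", xml_escape(collection$source)),
           sprintf("  <date>%s</date>", xml_escape(collection$date)),
           sprintf("  <key>%s</key>", xml_escape(collection$key)),
           write_infons(collection$infons, 2L))
  for (doc in collection$documents) {
    out <- c(out, write_document_xml(doc, mode, overlap_policy, include_offsets))
  }
  paste(c(out, "</collection>", ""), collapse = "\n")
}

write_infons <- function(infons, indent) {
  if (!length(infons)) return(character(0))
  pad <- strrep(" ", indent)
  sprintf("%s<infon key=\"%s\">%s</infon>", pad,
          xml_escape_attr(names(infons)),
          xml_escape(vapply(infons, as.character, character(1))))
}

write_document_xml <- function(doc, mode, overlap_policy, include_offsets) {
  out <- c("  <document>",
           sprintf("    <id>%s</id>", xml_escape(doc$id)),
           write_infons(doc$infons, 4L))
  for (p in doc$passages) {
    out <- c(out, write_passage_xml(p, mode, overlap_policy, include_offsets))
  }
  c(out, "  </document>")
}

write_passage_xml <- function(p, mode, overlap_policy, include_offsets) {
  out <- c("    <passage>",
           write_infons(p$infons, 6L),
           sprintf("      <offset>%d</offset>", p$offset))
  inline_here <- identical(mode, "inline")
  if (!is.null(p$text)) {
    out <- c(out, write_text_xml(p$text, p$offset, p$annotations, inline_here,
                                 overlap_policy, 6L))
  }
  for (s in p$sentences %||% list()) {
    out <- c(out, write_sentence_xml(s, mode, overlap_policy, include_offsets))
  }
  if (!inline_here) {
    for (a in p$annotations) out <- c(out, write_annotation_xml(a, 6L, include_offsets))
  }
  for (r in p$relations) out <- c(out, write_relation_xml(r, 6L))
  c(out, "    </passage>")
}

write_sentence_xml <- function(s, mode, overlap_policy, include_offsets) {
  inline_here <- identical(mode, "inline")
  out <- c("      <sentence>",
           write_infons(s$infons, 8L),
           sprintf("        <offset>%d</offset>", s$offset),
           write_text_xml(s$text, s$offset, s$annotations, inline_here,
                          overlap_policy, 8L))
  if (!inline_here) {
    for (a in s$annotations) out <- c(out, write_annotation_xml(a, 8L, include_offsets))
  }
  c(out, "      </sentence>")
}

write_text_xml <- function(text, base, annotations, inline, overlap_policy, indent) {
  pad <- strrep(" ", indent)
  if (!inline || !length(annotations)) {
    return(sprintf("%s<text>%s</text>", pad, xml_escape(text)))
  }
  anns <- resolve_overlaps(annotations, overlap_policy)
  pieces <- character(0)
  pos <- 0L  # local 0-based
  for (a in anns) {
    if (nrow(a$locations) != 1L) {
      stop("inline mode cannot represent discontinuous annotation '", a$id, "'",
           call. = FALSE)
    }
    start <- ann_offset(a) - base
    if (start > pos) pieces <- c(pieces, xml_escape(substr0(text, pos, start - pos)))
    attrs <- c(id = a$id, vapply(a$infons, as.character, character(1)))
    attr_str <- paste(sprintf("%s=\"%s\"", names(attrs), xml_escape_attr(attrs)),
                      collapse = " ")
    pieces <- c(pieces, sprintf("<mark %s>%s</mark>", attr_str,
                                xml_escape(substr0(text, start, ann_length(a)))))
    pos <- start + ann_length(a)
  }
  if (pos < nchar(text)) pieces <- c(pieces, xml_escape(substr0(text, pos, nchar(text) - pos)))
  sprintf("%s<text>%s</text>", pad, paste(pieces, collapse = ""))
}

# Select a non-overlapping subset of annotations for inline marking.
resolve_overlaps <- function(annotations, policy) {
  if (!length(annotations)) return(annotations)
  off <- vapply(annotations, ann_offset, integer(1))
  len <- vapply(annotations, ann_length, integer(1))
  ord <- order(-len, off)
  kept <- integer(0)
  dropped <- FALSE
  for (i in ord) {
    clash <- any(off[kept] < off[i] + len[i] & off[i] < off[kept] + len[kept])
    if (clash) dropped <- TRUE else kept <- c(kept, i)
  }
  if (dropped && policy != "longest-wins") {
    stop("overlapping annotation spans in inline mode; ",
         "use overlap_policy = \"longest-wins\"", call. = FALSE)
  }
  annotations[sort(kept)]
}

write_annotation_xml <- function(a, indent, include_offsets = TRUE) {
  pad <- strrep(" ", indent)
  out <- c(sprintf("%s<annotation id=\"%s\">", pad, xml_escape_attr(a$id)),
           write_infons(a$infons, indent + 2L))
  if (include_offsets) {
    out <- c(out, sprintf("%s  <location offset=\"%d\" length=\"%d\"/>", pad,
                          a$locations$offset, a$locations$length))
  }
  c(out,
    sprintf("%s  <text>%s</text>", pad, xml_escape(a$text)),
    sprintf("%s</annotation>", pad))
}

write_relation_xml <- function(r, indent) {
  pad <- strrep(" ", indent)
  c(sprintf("%s<relation id=\"%s\">", pad, xml_escape_attr(r$id)),
    write_infons(r$infons, indent + 2L),
    sprintf("%s  <node refid=\"%s\" role=\"%s\"/>", pad,
            xml_escape_attr(r$nodes$refid), xml_escape_attr(r$nodes$role)),
    sprintf("%s</relation>", pad))
}

#' Check annotation offsets and relation references
#'
#' Content-level validation of a collection: every annotation location must
#' slice out exactly the annotation's `text` from the reconstructed document
#' text, and every relation node must reference an existing annotation.
#' Violations are returned as data, never raised.
#'
#' @param collection a `bioc_collection`.
#' @return a tibble with columns `document_id`, `element_id`, `kind`
#'   (`text-mismatch`, `dangling-node`, `negative-offset`) and `detail`;
#'   zero rows when the collection is clean.
#' @export
validate_offsets <- function(collection) {
  rows <- list()
  add <- function(doc_id, el_id, kind, detail) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      document_id = doc_id, element_id = el_id, kind = kind, detail = detail)
  }
  for (doc in collection$documents) {
    txt <- document_text(doc)
    anns <- document_annotations(doc)
    for (a in anns) {
      if (any(a$locations$offset < 0L) || any(a$locations$length < 0L)) {
        add(doc$id, a$id, "negative-offset", "negative offset or length")
        next
      }
      slices <- mapply(substr0, a$locations$offset, a$locations$length,
                       MoreArgs = list(text = txt))
      covered <- if (nrow(a$locations) == 1L) slices[[1L]] else paste(slices, collapse = " ")
      if (!identical(covered, a$text)) {
        add(doc$id, a$id, "text-mismatch",
            sprintf("location covers '%s' but annotation text is '%s'", covered, a$text))
      }
    }
    ids <- vapply(anns, function(a) a$id, character(1))
    for (r in document_relations(doc)) {
      missing <- setdiff(r$nodes$refid, ids)
      if (length(missing)) {
        add(doc$id, r$id, "dangling-node",
            paste("unresolved refid:", paste(missing, collapse = ", ")))
      }
    }
  }
  if (!length(rows)) {
    tibble::tibble(document_id = character(0), element_id = character(0),
                   kind = character(0), detail = character(0))
  } else {
    do.call(rbind, rows)
  }
}
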