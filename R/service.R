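stop_bad_request <- function(msg) {
  cond <- structure(class = c("biocmine_bad_request", "error", "condition"),
                    list(message = msg, call = NULL, status = 400L))
  stop(cond)
}

stop_payload_too_large <- function(msg) {
  cond <- structure(class = c("biocmine_payload_too_large", "biocmine_bad_request",
                              "error", "condition"),
                    list(message = msg, call = NULL, status = 413L))
  stop(cond)
}

#' Build an annotation request
#'
#' The request object consumed by [handle_annotate()]; the same structure
#' backs both the command-line interface and the REST endpoint, so the two
#' paths share a single code path and produce identical results.
#'
#' @param collection a `bioc_collection` or a character scalar of BioC XML.
#' @param entity_types entity types to annotate (default: all available in
#'   the chosen lexicon).
#' @param relation_type_pairs list of unordered type pairs for relation
#'   extraction (default none).
#' @param mode output annotation mode, `"standoff"` (default) or
#'   `"inline"`.
#' @param include_offsets emit location anchors in standoff mode.
#' @param filter optional sentence-filter expression (string or
#'   `filter_expr`); unselected sentences are dropped from the response.
#' @param lexicon_id name of the pre-loaded vocabulary to use.
#' @return a list of class `annotation_request`.
#' @export
annotation_request <- function(collection, entity_types = NULL,
                               relation_type_pairs = NULL,
                               mode = c("standoff", "inline"),
                               include_offsets = TRUE, filter = NULL,
                               lexicon_id = NULL) {
  structure(list(collection = collection, entity_types = entity_types,
                 relation_type_pairs = relation_type_pairs,
                 mode = match.arg(mode), include_offsets = include_offsets,
                 filter = filter, lexicon_id = lexicon_id),
            class = "annotation_request")
}

#' Handle an annotation request end to end
#'
#' Validates the payload, runs the full pipeline (annotate, disambiguate,
#' pair up, score, rank) and serializes the enriched collection in the
#' requested mode. The handler is stateless: identical requests yield
#' byte-identical responses. Invalid input raises a condition of class
#' `biocmine_bad_request` (or `biocmine_payload_too_large`), which the REST
#' layer maps to 400/413 responses.
#'
#' @param request an [annotation_request()].
#' @param lexicons a single [lexicon()] or a named list of lexicons.
#' @param config a [mine_config()].
#' @param rules optional [type_rules()] table.
#' @param patterns optional pattern table.
#' @param parses optional named parse list.
#' @return character scalar: the BioC XML response.
#' @export
handle_annotate <- function(request, lexicons, config = mine_config(),
                            rules = NULL, patterns = NULL, parses = NULL) {
  if (inherits(lexicons, "lexicon")) lexicons <- list(default = lexicons)
  lex_id <- request$lexicon_id %||% names(lexicons)[1L]
  if (!lex_id %in% names(lexicons)) {
    stop_bad_request(sprintf(
      "unknown lexicon '%s'; available vocabularies: %s",
      lex_id, paste(names(lexicons), collapse = ", ")))
  }
  lex <- lexicons[[lex_id]]
  coll <- request$collection
  if (is.character(coll)) {
    coll <- tryCatch(read_bioc(coll), error = function(e) {
      stop_bad_request(paste("invalid BioC payload:", conditionMessage(e)))
    })
  }
  payload_chars <- sum(vapply(coll$documents,
                              function(d) nchar(document_text(d)), numeric(1)))
  if (payload_chars > config$max_chars) {
    stop_payload_too_large(sprintf(
      "payload of %d characters exceeds the configured limit of %d",
      payload_chars, as.integer(config$max_chars)))
  }
  if (!is.null(request$entity_types)) {
    unknown <- setdiff(request$entity_types, lex$types_available)
    if (length(unknown)) {
      stop_bad_request(sprintf(
        "requested entity type(s) not in lexicon '%s': %s (available: %s)",
        lex_id, paste(unknown, collapse = ", "),
        paste(lex$types_available, collapse = ", ")))
    }
  }
  filt <- request$filter
  if (!is.null(filt) && is.character(filt)) {
    filt <- tryCatch(parse_filter(filt, known_types = lex$types_available),
                     error = function(e) stop_bad_request(conditionMessage(e)))
  }
  # the pipeline always sees every entity type (species mentions drive
  # organism disambiguation even when only, say, chemicals were requested);
  # the type restriction is applied to the finished result, which makes it
  # exactly equivalent to post-hoc filtering of the unrestricted response
  res <- mine_collection(coll, lex,
                         relation_type_pairs = request$relation_type_pairs,
                         parses = parses, patterns = patterns, rules = rules,
                         config = config)
  out <- res$collection
  if (!is.null(request$entity_types)) {
    out$documents <- lapply(out$documents, restrict_types,
                            types = request$entity_types)
  }
  if (!is.null(filt)) {
    out$documents <- lapply(out$documents, filter_document, expr = filt)
  }
  write_bioc(out, mode = request$mode, overlap_policy = "longest-wins",
             include_offsets = request$include_offsets)
}

# drop annotations outside the requested types, plus relations that
# reference them
restrict_types <- function(doc, types) {
  kept <- character(0)
  prune <- function(anns) Filter(function(a) ann_type(a) %in% types, anns)
  for (pi in seq_along(doc$passages)) {
    p <- doc$passages[[pi]]
    p$annotations <- prune(p$annotations)
    if (!is.null(p$sentences)) {
      p$sentences <- lapply(p$sentences, function(s) {
        s$annotations <- prune(s$annotations)
        s
      })
    }
    doc$passages[[pi]] <- p
  }
  ids <- vapply(document_annotations(doc), function(a) a$id, character(1))
  for (pi in seq_along(doc$passages)) {
    doc$passages[[pi]]$relations <- Filter(function(r) {
      all(r$nodes$refid %in% ids)
    }, doc$passages[[pi]]$relations)
  }
  doc
}

# keep only sentences selected by the filter; drop annotations of removed
# sentences and relations that reference them; re-enumerate densely,
# recording the original ordinal in a source_index infon
filter_document <- function(doc, expr) {
  res <- apply_filter(doc, expr)
  keep <- res$selected
  kept_ann <- character(0)
  for (pi in seq_along(doc$passages)) {
    ss <- doc$passages[[pi]]$sentences
    if (is.null(ss)) next
    ss <- Filter(function(s) s$index %in% keep, ss)
    ss <- lapply(ss, function(s) {
      s$infons$source_index <- as.character(s$index)
      s
    })
    kept_ann <- c(kept_ann, unlist(lapply(ss, function(s)
      vapply(s$annotations, function(a) a$id, character(1)))))
    doc$passages[[pi]]$sentences <- ss
  }
  for (pi in seq_along(doc$passages)) {
    kept_ann <- c(kept_ann, vapply(doc$passages[[pi]]$annotations,
                                   function(a) a$id, character(1)))
    doc$passages[[pi]]$relations <- Filter(function(r) {
      all(r$nodes$refid %in% kept_ann)
    }, doc$passages[[pi]]$relations)
  }
  renumber_sentences(doc)
}

#' Serve the annotation pipeline over HTTP
#'
#' A deliberately small, single-threaded HTTP/1.1 loop over base-R sockets
#' exposing two routes: `POST /annotate` (BioC XML body; query parameters
#' `types`, `relations`, `mode`, `filter`, `lexicon`, `offsets`) and
#' `GET /lexicons` (the available vocabulary names). Each request is
#' dispatched to [handle_annotate()], so CLI, in-process and HTTP usage all
#' share one code path. Intended for local curation setups, not as a
#' hardened internet-facing server.
#'
#' @param lexicons named list of [lexicon()] objects.
#' @inheritParams handle_annotate
#' @param host,port listening address.
#' @param max_requests stop after this many requests (for supervised runs;
#'   default unlimited).
#' @return invisibly, the number of requests served.
#' @export
serve_rest <- function(lexicons, config = mine_config(), rules = NULL,
                       patterns = NULL, host = "127.0.0.1", port = 8600L,
                       max_requests = Inf) {
  if (inherits(lexicons, "lexicon")) lexicons <- list(default = lexicons)
  served <- 0L
  message(sprintf("biocmine service listening on %s:%d", host, port))
  while (served < max_requests) {
    con <- socketConnection(host = host, port = port, server = TRUE,
                            blocking = TRUE, open = "r+b")
    tryCatch({
      req <- read_http_request(con)
      resp <- tryCatch(
        dispatch_request(req, lexicons, config, rules, patterns),
        biocmine_payload_too_large = function(e)
          http_response(413L, "text/plain", conditionMessage(e)),
        biocmine_bad_request = function(e)
          http_response(400L, "text/plain", conditionMessage(e)),
        error = function(e)
          http_response(500L, "text/plain", conditionMessage(e)))
      writeChar(resp, con, eos = NULL)
    }, error = function(e) message("request failed: ", conditionMessage(e)),
      finally = close(con))
    served <- served + 1L
  }
  invisible(served)
}

read_http_request <- function(con) {
  request_line <- readLines(con, n = 1L, warn = FALSE)
  if (!length(request_line)) stop("empty request", call. = FALSE)
  parts <- strsplit(trimws(request_line), " ", fixed = TRUE)[[1L]]
  headers <- character(0)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line) || !nzchar(trimws(line))) break
    headers <- c(headers, trimws(line))
  }
  clen <- 0L
  hit <- grep("^content-length:", headers, ignore.case = TRUE, value = TRUE)
  if (length(hit)) clen <- as.integer(trimws(sub("^[^:]+:", "", hit[1L])))
  body <- if (clen > 0L) {
    rawToChar(readBin(con, what = "raw", n = clen))
  } else ""
  target <- strsplit(parts[2L], "?", fixed = TRUE)[[1L]]
  query <- list()
  if (length(target) > 1L) {
    for (kv in strsplit(target[2L], "&", fixed = TRUE)[[1L]]) {
      kvp <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(kvp) == 2L) query[[kvp[1L]]] <- utils::URLdecode(kvp[2L])
    }
  }
  list(method = parts[1L], path = target[1L], query = query, body = body)
}

dispatch_request <- function(req, lexicons, config, rules, patterns) {
  if (req$method == "GET" && req$path == "/lexicons") {
    listing <- paste0("[", paste(sprintf("\"%s\"", names(lexicons)),
                                 collapse = ", "), "]")
    return(http_response(200L, "application/json", listing))
  }
  if (req$method == "POST" && req$path == "/annotate") {
    q <- req$query
    types <- if (!is.null(q$types)) strsplit(q$types, ",", fixed = TRUE)[[1L]]
    pairs <- if (!is.null(q$relations)) {
      lapply(strsplit(q$relations, ",", fixed = TRUE)[[1L]],
             function(p) strsplit(p, "-", fixed = TRUE)[[1L]])
    }
    request <- annotation_request(
      collection = req$body, entity_types = types,
      relation_type_pairs = pairs,
      mode = q$mode %||% "standoff",
      include_offsets = !identical(q$offsets, "false"),
      filter = q$filter, lexicon_id = q$lexicon)
    xml <- handle_annotate(request, lexicons, config, rules, patterns)
    return(http_response(200L, "application/xml", xml))
  }
  http_response(404L, "text/plain", paste("no route for", req$method, req$path))
}

http_response <- function(status, type, body) {
  reason <- c("200" = "OK", "400" = "Bad Request", "404" = "Not Found",
              "413" = "Payload Too Large", "500" = "Internal Server Error")
  paste0("HTTP/1.1 ", status, " ", reason[[as.character(status)]], "\r\n",
         "Content-Type: ", type, "; charset=utf-8\r\n",
         "Content-Length: ", nchar(body, type = "bytes"), "\r\n",
         "Connection: close\r\n\r\n", body)
}
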