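#' Fixture generation parameters
#'
#' Defines the statistical conditions the synthetic study corpus emulates:
#' vocabulary sizes per entity type, the rates of the three ambiguity
#' classes (common-word collisions, cross-type conflicts, cross-organism
#' identifier sharing), the density of planted gold relations realized
#' through a fixed inventory of positive/negative dependency-path shapes,
#' and the per-document focus-organism behaviour. The same seed always
#' produces byte-identical outputs.
#'
#' @param seed integer seed for the generator stream.
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per abstract (including the
#'   species-mention sentences, when present).
#' @param n_proteins number of protein base names.
#' @param n_chemicals,n_diseases,n_methods vocabulary sizes.
#' @param organisms named character vector: taxonomy id to species name.
#' @param ambig_common fraction of chemical surfaces that are verbatim
#'   common-language words (folD/SEX-style collisions).
#' @param ambig_type fraction of protein surfaces also registered as an
#'   experimental method (GFP-style cross-type ambiguity).
#' @param ambig_id fraction of protein base names registered in two
#'   organisms (cross-identifier ambiguity).
#' @param relation_density probability that a body sentence realizes a
#'   planted gold interaction through a positive path shape.
#' @param negative_density probability of a negative-pattern co-occurrence
#'   sentence.
#' @param cue_rate,amb_rate,entity_rate probabilities of method-cue,
#'   unresolved cross-type, and single-entity sentences.
#' @param species_mention_rate probability that a document states its focus
#'   organism explicitly (two species sentences are planted when it does).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_docs = 50L, sentences_per_doc = 10L,
                         n_proteins = 20L, n_chemicals = 12L, n_diseases = 8L,
                         n_methods = 6L,
                         organisms = c("taxon:4932" = "Saccharomyces cerevisiae",
                                       "taxon:562" = "Escherichia coli",
                                       "taxon:9606" = "Homo sapiens"),
                         ambig_common = 0.1, ambig_type = 0.1, ambig_id = 0.3,
                         relation_density = 0.1, negative_density = 0.15,
                         cue_rate = 0.08, amb_rate = 0.08, entity_rate = 0.2,
                         species_mention_rate = 0.9) {
  stopifnot(all(c(ambig_common, ambig_type, ambig_id, relation_density,
                  negative_density, cue_rate, amb_rate, entity_rate,
                  species_mention_rate) >= 0),
            all(c(ambig_common, ambig_type, ambig_id, relation_density,
                  negative_density, cue_rate, amb_rate, entity_rate,
                  species_mention_rate) <= 1))
  structure(list(
    seed = as.integer(seed), n_docs = as.integer(n_docs),
    sentences_per_doc = as.integer(sentences_per_doc),
    n_proteins = as.integer(n_proteins), n_chemicals = as.integer(n_chemicals),
    n_diseases = as.integer(n_diseases), n_methods = as.integer(n_methods),
    organisms = organisms, ambig_common = ambig_common,
    ambig_type = ambig_type, ambig_id = ambig_id,
    relation_density = relation_density, negative_density = negative_density,
    cue_rate = cue_rate, amb_rate = amb_rate, entity_rate = entity_rate,
    species_mention_rate = species_mention_rate), class = "fixture_spec")
}

# sampling helpers immune to R's length-1 `sample(x)` expansion
pick <- function(x, n = 1L) x[sample.int(length(x), n)]

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# common-language filler vocabulary; every word is in the shipped stoplist,
# so collision surfaces drawn from it are flagged case-sensitive
.filler_words <- c(
  "the", "of", "and", "in", "to", "was", "were", "for", "with", "that",
  "these", "results", "samples", "analysis", "during", "between", "further",
  "however", "observed", "measured", "obtained", "present", "previous",
  "consistent", "significant", "experiments", "conditions", "approach",
  "compared", "reported", "described", "similar", "findings", "relative")

.positive_verbs <- c(interacted = "interact",
                     coimmunoprecipitated = "coimmunoprecipitate",
                     associated = "associate")
.negative_verbs <- c(colocalized = "colocalize")

gen_names <- function(n, used, style = c("protein", "word"), min_len = 6L) {
  style <- match.arg(style)
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    nsyl <- sample(2:3, 1L)
    base <- paste(vapply(seq_len(nsyl), function(i)
      paste0(sample(cons, 1L), sample(vow, 1L)), character(1)), collapse = "")
    surface <- if (style == "protein") {
      paste0(toupper(substr(base, 1L, 1L)), substr(base, 2L, nchar(base)),
             sample(1:9, 1L), "p")
    } else {
      while (nchar(base) < min_len) base <- paste0(base, sample(cons, 1L), sample(vow, 1L))
      base
    }
    key <- normalize_surface(surface)
    if (key %in% used$keys || tolower(surface) %in% .filler_words) next
    used$keys <- c(used$keys, key)
    out <- c(out, surface)
  }
  out
}

#' Generate a synthetic terminology lexicon
#'
#' Builds a lexicon table with, at the configured rates: chemical surfaces
#' colliding verbatim with common-language words, protein surfaces also
#' registered as experimental methods, and protein base names shared by two
#' organisms (one concept identifier per organism). Alongside the table, the
#' matching context-rule table (method-cue rules for every cross-type
#' surface) is returned.
#'
#' @param spec a [fixture_spec()].
#' @return list with `table` (lexicon tibble incl. `organism_id`), `rules`
#'   (a [type_rules()] table) and bookkeeping vectors used by
#'   [gen_corpus()].
#' @export
gen_lexicon <- function(spec) {
  with_seed(spec$seed, {
    used <- new.env(parent = emptyenv())
    used$keys <- character(0)
    orgs <- names(spec$organisms)
    rows <- list()
    add <- function(surface, concept_id, entity_type, preferred_name, source_db,
                    organism_id = NA_character_) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        surface = surface, concept_id = concept_id, entity_type = entity_type,
        preferred_name = preferred_name, source_db = source_db,
        organism_id = organism_id)
    }
    # species entries
    for (o in orgs) {
      add(spec$organisms[[o]], paste0("TAX:", sub("taxon:", "", o)),
          "species", spec$organisms[[o]], "taxonomy-synthetic", o)
    }
    # proteins: base names, a fraction shared across two organisms
    bases <- gen_names(spec$n_proteins, used, "protein")
    n_shared <- floor(spec$ambig_id * spec$n_proteins)
    shared <- seq_len(n_shared)
    protein_orgs <- vector("list", spec$n_proteins)
    for (i in seq_len(spec$n_proteins)) {
      protein_orgs[[i]] <- if (i %in% shared) sample(orgs, 2L) else sample(orgs, 1L)
      for (o in protein_orgs[[i]]) {
        add(bases[i], sprintf("P:%s:%s", sub("taxon:", "", o), toupper(bases[i])),
            "protein", bases[i], "uniprot-synthetic", o)
      }
    }
    # cross-type: some single-organism protein surfaces double as methods
    single_org <- setdiff(seq_len(spec$n_proteins), shared)
    n_cross <- min(length(single_org), floor(spec$ambig_type * spec$n_proteins))
    cross_idx <- if (n_cross) pick(single_org, n_cross) else integer(0)
    for (i in cross_idx) {
      add(bases[i], sprintf("M:X%02d", i), "experimental_method",
          paste(bases[i], "assay"), "methods-synthetic")
    }
    # chemicals: a fraction collide verbatim with common words
    n_coll <- floor(spec$ambig_common * spec$n_chemicals)
    candidates <- .filler_words[nchar(.filler_words) >= 6L]
    collision_words <- if (n_coll) sample(candidates, n_coll) else character(0)
    chem_surfaces <- c(collision_words,
                       gen_names(spec$n_chemicals - n_coll, used, "word"))
    for (i in seq_along(chem_surfaces)) {
      add(chem_surfaces[i], sprintf("C:%03d", i), "chemical",
          chem_surfaces[i], "chebi-synthetic")
    }
    # diseases: half get a two-token surface to exercise multi-token matching
    dis_bases <- gen_names(spec$n_diseases, used, "word")
    dis_surfaces <- ifelse(seq_along(dis_bases) %% 2L == 0L,
                           paste(dis_bases, "syndrome"), dis_bases)
    for (i in seq_along(dis_surfaces)) {
      add(dis_surfaces[i], sprintf("D:%03d", i), "disease",
          dis_surfaces[i], "mesh-synthetic")
    }
    # experimental methods (beyond the cross-type ones)
    met <- gen_names(spec$n_methods, used, "word")
    for (i in seq_along(met)) {
      add(met[i], sprintf("M:%03d", i), "experimental_method", met[i],
          "methods-synthetic")
    }
    table <- do.call(rbind, rows)
    rules <- if (length(cross_idx)) {
      type_rules(tibble::tibble(
        pattern = normalize_surface(bases[cross_idx]),
        preferred_type = "experimental_method",
        cues = "microscopy,fluorescence", window = 4L))
    } else {
      type_rules(tibble::tibble(pattern = character(0),
                                preferred_type = character(0),
                                cues = character(0), window = integer(0)))
    }
    list(table = table, rules = rules, protein_bases = bases,
         protein_orgs = protein_orgs, cross_idx = cross_idx,
         collision_words = collision_words)
  })
}

protein_concept <- function(base, org) {
  sprintf("P:%s:%s", sub("taxon:", "", org), toupper(base))
}

#' Generate a synthetic BioC corpus with planted entities and relations
#'
#' Every document gets a title passage and a sentence-segmented abstract.
#' Body sentences realize, at the configured rates: gold protein
#' interactions through positive path shapes ("X interacted with Y"),
#' negative co-occurrences through negative shapes ("X colocalized with Y",
#' "X was detected near Y"), method-cue and unresolved cross-type mentions,
#' single-entity mentions and common-word filler. A ground-truth manifest
#' records every planted entity span, the per-sentence distant-supervision
#' label and the sentence template (which [gen_parses()] turns into a
#' consistent dependency tree).
#'
#' @param spec a [fixture_spec()].
#' @param lex_fixture result of [gen_lexicon()] for the same spec.
#' @return list with `collection` (un-annotated `bioc_collection`), `gold`
#'   (tibble `document_id`, `id1`, `id2`, `pair`) and `manifest` (list of
#'   tibbles `entities` and `sentences`).
#' @export
gen_corpus <- function(spec, lex_fixture) {
  with_seed(spec$seed + 1L, {
    orgs <- names(spec$organisms)
    bases <- lex_fixture$protein_bases
    protein_orgs <- lex_fixture$protein_orgs
    cross_surfaces <- bases[lex_fixture$cross_idx]
    chem_rows <- lex_fixture$table[lex_fixture$table$entity_type == "chemical", ]
    dis_rows <- lex_fixture$table[lex_fixture$table$entity_type == "disease", ]
    docs <- list()
    gold_rows <- list()
    ent_rows <- list()
    sent_rows <- list()
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc%03d", d)
      focus <- sample(orgs, 1L)
      has_species <- stats::runif(1L) < spec$species_mention_rate
      pool_idx <- which(vapply(protein_orgs, function(po) focus %in% po, logical(1)))
      pool_idx <- pick(pool_idx, min(6L, length(pool_idx)))
      n_species_sent <- if (has_species) 2L else 0L
      n_body <- spec$sentences_per_doc - n_species_sent
      cats <- sample(c("pos", "neg", "cue", "amb", "entity", "filler"), n_body,
                     replace = TRUE,
                     prob = c(spec$relation_density, spec$negative_density,
                              if (length(cross_surfaces)) spec$cue_rate else 0,
                              if (length(cross_surfaces)) spec$amb_rate else 0,
                              spec$entity_rate,
                              max(0.01, 1 - spec$relation_density -
                                    spec$negative_density - spec$cue_rate -
                                    spec$amb_rate - spec$entity_rate)))
      doc_gold <- character(0)
      # build sentence payloads: list(tokens, template, verb, entities);
      # gold-bearing slots are realized first so that negative co-occurrences
      # can be drawn outside the document's final gold set, whatever the
      # slot order
      payloads <- vector("list", length(cats))
      for (slot in order(cats != "pos")) {
        cat <- cats[slot]
        payloads[[slot]] <- switch(cat,
          pos = {
            ij <- pick(pool_idx, 2L)
            verb <- sample(names(.positive_verbs), 1L)
            cid <- protein_concept(bases[ij], focus)
            doc_gold <- unique(c(doc_gold, unordered_pair(cid[1L], cid[2L])))
            gold_rows[[length(gold_rows) + 1L]] <- tibble::tibble(
              document_id = doc_id, id1 = cid[1L], id2 = cid[2L])
            list(template = "pos", verb = verb,
                 tokens = c(bases[ij[1L]], verb, "with", bases[ij[2L]], "."),
                 entities = list(
                   list(pos = 1L, surface = bases[ij[1L]], concept = cid[1L],
                        type = "protein", org = focus),
                   list(pos = 4L, surface = bases[ij[2L]], concept = cid[2L],
                        type = "protein", org = focus)))
          },
          neg = {
            repeat {
              ij <- pick(pool_idx, 2L)
              cid <- protein_concept(bases[ij], focus)
              if (!unordered_pair(cid[1L], cid[2L]) %in% doc_gold) break
            }
            if (stats::runif(1L) < 0.5) {
              verb <- sample(names(.negative_verbs), 1L)
              list(template = "neg1", verb = verb,
                   tokens = c(bases[ij[1L]], verb, "with", bases[ij[2L]], "."),
                   entities = list(
                     list(pos = 1L, surface = bases[ij[1L]], concept = cid[1L],
                          type = "protein", org = focus),
                     list(pos = 4L, surface = bases[ij[2L]], concept = cid[2L],
                          type = "protein", org = focus)))
            } else {
              list(template = "neg2", verb = "detect",
                   tokens = c(bases[ij[1L]], "was", "detected", "near",
                              bases[ij[2L]], "."),
                   entities = list(
                     list(pos = 1L, surface = bases[ij[1L]], concept = cid[1L],
                          type = "protein", org = focus),
                     list(pos = 5L, surface = bases[ij[2L]], concept = cid[2L],
                          type = "protein", org = focus)))
            }
          },
          cue = {
            i <- pick(lex_fixture$cross_idx, 1L)
            list(template = "cue", verb = "confirm",
                 tokens = c(bases[i], "microscopy", "confirmed", "the",
                            "localization", "."),
                 entities = list(
                   list(pos = 1L, surface = bases[i],
                        concept = sprintf("M:X%02d", i),
                        type = "experimental_method", org = NA_character_)))
          },
          amb = {
            i <- pick(lex_fixture$cross_idx, 1L)
            org <- protein_orgs[[i]][1L]
            list(template = "amb", verb = "increase",
                 tokens = c(bases[i], "expression", "increased", "steadily", "."),
                 entities = list(
                   list(pos = 1L, surface = bases[i],
                        concept = protein_concept(bases[i], org),
                        type = "protein", org = org)))
          },
          entity = {
            row <- if (stats::runif(1L) < 0.5) {
              chem_rows[sample(nrow(chem_rows), 1L), ]
            } else {
              dis_rows[sample(nrow(dis_rows), 1L), ]
            }
            etoks <- strsplit(row$surface, " ", fixed = TRUE)[[1L]]
            list(template = "entity", verb = "increase",
                 tokens = c("The", etoks, "level", "increased", "."),
                 entities = list(
                   list(pos = 2L, surface = row$surface, concept = row$concept_id,
                        type = row$entity_type, org = NA_character_)))
          },
          filler = {
            n <- sample(6:9, 1L)
            words <- sample(.filler_words, n, replace = TRUE)
            if (length(lex_fixture$collision_words) &&
                stats::runif(1L) < 0.6) {
              words[sample.int(n, 1L)] <- pick(lex_fixture$collision_words, 1L)
            }
            list(template = "filler", verb = NA_character_,
                 tokens = c(words, "."), entities = list())
          })
      }
      if (has_species) {
        sp_payload <- list(
          template = "species", verb = "perform",
          tokens = c("These", "experiments", "were", "performed", "in",
                     strsplit(spec$organisms[[focus]], " ", fixed = TRUE)[[1L]],
                     "cultures", "."),
          entities = list(list(
            pos = 6L, surface = spec$organisms[[focus]],
            concept = paste0("TAX:", sub("taxon:", "", focus)),
            type = "species", org = focus)))
        payloads <- append(payloads, list(sp_payload), after = 0L)
        payloads <- append(payloads, list(sp_payload), after = length(payloads))
      }
      # title sentence (never carries planted entities)
      title_tokens <- c("Functional", "analysis", "of", "cellular",
                        "mechanisms", ".")
      payloads <- append(payloads, list(list(template = "title",
                                             verb = NA_character_,
                                             tokens = title_tokens,
                                             entities = list())), after = 0L)
      # realize text with exact offsets; title is its own passage
      built <- realize_sentences(payloads, doc_id)
      ent_rows <- c(ent_rows, built$entities)
      sent_rows <- c(sent_rows, built$sentences)
      docs[[length(docs) + 1L]] <- built$document
    }
    gold <- if (length(gold_rows)) {
      unique(do.call(rbind, gold_rows))
    } else {
      tibble::tibble(document_id = character(0), id1 = character(0),
                     id2 = character(0))
    }
    list(
      collection = bioc_collection(documents = docs, source = "biocmine-fixture",
                                   date = "2014-11-27",
                                   infons = list(seed = as.character(spec$seed))),
      gold = gold_table(gold),
      manifest = list(
        entities = if (length(ent_rows)) do.call(rbind, ent_rows) else
          tibble::tibble(document_id = character(0), sentence_index = integer(0),
                         offset = integer(0), length = integer(0),
                         surface = character(0), concept_id = character(0),
                         entity_type = character(0), organism_id = character(0)),
        sentences = do.call(rbind, sent_rows)))
  })
}

# lay the sentences out with exact offsets; sentence 0 forms the title
# passage, the rest the abstract passage
realize_sentences <- function(payloads, doc_id) {
  ent_rows <- list()
  sent_rows <- list()
  sentences <- list()
  offset <- 0L
  for (k in seq_along(payloads)) {
    pl <- payloads[[k]]
    toks <- pl$tokens
    widths <- nchar(toks)
    starts <- offset + c(0L, cumsum(widths[-length(widths)] + 1L))
    text <- paste(toks, collapse = " ")
    sent_index <- k - 1L
    for (e in pl$entities) {
      n_tok <- length(strsplit(e$surface, " ", fixed = TRUE)[[1L]])
      ent_rows[[length(ent_rows) + 1L]] <- tibble::tibble(
        document_id = doc_id, sentence_index = sent_index,
        offset = starts[e$pos], length = nchar(e$surface),
        surface = e$surface, concept_id = e$concept,
        entity_type = e$type, organism_id = e$org)
    }
    sent_rows[[length(sent_rows) + 1L]] <- tibble::tibble(
      document_id = doc_id, sentence_index = sent_index,
      template = pl$template, verb = pl$verb, label = if (pl$template == "pos")
        "positive" else "negative",
      tokens = list(toks),
      entity_positions = list(vapply(pl$entities, function(e) e$pos, integer(1))))
    sentences[[length(sentences) + 1L]] <- bioc_sentence(
      offset = starts[1L], text = text, index = sent_index)
    offset <- starts[length(starts)] + widths[length(widths)] + 1L
  }
  title <- sentences[[1L]]
  abstract <- sentences[-1L]
  doc <- bioc_document(doc_id, passages = list(
    bioc_passage(offset = title$offset,
                 text = title$text,
                 infons = list(type = "title"),
                 sentences = list(title)),
    bioc_passage(offset = abstract[[1L]]$offset,
                 text = paste(vapply(abstract, function(s) s$text, character(1)),
                              collapse = " "),
                 infons = list(type = "abstract"),
                 sentences = abstract)))
  list(document = renumber_sentences(doc), entities = ent_rows,
       sentences = sent_rows)
}

#' Generate CoNLL dependency parses consistent with the planted templates
#'
#' Deterministically derives one dependency tree per sentence from the
#' corpus manifest: positive shapes attach the first entity to the verb as
#' `subj` and the second as `pobj` (top node = the verb's lemma), negative
#' shapes use their own inventory paths, filler sentences get a simple
#' chain. No randomness is involved, so parses always align with the
#' corpus they were generated for.
#'
#' @param manifest the `manifest` element of a [gen_corpus()] result.
#' @return named list: document id to CoNLL text (6 columns, blank-line
#'   sentence separation).
#' @export
gen_parses <- function(manifest) {
  sent <- manifest$sentences
  out <- list()
  for (doc_id in unique(sent$document_id)) {
    sub <- sent[sent$document_id == doc_id, ]
    sub <- sub[order(sub$sentence_index), ]
    blocks <- vapply(seq_len(nrow(sub)), function(i) {
      conll_block(sub$tokens[[i]], sub$template[i], sub$verb[i])
    }, character(1))
    out[[doc_id]] <- paste(blocks, collapse = "\n\n")
  }
  out
}

.verb_lemmas <- c(.positive_verbs, .negative_verbs,
                  detected = "detect", confirmed = "confirm",
                  increased = "increase", performed = "perform", was = "be",
                  were = "be")

conll_block <- function(tokens, template, verb) {
  n <- length(tokens)
  lemma <- tolower(tokens)
  known <- lemma %in% names(.verb_lemmas)
  lemma[known] <- .verb_lemmas[lemma[known]]
  head <- rep(0L, n)
  label <- rep("dep", n)
  pos <- rep("NN", n)
  pos[tokens == "."] <- "PUNCT"
  if (template %in% c("pos", "neg1")) {
    head <- c(2L, 0L, 2L, 2L, 2L)
    label <- c("subj", "root", "modpp", "pobj", "punct")
    pos[2L] <- "VBD"
  } else if (template == "neg2") {
    head <- c(3L, 3L, 0L, 3L, 4L, 3L)
    label <- c("subjpass", "aux", "root", "modpp", "pobj", "punct")
    pos[3L] <- "VBN"
  } else if (template == "cue") {
    head <- c(2L, 3L, 0L, 5L, 3L, 3L)
    label <- c("nn", "subj", "root", "det", "obj", "punct")
    pos[3L] <- "VBD"
  } else if (template == "amb") {
    head <- c(2L, 3L, 0L, 3L, 3L)
    label <- c("nn", "subj", "root", "adv", "punct")
    pos[3L] <- "VBD"
  } else if (template == "entity") {
    k <- n - 4L  # entity token count
    lvl <- 2L + k
    head <- c(lvl,                       # The -> level
              if (k > 1L) seq(3L, 1L + k) else integer(0),  # Xi -> X(i+1)
              lvl,                       # last X -> level
              lvl + 1L,                  # level -> increased
              0L,                        # increased (root)
              lvl + 1L)                  # . -> increased
    label <- c("det", rep("nn", k), "subj", "root", "punct")
    pos[lvl + 1L] <- "VBD"
  } else if (template == "species") {
    head <- c(2L, 4L, 4L, 0L, 4L, 7L, 8L, 5L, 4L)
    label <- c("det", "subjpass", "aux", "root", "modpp", "nn", "nn", "pobj",
               "punct")
    pos[4L] <- "VBN"
  } else {  # filler / title: forward chain, last word is the root
    root <- n - 1L
    head <- c(seq(2L, root), 0L, root)[seq_len(n)]
    if (n == 2L) head <- c(0L, 1L)
    label <- c(rep("dep", n - 2L), "root", "punct")
    if (n == 2L) label <- c("root", "punct")
  }
  paste(sprintf("%d\t%s\t%s\t%s\t%d\t%s",
                seq_len(n), tokens, lemma, pos, head, label), collapse = "\n")
}

#' Write generated parses to per-document CoNLL files
#'
#' @param parses named list from [gen_parses()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_parses <- function(parses, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc_id in names(parses)) {
    writeLines(parses[[doc_id]], file.path(dir, paste0(doc_id, ".conll")))
  }
  invisible(dir)
}

#' Read per-document CoNLL files written by [write_parses()]
#'
#' @param dir directory of `<document id>.conll` files.
#' @param collection the matching collection.
#' @return named list of `dependency_tree` lists.
#' @export
read_parses_dir <- function(dir, collection) {
  out <- list()
  for (doc in collection$documents) {
    path <- file.path(dir, paste0(doc$id, ".conll"))
    if (file.exists(path)) out[[doc$id]] <- load_parses(path, doc)
  }
  out
}

#' Generate the complete fixture bundle
#'
#' Convenience wrapper tying the three generators together.
#'
#' @param spec a [fixture_spec()].
#' @param stoplist stoplist for the built lexicon.
#' @return list with `spec`, `lexicon_table`, `lexicon`, `rules`,
#'   `collection`, `gold`, `manifest`, `parses` (CoNLL text by document)
#'   and `trees` (loaded `dependency_tree` lists by document).
#' @export
gen_fixtures <- function(spec = fixture_spec(), stoplist = default_stoplist()) {
  lf <- gen_lexicon(spec)
  corpus <- gen_corpus(spec, lf)
  parses <- gen_parses(corpus$manifest)
  trees <- list()
  for (doc in corpus$collection$documents) {
    trees[[doc$id]] <- load_parses(parses[[doc$id]], doc)
  }
  list(spec = spec, lexicon_table = lf$table,
       lexicon = lexicon(lf$table, stoplist = stoplist), rules = lf$rules,
       collection = corpus$collection, gold = corpus$gold,
       manifest = corpus$manifest, parses = parses, trees = trees)
}

#' Attach ground-truth annotations from a manifest
#'
#' Places the manifest's entity spans on the collection's sentences as
#' resolved annotations — the ground-truth counterpart of running the
#' recognizer, used as the oracle for distant-supervision labelling.
#'
#' @param collection a fixture collection.
#' @param manifest the matching manifest.
#' @return the collection with annotations attached.
#' @export
attach_manifest_annotations <- function(collection, manifest) {
  ents <- manifest$entities
  for (di in seq_along(collection$documents)) {
    doc <- collection$documents[[di]]
    sub <- ents[ents$document_id == doc$id, ]
    k <- 0L
    for (pi in seq_along(doc$passages)) {
      ss <- doc$passages[[pi]]$sentences %||% list()
      for (si in seq_along(ss)) {
        s <- ss[[si]]
        rows <- sub[sub$sentence_index == s$index, ]
        anns <- lapply(seq_len(nrow(rows)), function(r) {
          k <<- k + 1L
          infons <- list(type = rows$entity_type[r],
                         concept_id = rows$concept_id[r],
                         preferred_name = rows$surface[r],
                         score = "1", sentence_index = as.character(s$index))
          if (!is.na(rows$organism_id[r])) {
            infons$organism_id <- rows$organism_id[r]
          }
          bioc_annotation(id = sprintf("G%d", k), text = rows$surface[r],
                          offset = rows$offset[r], length = rows$length[r],
                          infons = infons)
        })
        doc$passages[[pi]]$sentences[[si]]$annotations <- anns
      }
    }
    collection$documents[[di]] <- doc
  }
  collection
}

#' Planted-relation recovery of a ranked interaction list
#'
#' Deduplicates the ranked candidates by (document, unordered concept pair)
#' keeping the best rank, takes the top `|gold|` of them, and reports the
#' fraction of gold interactions present.
#'
#' @param interactions ranked tibble from [mine_collection()].
#' @param gold gold table.
#' @return recovery fraction in `[0, 1]` (`NA` for an empty gold set).
#' @export
relation_recovery <- function(interactions, gold) {
  gold_keys <- unique(paste(gold$document_id, gold$pair))
  if (!length(gold_keys)) return(NA_real_)
  if (!nrow(interactions)) return(0)
  key <- paste(interactions$document_id, interactions$pair)
  dedup <- interactions[!duplicated(key), ]
  top <- utils::head(dedup, length(gold_keys))
  mean(gold_keys %in% paste(top$document_id, top$pair))
}

#' Entity-level precision/recall against the manifest
#'
#' A predicted annotation (document, offset, length, type, resolved concept)
#' is correct when the manifest records exactly that entity.
#'
#' @param collection annotated collection (pipeline output).
#' @param manifest fixture manifest.
#' @return list with `precision`, `recall`, `n_predicted`, `n_gold`.
#' @export
entity_scores <- function(collection, manifest) {
  ents <- manifest$entities
  gold_keys <- paste(ents$document_id, ents$offset, ents$length,
                     ents$entity_type, ents$concept_id)
  pred_keys <- character(0)
  for (doc in collection$documents) {
    for (a in document_annotations(doc)) {
      pred_keys <- c(pred_keys, paste(doc$id, ann_offset(a), ann_length(a),
                                      ann_type(a), ann_concept(a)))
    }
  }
  list(precision = if (length(pred_keys)) mean(pred_keys %in% gold_keys) else NA_real_,
       recall = if (length(gold_keys)) mean(gold_keys %in% pred_keys) else NA_real_,
       n_predicted = length(pred_keys), n_gold = length(gold_keys))
}
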