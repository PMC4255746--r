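test_that("tokenizer yields offsets that slice the input exactly", {
  toks <- tokenize("Tim18p coimmunoprecipitated with Tim12p")
  # frozen from direct character counting (word lengths 6, 20, 4, 6)
  expect_identical(toks$offset, c(0L, 7L, 28L, 33L))
  expect_identical(toks$text[4L], "Tim12p")
  expect_identical(nrow(tokenize("")), 0L)
})

test_that("hyphenated words split into word and punctuation tokens that reconstruct the input", {
  text <- "IL-2-dependent"
  toks <- tokenize(text)
  expect_identical(toks$text, c("IL", "-", "2", "-", "dependent"))
  rebuilt <- vapply(seq_len(nrow(toks)), function(i)
    substr(text, toks$offset[i] + 1L, toks$offset[i] + toks$length[i]),
    character(1))
  expect_identical(rebuilt, toks$text)
})

test_that("surface normalization unifies case, hyphen, Greek and plural variants", {
  expect_identical(normalize_surface(c("IL-2", "Il 2")), c("il2", "il2"))
  expect_identical(normalize_surface(c("alpha-synuclein", "α-synuclein")),
                   c("alphasynuclein", "alphasynuclein"))
  expect_identical(normalize_surface("receptors"), "receptor")
  expect_identical(normalize_surface("class"), "class")  # -ss guard
})

test_that("normalization is idempotent on random strings", {
  set.seed(101)
  alphabet <- c(letters, LETTERS, 0:9, "-", "/", " ", "α", "β", "s")
  strings <- replicate(1000, paste(sample(alphabet, sample(1:12, 1L),
                                          replace = TRUE), collapse = ""))
  once <- normalize_surface(strings)
  expect_identical(normalize_surface(once), once)
})

test_that("lexicon loading builds the index, keeps ambiguity and flags case-sensitive entries", {
  tsv <- paste(
    "surface\tconcept_id\tentity_type\tpreferred_name\tsource_db",
    "Tim18p\tP1\tprotein\tTIM18\tuniprot",
    "Tim-18p\tP1\tprotein\tTIM18\tuniprot",
    "Tim12p\tP2\tprotein\tTIM12\tuniprot",
    sep = "\n")
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  writeLines(tsv, path)
  lex <- load_lexicon(path)
  expect_identical(nrow(lex$entries), 3L)
  expect_true(length(ls(lex$index)) >= 2L)

  # folD (short) and SEX (stoplist collision) are case-sensitive
  lex2 <- lexicon(tibble::tibble(
    surface = c("folD", "SEX", "aspirin"),
    concept_id = c("G1", "C1", "C2"),
    entity_type = c("gene", "chemical", "chemical"),
    preferred_name = c("folD", "sodium ethyl xanthate", "aspirin"),
    source_db = "db"))
  cs <- setNames(lex2$entries$case_sensitive, lex2$entries$surface)
  expect_true(cs[["folD"]])
  expect_true(cs[["SEX"]])
  expect_false(cs[["aspirin"]])

  # one surface, two same-type ids -> one key, two entries
  lex3 <- lexicon(tibble::tibble(
    surface = c("Adh1p", "Adh1p"), concept_id = c("Y1", "H1"),
    entity_type = "protein", preferred_name = "ADH1", source_db = "db"),
    stoplist = character(0))
  expect_identical(nrow(biocmine:::lexicon_lookup(lex3, "adh1p")), 2L)
})

test_that("missing columns and empty surfaces are rejected at load time", {
  expect_error(lexicon(tibble::tibble(surface = "x", concept_id = "c")),
               "entity_type")
  expect_warning(
    lex <- lexicon(tibble::tibble(
      surface = c("", "ok-term"), concept_id = c("c1", "c2"),
      entity_type = "chemical", preferred_name = "n", source_db = "db")),
    "empty surface")
  expect_identical(nrow(lex$entries), 1L)
})

test_that("the matcher finds dictionary terms at exact offsets and honours exact-case rules", {
  lex <- tiny_protein_lexicon()
  anns <- annotate_text("Tim18p binds Tim12p", 0L, lex)
  expect_length(anns, 2L)
  expect_identical(vapply(anns, function(a) a$locations$offset[1L], integer(1)),
                   c(0L, 13L))
  expect_identical(vapply(anns, function(a) infon(a, "concept_id"), character(1)),
                   c("P1", "P2"))

  fold_lex <- lexicon(tibble::tibble(
    surface = "folD", concept_id = "G1", entity_type = "gene",
    preferred_name = "folD", source_db = "db"))
  expect_length(annotate_text("the fold of the protein", 0L, fold_lex), 0L)
  expect_length(annotate_text("the folD gene", 0L, fold_lex), 1L)
})

test_that("no annotation crosses a sentence boundary when segmentation is present", {
  lex <- lexicon(tibble::tibble(
    surface = "heat shock", concept_id = "C1", entity_type = "chemical",
    preferred_name = "heat shock", source_db = "db"), stoplist = character(0))
  s1 <- bioc_sentence(0L, "cells under heat", index = 0L)
  s2 <- bioc_sentence(17L, "shock responded .", index = 1L)
  p <- bioc_passage(0L, text = "cells under heat shock responded .",
                    sentences = list(s1, s2))
  expect_length(annotate_passage(p, lex), 0L)
  p_flat <- bioc_passage(0L, text = "cells under heat shock responded .")
  expect_length(annotate_passage(p_flat, lex), 1L)
})

test_that("matcher equals the brute-force window oracle and type restriction equals post-hoc filtering", {
  for (seed in 1:40) {
    tab <- random_lexicon_table(seed)
    lex <- lexicon(tab, stoplist = default_stoplist())
    set.seed(seed + 1000)
    words <- sample(c(word_pool, tab$surface), sample(10:40, 1L), replace = TRUE)
    text <- paste(words, collapse = " ")
    got <- annotate_text(text, 0L, lex)
    got_keys <- annotation_key_set(got)
    want <- oracle_annotate(text, 0L, lex$entries, lex$types_available)
    want_keys <- sort(paste(want$offset, want$length, want$concept_id, want$type))
    expect_identical(got_keys, want_keys)

    restricted <- annotate_text(text, 0L, lex, types = "chemical")
    full_chem <- Filter(function(a) infon(a, "type") == "chemical", got)
    expect_identical(annotation_key_set(restricted),
                     annotation_key_set(full_chem))
  }
})
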