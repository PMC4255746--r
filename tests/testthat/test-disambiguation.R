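mk_ann <- function(id, text, offset, type, concept, org = NULL, extra = list()) {
  infons <- c(list(type = type, concept_id = concept, preferred_name = text,
                   score = "1"), extra)
  if (!is.null(org)) infons$organism_id <- org
  bioc_annotation(id, text, offset = offset, length = nchar(text),
                  infons = infons)
}

test_that("common-word filter keeps exact-case matches and drops case violations", {
  lex <- lexicon(tibble::tibble(
    surface = c("folD", "SEX", "aspirin"),
    concept_id = c("G1", "C1", "C2"),
    entity_type = c("gene", "chemical", "chemical"),
    preferred_name = c("folD", "SEX", "aspirin"), source_db = "db"))
  anns <- c(
    annotate_text("the folD gene", 0L, lex, enforce_case = FALSE),
    annotate_text("sex differences in aspirin response", 20L, lex,
                  enforce_case = FALSE),
    annotate_text("took Aspirin daily", 80L, lex, enforce_case = FALSE))
  expect_length(anns, 4L)  # folD, sex, aspirin, Aspirin
  kept <- apply_common_word_filter(anns)
  surfaces <- vapply(kept, function(a) a$text, character(1))
  expect_true("folD" %in% surfaces)      # exact case: kept
  expect_false("sex" %in% surfaces)      # wrong case for chemical SEX: dropped
  expect_true("Aspirin" %in% surfaces)   # case-insensitive entry passes through
})

test_that("context rules resolve cross-type conflicts only when a cue is in the window", {
  rules <- type_rules(tibble::tibble(
    pattern = "gfp", preferred_type = "experimental_method",
    cues = "microscopy,fluorescence", window = 5L))
  with_cue <- "GFP signal under fluorescence microscopy was strong"
  no_cue <- "GFP binds the receptor complex here"
  cands <- function(base) list(
    mk_ann("T1", "GFP", base, "protein", "P:GFP"),
    mk_ann("T2", "GFP", base, "experimental_method", "M:GFP"))
  out1 <- resolve_type_conflicts(cands(0L), rules, tokenize(with_cue, 0L))
  expect_length(out1, 1L)
  expect_identical(infon(out1[[1L]], "type"), "experimental_method")

  out2 <- resolve_type_conflicts(cands(0L), rules, tokenize(no_cue, 0L))
  expect_length(out2, 2L)
  expect_true(all(vapply(out2, function(a) infon(a, "ambiguous") == "true",
                         logical(1))))

  solo <- list(mk_ann("T3", "Tim18p", 0L, "protein", "P9"))
  expect_identical(resolve_type_conflicts(solo, rules, tokenize("Tim18p", 0L)),
                   solo)
})

test_that("rules naming unknown entity types are a configuration error", {
  expect_error(
    type_rules(tibble::tibble(pattern = "gfp", preferred_type = "method",
                              cues = "x", window = 3L),
               types_available = c("protein", "chemical")),
    "unknown entity type")
})

test_that("organism ranking counts species mentions and gamma-weighted resolving genes", {
  anns <- c(
    lapply(1:3, function(i) mk_ann(paste0("S", i), "Saccharomyces cerevisiae",
                                   i * 50L, "species", "TAX:4932",
                                   org = "taxon:4932")),
    list(mk_ann("S4", "Escherichia coli", 400L, "species", "TAX:562",
                org = "taxon:562")))
  ranked <- rank_organisms(anns, gamma = 0)
  expect_equal(ranked$score, c(0.75, 0.25))
  expect_identical(ranked$organism_id, c("taxon:4932", "taxon:562"))

  # no species mentions: two genes resolvable only to human rank human first
  genes <- list(
    mk_ann("T1", "BRCA1", 0L, "gene", "H:BRCA1", org = "taxon:9606"),
    mk_ann("T2", "TP53", 30L, "gene", "H:TP53", org = "taxon:9606"))
  ranked2 <- rank_organisms(genes, gamma = 0.5)
  expect_identical(ranked2$organism_id, "taxon:9606")
  expect_equal(sum(ranked2$score), 1)

  expect_identical(nrow(rank_organisms(list())), 0L)
})

test_that("organism scores sum to one and are invariant under annotation permutation", {
  set.seed(5)
  anns <- c(
    lapply(1:4, function(i) mk_ann(paste0("S", i), "sp", i * 10L, "species",
                                   paste0("TAX:", sample(c(1, 2, 3), 1L)),
                                   org = paste0("taxon:", sample(c(1, 2, 3), 1L)))),
    list(mk_ann("G1", "gene1", 100L, "protein", "P:1", org = "taxon:2")))
  r1 <- rank_organisms(anns)
  expect_equal(sum(r1$score), 1, tolerance = 1e-9)
  for (i in 1:5) {
    expect_identical(rank_organisms(sample(anns)), r1)
  }
})

test_that("identifier pruning removes foreign organisms, ranks by focus score, and never empties", {
  organisms <- tibble::tibble(organism_id = c("taxon:4932", "taxon:9606"),
                              score = c(0.8, 0.2))
  grp <- list(
    mk_ann("T1", "Adh1p", 0L, "protein", "H1", org = "taxon:9606"),
    mk_ann("T1", "Adh1p", 0L, "protein", "M1", org = "taxon:10090"))
  human_only <- disambiguate_ids(grp, tibble::tibble(
    organism_id = "taxon:9606", score = 1))
  expect_identical(infon(human_only, "concept_id"), "H1")
  expect_identical(infon(human_only, "candidate_ids"), "")

  grp2 <- list(
    mk_ann("T1", "Adh1p", 0L, "protein", "H1", org = "taxon:9606"),
    mk_ann("T1", "Adh1p", 0L, "protein", "Y1", org = "taxon:4932"))
  both <- disambiguate_ids(grp2, organisms)
  expect_identical(infon(both, "concept_id"), "Y1")
  expect_identical(infon(both, "candidate_ids"), "H1")

  # fail-safe: pruning would empty the list -> keep everything
  rat <- list(mk_ann("T1", "Adh1p", 0L, "protein", "R1", org = "taxon:10116"))
  kept <- disambiguate_ids(rat, tibble::tibble(organism_id = "taxon:9606",
                                               score = 1))
  expect_identical(infon(kept, "concept_id"), "R1")
})

test_that("disambiguation never invents concept ids and the full sequence is idempotent", {
  fx <- gen_fixtures(fixture_spec(seed = 9, n_docs = 4))
  res <- mine_collection(fx$collection, fx$lexicon, rules = fx$rules)
  input_ids <- unique(fx$lexicon$entries$concept_id)
  for (doc in res$collection$documents) {
    for (a in document_annotations(doc)) {
      cands <- c(infon(a, "concept_id"),
                 strsplit(infon(a, "candidate_ids", ""), ",")[[1L]])
      expect_true(all(cands[nzchar(cands)] %in% input_ids))
    }
  }
  once <- res$collection$documents[[1L]]
  twice <- disambiguate_document(once, rules = fx$rules)$document
  expect_identical(twice, once)
})
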