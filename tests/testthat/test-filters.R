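test_that("filter grammar parses atoms, keywords and precedence correctly", {
  ast <- parse_filter("has_type(chemical) AND has_type(disease)")
  expect_identical(ast$op, "and")
  expect_identical(ast$args[[1L]]$atom, "has_type")
  expect_identical(ast$args[[2L]]$atom_args, "disease")

  # NOT binds tighter than AND, AND tighter than OR
  prec <- parse_filter("NOT has_term(gfp) OR has_type(gene)")
  expect_identical(prec$op, "or")
  expect_identical(prec$args[[1L]]$op, "not")
  expect_identical(prec$args[[2L]]$atom, "has_type")

  mixed <- parse_filter("has_type(a) OR has_type(b) AND has_type(c)")
  expect_identical(mixed$op, "or")
  expect_identical(mixed$args[[2L]]$op, "and")

  # keywords are case-insensitive; parentheses override precedence
  grouped <- parse_filter("(has_type(a) or has_type(b)) and not has_type(c)")
  expect_identical(grouped$op, "and")
  expect_identical(grouped$args[[1L]]$op, "or")
})

test_that("syntax errors carry a column position; unknown types fail validation", {
  err <- tryCatch(parse_filter("has_type("), error = identity)
  expect_match(conditionMessage(err), "column 9")
  expect_error(parse_filter("has_type(chemical) AND"), "column")
  expect_error(parse_filter("frobnicate(x)"), "unknown atom")
  expect_error(parse_filter("has_type(plasmid)",
                            known_types = c("chemical", "disease")),
               "unknown entity type")
  expect_error(parse_filter(""), "column 1")
})

test_that("expressions round-trip through the printer", {
  exprs <- c("has_type(chemical) AND has_type(disease)",
             "NOT has_term(gfp) OR has_type(gene)",
             "(has_concept(C:1) OR has_term(il2)) AND NOT has_type(protein)",
             "has_relation(chemical, disease)")
  for (e in exprs) {
    ast <- parse_filter(e)
    expect_identical(parse_filter(format_filter(ast)), ast)
  }
})

filter_demo_doc <- function() {
  mk_sent <- function(idx, offset, text, anns) {
    bioc_sentence(offset, text, index = idx, annotations = anns)
  }
  texts <- c("aspirin treats headache today .",
             "the buffer was exchanged twice .",
             "aspirin alone was given .",
             "headache persisted in controls .")
  offs <- cumsum(c(0L, nchar(texts) + 1L))[1:4]
  anns <- list(
    list(mk_rel_ann("T1", "aspirin", offs[1L], "chemical", "C1"),
         mk_rel_ann("T2", "headache", offs[1L] + 15L, "disease", "D1")),
    list(),
    list(mk_rel_ann("T3", "aspirin", offs[3L], "chemical", "C1")),
    list(mk_rel_ann("T4", "headache", offs[4L], "disease", "D1")))
  ss <- Map(mk_sent, 0:3, offs, texts, anns)
  bioc_document("d", passages = list(
    bioc_passage(0L, text = paste(texts, collapse = " "), sentences = ss,
                 relations = list(bioc_relation("R1",
                   nodes = data.frame(refid = c("T1", "T2"),
                                      role = c("arg1", "arg2")),
                   infons = list(type = "interaction", score = "1"))))))
}

test_that("sentence selection matches the stated conditions and reports size ratios", {
  doc <- filter_demo_doc()
  res <- apply_filter(doc, "has_type(chemical) AND has_type(disease)")
  expect_identical(res$selected, 0L)
  expect_lt(res$reduction_ratio, 1)
  expect_identical(apply_filter(doc, "has_type(chemical)")$selected, c(0L, 2L))
  expect_identical(apply_filter(doc, "has_relation(chemical, disease)")$selected, 0L)
  expect_identical(apply_filter(doc, "has_concept(C1)")$selected, c(0L, 2L))
  expect_identical(apply_filter(doc, "has_term(Aspirin)")$selected, c(0L, 2L))

  # all-matching NOT: a document whose every sentence has a protein
  all_prot <- bioc_document("p", passages = list(
    bioc_passage(0L, text = "Aaa1p binds .",
                 sentences = list(bioc_sentence(
                   0L, "Aaa1p binds .", index = 0L,
                   annotations = list(mk_rel_ann("T1", "Aaa1p", 0L,
                                                 "protein", "P1")))))))
  expect_length(apply_filter(all_prot, "NOT has_type(protein)")$selected, 0L)
})

test_that("a filter and its negation partition the sentence set", {
  doc <- filter_demo_doc()
  exprs <- c("has_type(chemical)", "has_term(headache) OR has_type(chemical)",
             "NOT has_type(disease) AND has_type(chemical)")
  all_idx <- vapply(document_sentences(doc), function(s) s$index, integer(1))
  for (e in exprs) {
    yes <- apply_filter(doc, e)$selected
    no <- apply_filter(doc, sprintf("NOT (%s)", e))$selected
    expect_identical(sort(c(yes, no)), sort(all_idx))
    expect_length(intersect(yes, no), 0L)
  }
})

test_that("OR never shrinks and AND never grows a selection", {
  doc <- filter_demo_doc()
  base <- apply_filter(doc, "has_type(chemical)")$selected
  wider <- apply_filter(doc, "has_type(chemical) OR has_type(disease)")$selected
  narrower <- apply_filter(doc, "has_type(chemical) AND has_type(disease)")$selected
  expect_true(all(base %in% wider))
  expect_true(all(narrower %in% base))
})

test_that("the filter engine matches a per-sentence truth-table oracle on random inputs", {
  types <- c("protein", "chemical", "disease")
  concepts <- sprintf("C:%02d", 1:20)
  terms <- c("cells", "buffer", "lysed", "imaging")
  for (seed in 1:30) {
    coll <- random_collection(seed + 500)
    set.seed(seed)
    expr_str <- random_filter_ast(sample(0:3, 1L), types, concepts, terms)
    ast <- parse_filter(expr_str)
    for (doc in coll$documents) {
      got <- apply_filter(doc, ast)$selected
      want <- Filter(function(i) {
        s <- document_sentences(doc)[[i + 1L]]
        oracle_filter_sentence(ast, s)
      }, vapply(document_sentences(doc), function(s) s$index, integer(1)))
      expect_identical(got, as.integer(want))
    }
  }
})
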