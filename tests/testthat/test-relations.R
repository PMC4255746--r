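two_sentence_doc <- function() {
  s1 <- bioc_sentence(0L, "Tim18p coimmunoprecipitated with Tim12p .", index = 0L)
  s2 <- bioc_sentence(42L, "cells were lysed .", index = 1L)
  bioc_document("d1", passages = list(
    bioc_passage(0L, text = paste(s1$text, s2$text),
                 sentences = list(s1, s2))))
}

test_that("CoNLL blocks load, validate and align token offsets to the text", {
  conll <- paste(figure1_conll(),
                 paste("1\tcells\tcell\tNN\t3\tsubjpass",
                       "2\twere\tbe\tVBD\t3\taux",
                       "3\tlysed\tlyse\tVBN\t0\troot",
                       "4\t.\t.\tPUNCT\t3\tpunct", sep = "\n"),
                 sep = "\n\n")
  trees <- load_parses(conll, two_sentence_doc())
  expect_length(trees, 2L)
  # "Tim18p" aligns at its true offset in sentence text
  expect_identical(trees[[1L]]$alignment$offset[1L], 0L)
  expect_identical(trees[[1L]]$alignment$offset[4L], 33L)
  expect_identical(trees[[2L]]$alignment$offset[1L], 42L)
})

test_that("structurally invalid parse tables are rejected with the sentence named", {
  doc <- bioc_document("d1", passages = list(
    bioc_passage(0L, text = "a b",
                 sentences = list(bioc_sentence(0L, "a b", index = 0L)))))
  two_roots <- "1\ta\ta\tNN\t0\troot\n2\tb\tb\tNN\t0\troot"
  expect_error(load_parses(two_roots, doc), "exactly one root")
  cyclic <- "1\ta\ta\tNN\t2\tdep\n2\tb\tb\tNN\t1\tdep"
  expect_error(load_parses(cyclic, doc), "root|cycl")
  mismatch <- paste0(figure1_conll(), "\n\n1\textra\textra\tNN\t0\troot")
  expect_error(load_parses(mismatch, doc), "blocks")
})

test_that("the Figure-style sentence yields top node coimmunoprecipitate, [subj], [pobj]", {
  trees <- load_parses(figure1_conll(), figure1_document())
  path <- extract_path(trees[[1L]], 1L, 4L)
  expect_identical(path$top_lemma, "coimmunoprecipitate")
  expect_identical(path$left_path, "subj")
  expect_identical(path$right_path, "pobj")
  # symmetric under entity swap up to left/right exchange
  swapped <- extract_path(trees[[1L]], 4L, 1L)
  expect_identical(swapped, path)
})

test_that("path extraction handles entity-at-LCA, chains and degenerate input", {
  # chain a <- b <- c (c is root); entities at a and c
  nodes <- tibble::tibble(index = 1:3, surface = c("a", "b", "c"),
                          lemma = c("a", "b", "c"), pos = "NN",
                          head = c(2L, 3L, 0L),
                          label = c("dep_a", "dep_b", "root"))
  tree <- as_tree(nodes)
  path <- extract_path(tree, 1L, 3L)
  expect_identical(path$top_lemma, "c")
  expect_identical(path$left_path, c("dep_b", "dep_a"))
  expect_length(path$right_path, 0L)
  expect_error(extract_path(tree, 2L, 2L), "degenerate")
})

test_that("LCA and paths agree with the ancestor-set-intersection oracle on random trees", {
  set.seed(77)
  for (i in 1:150) {
    n <- sample(3:12, 1L)
    nodes <- random_tree_nodes(n)
    tree <- as_tree(nodes)
    ab <- sample(n, 2L)
    a <- min(ab); b <- max(ab)
    lca <- oracle_lca(nodes, a, b)
    path <- extract_path(tree, a, b)
    expect_identical(path$top_lemma, nodes$lemma[lca])
    # oracle paths: labels from each node up to (excluding) the LCA, reversed
    up_labels <- function(x) {
      out <- character(0)
      while (x != lca) {
        out <- c(out, nodes$label[x])
        x <- nodes$head[x]
      }
      rev(out)
    }
    expect_identical(path$left_path, up_labels(a))
    expect_identical(path$right_path, up_labels(b))
  }
})

test_that("candidate pairs follow type-pair specs and suppress self-interactions", {
  anns <- list(
    mk_rel_ann("T1", "Aaa1p", 0L, "protein", "P1"),
    mk_rel_ann("T2", "Bbb2p", 10L, "protein", "P2"),
    mk_rel_ann("T3", "Ccc3p", 20L, "protein", "P3"))
  pp <- candidate_pairs(anns, 0L, list(c("protein", "protein")))
  expect_identical(nrow(pp), 3L)

  mixed <- list(mk_rel_ann("T1", "aspirin", 0L, "chemical", "C1"),
                mk_rel_ann("T2", "headache", 10L, "disease", "D1"))
  cd <- candidate_pairs(mixed, 2L, list(c("chemical", "disease")))
  expect_identical(nrow(cd), 1L)
  expect_identical(cd$sentence_index, 2L)
  expect_identical(nrow(candidate_pairs(mixed, 2L, list(c("protein", "protein")))),
                   0L)

  dup <- list(mk_rel_ann("T1", "Aaa1p", 0L, "protein", "P1"),
              mk_rel_ann("T2", "Aaa1p", 10L, "protein", "P1"))
  expect_identical(nrow(candidate_pairs(dup, 0L, list(c("protein", "protein")))),
                   0L)
  expect_identical(nrow(candidate_pairs(dup, 0L, list(c("protein", "protein")),
                                        allow_self = TRUE)), 1L)
})

test_that("distant supervision labels sentences by gold pair containment", {
  gold <- biocmine:::gold_table(tibble::tibble(
    document_id = "d1", id1 = "P1", id2 = "P2"))
  mk_doc <- function(concepts) {
    anns <- lapply(seq_along(concepts), function(i)
      mk_rel_ann(paste0("T", i), "x", (i - 1L) * 5L, "protein", concepts[i]))
    s <- bioc_sentence(0L, strrep("x ", 10L), index = 0L, annotations = anns)
    bioc_document("d1", passages = list(
      bioc_passage(0L, text = s$text, sentences = list(s))))
  }
  expect_identical(distant_label(mk_doc(c("P1", "P2")), gold)$label, "positive")
  expect_identical(distant_label(mk_doc(c("P1", "P3")), gold)$label, "negative")
  expect_identical(distant_label(mk_doc("P1"), gold)$label, "negative")
})

test_that("pattern learning counts, decides by theta, and is permutation-invariant", {
  fx <- gen_fixtures(fixture_spec(seed = 13, n_docs = 8))
  coll <- attach_manifest_annotations(fx$collection, fx$manifest)
  pat <- learn_patterns(coll, fx$trees, fx$gold)
  expect_true(all(pat$decision[pat$n_pos > 0 & pat$n_neg == 0] == "yes"))
  expect_true(all(pat$decision[pat$n_pos == 0] == "no"))

  # permuting document order leaves the table unchanged
  perm <- coll
  set.seed(1)
  perm$documents <- sample(perm$documents)
  expect_identical(learn_patterns(perm, fx$trees, fx$gold), pat)

  # explicit ratio cases
  expect_identical(biocmine:::pattern_decision(1L, 0L), "yes")
  expect_identical(biocmine:::pattern_decision(1L, 3L), "no")   # 0.25 < 0.5
  expect_identical(biocmine:::pattern_decision(2L, 2L), "yes")  # 0.5 >= 0.5

  empty <- learn_patterns(bioc_collection(), list(), fx$gold)
  expect_identical(nrow(empty), 0L)
})

test_that("syntactic scoring returns the positive fraction, zero for no-patterns, backoff otherwise", {
  patterns <- tibble::tibble(
    top_lemma = c("interact", "colocalize"),
    left_path = c("subj", "subj"), right_path = c("pobj", "pobj"),
    n_pos = c(3L, 0L), n_neg = c(1L, 4L), decision = c("yes", "no"))
  yes_path <- list(top_lemma = "interact", left_path = "subj",
                   right_path = "pobj")
  no_path <- list(top_lemma = "colocalize", left_path = "subj",
                  right_path = "pobj")
  new_path <- list(top_lemma = "bind", left_path = "subj", right_path = "obj")
  expect_equal(score_syntax(yes_path, patterns)$score, 0.75)
  expect_equal(score_syntax(no_path, patterns)$score, 0)
  expect_equal(score_syntax(new_path, patterns)$score, 0.25)
  expect_true(is.na(score_syntax(NULL, patterns)$score))
})

test_that("pattern tables round-trip through their TSV format", {
  patterns <- tibble::tibble(
    top_lemma = c("interact", "lyse"), left_path = c("subj", ""),
    right_path = c("modpp>pobj", "obj"), n_pos = c(2L, 0L), n_neg = c(0L, 1L),
    decision = c("yes", "no"))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  write_patterns(patterns, path)
  expect_identical(read_patterns(path), patterns)
})
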