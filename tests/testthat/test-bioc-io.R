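test_that("a minimal collection survives a read/write round-trip byte-identically in text", {
  xml <- paste0(
    "<collection><source>s</source><date>2014-01-01</date><key>k</key>",
    "<document><id>d1</id><passage><offset>0</offset>",
    "<text>Tim18p binds Tim12p</text></passage></document></collection>")
  coll <- read_bioc(xml)
  expect_length(coll$documents, 1L)
  expect_identical(coll$documents[[1L]]$passages[[1L]]$text, "Tim18p binds Tim12p")
  rt <- read_bioc(write_bioc(coll))
  expect_identical(rt, coll)
})

test_that("annotations whose location matches their text are accepted, mismatches are reported as data", {
  text <- "some text Tim18p trailing words"
  good <- bioc_annotation("T1", "Tim18p", offset = 10L, length = 6L,
                          infons = list(type = "protein", concept_id = "P1",
                                        preferred_name = "TIM18", score = "1"))
  doc <- bioc_document("d1", passages = list(
    bioc_passage(0L, text = text, annotations = list(good))))
  coll <- bioc_collection(documents = list(doc))
  expect_identical(nrow(validate_offsets(coll)), 0L)

  bad <- good
  bad$id <- "T2"
  bad$locations$offset <- 11L  # off by one
  coll$documents[[1L]]$passages[[1L]]$annotations <- list(good, bad)
  v <- validate_offsets(coll)
  expect_identical(nrow(v), 1L)
  expect_identical(v$element_id, "T2")
  expect_identical(v$kind, "text-mismatch")
})

test_that("a relation referencing a deleted annotation yields one dangling-node violation", {
  coll <- random_collection(11)
  # force a known relation then delete its target
  a1 <- bioc_annotation("TX1", "cells", offset = 4L, length = 5L,
                        infons = list(type = "protein", concept_id = "P1"))
  p <- bioc_passage(0L, text = "the cells were lysed",
                    annotations = list(a1),
                    relations = list(bioc_relation("R9",
                      nodes = data.frame(refid = c("TX1", "GONE"),
                                         role = c("arg1", "arg2")))))
  doc <- bioc_document("dx", passages = list(p))
  v <- validate_offsets(bioc_collection(documents = list(doc)))
  expect_identical(v$kind, "dangling-node")
  expect_identical(v$element_id, "R9")
})

test_that("reading rejects malformed XML, negative offsets and unresolvable relation nodes", {
  expect_error(read_bioc("<collection><document>"), regexp = NULL)
  neg <- paste0(
    "<collection><source/><date/><key/><document><id>d</id>",
    "<passage><offset>0</offset><text>abc def</text>",
    "<annotation id=\"T1\"><infon key=\"type\">x</infon>",
    "<location offset=\"-2\" length=\"3\"/><text>abc</text></annotation>",
    "</passage></document></collection>")
  expect_error(read_bioc(neg), "T1")
  dangling <- paste0(
    "<collection><source/><date/><key/><document><id>d</id>",
    "<passage><offset>0</offset><text>abc</text>",
    "<relation id=\"R1\"><node refid=\"T9\" role=\"arg1\"/>",
    "<node refid=\"T8\" role=\"arg2\"/></relation>",
    "</passage></document></collection>")
  expect_error(read_bioc(dangling), "R1")
})

test_that("inline mode embeds a mark whose content is exactly the covered span", {
  a <- bioc_annotation("T1", "aspirin", offset = 0L, length = 7L,
                       infons = list(type = "chemical", concept_id = "C1"))
  doc <- bioc_document("d", passages = list(
    bioc_passage(0L, text = "aspirin reduces inflammation",
                 annotations = list(a))))
  xml <- write_bioc(bioc_collection(documents = list(doc)), mode = "inline")
  expect_match(xml, ">aspirin</mark>", fixed = TRUE)
  # marks re-parse to the same annotation set as standoff output
  standoff <- read_bioc(write_bioc(bioc_collection(documents = list(doc))))
  inline <- read_bioc(xml)
  expect_identical(
    annotation_key_set(document_annotations(inline$documents[[1L]])),
    annotation_key_set(document_annotations(standoff$documents[[1L]])))
})

test_that("nested inline annotations keep only the longer span under longest-wins, error otherwise", {
  outer <- bioc_annotation("T1", "acetylsalicylic acid", offset = 0L, length = 20L,
                           infons = list(type = "chemical", concept_id = "C1"))
  inner <- bioc_annotation("T2", "acid", offset = 16L, length = 4L,
                           infons = list(type = "chemical", concept_id = "C2"))
  doc <- bioc_document("d", passages = list(
    bioc_passage(0L, text = "acetylsalicylic acid helps",
                 annotations = list(outer, inner))))
  coll <- bioc_collection(documents = list(doc))
  expect_error(write_bioc(coll, mode = "inline"), "longest-wins")
  xml <- write_bioc(coll, mode = "inline", overlap_policy = "longest-wins")
  marked <- read_bioc(xml)
  anns <- document_annotations(marked$documents[[1L]])
  expect_length(anns, 1L)
  expect_identical(anns[[1L]]$text, "acetylsalicylic acid")
})

test_that("standoff output can suppress location anchors on request", {
  a <- bioc_annotation("T1", "aspirin", offset = 0L, length = 7L,
                       infons = list(type = "chemical", concept_id = "C1"))
  doc <- bioc_document("d", passages = list(
    bioc_passage(0L, text = "aspirin", annotations = list(a))))
  xml <- write_bioc(bioc_collection(documents = list(doc)),
                    include_offsets = FALSE)
  expect_false(grepl("<location", xml, fixed = TRUE))
  expect_match(xml, "<annotation id=\"T1\">", fixed = TRUE)
})

test_that("unknown infons are preserved verbatim through a round-trip", {
  xml <- paste0(
    "<collection><source/><date/><key/>",
    "<infon key=\"curation_log\">free-form record</infon>",
    "<document><id>d</id><infon key=\"custom\">v1</infon>",
    "<passage><offset>0</offset><text>x y</text></passage>",
    "</document></collection>")
  coll <- read_bioc(xml)
  rt <- read_bioc(write_bioc(coll))
  expect_identical(infon(rt, "curation_log"), "free-form record")
  expect_identical(infon(rt$documents[[1L]], "custom"), "v1")
})
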