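Package: biocmine
Title: Dictionary-Based Entity Recognition and Relation Mining for BioC Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained biomedical text-mining engine for assisted
    literature curation. Reads and writes BioC XML collections (stand-off or
    in-line annotations), annotates text by normalized longest-match lexical
    lookup against database-derived terminologies, resolves term ambiguity
    (common-word collisions, cross-type conflicts, and cross-organism
    identifier ambiguity via focus-organism ranking), generates candidate
    interactions by sentence co-occurrence, scores them with dependency-path
    patterns learned by distant supervision from a gold interaction database,
    combines frequency, context, concept-weight and syntactic factors into
    ranked confidence scores, and triages sentences with a boolean filter
    language. Includes deterministic fixture generators (lexicons, corpora
    with planted entities and relations, aligned synthetic dependency parses)
    so the whole pipeline is testable offline, plus a command-line interface
    and a minimal RESTful annotation service.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    stringi,
    tibble,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
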