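Package: procoref
Title: Rule-Based Protein Coreference Resolution for Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves anaphoric references to proteins in biomedical abstracts
    with a rule-based pipeline: markable detection over parsed noun phrases,
    anaphor selection with pleonastic-it and person filters, antecedent
    candidate collection inside a sentence window with syntactic-dependency
    and pronoun-family filters, and antecedent prediction by a pairwise
    decision list (number agreement, protein semantic constraint, discourse
    preference). Protein/non-protein semantic classification of expressions
    uses gold protein mentions and small keyword and head-word lexicons.
    Reads and writes BioNLP-ST style standoff annotation (.txt/.a1/.a2),
    scores predictions with the shared task's protein-coreference-link metric
    and with MUC, B-cubed, CEAF-M, CEAF-E and BLANC, and generates synthetic
    annotated corpora with gold parses for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
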