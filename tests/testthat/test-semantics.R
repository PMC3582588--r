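# Protein/non-protein classification: ANTE-SEM, PRO-ANA-SEM, DEFNP-ANA-SEM.

test_that("nominal expressions classify by head word, premodifier, coordination", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  prot <- fx$document$proteins
  # head word coincides with a protein mention
  expect_equal(ante_sem(markable_named(m, "c-Myc"), prot, fx$sentences),
               "PROTEIN")
  # "protein" head with a protein-mention premodifier
  expect_equal(ante_sem(markable_named(m, "the c-Myc protein"), prot,
                        fx$sentences), "PROTEIN")
  # no rule fires
  expect_equal(ante_sem(markable_named(m, "apoptosis"), prot, fx$sentences),
               "NON_PROTEIN")
  # pronouns violate the precondition
  expect_error(ante_sem(markable_named(m, "its"), prot, fx$sentences),
               "nominal")
  # coordinated NP with protein constituents
  fx9 <- fixtures[["PMID-9291089"]]
  m9 <- detect_markables(fx9$sentences, fx9$document$text)
  coord <- markable_named(m9, "AML1/CBF beta, C/EBP, Ets, c-Myb, HOX, and MZF-1")
  expect_equal(ante_sem(coord, fx9$document$proteins, fx9$sentences), "PROTEIN")
})

test_that("ante_sem is monotone in the protein mention set", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  prot <- fx$document$proteins
  nominals <- m[m$kind == "chunk", ]
  base <- vapply(seq_len(nrow(nominals)), function(i) {
    ante_sem(nominals[i, ], prot, fx$sentences)
  }, character(1))
  # add a mention over the head of "apoptosis" (S3): nothing flips to NON
  extra <- rbind(prot, data.frame(id = "T99", type = "Protein",
                                  start = markable_named(m, "apoptosis")$start,
                                  end = markable_named(m, "apoptosis")$end,
                                  text = "apoptosis"))
  grown <- vapply(seq_len(nrow(nominals)), function(i) {
    ante_sem(nominals[i, ], extra, fx$sentences)
  }, character(1))
  expect_false(any(base == "PROTEIN" & grown == "NON_PROTEIN"))
  expect_equal(grown[nominals$text == "apoptosis"], "PROTEIN")
})

test_that("possessive pronouns classify from their context noun phrase", {
  # all four printed possessive contexts carry a protein keyword
  cases <- list(c("PMID-7964516", "its"), c("PMID-10221658", "its"),
                c("PMID-8692924", "its"), c("PMID-9261367", "its"))
  for (cs in cases) {
    fx <- fixtures[[cs[1]]]
    m <- detect_markables(fx$sentences, fx$document$text)
    its <- m[m$text == cs[2] & m$kind == "pronoun", ][1, ]
    expect_equal(pro_ana_sem(its, fx$sentences), "PROTEIN", label = cs[1])
  }
  # no keyword in context -> UNKNOWN; non-possessive -> UNKNOWN
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  its <- m[m$text == "its", ][1, ]
  empty <- default_lexicons()
  empty$protein_keywords <- character(0)
  expect_equal(pro_ana_sem(its, fx$sentences, empty), "UNKNOWN")
  it_pers <- detect_markables(fixtures[["PMID-1560002"]]$sentences,
                              fixtures[["PMID-1560002"]]$document$text)
  expect_equal(pro_ana_sem(it_pers[it_pers$text == "it", ][1, ],
                           fixtures[["PMID-1560002"]]$sentences), "UNKNOWN")
})

test_that("definite NPs classify by the protein head-word list", {
  fx <- fixtures[["PMID-10358173"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  expect_equal(defnp_ana_sem(markable_named(m, "this transcription factor")),
               "PROTEIN")
  fx9 <- fixtures[["PMID-9291089"]]
  m9 <- detect_markables(fx9$sentences, fx9$document$text)
  expect_equal(defnp_ana_sem(markable_named(m9, "these factors")), "PROTEIN")
  m76 <- detect_markables(fixtures[["PMID-7964516"]]$sentences,
                          fixtures[["PMID-7964516"]]$document$text)
  phen <- markable_named(m76, "the phenomenon of activation-induced apoptosis")
  expect_equal(defnp_ana_sem(phen), "NON_PROTEIN")
  # the shipped head-word list has the eight enumerated words
  expect_length(default_lexicons()$protein_headwords, 8L)
  # empty lexicon degrades to NON_PROTEIN everywhere
  empty <- default_lexicons()
  empty$protein_headwords <- character(0)
  expect_equal(defnp_ana_sem(markable_named(m, "this transcription factor"),
                             empty), "NON_PROTEIN")
})

test_that("lexicons load from YAML with defaults for absent keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines("protein_headwords: [enzyme, kinase]", path)
  lx <- load_lexicons(path)
  expect_equal(lx$protein_headwords, c("enzyme", "kinase"))
  expect_equal(lx$protein_keywords, default_lexicons()$protein_keywords)
})
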