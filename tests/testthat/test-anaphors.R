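# Anaphor selection: typology, pleonastic-it patterns, person and semantic
# filters.

mk_tokens <- function(words, pos, lemmas = tolower(words)) {
  n <- length(words)
  starts <- cumsum(c(0L, nchar(words[-n]) + 1L))
  data.frame(start = starts, end = starts + nchar(words), text = words,
             pos = pos, lemma = lemmas, stringsAsFactors = FALSE)
}

test_that("all four pleonastic-it patterns are recognized", {
  # It be [Adj|Adv|verb]* that
  tk <- mk_tokens(c("It", "is", "thought", "that", "X", "binds", "Y"),
                  c("PRP", "VBZ", "VBN", "IN", "NN", "VBZ", "NN"),
                  c("it", "be", "think", "that", "x", "bind", "y"))
  expect_true(is_pleonastic_it(tk, 1L))
  # It be Adj [for NP] to VP
  tk <- mk_tokens(c("It", "is", "important", "for", "the", "cell", "to",
                    "respond"),
                  c("PRP", "VBZ", "JJ", "IN", "DT", "NN", "TO", "VB"),
                  c("it", "be", "important", "for", "the", "cell", "to",
                    "respond"))
  expect_true(is_pleonastic_it(tk, 1L))
  # It seems|appears|means|follows [that]
  tk <- mk_tokens(c("It", "seems", "that", "X", "binds", "Y"),
                  c("PRP", "VBZ", "IN", "NN", "VBZ", "NN"),
                  c("it", "seem", "that", "x", "bind", "y"))
  expect_true(is_pleonastic_it(tk, 1L))
  # NP makes|finds|take it [Adj]* [to VP | Ving]
  tk <- mk_tokens(c("This", "makes", "it", "possible", "to", "dissect",
                    "signaling"),
                  c("DT", "VBZ", "PRP", "JJ", "TO", "VB", "NN"),
                  c("this", "make", "it", "possible", "to", "dissect",
                    "signaling"))
  expect_true(is_pleonastic_it(tk, 3L))
})

test_that("referential 'it' is not filtered as pleonastic", {
  fx <- fixtures[["PMID-1560002"]]
  s2 <- fx$sentences[[2]]
  it_idx <- which(s2$tokens$text == "it")
  expect_false(is_pleonastic_it(s2$tokens, it_idx))
  tk <- mk_tokens(c("it", "binds", "DNA"), c("PRP", "VBZ", "NN"),
                  c("it", "bind", "dna"))
  expect_false(is_pleonastic_it(tk, 1L))
  expect_error(is_pleonastic_it(tk, 2L), "not 'it'")
})

test_that("anaphor types map deterministically from surface form", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  expect_equal(classify_anaphor_type(markable_named(m, "its")), "PRON_POSS")
  expect_equal(classify_anaphor_type(markable_named(m, "which")), "RELAT")
  expect_equal(classify_anaphor_type(markable_named(m, "the c-Myc protein")),
               "DNP")
  expect_equal(classify_anaphor_type(markable_named(m, "apoptosis")), "OTHER")
  m2 <- detect_markables(fixtures[["PMID-1560002"]]$sentences,
                         fixtures[["PMID-1560002"]]$document$text)
  expect_equal(classify_anaphor_type(m2[m2$text == "it", ][1, ]), "PRON_PERS")
})

test_that("the worked example selects exactly the printed anaphors", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins,
                        config = preset_config("rb-full"))
  expect_setequal(an$text, fx$expect$anaphors)
  # first-person pronoun "we" is a markable but never an anaphor
  expect_true("we" %in% m$text)
  expect_false("we" %in% an$text)
})

test_that("semantic filters only remove anaphors; disabling them widens the set", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  full <- select_anaphors(m, fx$sentences, fx$document$proteins,
                          config = preset_config("rb-full"))
  loose <- select_anaphors(m, fx$sentences, fx$document$proteins,
                           config = rule_config(pro_ana_sem_filter = FALSE,
                                                defnp_ana_sem_filter = FALSE))
  expect_true(all(full$text %in% loose$text))
  # without DEFNP-ANA-SEM the non-protein definite NP becomes an anaphor
  expect_true("the phenomenon of activation-induced apoptosis" %in% loose$text)
  expect_false("the phenomenon of activation-induced apoptosis" %in% full$text)
  # anaphors are always a subset of markables
  key <- function(df) paste(df$start, df$end)
  expect_true(all(key(full) %in% key(m)))
  expect_true(all(key(loose) %in% key(m)))
})

test_that("selection keeps the number-violating personal pronoun anaphor", {
  fx <- fixtures[["PMID-1560002"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins,
                        config = preset_config("rb-full"))
  expect_true("it" %in% an$text)
})
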