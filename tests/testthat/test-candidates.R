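# Antecedent candidate collection: window, dependency filter, pronoun
# family filter.

candidates_for <- function(fx, anaphor_text, config = preset_config("rb-full")) {
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins, config = config)
  a <- an[an$text == anaphor_text, ][1, ]
  collect_candidates(a, m, fx$sentences, an, fx$document$proteins,
                     config = config)
}

test_that("the worked example's candidate row for 'its' is reproduced", {
  fx <- fixtures[["PMID-7964516"]]
  cands <- candidates_for(fx, "its")
  for (want in fx$expect$its_candidates_include) {
    expect_true(want %in% cands$text, label = want)
  }
  for (drop in fx$expect$its_candidates_exclude) {
    expect_false(drop %in% cands$text, label = drop)
  }
  # ordered nearest first by end offset
  expect_true(!is.unsorted(rev(cands$end)))
  # all precede the anaphor and lie in the window
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins,
                        config = preset_config("rb-full"))
  its <- an[an$text == "its", ]
  expect_true(all(cands$end <= its$start))
  expect_true(all(cands$sentence >= its$sentence - 2L))
})

test_that("window arithmetic excludes far sentences; window 0 is same-sentence", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins,
                        config = preset_config("rb-full"))
  its <- an[an$text == "its", ]
  w0 <- collect_candidates(its, m, fx$sentences, an, fx$document$proteins,
                           config = rule_config(window = 0L))
  expect_true(all(w0$sentence == its$sentence))
  w1 <- collect_candidates(its, m, fx$sentences, an, fx$document$proteins,
                           config = rule_config(window = 1L))
  w2 <- collect_candidates(its, m, fx$sentences, an, fx$document$proteins,
                           config = rule_config(window = 2L))
  # enlarging the window never shrinks the candidate set
  key <- function(df) paste(df$start, df$end)
  expect_true(all(key(w0) %in% key(w1)))
  expect_true(all(key(w1) %in% key(w2)))
  expect_gt(nrow(w2), nrow(w0))
  expect_error(collect_candidates(its, m, fx$sentences, an,
                                  fx$document$proteins,
                                  config = rule_config(window = -1L)))
})

test_that("prepositional arguments cannot corefer with the anaphor", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins,
                        config = preset_config("rb-full"))
  its <- an[an$text == "its", ]
  form <- markable_named(
    m, "a dominant negative form of its heterodimeric binding partner, Max")
  expect_false(dependency_filter(its, form, fx$sentences))
  # unrelated candidate is kept
  expect_true(dependency_filter(its, markable_named(m, "c-Myc"), fx$sentences))

  # "two such truncated forms of the protein": the prepositional argument is
  # dropped as a candidate of "the protein"
  tks <- list(
    procoref:::tok("two", "CD"), procoref:::tok("such", "JJ"),
    procoref:::tok("truncated", "JJ"), procoref:::tok("forms", "NNS", "form"),
    procoref:::tok("of", "IN"), procoref:::tok("the", "DT"),
    procoref:::tok("protein", "NN"), procoref:::tok("remained", "VBD", "remain"),
    procoref:::tok(".", ".", ".", glue = TRUE))
  sp <- procoref:::sent_spec(
    tks,
    chunks = list(procoref:::chk(1, 4, 4), procoref:::chk(6, 7, 7),
                  procoref:::chk(1, 7, 4)),
    edges = list(procoref:::edg("prep-arg12", "chunk", 1, "chunk", 2)))
  d <- procoref:::build_document("trunc", list(sp))
  md <- detect_markables(d$sentences, d$document$text)
  the_protein <- markable_named(md, "the protein")
  forms <- markable_named(md, "two such truncated forms of the protein")
  expect_false(dependency_filter(the_protein, forms, d$sentences))
})

test_that("candidate pronouns must share the anaphor's pronoun family", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  its <- m[m$text == "its", ][1, ]
  this <- m[m$text == "this" & m$kind == "pronoun", ][1, ]
  expect_false(pronoun_family_filter(its, this))
  it_row <- its; it_row$head_lemma <- "it"; it_row$kind <- "pronoun"
  expect_true(pronoun_family_filter(its, it_row))
  # non-pronoun candidates always pass
  expect_true(pronoun_family_filter(its, markable_named(m, "c-Myc")))
  # anaphoric pronouns are excluded from candidate sets entirely
  cands <- candidates_for(fx, "its")
  expect_false("this" %in% cands$text)
})

test_that("the hard semantic candidate filter drops non-protein candidates", {
  fx <- fixtures[["PMID-7964516"]]
  cfg <- rule_config(hard_semantic_candidate_filter = TRUE)
  cands <- candidates_for(fx, "its", cfg)
  expect_true(all(cands$sem_class != "NON_PROTEIN"))
  soft <- candidates_for(fx, "its")
  expect_lt(nrow(cands), nrow(soft))
})
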