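# Antecedent prediction: decision list, tournament, fixed relative rule,
# whole-document resolution.

resolve_fx <- function(id, preset) {
  fx <- fixtures[[id]]
  resolve_document(fx$document, fx$sentences, preset_config(preset))
}

test_that("pairwise preference is asymmetric and rules decide in order", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins,
                        config = preset_config("rb-full"))
  its <- an[an$text == "its", ]
  cands <- collect_candidates(its, m, fx$sentences, an, fx$document$proteins,
                              config = preset_config("rb-full"))
  cfg <- preset_config("rb-full")
  for (i in seq_len(nrow(cands) - 1L)) {
    for (j in seq(i + 1L, nrow(cands))) {
      ab <- prefer(cands[i, ], cands[j, ], its, cfg)
      ba <- prefer(cands[j, ], cands[i, ], its, cfg)
      w1 <- if (ab$winner == 1L) i else j
      w2 <- if (ba$winner == 1L) j else i
      expect_equal(w1, w2)
      expect_equal(ab$rule, ba$rule)
    }
  }
  # number agreement decides before the semantic constraint
  studies <- cands[cands$text == "studies", ]
  cmyc <- cands[cands$text == "c-Myc", ]
  expect_equal(prefer(studies, cmyc, its, cfg)$rule, "NUM-AGREE")
  # protein preferred over nearer non-protein for a protein anaphor
  apop <- cands[cands$text == "apoptosis", ]
  res <- prefer(apop, cmyc, its, cfg)
  expect_equal(res$rule, "SEM-CONS")
  expect_equal(res$winner, 2L)
  # with rule 2 off the default prefers the closer candidate
  res_min <- prefer(apop, cmyc, its, preset_config("rb-min"))
  expect_equal(res_min$rule, "DEFAULT")
  expect_equal(res_min$winner, 1L)
})

test_that("tournament equals the pairwise maximum and handles edge cases", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins,
                        config = preset_config("rb-full"))
  its <- an[an$text == "its", ]
  cands <- collect_candidates(its, m, fx$sentences, an, fx$document$proteins,
                              config = preset_config("rb-full"))
  for (preset in c("rb-min", "rb-min+1", "rb-full")) {
    cfg <- preset_config(preset)
    win <- predict_antecedent(its, cands, cfg)
    # Condorcet check: the tournament winner beats every other candidate
    wi <- which(cands$start == win$start & cands$end == win$end)
    for (j in setdiff(seq_len(nrow(cands)), wi)) {
      expect_equal(prefer(cands[wi, ], cands[j, ], its, cfg)$winner, 1L)
    }
    # visiting candidates farthest-first gives the same winner
    win_rev <- predict_antecedent(its, cands[rev(seq_len(nrow(cands))), ], cfg)
    expect_equal(win_rev$start, win$start)
  }
  # with all rules disabled the nearest candidate wins
  expect_equal(predict_antecedent(its, cands, preset_config("rb-min"))$text,
               cands$text[1])
  expect_null(predict_antecedent(its, cands[0, ], preset_config("rb-full")))
  one <- predict_antecedent(its, cands[5, ], preset_config("rb-min"))
  expect_equal(one$text, cands$text[5])
  expect_equal(one$rule, "ONLY-CANDIDATE")
})

test_that("relative pronouns resolve through the parser attachment only", {
  fx <- fixtures[["PMID-7964516"]]
  m <- detect_markables(fx$sentences, fx$document$text)
  an <- select_anaphors(m, fx$sentences, fx$document$proteins,
                        config = preset_config("rb-full"))
  whichm <- an[an$text == "which", ]
  lk <- resolve_relative(whichm, fx$sentences[[3]])
  expect_equal(
    substring(fx$document$text, lk$antecedent_start + 1, lk$antecedent_end),
    "a dominant negative form of its heterodimeric binding partner, Max")
  expect_error(resolve_relative(an[an$text == "its", ], fx$sentences[[3]]),
               "RELAT")
  # unattached relative: no link, resolution fails quietly
  fx9 <- fixtures[["PMID-9261367"]]
  m9 <- detect_markables(fx9$sentences, fx9$document$text)
  an9 <- select_anaphors(m9, fx9$sentences, fx9$document$proteins,
                         config = preset_config("rb-full"))
  that_row <- an9[an9$text == "that", ]
  expect_null(resolve_relative(that_row, fx9$sentences[[1]]))
})

test_that("ablating the semantic constraint changes exactly its decisions", {
  # full system picks the protein antecedent, ablation the closer candidate
  lk_full <- resolve_fx("PMID-10358173", "rb-full")
  lk_no2 <- resolve_fx("PMID-10358173", "rb-min+1,3")
  expect_equal(lk_full$antecedent_text, "IRF-1")
  expect_equal(lk_no2$antecedent_text, "part")

  lk_full <- resolve_fx("PMID-7964516", "rb-full")
  lk_no2 <- resolve_fx("PMID-7964516", "rb-min+1,3")
  expect_equal(lk_full$antecedent_text[lk_full$anaphor_text == "its"], "c-Myc")
  expect_equal(lk_no2$antecedent_text[lk_no2$anaphor_text == "its"],
               "apoptosis")
  # the two configurations differ exactly on the anaphor the semantic
  # constraint decides
  common <- merge(lk_full, lk_no2, by = c("anaphor_start", "anaphor_end"))
  differing <- common[common$antecedent_start.x != common$antecedent_start.y, ]
  expect_equal(differing$anaphor_text.x, "its")
  lk_full10 <- resolve_fx("PMID-10358173", "rb-full")
  lk_no210 <- resolve_fx("PMID-10358173", "rb-min+1,3")
  common <- merge(lk_full10, lk_no210, by = c("anaphor_start", "anaphor_end"))
  differing <- common[common$antecedent_start.x != common$antecedent_start.y, ]
  expect_equal(differing$anaphor_text.x, "this transcription factor")
})

test_that("document resolution emits at most one preceding antecedent per anaphor", {
  set.seed(11)
  corpus <- generate_corpus(generator_config(n_documents = 5, seed = 11))
  entries <- c(unname(fixtures), corpus)
  for (entry in entries) {
    links <- resolve_document(entry$document, entry$sentences,
                              preset_config("rb-full"))
    expect_false(anyDuplicated(links[, c("anaphor_start", "anaphor_end")]) > 0)
    expect_true(all(links$antecedent_start < links$anaphor_start))
    # deterministic
    again <- resolve_document(entry$document, entry$sentences,
                              preset_config("rb-full"))
    expect_identical(links, again)
  }
})

test_that("unparsed sentences are skipped with a warning", {
  fx <- fixtures[["PMID-7964516"]]
  sents <- fx$sentences
  s3 <- sents[[3]]
  sents[[3]] <- parsed_sentence(s3$index, s3$start, s3$end, s3$tokens,
                                s3$chunks, s3$edges, parsed = FALSE)
  expect_warning(links <- resolve_document(fx$document, sents,
                                           preset_config("rb-full")),
                 "unparsed")
  expect_false("its" %in% links$anaphor_text)
})
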