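# Standoff annotation reading, writing and protein-link derivation.

test_that("term lines parse into validated protein mentions", {
  dir <- withr::local_tempdir()
  writeLines("The Tax protein binds DNA.", file.path(dir, "d.txt"))
  writeLines("T1\tProtein 4 7\tTax", file.path(dir, "d.a1"))
  doc <- read_standoff(file.path(dir, "d.txt"), file.path(dir, "d.a1"))
  expect_equal(nrow(doc$proteins), 1L)
  expect_equal(doc$proteins$text, "Tax")
  expect_equal(doc$proteins$start, 4L)

  # span beyond the text and text mismatches are parse errors naming the file
  writeLines("T1\tProtein 4 999\tTax", file.path(dir, "bad.a1"))
  expect_error(read_standoff(file.path(dir, "d.txt"), file.path(dir, "bad.a1")),
               "bad.a1.*outside text")
  writeLines("T1\tProtein 4 7\tTux", file.path(dir, "bad2.a1"))
  expect_error(read_standoff(file.path(dir, "d.txt"), file.path(dir, "bad2.a1")),
               "does not match")
  writeLines("T1 Protein 4 7 Tax", file.path(dir, "bad3.a1"))
  expect_error(read_standoff(file.path(dir, "d.txt"), file.path(dir, "bad3.a1")),
               "malformed")
})

test_that("write_predictions then read_standoff is a fixed point on links", {
  for (id in c("PMID-7964516", "PMID-9252117")) {
    fx <- fixtures[[id]]
    base <- write_standoff_tmp(fx$document)
    doc2 <- read_standoff(paste0(base, ".txt"), paste0(base, ".a1"),
                          paste0(base, ".a2"))
    key_cols <- c("anaphor_start", "anaphor_end", "antecedent_start",
                  "antecedent_end")
    sort_links <- function(l) l[do.call(order, l[key_cols]), key_cols]
    expect_equal(sort_links(doc2$gold_links),
                 sort_links(fx$document$gold_links),
                 ignore_attr = TRUE)
    # second round trip is byte-stable
    a2_again <- tempfile(fileext = ".a2")
    write_predictions(doc2, doc2$gold_links, a2_again)
    expect_identical(readLines(a2_again), readLines(paste0(base, ".a2")))
  }
})

test_that("a2 writing is deterministic, deduplicates terms, rejects bad spans", {
  fx <- fixtures[["PMID-7964516"]]
  doc <- fx$document
  path <- tempfile(fileext = ".a2")
  # empty link set -> no relation lines, no terms
  write_predictions(doc, doc$gold_links[0, ], path)
  expect_identical(readLines(path), character(0))
  # two links sharing an antecedent: antecedent term emitted once
  g <- doc$gold_links[1, ]
  two <- rbind(g, g)
  two$anaphor_start[2] <- doc$gold_links$anaphor_start[2]
  two$anaphor_end[2] <- doc$gold_links$anaphor_end[2]
  write_predictions(doc, two, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^T", lines)), 3L)  # 2 anaphors + 1 shared antecedent
  expect_equal(sum(grepl("^R", lines)), 2L)
  # invalid span fails before writing anything
  bad <- g; bad$antecedent_end <- nchar(doc$text) + 50L
  path2 <- tempfile(fileext = ".a2")
  expect_error(write_predictions(doc, bad, path2), "invalid span")
  expect_false(file.exists(path2))
})

test_that("a2 reading reports dangling term references", {
  dir <- withr::local_tempdir()
  writeLines("A binds B.", file.path(dir, "d.txt"))
  writeLines("T1\tProtein 0 1\tA", file.path(dir, "d.a1"))
  writeLines(c("T2\tExp 8 9\tB", "R1\tCoref Anaphora:T2 Antecedent:T9"),
             file.path(dir, "d.a2"))
  expect_error(read_standoff(file.path(dir, "d.txt"), file.path(dir, "d.a1"),
                             file.path(dir, "d.a2")),
               "dangling term reference T9")
})

test_that("protein links derive one link per protein inside the antecedent", {
  fx <- fixtures[["PMID-9252117"]]
  doc <- fx$document
  pl <- derive_protein_links(doc$gold_links, doc$proteins)
  both <- markable_named(
    detect_markables(fx$sentences, doc$text), "both factors")
  got <- pl[pl$anaphor_start == both$start, ]
  expect_equal(nrow(got), fx$expect$n_protein_links)
  # every emitted link's protein lies inside the source antecedent span
  for (i in seq_len(nrow(pl))) {
    src <- doc$gold_links[
      doc$gold_links$anaphor_start == pl$anaphor_start[i], ]
    p <- doc$proteins[doc$proteins$id == pl$protein_id[i], ]
    expect_true(any(p$start >= src$antecedent_start &
                      p$end <= src$antecedent_end))
  }

  # a link whose antecedent holds no protein contributes nothing
  no_prot <- data.frame(anaphor_start = 0L, anaphor_end = 4L,
                        antecedent_start = 5L, antecedent_end = 8L)
  expect_equal(nrow(derive_protein_links(no_prot, doc$proteins)), 0L)
  expect_equal(nrow(derive_protein_links(doc$gold_links[0, ], doc$proteins)), 0L)
  # output size bound: links x max proteins per antecedent
  expect_lte(nrow(pl), nrow(doc$gold_links) * nrow(doc$proteins))
})
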