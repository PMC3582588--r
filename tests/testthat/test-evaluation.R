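# Scorers: protein-link metric and the five partition metrics, checked
# against hand-derived values and independent brute-force oracles.

test_that("protein-link scoring counts matched links once", {
  g <- data.frame(anaphor_start = c(0L, 10L, 20L), anaphor_end = c(5L, 15L, 25L),
                  protein_id = c("T1", "T2", "T3"))
  # perfect response
  sc <- score_protein_links(g, g)
  expect_equal(c(sc$recall, sc$precision, sc$f_score), c(1, 1, 1))
  # wrong protein id never matches
  r <- g[1, ]; r$protein_id <- "T9"
  expect_equal(score_protein_links(g[1, ], r)$f_score, 0)
  # gold {a,b,c}, response {a,d}: R=1/3, P=1/2, F=2/5
  r2 <- rbind(g[1, ], data.frame(anaphor_start = 50L, anaphor_end = 55L,
                                 protein_id = "T7"))
  sc2 <- score_protein_links(g, r2)
  expect_equal(sc2$recall, 1 / 3)
  expect_equal(sc2$precision, 1 / 2)
  expect_equal(sc2$f_score, 2 / 5)
  # lenient mode accepts overlapping anaphor spans, strict does not
  r3 <- g[1, ]; r3$anaphor_start <- 2L; r3$anaphor_end <- 7L
  expect_equal(score_protein_links(g[1, ], r3, "lenient")$f_score, 1)
  expect_equal(score_protein_links(g[1, ], r3, "strict")$f_score, 0)
  # duplicated links are deduplicated, and a gold link is credited once
  expect_equal(score_protein_links(g[1, ], rbind(g[1, ], g[1, ]))$precision, 1)
  two_claims <- rbind(r3, g[1, ])  # both match the single gold link
  sc3 <- score_protein_links(g[1, ], two_claims)
  expect_equal(sc3$counts$recall_num, 1)
  expect_equal(sc3$precision, 1 / 2)
})

test_that("hand-derived partition scores are reproduced", {
  key <- part(c("A", "B", "C"))
  resp <- part(c("A", "B"), "C")
  m <- muc_score(key, resp)
  expect_equal(c(m$recall, m$precision, m$f_score), c(0.5, 1, 2 / 3))
  b <- b_cubed_score(key, resp)
  expect_equal(b$recall, 5 / 9)
  expect_equal(b$precision, 1)
  # all-singleton response recalls no links
  expect_equal(muc_score(key, part("A", "B", "C"))$recall, 0)
  # all-singleton key: undefined recall reported as 0 with a flag
  m2 <- muc_score(part("A", "B"), part(c("A", "B")))
  expect_true("no-key-links" %in% m2$flags)
  # CEAF-M has R = P on identical mention universes
  cm <- ceaf_score(key, resp, "mention")
  expect_equal(cm$recall, cm$precision)
  # BLANC: key {A,B},{C} vs response {A,B,C}
  bl <- blanc_score(part(c("A", "B"), "C"), part(c("A", "B", "C")))
  expect_equal(bl$recall, (1 + 0) / 2)
  expect_equal(bl$precision, (1 / 3 + 0) / 2)
  # swapping key and response swaps precision and recall
  bl2 <- blanc_score(part(c("A", "B", "C")), part(c("A", "B"), "C"))
  expect_equal(bl2$recall, bl$precision)
  expect_equal(bl2$precision, bl$recall)
  expect_error(b_cubed_score(mention_partition(list()), resp), "empty")
})

test_that("every scorer equals its brute-force oracle on all small partition pairs", {
  # exhaustive cross-product of all set partitions over up to 4 mentions
  # (the acceptance suite extends this to 6)
  for (n in 2:4) {
    parts <- lapply(enumerate_partitions(as.list(LETTERS[1:n])),
                    function(p) mention_partition(lapply(p, unlist)))
    for (k in parts) {
      for (r in parts) {
        expect_lt(max(abs(score_vec(muc_score(k, r)) - oracle_muc(k, r))), 1e-9)
        expect_lt(max(abs(score_vec(b_cubed_score(k, r)) - oracle_b3(k, r))),
                  1e-9)
        expect_lt(max(abs(score_vec(ceaf_score(k, r, "mention")) -
                            oracle_ceaf(k, r, "mention"))), 1e-9)
        expect_lt(max(abs(score_vec(ceaf_score(k, r, "entity")) -
                            oracle_ceaf(k, r, "entity"))), 1e-9)
        expect_lt(max(abs(score_vec(blanc_score(k, r)) - oracle_blanc(k, r))),
                  1e-9)
      }
    }
  }
})

test_that("scorers handle differing mention universes (twinless mentions)", {
  key <- part(c("A", "B"), "C")
  resp <- part(c("A", "D"))
  for (f in list(muc_score, b_cubed_score,
                 function(k, r) ceaf_score(k, r, "mention"),
                 function(k, r) ceaf_score(k, r, "entity"), blanc_score)) {
    sc <- f(key, resp)
    expect_true(sc$recall >= 0 && sc$recall <= 1)
    expect_true(sc$precision >= 0 && sc$precision <= 1)
  }
  expect_lt(max(abs(score_vec(b_cubed_score(key, resp)) -
                      oracle_b3(key, resp))), 1e-9)
  expect_lt(max(abs(score_vec(blanc_score(key, resp)) -
                      oracle_blanc(key, resp))), 1e-9)
})

test_that("partitions build from links by transitive closure", {
  links <- data.frame(anaphor_start = c(10L, 20L), anaphor_end = c(12L, 22L),
                      antecedent_start = c(0L, 10L), antecedent_end = c(2L, 12L))
  p <- partition_from_links(links, mentions = "99-100")
  sizes <- sort(vapply(p$chains, length, integer(1)))
  expect_equal(sizes, c(1L, 3L))  # one chain 0-2/10-12/20-22 plus a singleton
  expect_error(mention_partition(list(c("A", "B"), c("B", "C"))), "disjoint")
})
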