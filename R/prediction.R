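# Step 4 -- antecedent prediction. Relative pronouns are resolved by the
# parser's attachment; all other anaphors by a pairwise decision list:
#   Rule 1 NUM-AGREE  prefer the candidate that does not conflict in number;
#   Rule 2 SEM-CONS   for a protein anaphor, prefer a protein candidate;
#   Rule 3 DISC-PREF  for some anaphor types, prefer the farther candidate;
#   DEFAULT           prefer the closer candidate (never ties).

#' Decision-list configuration
#'
#' @param rule1,rule2,rule3 Enable number agreement (NUM-AGREE), the protein
#'   semantic constraint (SEM-CONS) and discourse preference (DISC-PREF).
#' @param window Candidate window in sentences (default 2: the two nearest
#'   preceding sentences plus the anaphor's sentence).
#' @param disc_pref_map Named character vector mapping anaphor types to
#'   `"near"` or `"far"`; Rule 3 only acts on types mapped to `"far"`
#'   (default: personal and demonstrative pronouns).
#' @param pro_ana_sem_filter,defnp_ana_sem_filter,pleonastic_filter Anaphor
#'   selection filters (Step 2).
#' @param exclude_self_contained_dnp Do not treat definite NPs that contain
#'   a gold protein mention as anaphors.
#' @param filtered_dependency_labels Dependency labels whose arguments
#'   cannot corefer (Step 3 filter).
#' @param hard_semantic_candidate_filter Remove non-protein candidates of
#'   protein anaphors already at Step 3 instead of leaving the preference to
#'   Rule 2.
#' @param relative_labels Edge labels encoding relative-clause attachment.
#' @return A list of class `rule_config`.
#' @seealso [preset_config()] for the named ablation presets.
#' @export
rule_config <- function(rule1 = TRUE, rule2 = TRUE, rule3 = TRUE,
                        window = 2L,
                        disc_pref_map = c(PRON_PERS = "far", PRON_DEM = "far"),
                        pro_ana_sem_filter = TRUE,
                        defnp_ana_sem_filter = TRUE,
                        pleonastic_filter = TRUE,
                        exclude_self_contained_dnp = TRUE,
                        filtered_dependency_labels = c("poss-arg12", "prep-arg12"),
                        hard_semantic_candidate_filter = FALSE,
                        relative_labels = c("relative-arg", "rel-arg12")) {
  structure(list(
    rule1 = rule1, rule2 = rule2, rule3 = rule3, window = as.integer(window),
    disc_pref_map = disc_pref_map,
    pro_ana_sem_filter = pro_ana_sem_filter,
    defnp_ana_sem_filter = defnp_ana_sem_filter,
    pleonastic_filter = pleonastic_filter,
    exclude_self_contained_dnp = exclude_self_contained_dnp,
    filtered_dependency_labels = filtered_dependency_labels,
    hard_semantic_candidate_filter = hard_semantic_candidate_filter,
    relative_labels = relative_labels), class = "rule_config")
}

#' Named system presets
#'
#' `rb-min` disables all three comparison rules (the closest candidate
#' wins); `rb-min+1`, `rb-min+2`, `rb-min+3` enable one rule each;
#' `rb-min+1,3` enables number agreement and discourse preference;
#' `rb-full` enables all three. `rb-full-no-pro-ana-sem` and
#' `rb-full-no-defnp-ana-sem` switch off the corresponding anaphor-selection
#' semantic filter of the full system.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [rule_config()].
#' @return A `rule_config`.
#' @export
preset_config <- function(name = c("rb-full", "rb-min", "rb-min+1", "rb-min+2",
                                   "rb-min+3", "rb-min+1,3",
                                   "rb-full-no-pro-ana-sem",
                                   "rb-full-no-defnp-ana-sem"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    "rb-min" = list(rule1 = FALSE, rule2 = FALSE, rule3 = FALSE),
    "rb-min+1" = list(rule1 = TRUE, rule2 = FALSE, rule3 = FALSE),
    "rb-min+2" = list(rule1 = FALSE, rule2 = TRUE, rule3 = FALSE),
    "rb-min+3" = list(rule1 = FALSE, rule2 = FALSE, rule3 = TRUE),
    "rb-min+1,3" = list(rule1 = TRUE, rule2 = FALSE, rule3 = TRUE),
    "rb-full" = list(),
    "rb-full-no-pro-ana-sem" = list(pro_ana_sem_filter = FALSE),
    "rb-full-no-defnp-ana-sem" = list(defnp_ana_sem_filter = FALSE))
  do.call(rule_config, utils::modifyList(args, list(...)))
}

# a closer than b? (nearest = largest end offset; inner chunk on ties)
closer_than <- function(a, b) {
  a$end > b$end || (a$end == b$end && a$start > b$start)
}

number_compatible <- function(cand_number, ana_number) {
  cand_number == "unknown" || ana_number == "unknown" ||
    cand_number == ana_number
}

#' Pairwise candidate comparison under the decision list
#'
#' Applies the enabled rules in order; a rule decides only when exactly one
#' candidate satisfies its condition, otherwise the next rule is consulted.
#' The default rule (closer candidate) never ties.
#'
#' @param cand_a,cand_b One-row candidate data frames (with `number` and
#'   `sem_class` filled), both preceding the anaphor.
#' @param anaphor One-row anaphor data frame.
#' @param config A [rule_config()].
#' @return List with `winner` (1 or 2) and `rule` (the deciding rule name:
#'   `"NUM-AGREE"`, `"SEM-CONS"`, `"DISC-PREF"` or `"DEFAULT"`).
#' @export
prefer <- function(cand_a, cand_b, anaphor, config = rule_config()) {
  stopifnot(!(cand_a$start == cand_b$start && cand_a$end == cand_b$end))
  if (isTRUE(config$rule1)) {
    ca <- number_compatible(cand_a$number, anaphor$number)
    cb <- number_compatible(cand_b$number, anaphor$number)
    if (ca != cb) {
      return(list(winner = if (ca) 1L else 2L, rule = "NUM-AGREE"))
    }
  }
  if (isTRUE(config$rule2) && identical(anaphor$sem_class, "PROTEIN")) {
    ca <- identical(cand_a$sem_class, "PROTEIN")
    cb <- identical(cand_b$sem_class, "PROTEIN")
    if (ca != cb) {
      return(list(winner = if (ca) 1L else 2L, rule = "SEM-CONS"))
    }
  }
  if (isTRUE(config$rule3)) {
    pref <- config$disc_pref_map[classify_anaphor_type(anaphor)]
    if (!is.na(pref) && pref == "far") {
      a_farther <- !closer_than(cand_a, cand_b)
      return(list(winner = if (a_farther) 1L else 2L, rule = "DISC-PREF"))
    }
  }
  list(winner = if (closer_than(cand_a, cand_b)) 1L else 2L, rule = "DEFAULT")
}

#' Predict the antecedent of an anaphor from its candidate set
#'
#' Nearest-first tournament: the nearest candidate starts as incumbent and
#' is challenged by each farther candidate in order under [prefer()]; the
#' surviving candidate is the antecedent. With all rules disabled this
#' returns the nearest candidate.
#'
#' @param anaphor One-row anaphor data frame.
#' @param candidates Candidate data frame from [collect_candidates()]
#'   (nearest first).
#' @param config A [rule_config()].
#' @return The winning one-row candidate with a `rule` column recording the
#'   last deciding rule, or `NULL` for an empty candidate set.
#' @export
predict_antecedent <- function(anaphor, candidates, config = rule_config()) {
  if (is.null(candidates) || !nrow(candidates)) return(NULL)
  inc <- 1L
  rule <- "ONLY-CANDIDATE"
  for (ch in seq_len(nrow(candidates))[-1]) {
    res <- prefer(candidates[inc, ], candidates[ch, ], anaphor, config)
    if (res$winner == 2L) inc <- ch
    rule <- res$rule
  }
  out <- candidates[inc, , drop = FALSE]
  out$rule <- rule
  out
}

#' Resolve a relative pronoun by parser attachment
#'
#' @param anaphor One-row anaphor of type `RELAT`.
#' @param sentence The [parsed_sentence()] containing it.
#' @param config A [rule_config()].
#' @return A one-row link data frame, or `NULL` when the parser attached the
#'   relative clause to nothing (resolution then simply fails, as it does
#'   when the parse is wrong).
#' @export
resolve_relative <- function(anaphor, sentence, config = rule_config()) {
  if (classify_anaphor_type(anaphor) != "RELAT") {
    stop("resolve_relative requires a RELAT anaphor", call. = FALSE)
  }
  tok <- which(sentence$tokens$start == anaphor$start &
                 sentence$tokens$end == anaphor$end)
  if (!length(tok)) return(NULL)
  ci <- relative_argument(sentence, tok[1], labels = config$relative_labels)
  if (is.null(ci)) return(NULL)
  data.frame(anaphor_start = anaphor$start, anaphor_end = anaphor$end,
             antecedent_start = sentence$chunks$start[ci],
             antecedent_end = sentence$chunks$end[ci],
             rule = "FIXED-RELAT", stringsAsFactors = FALSE)
}

#' Resolve all anaphors of a document
#'
#' Runs the full pipeline on one parsed document: markable detection,
#' anaphor selection, candidate collection and antecedent prediction
#' (relative pronouns through the fixed attachment rule). At most one link
#' per anaphor is produced; every antecedent precedes its anaphor. Unparsed
#' sentences are skipped with a warning.
#'
#' @param document A `coref_document`.
#' @param sentences Parsed sentences (from [parse_document()] or a gold
#'   parse fixture).
#' @param config A [rule_config()] or preset.
#' @param lexicons Lexicon list.
#' @return Data frame of links: anaphor and antecedent spans and texts,
#'   `anaphor_type` and the deciding `rule`.
#' @export
resolve_document <- function(document, sentences, config = rule_config(),
                             lexicons = default_lexicons()) {
  unparsed <- vapply(sentences, function(s) !isTRUE(s$parsed), logical(1))
  if (any(unparsed)) {
    warning(sprintf("%s: skipping %d unparsed sentence(s)", document$doc_id,
                    sum(unparsed)), call. = FALSE)
  }
  markables <- detect_markables(sentences, document$text)
  anaphors <- select_anaphors(markables, sentences, document$proteins,
                              lexicons, config)
  links <- list()
  for (i in seq_len(nrow(anaphors))) {
    an <- anaphors[i, ]
    if (an$anaphor_type == "RELAT") {
      lk <- resolve_relative(an, sentences[[an$sentence]], config)
    } else {
      cands <- collect_candidates(an, markables, sentences, anaphors,
                                  document$proteins, lexicons, config)
      win <- predict_antecedent(an, cands, config)
      lk <- if (is.null(win)) NULL else {
        data.frame(anaphor_start = an$start, anaphor_end = an$end,
                   antecedent_start = win$start, antecedent_end = win$end,
                   rule = win$rule, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(lk)) {
      lk$anaphor_type <- an$anaphor_type
      links[[length(links) + 1L]] <- lk
    }
  }
  if (!length(links)) {
    return(data.frame(anaphor_start = integer(0), anaphor_end = integer(0),
                      anaphor_text = character(0), antecedent_start = integer(0),
                      antecedent_end = integer(0), antecedent_text = character(0),
                      anaphor_type = character(0), rule = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, links)
  out$anaphor_text <- vapply(seq_len(nrow(out)), function(i) {
    span_text(document$text, out$anaphor_start[i], out$anaphor_end[i])
  }, character(1))
  out$antecedent_text <- vapply(seq_len(nrow(out)), function(i) {
    span_text(document$text, out$antecedent_start[i], out$antecedent_end[i])
  }, character(1))
  out <- out[, c("anaphor_start", "anaphor_end", "anaphor_text",
                 "antecedent_start", "antecedent_end", "antecedent_text",
                 "anaphor_type", "rule")]
  rownames(out) <- NULL
  out
}
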