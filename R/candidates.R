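# Step 3 -- antecedent candidate selection. For each anaphor, preceding
# markables within a sentence window are collected, then filtered by
# syntactic dependency constraints and the pronoun-family constraint.

#' Dependency-relation candidate filter
#'
#' Arguments of certain dependency relations (by default `poss-arg12` and
#' `prep-arg12`, the possessive and prepositional argument relations) cannot
#' corefer: in "a dominant negative form of its heterodimeric binding
#' partner", "dominant negative form" can never be the antecedent of "its".
#' A candidate is dropped when it and the anaphor (or the noun phrase
#' containing the anaphor) are the two arguments of a filtered relation, or
#' when the candidate's span contains the anaphor.
#'
#' @param anaphor,candidate One-row markable data frames.
#' @param sentences Parsed sentences.
#' @param labels Dependency labels to filter on.
#' @return `TRUE` to keep the candidate, `FALSE` to drop it.
#' @export
dependency_filter <- function(anaphor, candidate, sentences,
                              labels = c("poss-arg12", "prep-arg12")) {
  if (span_contains(candidate$start, candidate$end, anaphor$start, anaphor$end)) {
    return(FALSE)
  }
  if (candidate$sentence != anaphor$sentence) return(TRUE)
  s <- sentences[[anaphor$sentence]]
  ed <- s$edges
  for (i in seq_len(nrow(ed))) {
    if (!ed$label[i] %in% labels) next
    s1 <- edge_arg_span(s, ed$arg1_kind[i], ed$arg1[i])
    s2 <- edge_arg_span(s, ed$arg2_kind[i], ed$arg2[i])
    cand_matches <- function(sp) {
      (sp[1] >= candidate$start && sp[2] <= candidate$end) ||
        (candidate$start >= sp[1] && candidate$end <= sp[2])
    }
    ana_matches <- function(sp) {
      sp[1] <= anaphor$start && anaphor$end <= sp[2]
    }
    if ((cand_matches(s1) && ana_matches(s2)) ||
          (cand_matches(s2) && ana_matches(s1))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Pronoun-family candidate filter
#'
#' A candidate pronoun must belong to the same pronoun family as a pronoun
#' anaphor (the family of "its" is it/its/itself). Non-pronoun candidates,
#' and candidates of non-pronoun anaphors, always pass.
#'
#' @param anaphor,candidate One-row markable data frames.
#' @param families Named list of pronoun families.
#' @return `TRUE` to keep the candidate.
#' @export
pronoun_family_filter <- function(anaphor, candidate,
                                  families = default_lexicons()$pronoun_families) {
  if (candidate$kind != "pronoun") return(TRUE)
  if (anaphor$kind != "pronoun") return(TRUE)
  fa <- pronoun_family_of(anaphor$head_lemma, families)
  fc <- pronoun_family_of(candidate$head_lemma, families)
  if (is.na(fa) || is.na(fc)) return(FALSE)
  fa == fc
}

#' Collect antecedent candidates for an anaphor
#'
#' Candidates are the markables that end before the anaphor starts, lie
#' within `config$window` sentences of it (window 2 means the two nearest
#' preceding sentences plus the anaphor's own sentence), and survive the
#' filters: pronoun markables are excluded when they were themselves
#' selected as anaphors or removed by the person/pleonastic filters; the
#' pronoun-family and dependency filters apply; optionally
#' (`config$hard_semantic_candidate_filter`) non-protein candidates of a
#' protein anaphor are removed. The result is ordered nearest first (by end
#' offset, inner chunk first on ties) and carries each candidate's semantic
#' class and grammatical number.
#'
#' @param anaphor One-row anaphor data frame (from [select_anaphors()]).
#' @param markables Full markable data frame.
#' @param sentences Parsed sentences.
#' @param anaphors The selected anaphor set (to exclude anaphoric pronouns).
#' @param proteins Protein mention data frame.
#' @param lexicons Lexicon list.
#' @param config A [rule_config()].
#' @return Data frame of candidate markables, nearest first.
#' @export
collect_candidates <- function(anaphor, markables, sentences, anaphors,
                               proteins, lexicons = default_lexicons(),
                               config = rule_config()) {
  stopifnot(config$window >= 0)
  cand <- markables[markables$end <= anaphor$start &
                      markables$sentence >= anaphor$sentence - config$window, ,
                    drop = FALSE]
  if (!nrow(cand)) return(cand)

  keep <- vapply(seq_len(nrow(cand)), function(i) {
    m <- cand[i, ]
    if (m$kind == "pronoun") {
      if (person_filtered(m)) return(FALSE)
      if (pleonastic_here(m, sentences)) return(FALSE)
      if (any(anaphors$kind == "pronoun" & anaphors$start == m$start &
                anaphors$end == m$end)) return(FALSE)
      if (!pronoun_family_filter(anaphor, m, lexicons$pronoun_families)) {
        return(FALSE)
      }
    }
    dependency_filter(anaphor, m, sentences, config$filtered_dependency_labels)
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(cand)

  cand$sem_class <- vapply(seq_len(nrow(cand)), function(i) {
    candidate_sem_class(cand[i, ], proteins, sentences, lexicons)
  }, character(1))
  if (isTRUE(config$hard_semantic_candidate_filter) &&
        identical(anaphor$sem_class, "PROTEIN")) {
    cand <- cand[cand$sem_class != "NON_PROTEIN", , drop = FALSE]
  }
  cand <- cand[order(-cand$end, -cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
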