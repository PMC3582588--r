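# Step 2 -- anaphor selection. Pronouns and definite noun phrases are the
# base anaphor set; syntactic filters (person, pleonastic it) and semantic
# filters (PRO-ANA-SEM, DEFNP-ANA-SEM) remove expressions that cannot be
# anaphoric protein references.

FIRST_SECOND_PERSON <- c("i", "we", "you", "me", "us", "my", "our", "your")
GENDERED_PERSON <- c("he", "she", "him", "her", "his", "hers")

#' Detect pleonastic (non-referential) "it"
#'
#' Matches four surface patterns over lemma/POS sequences (optional slots
#' limited to three tokens):
#' 1. `It be (Adj|Adv|verb)* that ...`
#' 2. `It be Adj (for NP) to VP`
#' 3. `It (seem|appear|mean|follow) (that) ...`
#' 4. `NP (make|find|take) it (Adj)* (for NP)* (to VP | Ving)`
#'
#' @param tokens Token data frame of the sentence (`text`, `pos`, `lemma`).
#' @param it_index Row index of the "it" token.
#' @param max_gap Maximum length of the optional slots.
#' @return `TRUE` when any pattern matches.
#' @export
is_pleonastic_it <- function(tokens, it_index, max_gap = 3L) {
  lm <- tolower(tokens$lemma)
  pos <- tokens$pos
  n <- length(lm)
  if (lm[it_index] != "it") stop("token is not 'it'", call. = FALSE)
  i <- it_index

  # patterns 1 and 2: It be ...
  if (i < n && lm[i + 1L] == "be") {
    j <- i + 2L
    # pattern 1: skip up to max_gap Adj/Adv/verb tokens, then "that"
    k <- j
    steps <- 0L
    while (k <= n && steps <= max_gap) {
      if (lm[k] == "that") return(TRUE)
      if (!(substr(pos[k], 1, 2) %in% c("JJ", "RB", "VB"))) break
      k <- k + 1L
      steps <- steps + 1L
    }
    # pattern 2: be Adj [for NP] to VP
    if (j <= n && substr(pos[j], 1, 2) == "JJ") {
      k <- j + 1L
      if (k <= n && lm[k] == "for") {
        # skip the NP after "for" (up to max_gap + determiner tokens)
        k <- k + 1L
        steps <- 0L
        while (k <= n && steps <= max_gap + 1L && lm[k] != "to") {
          k <- k + 1L
          steps <- steps + 1L
        }
      }
      if (k <= n && lm[k] == "to" && k < n && substr(pos[k + 1L], 1, 2) == "VB") {
        return(TRUE)
      }
    }
  }

  # pattern 3: It seems|appears|means|follows [that]
  if (i < n && lm[i + 1L] %in% c("seem", "appear", "mean", "follow")) {
    return(TRUE)
  }

  # pattern 4: NP makes|finds|takes it [Adj]* [for NP]* [to VP | Ving]
  if (i > 1L && lm[i - 1L] %in% c("make", "find", "take")) {
    k <- i + 1L
    steps <- 0L
    while (k <= n && steps <= max_gap && substr(pos[k], 1, 2) == "JJ") {
      k <- k + 1L
      steps <- steps + 1L
    }
    if (k <= n && lm[k] == "for") {
      k <- k + 1L
      steps <- 0L
      while (k <= n && steps <= max_gap + 1L && lm[k] != "to" &&
               pos[k] != "VBG") {
        k <- k + 1L
        steps <- steps + 1L
      }
    }
    if (k <= n &&
          ((lm[k] == "to" && k < n && substr(pos[k + 1L], 1, 2) == "VB") ||
             pos[k] == "VBG")) {
      return(TRUE)
    }
  }
  FALSE
}

#' Anaphor type of a markable
#'
#' Deterministic mapping from surface form and POS to the anaphor typology:
#' `RELAT` (relative pronouns), `PRON_POSS`, `PRON_PERS`, `PRON_DEM`,
#' `PRON_REFL`, `PRON_OTHER`, `DNP` (definite noun phrases), `OTHER`.
#'
#' @param markable One-row markable data frame.
#' @return Type label.
#' @export
classify_anaphor_type <- function(markable) {
  st <- markable$syn_type
  if (st %in% c("RELAT", "PRON_POSS", "PRON_PERS", "PRON_DEM", "PRON_REFL",
                "PRON_OTHER", "DNP")) return(st)
  "OTHER"
}

# Is this pronoun markable removed by the person filters (first/second
# person, gendered third person)?
person_filtered <- function(markable) {
  tolower(markable$head_lemma) %in% c(FIRST_SECOND_PERSON, GENDERED_PERSON)
}

pleonastic_here <- function(markable, sentences, max_gap = 3L) {
  if (tolower(markable$head_lemma) != "it") return(FALSE)
  s <- sentences[[markable$sentence]]
  idx <- which(s$tokens$start == markable$start & s$tokens$end == markable$end)
  if (!length(idx)) return(FALSE)
  is_pleonastic_it(s$tokens, idx[1], max_gap = max_gap)
}

#' Select anaphors from the markable set
#'
#' Keeps pronouns and definite noun phrases, then filters: first/second
#' person and gendered pronouns; pleonastic "it" (when
#' `config$pleonastic_filter`); possessive pronouns whose context gives no
#' protein cue (PRO-ANA-SEM, when `config$pro_ana_sem_filter`); definite NPs
#' with a non-protein head word (DEFNP-ANA-SEM, when
#' `config$defnp_ana_sem_filter`); and, when
#' `config$exclude_self_contained_dnp`, definite NPs that already contain a
#' gold protein mention (these are self-contained protein references, not
#' anaphors). Relative pronouns are always kept.
#'
#' @param markables Markable data frame from [detect_markables()].
#' @param sentences Parsed sentences.
#' @param proteins Protein mention data frame.
#' @param lexicons Lexicon list.
#' @param config A [rule_config()].
#' @return Subset of `markables` with `anaphor_type` and filled `sem_class`.
#' @export
select_anaphors <- function(markables, sentences, proteins,
                            lexicons = default_lexicons(),
                            config = rule_config()) {
  keep <- logical(nrow(markables))
  atype <- character(nrow(markables))
  sem <- markables$sem_class
  for (i in seq_len(nrow(markables))) {
    m <- markables[i, ]
    atype[i] <- classify_anaphor_type(m)
    if (m$kind == "pronoun") {
      if (person_filtered(m)) next
      if (atype[i] == "RELAT") { keep[i] <- TRUE; next }
      if (isTRUE(config$pleonastic_filter) && pleonastic_here(m, sentences)) next
      if (atype[i] == "PRON_POSS") {
        sem[i] <- pro_ana_sem(m, sentences, lexicons)
        if (isTRUE(config$pro_ana_sem_filter) && sem[i] == "UNKNOWN") next
      }
      keep[i] <- TRUE
    } else if (m$syn_type == "DNP") {
      if (isTRUE(config$exclude_self_contained_dnp) && nrow(proteins) &&
            any(proteins$start >= m$start & proteins$end <= m$end)) next
      sem[i] <- defnp_ana_sem(m, lexicons)
      if (isTRUE(config$defnp_ana_sem_filter) && sem[i] == "NON_PROTEIN") next
      keep[i] <- TRUE
    }
  }
  out <- markables[keep, , drop = FALSE]
  out$anaphor_type <- atype[keep]
  out$sem_class <- sem[keep]
  rownames(out) <- NULL
  out
}
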