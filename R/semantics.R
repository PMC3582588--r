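# Protein/non-protein semantic classification of expressions. Three rule
# sets are used at different places in the pipeline:
#   ANTE-SEM      -- nominal expressions, using the gold protein mentions;
#   PRO-ANA-SEM   -- possessive pronoun anaphors, using context keywords;
#   DEFNP-ANA-SEM -- definite noun phrase anaphors, using a head-word list.

#' Classify a nominal expression as protein or non-protein (ANTE-SEM)
#'
#' An expression is a protein reference when (a) its head word exactly
#' coincides with a gold protein mention, (b) its head noun is "protein" or
#' "gene" and a protein mention premodifies the head within the chunk
#' (e.g. "the Tax protein"), or (c) it is a coordinated noun phrase with a
#' protein constituent. Otherwise it is non-protein.
#'
#' @param markable One-row markable data frame; must be a nominal (chunk),
#'   not a pronoun.
#' @param proteins Protein mention data frame (`id`, `start`, `end`).
#' @param sentences Parsed sentences (for the coordination check).
#' @return `"PROTEIN"` or `"NON_PROTEIN"`.
#' @export
ante_sem <- function(markable, proteins, sentences = NULL) {
  if (markable$kind == "pronoun") {
    stop("ante_sem applies to nominal expressions, not pronouns", call. = FALSE)
  }
  if (!nrow(proteins)) return("NON_PROTEIN")
  # (a) head word coincides with a protein mention
  if (any(proteins$start == markable$head_start &
            proteins$end == markable$head_end)) {
    return("PROTEIN")
  }
  # (b) "protein"/"gene" head with a protein-mention premodifier
  if (tolower(markable$head_lemma) %in% c("protein", "gene")) {
    premod <- proteins$start >= markable$start &
      proteins$end <= markable$head_start
    if (any(premod)) return("PROTEIN")
  }
  # (c) coordinated NP with a protein constituent
  if (!is.null(sentences)) {
    s <- sentences[[markable$sentence]]
    inside <- s$tokens$start >= markable$start & s$tokens$end <= markable$end
    has_cc <- any(s$tokens$pos[inside] == "CC")
    contained <- proteins$start >= markable$start & proteins$end <= markable$end
    if (has_cc && any(contained)) return("PROTEIN")
  }
  "NON_PROTEIN"
}

#' Classify a possessive pronoun anaphor by its context (PRO-ANA-SEM)
#'
#' For "its"/"their", the noun phrase in which the pronoun is the determiner
#' is inspected; if it contains a protein keyword (lemma match,
#' case-insensitive, multiword keys as consecutive token sequences) the
#' pronoun is a protein reference, otherwise its type stays unknown.
#' Non-possessive pronouns have no determiner context and return
#' `"UNKNOWN"`.
#'
#' @param markable One-row pronoun markable.
#' @param sentences Parsed sentences.
#' @param lexicons Lexicon list, see [default_lexicons()].
#' @return `"PROTEIN"` or `"UNKNOWN"`.
#' @export
pro_ana_sem <- function(markable, sentences, lexicons = default_lexicons()) {
  if (!tolower(markable$head_lemma) %in% c("its", "their")) return("UNKNOWN")
  s <- sentences[[markable$sentence]]
  ck <- s$chunks
  # smallest NP whose first token is the possessive
  containing <- which(ck$np & ck$start == markable$start & ck$end > markable$end)
  if (!length(containing)) return("UNKNOWN")
  best <- containing[which.min(ck$end[containing] - ck$start[containing])]
  tok_in <- which(s$tokens$start >= ck$start[best] &
                    s$tokens$end <= ck$end[best])
  lemmas <- tolower(s$tokens$lemma[tok_in])
  for (kw in lexicons$protein_keywords) {
    parts <- tolower(strsplit(kw, " ", fixed = TRUE)[[1]])
    n <- length(parts)
    if (n > length(lemmas)) next
    for (j in seq_len(length(lemmas) - n + 1L)) {
      if (all(lemmas[j:(j + n - 1L)] == parts)) return("PROTEIN")
    }
  }
  "UNKNOWN"
}

#' Classify a definite noun phrase anaphor by its head word (DEFNP-ANA-SEM)
#'
#' A definite NP is a protein reference iff its singular-normalized head
#' word is in the protein head-word list ("protein", "gene", "factor", ...).
#'
#' @param markable One-row markable of definite-NP type.
#' @param lexicons Lexicon list.
#' @return `"PROTEIN"` or `"NON_PROTEIN"`.
#' @export
defnp_ana_sem <- function(markable, lexicons = default_lexicons()) {
  hw <- tolower(markable$head_lemma)
  hws <- c(hw, sub("s$", "", hw))
  if (any(hws %in% tolower(lexicons$protein_headwords))) "PROTEIN" else "NON_PROTEIN"
}

# Semantic class of an arbitrary candidate markable, used when comparing
# candidates: nominals through ANTE-SEM, possessives through PRO-ANA-SEM,
# other pronouns unknown.
candidate_sem_class <- function(markable, proteins, sentences, lexicons) {
  if (markable$kind == "pronoun") {
    if (tolower(markable$head_lemma) %in% c("its", "their")) {
      return(pro_ana_sem(markable, sentences, lexicons))
    }
    return("UNKNOWN")
  }
  ante_sem(markable, proteins, sentences)
}
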