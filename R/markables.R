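# Step 1 -- markable detection. Markables are the text chunks that may
# participate in coreference: noun-phrase chunks without subordinate
# clauses (one per head word, the longest) plus pronoun tokens.

PRONOUN_POS <- c("PRP", "PRP$", "WDT", "WP", "WP$")
DEM_LEMMAS <- c("this", "that", "these", "those")
DEFINITE_FIRST <- c("the", "this", "that", "these", "those", "both")

#' Pick the representative chunk among chunks sharing a head word
#'
#' Of the noun-phrase chunks built around the same head token, only the
#' longest is retained as a markable; equal lengths are broken by earliest
#' start so the choice is stable.
#'
#' @param chunks Data frame of chunk rows (`start`, `end`, ...) sharing a
#'   head token, subordinate-clause chunks already removed.
#' @return The selected single-row data frame.
#' @export
dedupe_by_head <- function(chunks) {
  if (!nrow(chunks)) stop("dedupe_by_head: empty chunk set", call. = FALSE)
  len <- chunks$end - chunks$start
  sel <- which(len == max(len))
  if (length(sel) > 1L) sel <- sel[which.min(chunks$start[sel])]
  chunks[sel, , drop = FALSE]
}

pronoun_subtype <- function(lemma, pos) {
  lemma <- tolower(lemma)
  if (pos %in% c("WDT", "WP") && lemma %in% c("that", "which", "who")) return("RELAT")
  if (pos == "PRP$" || lemma %in% c("its", "their", "my", "our", "your",
                                    "his", "her")) return("PRON_POSS")
  if (lemma %in% c("itself", "themselves", "himself", "herself", "myself",
                   "ourselves", "yourself")) return("PRON_REFL")
  if (lemma %in% DEM_LEMMAS) return("PRON_DEM")
  if (lemma %in% c("it", "they", "them", "he", "she", "him", "i", "we",
                   "you", "me", "us")) return("PRON_PERS")
  "PRON_OTHER"
}

#' Grammatical number of a markable
#'
#' Pronouns are classified by a small lexicon (its/it/itself/this/that are
#' singular; their/they/them/these/those/both plural). Noun-phrase chunks
#' with an internal coordination (a CC token) are plural; otherwise the head
#' POS decides (NNS/NNPS plural, NN/NNP singular); anything else is
#' `unknown`, which never raises a number conflict.
#'
#' @param markable A one-row markable data frame (see [detect_markables()]).
#' @param sentences The parsed sentences the markable came from (needed for
#'   the coordination check; may be omitted for pronouns).
#' @return `"singular"`, `"plural"` or `"unknown"`.
#' @export
grammatical_number <- function(markable, sentences = NULL) {
  if (markable$kind == "pronoun") {
    lemma <- tolower(markable$head_lemma)
    if (lemma %in% c("its", "it", "itself", "this", "that")) return("singular")
    if (lemma %in% c("their", "they", "them", "themselves", "these", "those",
                     "both")) return("plural")
    return("unknown")
  }
  if (!is.null(sentences)) {
    s <- sentences[[markable$sentence]]
    inside <- s$tokens$start >= markable$start & s$tokens$end <= markable$end
    if (any(s$tokens$pos[inside] == "CC")) return("plural")
  }
  switch(markable$head_pos,
         NNS = , NNPS = "plural",
         NN = , NNP = "singular",
         "unknown")
}

markable_syn_type <- function(kind, first_lemma, first_pos, head_lemma, head_pos) {
  if (kind == "pronoun") return(pronoun_subtype(head_lemma, head_pos))
  if (tolower(first_lemma) %in% DEFINITE_FIRST || first_pos == "PRP$") {
    return("DNP")
  }
  "NP"
}

#' Detect markables in parsed sentences
#'
#' Collects noun-phrase chunks that do not contain a subordinate clause,
#' keeps only the longest chunk per head token ([dedupe_by_head()]), and
#' adds every pronoun token as a markable (standalone demonstratives too,
#' but not determiners that open a noun phrase). Unparsed sentences are
#' skipped.
#'
#' @param sentences List of [parsed_sentence()].
#' @param text Optional document text; when given, a `text` column with each
#'   markable's surface string is attached.
#' @return Data frame with one row per markable: `start`, `end`, `text`,
#'   `sentence`, `kind` (`"chunk"`/`"pronoun"`), head token fields
#'   (`head_start`, `head_end`, `head_text`, `head_pos`, `head_lemma`),
#'   `syn_type` (`NP`, `DNP` or pronoun subtype), `number` and a
#'   `sem_class` placeholder (`"UNKNOWN"`), sorted by start offset.
#' @export
detect_markables <- function(sentences, text = NULL) {
  rows <- list()
  for (s in sentences) {
    if (!isTRUE(s$parsed)) next
    tk <- s$tokens
    ck <- s$chunks
    keep <- which(ck$np & !ck$subclause)
    # pronoun token spans (pronouns become their own markables)
    pron_idx <- which(tk$pos %in% PRONOUN_POS |
                        (tk$pos == "DT" & tolower(tk$lemma) %in%
                           c(DEM_LEMMAS, "both", "either") &
                           !np_initial(tk, ck)))
    pron_spans <- tk[pron_idx, c("start", "end"), drop = FALSE]

    if (length(keep)) {
      sub <- ck[keep, , drop = FALSE]
      # a chunk that is exactly a pronoun token is represented by the pronoun
      is_pron_chunk <- vapply(seq_len(nrow(sub)), function(i) {
        any(pron_spans$start == sub$start[i] & pron_spans$end == sub$end[i])
      }, logical(1))
      sub <- sub[!is_pron_chunk, , drop = FALSE]
      if (nrow(sub)) {
        for (h in unique(sub$head)) {
          pick <- dedupe_by_head(sub[sub$head == h, , drop = FALSE])
          first_tok <- which(tk$start >= pick$start)[1]
          rows[[length(rows) + 1L]] <- data.frame(
            start = pick$start, end = pick$end,
            sentence = s$index, kind = "chunk",
            head_start = tk$start[pick$head], head_end = tk$end[pick$head],
            head_text = tk$text[pick$head], head_pos = tk$pos[pick$head],
            head_lemma = tk$lemma[pick$head],
            first_lemma = tk$lemma[first_tok], first_pos = tk$pos[first_tok],
            stringsAsFactors = FALSE)
        }
      }
    }
    for (i in pron_idx) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = tk$start[i], end = tk$end[i],
        sentence = s$index, kind = "pronoun",
        head_start = tk$start[i], head_end = tk$end[i],
        head_text = tk$text[i], head_pos = tk$pos[i], head_lemma = tk$lemma[i],
        first_lemma = tk$lemma[i], first_pos = tk$pos[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0), text = character(0),
                      sentence = integer(0), kind = character(0),
                      head_start = integer(0), head_end = integer(0),
                      head_text = character(0), head_pos = character(0),
                      head_lemma = character(0), syn_type = character(0),
                      number = character(0), sem_class = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  m$syn_type <- vapply(seq_len(nrow(m)), function(i) {
    markable_syn_type(m$kind[i], m$first_lemma[i], m$first_pos[i],
                      m$head_lemma[i], m$head_pos[i])
  }, character(1))
  m$first_lemma <- NULL
  m$first_pos <- NULL
  m$number <- vapply(seq_len(nrow(m)), function(i) {
    grammatical_number(m[i, ], sentences)
  }, character(1))
  m$sem_class <- "UNKNOWN"
  m <- m[order(m$start, m$end), , drop = FALSE]
  if (!is.null(text)) m <- markable_text(m, text) else m$text <- NA_character_
  rownames(m) <- NULL
  m
}

# TRUE for each token index: token is the first token of some NP chunk
np_initial <- function(tokens, chunks) {
  vapply(seq_len(nrow(tokens)), function(i) {
    any(chunks$np & chunks$start == tokens$start[i] &
          chunks$end > tokens$end[i])
  }, logical(1))
}

# attach surface text column to markables given the document
markable_text <- function(markables, text) {
  markables$text <- vapply(seq_len(nrow(markables)), function(i) {
    span_text(text, markables$start[i], markables$end[i])
  }, character(1))
  markables
}
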