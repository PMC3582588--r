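# Sentence segmentation and syntactic parse information behind a
# backend-agnostic contract. A backend is any function(document) that returns
# a list of parsed sentences carrying tokens, POS tags, lemmas, noun-phrase
# chunks with head words, and labelled dependency edges. Tests and the
# synthetic corpus rely exclusively on gold-parse fixtures, so no external
# parser is required.

#' Construct a parsed sentence
#'
#' @param index 1-based sentence ordinal within the document.
#' @param start,end Sentence span (0-based half-open character offsets).
#' @param tokens Data frame `start`, `end`, `text`, `pos`, `lemma`; ordered,
#'   non-overlapping, inside the sentence span.
#' @param chunks Data frame `start`, `end`, `head` (row index into `tokens`),
#'   `np` (noun-phrase flag), `subclause` (contains an embedded clause).
#' @param edges Data frame `label`, `arg1_kind`, `arg1`, `arg2_kind`, `arg2`;
#'   `*_kind` is `"chunk"` or `"token"`, the index pointing into `chunks` or
#'   `tokens` of the same sentence.
#' @param parsed `FALSE` marks a sentence the backend failed on; downstream
#'   steps skip it.
#' @return An object of class `parsed_sentence`.
#' @export
parsed_sentence <- function(index, start, end, tokens, chunks = NULL,
                            edges = NULL, parsed = TRUE) {
  if (is.null(chunks) || !nrow(chunks)) {
    chunks <- data.frame(start = integer(0), end = integer(0), head = integer(0),
                         np = logical(0), subclause = logical(0))
  }
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(label = character(0), arg1_kind = character(0),
                        arg1 = integer(0), arg2_kind = character(0),
                        arg2 = integer(0), stringsAsFactors = FALSE)
  }
  s <- structure(list(index = index, start = start, end = end,
                      tokens = tokens, chunks = chunks, edges = edges,
                      parsed = parsed),
                 class = "parsed_sentence")
  validate_parsed_sentence(s)
  s
}

validate_parsed_sentence <- function(s) {
  tk <- s$tokens
  if (nrow(tk)) {
    if (any(tk$start < s$start | tk$end > s$end)) {
      stop(sprintf("sentence %d: token outside sentence span", s$index),
           call. = FALSE)
    }
    if (any(diff(tk$start) <= 0) || any(tk$end[-nrow(tk)] > tk$start[-1])) {
      stop(sprintf("sentence %d: tokens not ordered/non-overlapping", s$index),
           call. = FALSE)
    }
  }
  ck <- s$chunks
  for (i in seq_len(nrow(ck))) {
    h <- ck$head[i]
    if (is.na(h) || h < 1L || h > nrow(tk)) {
      stop(sprintf("sentence %d: chunk %d head index out of range", s$index, i),
           call. = FALSE)
    }
    if (tk$start[h] < ck$start[i] || tk$end[h] > ck$end[i]) {
      stop(sprintf("sentence %d: chunk %d head lies outside its span",
                   s$index, i), call. = FALSE)
    }
  }
  # chunk nesting must form a forest: any two chunks disjoint or nested
  if (nrow(ck) > 1) {
    for (i in seq_len(nrow(ck) - 1L)) {
      for (j in seq(i + 1L, nrow(ck))) {
        o <- span_overlaps(ck$start[i], ck$end[i], ck$start[j], ck$end[j])
        nested <- (ck$start[i] <= ck$start[j] && ck$end[j] <= ck$end[i]) ||
          (ck$start[j] <= ck$start[i] && ck$end[i] <= ck$end[j])
        if (o && !nested) {
          stop(sprintf("sentence %d: chunks %d and %d cross", s$index, i, j),
               call. = FALSE)
        }
      }
    }
  }
  ed <- s$edges
  for (i in seq_len(nrow(ed))) {
    for (side in c(1, 2)) {
      kind <- ed[[paste0("arg", side, "_kind")]][i]
      idx <- ed[[paste0("arg", side)]][i]
      n <- if (kind == "chunk") nrow(ck) else nrow(tk)
      if (!kind %in% c("chunk", "token") || idx < 1L || idx > n) {
        stop(sprintf("sentence %d: edge %d has invalid argument", s$index, i),
             call. = FALSE)
      }
    }
  }
  invisible(s)
}

#' @export
print.parsed_sentence <- function(x, ...) {
  cat(sprintf("<parsed_sentence %d [%d,%d): %d tokens, %d chunks, %d edges%s>\n",
              x$index, x$start, x$end, nrow(x$tokens), nrow(x$chunks),
              nrow(x$edges), if (x$parsed) "" else ", UNPARSED"))
  invisible(x)
}

#' Parse a document with a pluggable backend
#'
#' Runs sentence segmentation and parsing through `backend`, then validates
#' the structural invariants the downstream pipeline relies on: sentences in
#' order, tokens ordered and non-overlapping, chunk heads inside their
#' chunks, chunk nesting forming a forest. A backend may mark individual
#' sentences as unparsed (`parsed = FALSE`); those are retained but skipped
#' by later steps.
#'
#' @param document A `coref_document`.
#' @param backend A function taking the document and returning a list of
#'   [parsed_sentence()] objects, e.g. [gold_parse_backend()].
#' @return List of `parsed_sentence`.
#' @export
parse_document <- function(document, backend) {
  stopifnot(is.function(backend))
  sents <- backend(document)
  for (s in sents) {
    if (!inherits(s, "parsed_sentence")) {
      stop("backend must return parsed_sentence objects", call. = FALSE)
    }
    validate_parsed_sentence(s)
  }
  if (length(sents)) {
    idx <- vapply(sents, `[[`, numeric(1), "index")
    starts <- vapply(sents, `[[`, numeric(1), "start")
    if (any(diff(idx) != 1) || idx[1] != 1L) {
      stop("sentence indices must be 1..n in order", call. = FALSE)
    }
    if (any(diff(starts) <= 0) && length(starts) > 1) {
      stop("sentence spans must be in document order", call. = FALSE)
    }
  }
  sents
}

#' Gold-parse fixture backend
#'
#' Returns a backend closure for [parse_document()] that loads the parse
#' from a fixture file instead of running a parser.
#'
#' @param path Path to a gold-parse fixture (see [load_gold_parse()]).
#' @return A backend function.
#' @export
gold_parse_backend <- function(path) {
  force(path)
  function(document) load_gold_parse(path, document$text)
}

# ---- gold-parse fixture serialization -------------------------------------
# One JSON object per line, one line per sentence:
# {"index":1,"start":0,"end":42,
#  "tokens":[{"start":0,"end":1,"pos":"NN","lemma":"t"},...],
#  "chunks":[{"start":0,"end":9,"head":2,"np":true,"subclause":false},...],
#  "edges":[{"label":"prep-arg12","arg1_kind":"chunk","arg1":1,
#            "arg2_kind":"chunk","arg2":2},...],
#  "parsed":true}
# Token surface text is recovered from the document text.

#' Load a gold-parse fixture
#'
#' @param path Fixture path (JSON lines, one sentence per line).
#' @param text The document text the spans refer to.
#' @return List of [parsed_sentence()].
#' @export
load_gold_parse <- function(path, text) {
  if (!file.exists(path)) stop("parse fixture not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
                    error = function(e) {
                      stop_parse(path, i, paste0("bad JSON: ", conditionMessage(e)))
                    })
    tokens <- as.data.frame(rec$tokens)
    if (!nrow(tokens)) stop_parse(path, i, "sentence with no tokens")
    tokens$text <- vapply(seq_len(nrow(tokens)), function(k) {
      span_text(text, tokens$start[k], tokens$end[k])
    }, character(1))
    tokens <- tokens[, c("start", "end", "text", "pos", "lemma")]
    chunks <- if (!is.null(rec$chunks) && length(rec$chunks)) {
      ck <- as.data.frame(rec$chunks)
      names(ck)[names(ck) == "np"] <- "np"
      ck[, c("start", "end", "head", "np", "subclause")]
    } else NULL
    edges <- if (!is.null(rec$edges) && length(rec$edges)) {
      as.data.frame(rec$edges)[, c("label", "arg1_kind", "arg1",
                                   "arg2_kind", "arg2")]
    } else NULL
    out[[i]] <- tryCatch(
      parsed_sentence(rec$index, rec$start, rec$end, tokens, chunks, edges,
                      parsed = if (is.null(rec$parsed)) TRUE else rec$parsed),
      error = function(e) stop_parse(path, i, conditionMessage(e)))
  }
  out
}

#' Write a gold-parse fixture
#'
#' Deterministic serialization: writing, reading and re-writing a fixture is
#' byte-stable.
#'
#' @param sentences List of [parsed_sentence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold_parse <- function(sentences, path) {
  lines <- vapply(sentences, function(s) {
    rec <- list(
      index = s$index, start = s$start, end = s$end,
      tokens = s$tokens[, c("start", "end", "pos", "lemma")],
      chunks = s$chunks, edges = s$edges, parsed = s$parsed)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Find the argument a relative pronoun attaches to
#'
#' The fixed resolution rule for relative pronouns links the pronoun to the
#' noun phrase the parser attached the relative clause to. Returns the chunk
#' index, or `NULL` when the parser found no attachment (in which case the
#' coreference link is simply not produced).
#'
#' @param sentence A [parsed_sentence()].
#' @param token_index Row index of the relative pronoun in `sentence$tokens`.
#' @param labels Edge labels that encode relative-clause attachment.
#' @return Chunk row index, or `NULL`.
#' @export
relative_argument <- function(sentence, token_index,
                              labels = c("relative-arg", "rel-arg12")) {
  tk <- sentence$tokens[token_index, ]
  if (!(tk$pos %in% c("WDT", "WP") ||
        tolower(tk$lemma) %in% c("that", "which", "who"))) {
    stop("token is not a relative pronoun: ", tk$text, call. = FALSE)
  }
  ed <- sentence$edges
  for (i in seq_len(nrow(ed))) {
    if (!ed$label[i] %in% labels) next
    a1 <- c(ed$arg1_kind[i], ed$arg1[i])
    a2 <- c(ed$arg2_kind[i], ed$arg2[i])
    if (a2[1] == "token" && as.integer(a2[2]) == token_index && a1[1] == "chunk") {
      return(as.integer(a1[2]))
    }
    if (a1[1] == "token" && as.integer(a1[2]) == token_index && a2[1] == "chunk") {
      return(as.integer(a2[2]))
    }
  }
  NULL
}

# span of edge argument (chunk or token) as c(start, end)
edge_arg_span <- function(sentence, kind, idx) {
  if (kind == "chunk") {
    c(sentence$chunks$start[idx], sentence$chunks$end[idx])
  } else {
    c(sentence$tokens$start[idx], sentence$tokens$end[idx])
  }
}
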