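# Internal construction kit for annotated documents with gold parses.
# Both the packaged worked examples and the synthetic-corpus generator build
# documents token by token, so character offsets, chunk spans, protein
# mention spans and gold links are correct by construction.

# token spec: list(text, pos, lemma = tolower(text), glue = FALSE)
tok <- function(text, pos, lemma = tolower(text), glue = FALSE) {
  list(text = text, pos = pos, lemma = lemma, glue = glue)
}

# chunk spec over token indices [from, to] with head token index
chk <- function(from, to, head, np = TRUE, sub = FALSE) {
  list(from = from, to = to, head = head, np = np, sub = sub)
}

# edge spec; each side is list(kind = "chunk"|"token", idx = <spec index>)
edg <- function(label, kind1, idx1, kind2, idx2) {
  list(label = label, a1 = list(kind = kind1, idx = idx1),
       a2 = list(kind = kind2, idx = idx2))
}

# sentence spec
sent_spec <- function(tokens, chunks = list(), edges = list(),
                      proteins = list(), parsed = TRUE) {
  list(tokens = tokens, chunks = chunks, edges = edges, proteins = proteins,
       parsed = parsed)
}

# Assemble a document from sentence specs.
# links: list of list(anaphor = ref, antecedent = ref) where a ref is
# list(sent, token = i) or list(sent, chunk = i).
build_document <- function(doc_id, sents, links = list()) {
  offset <- 0L
  text_parts <- character(0)
  sentences <- vector("list", length(sents))
  prot_rows <- list()

  for (si in seq_along(sents)) {
    sp <- sents[[si]]
    if (si > 1L) offset <- offset + 1L  # single space between sentences
    s_start <- offset
    starts <- integer(length(sp$tokens)); ends <- integer(length(sp$tokens))
    stext <- ""
    for (ti in seq_along(sp$tokens)) {
      t <- sp$tokens[[ti]]
      if (ti > 1L && !isTRUE(t$glue)) stext <- paste0(stext, " ")
      starts[ti] <- s_start + nchar(stext)
      stext <- paste0(stext, t$text)
      ends[ti] <- s_start + nchar(stext)
    }
    offset <- s_start + nchar(stext)
    text_parts <- c(text_parts, stext)

    tokens <- data.frame(
      start = starts, end = ends,
      text = vapply(sp$tokens, `[[`, character(1), "text"),
      pos = vapply(sp$tokens, `[[`, character(1), "pos"),
      lemma = vapply(sp$tokens, `[[`, character(1), "lemma"),
      stringsAsFactors = FALSE)
    chunks <- if (length(sp$chunks)) {
      data.frame(
        start = vapply(sp$chunks, function(c) starts[c$from], integer(1)),
        end = vapply(sp$chunks, function(c) ends[c$to], integer(1)),
        head = vapply(sp$chunks, function(c) as.integer(c$head), integer(1)),
        np = vapply(sp$chunks, function(c) isTRUE(c$np), logical(1)),
        subclause = vapply(sp$chunks, function(c) isTRUE(c$sub), logical(1)))
    } else NULL
    edges <- if (length(sp$edges)) {
      data.frame(
        label = vapply(sp$edges, `[[`, character(1), "label"),
        arg1_kind = vapply(sp$edges, function(e) e$a1$kind, character(1)),
        arg1 = vapply(sp$edges, function(e) as.integer(e$a1$idx), integer(1)),
        arg2_kind = vapply(sp$edges, function(e) e$a2$kind, character(1)),
        arg2 = vapply(sp$edges, function(e) as.integer(e$a2$idx), integer(1)),
        stringsAsFactors = FALSE)
    } else NULL
    sentences[[si]] <- parsed_sentence(si, s_start, offset, tokens, chunks,
                                       edges, parsed = sp$parsed)
    for (pr in sp$proteins) {
      prot_rows[[length(prot_rows) + 1L]] <-
        c(start = starts[pr[1]], end = ends[pr[2]])
    }
  }

  text <- paste(text_parts, collapse = " ")
  proteins <- if (length(prot_rows)) {
    pm <- do.call(rbind, prot_rows)
    data.frame(id = paste0("T", seq_len(nrow(pm))), type = "Protein",
               start = as.integer(pm[, "start"]), end = as.integer(pm[, "end"]),
               text = vapply(seq_len(nrow(pm)), function(i) {
                 span_text(text, pm[i, "start"], pm[i, "end"])
               }, character(1)), stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), type = character(0), start = integer(0),
               end = integer(0), text = character(0), stringsAsFactors = FALSE)
  }

  ref_span <- function(ref) {
    s <- sentences[[ref$sent]]
    if (!is.null(ref$token)) {
      c(s$tokens$start[ref$token], s$tokens$end[ref$token])
    } else {
      c(s$chunks$start[ref$chunk], s$chunks$end[ref$chunk])
    }
  }
  gold_links <- if (length(links)) {
    rows <- lapply(links, function(lk) {
      an <- ref_span(lk$anaphor); at <- ref_span(lk$antecedent)
      data.frame(anaphor_start = an[1], anaphor_end = an[2],
                 anaphor_text = span_text(text, an[1], an[2]),
                 antecedent_start = at[1], antecedent_end = at[2],
                 antecedent_text = span_text(text, at[1], at[2]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else NULL

  list(document = new_coref_document(doc_id, text, proteins, gold_links),
       sentences = sentences)
}
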