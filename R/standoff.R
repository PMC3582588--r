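# BioNLP-ST style standoff annotation I/O.
#
# .a1 holds given protein mentions, one term per line:
#     T1<TAB>Protein <start> <end><TAB><surface text>
# .a2 (or .ann) holds coreferential expressions and coreference relations:
#     T12<TAB>Exp <start> <end><TAB><surface text>
#     R1<TAB>Coref Anaphora:T12 Antecedent:T3
# Offsets are 0-based half-open character offsets into the .txt file.

#' Read a standoff-annotated document
#'
#' Reads a document triple: plain text, gold protein mentions (`.a1`) and,
#' optionally, gold coreference annotation (`.a2`). All spans are validated
#' against the text; coreference relations are resolved from term ids to
#' character spans.
#'
#' @param txt_path Path to the plain-text file.
#' @param a1_path Path to the `.a1` file with `Protein` term lines.
#' @param a2_path Optional path to an `.a2`/`.ann` file with expression terms
#'   and `Coref` relations.
#' @param doc_id Document identifier; defaults to the text file name without
#'   extension.
#' @return A `coref_document`: a list with `doc_id`, `text`, `proteins`
#'   (data frame `id`, `start`, `end`, `text`) and `gold_links` (data frame
#'   `anaphor_start`, `anaphor_end`, `anaphor_text`, `antecedent_start`,
#'   `antecedent_end`, `antecedent_text`, or `NULL` when no `.a2` was given).
#' @seealso [write_predictions()], [derive_protein_links()]
#' @export
read_standoff <- function(txt_path, a1_path, a2_path = NULL, doc_id = NULL) {
  if (!file.exists(txt_path)) stop("text file not found: ", txt_path, call. = FALSE)
  if (!file.exists(a1_path)) stop("a1 file not found: ", a1_path, call. = FALSE)
  text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(txt_path))

  a1 <- parse_term_lines(a1_path, text, expected_type = "Protein")
  if (anyDuplicated(a1$id)) {
    stop_parse(a1_path, 0L, "duplicate term ids in .a1")
  }
  gold_links <- NULL
  if (!is.null(a2_path)) {
    if (!file.exists(a2_path)) stop("a2 file not found: ", a2_path, call. = FALSE)
    gold_links <- parse_a2(a2_path, text, a1)
  }
  new_coref_document(doc_id, text, a1, gold_links)
}

new_coref_document <- function(doc_id, text, proteins, gold_links = NULL) {
  doc <- structure(
    list(doc_id = doc_id, text = text, proteins = proteins,
         gold_links = gold_links),
    class = "coref_document"
  )
  validate_coref_document(doc)
  doc
}

validate_coref_document <- function(doc) {
  p <- doc$proteins
  for (i in seq_len(nrow(p))) {
    if (!span_valid(doc$text, p$start[i], p$end[i])) {
      stop("protein mention ", p$id[i], " has an invalid span", call. = FALSE)
    }
    if (!identical(span_text(doc$text, p$start[i], p$end[i]), p$text[i])) {
      stop("protein mention ", p$id[i], " text does not match document text",
           call. = FALSE)
    }
  }
  g <- doc$gold_links
  if (!is.null(g) && nrow(g)) {
    ok <- vapply(seq_len(nrow(g)), function(i) {
      span_valid(doc$text, g$anaphor_start[i], g$anaphor_end[i]) &&
        span_valid(doc$text, g$antecedent_start[i], g$antecedent_end[i])
    }, logical(1))
    if (!all(ok)) stop("gold link with span outside text", call. = FALSE)
  }
  invisible(doc)
}

#' @export
print.coref_document <- function(x, ...) {
  cat(sprintf("<coref_document %s: %d chars, %d protein mentions, %s gold links>\n",
              x$doc_id, nchar(x$text), nrow(x$proteins),
              if (is.null(x$gold_links)) "no" else nrow(x$gold_links)))
  invisible(x)
}

# Parse "Tn<TAB>Type start end<TAB>text" term lines.
parse_term_lines <- function(path, text, expected_type = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ids <- character(0); types <- character(0)
  starts <- integer(0); ends <- integer(0); texts <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L || !grepl("^T[0-9]+$", fields[1])) {
      stop_parse(path, i, paste0("malformed term line: ", ln))
    }
    head <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
    if (length(head) != 3L) stop_parse(path, i, "expected 'Type start end'")
    start <- suppressWarnings(as.integer(head[2]))
    end <- suppressWarnings(as.integer(head[3]))
    if (is.na(start) || is.na(end)) stop_parse(path, i, "non-numeric offsets")
    if (!span_valid(text, start, end)) {
      stop_parse(path, i, sprintf("span [%d,%d) outside text of length %d",
                                  start, end, nchar(text)))
    }
    if (!identical(span_text(text, start, end), fields[3])) {
      stop_parse(path, i, sprintf(
        "term text %s does not match text at [%d,%d) (%s)",
        dQuote(fields[3]), start, end, dQuote(span_text(text, start, end))))
    }
    if (!is.null(expected_type) && head[1] != expected_type) {
      stop_parse(path, i, paste0("unexpected term type ", head[1]))
    }
    ids <- c(ids, fields[1]); types <- c(types, head[1])
    starts <- c(starts, start); ends <- c(ends, end); texts <- c(texts, fields[3])
  }
  data.frame(id = ids, type = types, start = starts, end = ends, text = texts,
             stringsAsFactors = FALSE)
}

# Parse an .a2: expression terms + Coref relations, resolving term ids
# (from the .a2 itself or from the .a1) to spans.
parse_a2 <- function(path, text, a1_terms) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  term_lines <- grepl("^T", lines)
  terms <- if (any(nzchar(lines[term_lines]))) {
    tmp <- tempfile(fileext = ".a2terms")
    writeLines(lines[term_lines], tmp)
    on.exit(unlink(tmp), add = TRUE)
    tt <- parse_term_lines(tmp, text)
    tt
  } else {
    data.frame(id = character(0), type = character(0), start = integer(0),
               end = integer(0), text = character(0), stringsAsFactors = FALSE)
  }
  all_terms <- rbind(a1_terms, terms)
  if (anyDuplicated(all_terms$id)) stop_parse(path, 0L, "term id clashes with .a1")

  an_s <- integer(0); an_e <- integer(0); an_t <- character(0)
  at_s <- integer(0); at_e <- integer(0); at_t <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || grepl("^T", ln)) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L || !grepl("^R[0-9]+$", fields[1])) {
      stop_parse(path, i, paste0("malformed relation line: ", ln))
    }
    parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
    if (length(parts) != 3L || parts[1] != "Coref") {
      stop_parse(path, i, "expected 'Coref Anaphora:Tx Antecedent:Ty'")
    }
    args <- sub("^[A-Za-z]+:", "", parts[2:3])
    names(args) <- sub(":.*$", "", parts[2:3])
    if (!setequal(names(args), c("Anaphora", "Antecedent"))) {
      stop_parse(path, i, "relation needs Anaphora and Antecedent arguments")
    }
    resolve <- function(tid) {
      j <- match(tid, all_terms$id)
      if (is.na(j)) stop_parse(path, i, paste0("dangling term reference ", tid))
      all_terms[j, ]
    }
    an <- resolve(args[["Anaphora"]])
    at <- resolve(args[["Antecedent"]])
    an_s <- c(an_s, an$start); an_e <- c(an_e, an$end); an_t <- c(an_t, an$text)
    at_s <- c(at_s, at$start); at_e <- c(at_e, at$end); at_t <- c(at_t, at$text)
  }
  data.frame(anaphor_start = an_s, anaphor_end = an_e, anaphor_text = an_t,
             antecedent_start = at_s, antecedent_end = at_e,
             antecedent_text = at_t, stringsAsFactors = FALSE)
}

#' Write predicted coreference links as a standoff .a2 file
#'
#' Emits one expression term per distinct anaphor/antecedent span (terms
#' sorted by start offset, ids continuing after the highest `.a1` term id)
#' and one `Coref` relation per link. Output is deterministic and
#' re-readable by [read_standoff()]. Antecedent-protein links are not
#' stored; they are recomputed with [derive_protein_links()].
#'
#' @param document A `coref_document`.
#' @param links Data frame with `anaphor_start`, `anaphor_end`,
#'   `antecedent_start`, `antecedent_end` (extra columns ignored).
#' @param a2_path Output path.
#' @return `a2_path`, invisibly.
#' @export
write_predictions <- function(document, links, a2_path) {
  text <- document$text
  links <- as.data.frame(links)
  if (nrow(links)) {
    ok <- vapply(seq_len(nrow(links)), function(i) {
      span_valid(text, links$anaphor_start[i], links$anaphor_end[i]) &&
        span_valid(text, links$antecedent_start[i], links$antecedent_end[i])
    }, logical(1))
    if (!all(ok)) stop("link with invalid span; nothing written", call. = FALSE)
  }

  spans <- unique(data.frame(
    start = c(links$anaphor_start, links$antecedent_start),
    end = c(links$anaphor_end, links$antecedent_end)))
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  a1_nums <- suppressWarnings(as.integer(sub("^T", "", document$proteins$id)))
  next_id <- if (length(a1_nums) && any(!is.na(a1_nums))) {
    max(a1_nums, na.rm = TRUE) + 1L
  } else 1L
  spans$id <- if (nrow(spans)) paste0("T", seq(next_id, length.out = nrow(spans))) else character(0)

  term_lines <- vapply(seq_len(nrow(spans)), function(i) {
    sprintf("%s\tExp %d %d\t%s", spans$id[i], spans$start[i], spans$end[i],
            span_text(text, spans$start[i], spans$end[i]))
  }, character(1))

  find_id <- function(s, e) spans$id[spans$start == s & spans$end == e]
  ord <- if (nrow(links)) order(links$anaphor_start, links$anaphor_end,
                                links$antecedent_start) else integer(0)
  rel_lines <- vapply(seq_along(ord), function(k) {
    i <- ord[k]
    sprintf("R%d\tCoref Anaphora:%s Antecedent:%s", k,
            find_id(links$anaphor_start[i], links$anaphor_end[i]),
            find_id(links$antecedent_start[i], links$antecedent_end[i]))
  }, character(1))

  writeLines(c(term_lines, rel_lines), a2_path)
  invisible(a2_path)
}

#' Derive protein coreference links from expression-level links
#'
#' The shared-task's primary metric scores (anaphor, antecedent protein)
#' pairs. For every expression-level link whose antecedent span contains one
#' or more gold protein mentions, one protein link is emitted per contained
#' mention; links whose antecedent contains no protein yield nothing.
#'
#' @param gold_links Data frame of expression links (columns
#'   `anaphor_start`, `anaphor_end`, `antecedent_start`, `antecedent_end`).
#' @param proteins Protein mention data frame (`id`, `start`, `end`).
#' @return Data frame `anaphor_start`, `anaphor_end`, `protein_id`.
#' @export
derive_protein_links <- function(gold_links, proteins) {
  out <- data.frame(anaphor_start = integer(0), anaphor_end = integer(0),
                    protein_id = character(0), stringsAsFactors = FALSE)
  if (is.null(gold_links) || !nrow(gold_links)) return(out)
  for (i in seq_len(nrow(gold_links))) {
    inside <- proteins$start >= gold_links$antecedent_start[i] &
      proteins$end <= gold_links$antecedent_end[i]
    if (any(inside)) {
      out <- rbind(out, data.frame(
        anaphor_start = gold_links$anaphor_start[i],
        anaphor_end = gold_links$anaphor_end[i],
        protein_id = proteins$id[inside], stringsAsFactors = FALSE))
    }
  }
  unique(out)
}
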