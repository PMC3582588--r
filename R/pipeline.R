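# Directory-level pipeline: resolve a directory of standoff documents,
# evaluate predictions against gold, and a corpus-level scoring helper.

read_document_set <- function(dir, with_gold = TRUE, parse_suffix = ".parse.jsonl") {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(txt) {
    base <- sub("\\.txt$", "", txt)
    a2 <- paste0(base, ".a2")
    doc <- read_standoff(txt, paste0(base, ".a1"),
                         if (with_gold && file.exists(a2)) a2 else NULL)
    parse_path <- paste0(base, parse_suffix)
    sentences <- if (file.exists(parse_path)) {
      parse_document(doc, gold_parse_backend(parse_path))
    } else NULL
    list(document = doc, sentences = sentences)
  })
}

#' Resolve every document in a directory
#'
#' Reads `<doc>.txt` / `<doc>.a1` (and `<doc>.parse.jsonl` gold parses, or a
#' supplied backend), runs [resolve_document()] and writes `<doc>.a2`
#' predictions to the output directory.
#'
#' @param input_dir Directory of standoff documents.
#' @param output_dir Output directory for predicted `.a2` files.
#' @param config A [rule_config()] or [preset_config()] result.
#' @param backend Optional parser backend; by default gold-parse fixture
#'   files next to the documents are used.
#' @param lexicons Lexicon list.
#' @param keep_going Continue past document-level errors (collecting them in
#'   the result) instead of stopping.
#' @return Invisibly, a list with per-document link data frames and `errors`.
#' @export
resolve_directory <- function(input_dir, output_dir,
                              config = preset_config("rb-full"),
                              backend = NULL, lexicons = default_lexicons(),
                              keep_going = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- read_document_set(input_dir, with_gold = FALSE)
  results <- list()
  errors <- character(0)
  for (entry in entries) {
    doc <- entry$document
    res <- tryCatch({
      sentences <- if (!is.null(backend)) parse_document(doc, backend)
        else entry$sentences
      if (is.null(sentences)) {
        stop("no parse available for ", doc$doc_id,
             " (supply a backend or a .parse.jsonl fixture)", call. = FALSE)
      }
      links <- resolve_document(doc, sentences, config, lexicons)
      write_predictions(doc, links, file.path(output_dir,
                                              paste0(doc$doc_id, ".a2")))
      links
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0(doc$doc_id, ": ", conditionMessage(res))
      if (!keep_going) stop(msg, call. = FALSE)
      errors <- c(errors, msg)
    } else {
      results[[doc$doc_id]] <- res
    }
  }
  invisible(list(links = results, errors = errors))
}

#' Score a resolved corpus in memory
#'
#' Pools gold and response protein links over all documents and scores them
#' with the protein-link metric; optionally also computes the
#' partition-based metrics (micro-averaged counts over documents).
#'
#' @param corpus List of `list(document, sentences)` entries, with gold
#'   links on the documents (e.g. [generate_corpus()] output or
#'   [packaged_examples()] fixtures).
#' @param config A [rule_config()].
#' @param lexicons Lexicon list.
#' @param metrics Character vector among `"protein-link"`, `"muc"`, `"b3"`,
#'   `"ceaf-m"`, `"ceaf-e"`, `"blanc"`.
#' @param match_mode Anaphor span matching for the protein-link metric.
#' @param by_type Also break the protein-link score down by anaphor type
#'   (PRON / DNP / RELAT).
#' @return A list of `coref_score` objects keyed by metric (with a
#'   `by_type` sublist when requested) plus `links` (response links per
#'   document).
#' @export
score_corpus <- function(corpus, config = preset_config("rb-full"),
                         lexicons = default_lexicons(),
                         metrics = "protein-link",
                         match_mode = c("lenient", "strict"),
                         by_type = FALSE) {
  match_mode <- match.arg(match_mode)
  gold_pl <- list(); resp_pl <- list(); resp_links <- list()
  agg <- list()
  for (entry in corpus) {
    doc <- entry$document
    links <- resolve_document(doc, entry$sentences, config, lexicons)
    resp_links[[doc$doc_id]] <- links
    g <- derive_protein_links(doc$gold_links, doc$proteins)
    r <- derive_protein_links(links, doc$proteins)
    if (nrow(g)) { g$doc_id <- doc$doc_id; gold_pl[[doc$doc_id]] <- g }
    if (nrow(r)) { r$doc_id <- doc$doc_id; resp_pl[[doc$doc_id]] <- r }

    part_metrics <- setdiff(metrics, "protein-link")
    if (length(part_metrics)) {
      key <- partition_from_links(doc$gold_links)
      resp <- partition_from_links(links, mentions = key$mentions)
      key <- mention_partition(key$chains, mentions = resp$mentions)
      for (m in part_metrics) {
        sc <- switch(m,
          muc = muc_score(key, resp),
          b3 = b_cubed_score(key, resp),
          "ceaf-m" = ceaf_score(key, resp, "mention"),
          "ceaf-e" = ceaf_score(key, resp, "entity"),
          blanc = blanc_score(key, resp),
          stop("unknown metric ", m))
        agg[[m]] <- if (is.null(agg[[m]])) list(sc) else c(agg[[m]], list(sc))
      }
    }
  }
  bind_or_empty <- function(lst) {
    if (length(lst)) do.call(rbind, lst) else {
      data.frame(anaphor_start = integer(0), anaphor_end = integer(0),
                 protein_id = character(0), doc_id = character(0))
    }
  }
  gold_all <- bind_or_empty(gold_pl)
  resp_all <- bind_or_empty(resp_pl)
  out <- list()
  if ("protein-link" %in% metrics) {
    out[["protein-link"]] <- score_protein_links(gold_all, resp_all, match_mode)
    if (by_type) {
      gold_types <- anaphor_surface_type(link_anaphor_texts(corpus, gold_all))
      resp_types <- anaphor_surface_type(link_anaphor_texts(corpus, resp_all))
      out$by_type <- lapply(c(PRON = "PRON", DNP = "DNP", RELAT = "RELAT"),
        function(tt) {
          score_protein_links(gold_all[gold_types == tt, , drop = FALSE],
                              resp_all[resp_types == tt, , drop = FALSE],
                              match_mode)
        })
    }
  }
  for (m in names(agg)) {
    sums <- vapply(agg[[m]], function(sc) unlist(sc$counts), numeric(4))
    if (m == "blanc") {
      # blanc counts are a 2x3 structure; average doc-level scores instead
      out[[m]] <- agg[[m]][[1]]
      out[[m]]$recall <- mean(vapply(agg[[m]], `[[`, numeric(1), "recall"))
      out[[m]]$precision <- mean(vapply(agg[[m]], `[[`, numeric(1), "precision"))
      out[[m]]$f_score <- mean(vapply(agg[[m]], `[[`, numeric(1), "f_score"))
    } else {
      out[[m]] <- coref_score(sum(sums["recall_num", ]), sum(sums["recall_den", ]),
                              sum(sums["precision_num", ]),
                              sum(sums["precision_den", ]),
                              metric = agg[[m]][[1]]$metric)
    }
  }
  out$links <- resp_links
  out
}

# surface texts of gold protein-link anaphors, for by-type breakdowns
link_anaphor_texts <- function(corpus, protein_links) {
  texts <- stats::setNames(
    vapply(corpus, function(e) e$document$text, character(1)),
    vapply(corpus, function(e) e$document$doc_id, character(1)))
  vapply(seq_len(nrow(protein_links)), function(i) {
    span_text(texts[[protein_links$doc_id[i]]],
              protein_links$anaphor_start[i], protein_links$anaphor_end[i])
  }, character(1))
}

#' Coarse anaphor type from surface form
#'
#' Maps an anaphor's surface string to the coarse typology used in
#' evaluation breakdowns: `RELAT` (that/which/who), `PRON` (other
#' pronouns), `DNP` (definite noun phrases), `OTHER`.
#'
#' @param text Character vector of anaphor surface strings.
#' @return Character vector of type labels.
#' @export
anaphor_surface_type <- function(text) {
  lw <- tolower(trimws(text))
  first <- sub("\\s.*$", "", lw)
  vapply(seq_along(lw), function(i) {
    if (lw[i] %in% c("that", "which", "who")) return("RELAT")
    if (lw[i] %in% c("it", "its", "itself", "they", "their", "them",
                     "themselves", "this", "these", "those", "both",
                     "either")) return("PRON")
    if (!grepl("\\s", lw[i])) return("OTHER")
    if (first[i] %in% c("the", "this", "that", "these", "those", "both",
                        "its", "their")) return("DNP")
    "OTHER"
  }, character(1))
}

#' Evaluate a prediction directory against a gold directory
#'
#' @param gold_dir Directory with `.txt`, `.a1`, gold `.a2`.
#' @param pred_dir Directory with predicted `.a2` files (same doc ids).
#' @param metrics Metrics to compute (see [score_corpus()]); `"all"` for
#'   every metric.
#' @param match_mode Protein-link anaphor span matching.
#' @return Data frame with one row per metric: recall, precision, F.
#' @export
evaluate_directories <- function(gold_dir, pred_dir,
                                 metrics = "protein-link",
                                 match_mode = c("lenient", "strict")) {
  match_mode <- match.arg(match_mode)
  if (identical(metrics, "all")) {
    metrics <- c("protein-link", "muc", "b3", "ceaf-m", "ceaf-e", "blanc")
  }
  gold <- read_document_set(gold_dir, with_gold = TRUE)
  rows <- list()
  scores <- list()
  gold_pl <- list(); resp_pl <- list()
  agg <- list()
  for (entry in gold) {
    doc <- entry$document
    pred_path <- file.path(pred_dir, paste0(doc$doc_id, ".a2"))
    pred <- if (file.exists(pred_path)) {
      parse_a2(pred_path, doc$text, doc$proteins)
    } else {
      data.frame(anaphor_start = integer(0), anaphor_end = integer(0),
                 anaphor_text = character(0), antecedent_start = integer(0),
                 antecedent_end = integer(0), antecedent_text = character(0))
    }
    g <- derive_protein_links(doc$gold_links, doc$proteins)
    r <- derive_protein_links(pred, doc$proteins)
    if (nrow(g)) { g$doc_id <- doc$doc_id; gold_pl[[doc$doc_id]] <- g }
    if (nrow(r)) { r$doc_id <- doc$doc_id; resp_pl[[doc$doc_id]] <- r }
    part_metrics <- setdiff(metrics, "protein-link")
    if (length(part_metrics)) {
      key <- partition_from_links(doc$gold_links)
      resp <- partition_from_links(pred, mentions = key$mentions)
      key <- mention_partition(key$chains, mentions = resp$mentions)
      for (m in part_metrics) {
        sc <- switch(m,
          muc = muc_score(key, resp), b3 = b_cubed_score(key, resp),
          "ceaf-m" = ceaf_score(key, resp, "mention"),
          "ceaf-e" = ceaf_score(key, resp, "entity"),
          blanc = blanc_score(key, resp))
        agg[[m]] <- c(agg[[m]], list(sc))
      }
    }
  }
  bind_or_empty <- function(lst) {
    if (length(lst)) do.call(rbind, lst) else {
      data.frame(anaphor_start = integer(0), anaphor_end = integer(0),
                 protein_id = character(0), doc_id = character(0))
    }
  }
  if ("protein-link" %in% metrics) {
    scores[["protein-link"]] <-
      score_protein_links(bind_or_empty(gold_pl), bind_or_empty(resp_pl),
                          match_mode)
  }
  for (m in names(agg)) {
    if (m == "blanc") {
      sc <- agg[[m]][[1]]
      sc$recall <- mean(vapply(agg[[m]], `[[`, numeric(1), "recall"))
      sc$precision <- mean(vapply(agg[[m]], `[[`, numeric(1), "precision"))
      sc$f_score <- mean(vapply(agg[[m]], `[[`, numeric(1), "f_score"))
      scores[[m]] <- sc
    } else {
      sums <- vapply(agg[[m]], function(sc) unlist(sc$counts), numeric(4))
      scores[[m]] <- coref_score(
        sum(sums["recall_num", ]), sum(sums["recall_den", ]),
        sum(sums["precision_num", ]), sum(sums["precision_den", ]),
        metric = agg[[m]][[1]]$metric)
    }
  }
  do.call(rbind, lapply(names(scores), function(m) {
    data.frame(metric = m, recall = scores[[m]]$recall,
               precision = scores[[m]]$precision,
               f_score = scores[[m]]$f_score, stringsAsFactors = FALSE)
  }))
}
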