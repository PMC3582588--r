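# Scoring. The task's primary metric counts protein coreference links
# (anaphor, antecedent-protein id). The standard partition-based coreference
# metrics (MUC, B-cubed, CEAF-M/E, BLANC) are provided for comparison.

#' Construct a recall/precision/F score with its underlying counts
#'
#' @param recall_num,recall_den,precision_num,precision_den Numerators and
#'   denominators (counts or count-like sums).
#' @param metric Metric name.
#' @param flags Character vector of degeneracy flags (e.g. an undefined side
#'   reported as 0).
#' @return An object of class `coref_score` with `recall`, `precision`,
#'   `f_score` and `counts`.
#' @export
coref_score <- function(recall_num, recall_den, precision_num, precision_den,
                        metric = "score", flags = character(0)) {
  r <- if (recall_den > 0) recall_num / recall_den else 0
  p <- if (precision_den > 0) precision_num / precision_den else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(recall = r, precision = p, f_score = f,
                 counts = list(recall_num = recall_num, recall_den = recall_den,
                               precision_num = precision_num,
                               precision_den = precision_den),
                 metric = metric, flags = flags),
            class = "coref_score")
}

#' @export
print.coref_score <- function(x, ...) {
  cat(sprintf("%-12s R=%5.1f%% P=%5.1f%% F=%5.1f%%%s\n", x$metric,
              100 * x$recall, 100 * x$precision, 100 * x$f_score,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

dedup_links <- function(links) {
  unique(links[, intersect(c("doc_id", "anaphor_start", "anaphor_end",
                             "protein_id"), names(links)), drop = FALSE])
}

#' Score protein coreference links
#'
#' The primary task metric: a response link is correct when it names the
#' same antecedent protein as a gold link and its anaphor span matches the
#' gold anaphor (equal spans in `strict` mode, overlapping spans in
#' `lenient` mode, the default). Each gold link is credited at most once via
#' maximum bipartite matching on the match relation.
#'
#' @param gold,response Data frames of protein links (`anaphor_start`,
#'   `anaphor_end`, `protein_id`, optional `doc_id`); see
#'   [derive_protein_links()].
#' @param match_mode `"lenient"` or `"strict"`.
#' @return A `coref_score`.
#' @export
score_protein_links <- function(gold, response,
                                match_mode = c("lenient", "strict")) {
  match_mode <- match.arg(match_mode)
  gold <- dedup_links(gold)
  response <- dedup_links(response)
  if (!"doc_id" %in% names(gold)) gold$doc_id <- "doc"
  if (!"doc_id" %in% names(response)) response$doc_id <- "doc"

  correct <- 0L
  for (d in unique(c(gold$doc_id, response$doc_id))) {
    g <- gold[gold$doc_id == d, , drop = FALSE]
    r <- response[response$doc_id == d, , drop = FALSE]
    if (!nrow(g) || !nrow(r)) next
    pairs <- NULL
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(nrow(r))) {
        if (g$protein_id[i] != r$protein_id[j]) next
        ok <- if (match_mode == "strict") {
          g$anaphor_start[i] == r$anaphor_start[j] &&
            g$anaphor_end[i] == r$anaphor_end[j]
        } else {
          span_overlaps(g$anaphor_start[i], g$anaphor_end[i],
                        r$anaphor_start[j], r$anaphor_end[j])
        }
        if (ok) pairs <- rbind(pairs, c(i, j))
      }
    }
    correct <- correct + max_bipartite_size(pairs, nrow(g), nrow(r))
  }
  coref_score(correct, nrow(gold), correct, nrow(response), "protein-link")
}

# size of a maximum matching in the bipartite graph given by `pairs`
# (2-column matrix of left/right indices)
max_bipartite_size <- function(pairs, n_left, n_right) {
  if (is.null(pairs) || !nrow(pairs)) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n_left), rep(TRUE, n_right)),
    edges = as.vector(t(cbind(pairs[, 1], n_left + pairs[, 2]))))
  igraph::max_bipartite_match(g)$matching_size
}

# ---- mention partitions ----------------------------------------------------

#' Construct a mention partition
#'
#' @param chains List of character vectors; each vector is one coreference
#'   chain (entity). Chains must be disjoint. Singleton chains are allowed
#'   and count as entities.
#' @param mentions Optional full mention universe; mentions not in any chain
#'   are added as singleton chains.
#' @return Object of class `mention_partition`.
#' @export
mention_partition <- function(chains, mentions = NULL) {
  chains <- lapply(chains, as.character)
  all_m <- unlist(chains, use.names = FALSE)
  if (anyDuplicated(all_m)) stop("chains are not disjoint", call. = FALSE)
  if (!is.null(mentions)) {
    extra <- setdiff(as.character(mentions), all_m)
    chains <- c(chains, as.list(extra))
    all_m <- c(all_m, extra)
  }
  structure(list(chains = chains, mentions = all_m),
            class = "mention_partition")
}

#' Build a mention partition from coreference links
#'
#' Mentions are identified by their spans (`"start-end"` strings); links
#' merge mentions into chains (transitive closure).
#'
#' @param links Data frame with `anaphor_start`, `anaphor_end`,
#'   `antecedent_start`, `antecedent_end`.
#' @param mentions Optional extra mention ids to include as singletons.
#' @return A [mention_partition()].
#' @export
partition_from_links <- function(links, mentions = NULL) {
  mid <- function(s, e) paste0(s, "-", e)
  ids <- unique(c(mid(links$anaphor_start, links$anaphor_end),
                  mid(links$antecedent_start, links$antecedent_end),
                  as.character(mentions)))
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(links))) {
    a <- find(mid(links$anaphor_start[i], links$anaphor_end[i]))
    b <- find(mid(links$antecedent_start[i], links$antecedent_end[i]))
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(ids, find, character(1))
  mention_partition(unname(split(ids, roots)))
}

chain_id_of <- function(partition) {
  out <- character(0)
  for (i in seq_along(partition$chains)) {
    ch <- partition$chains[[i]]
    out[ch] <- as.character(i)
  }
  out
}

#' MUC link-based score
#'
#' Recall is the number of key links recovered, computed per key chain as
#' `|S| - p(S)` where `p(S)` is the number of pieces the response partition
#' cuts `S` into, over `|S| - 1`; precision is symmetric. A key with only
#' singleton chains has an undefined recall, reported as 0 and flagged.
#'
#' @param key,response [mention_partition()] objects.
#' @return A `coref_score`.
#' @export
muc_score <- function(key, response) {
  side <- function(a, b) {
    b_of <- chain_id_of(b)
    num <- 0; den <- 0
    for (S in a$chains) {
      ids <- b_of[S]
      ids[is.na(ids)] <- paste0("twinless-", S[is.na(ids)])
      num <- num + length(S) - length(unique(ids))
      den <- den + length(S) - 1L
    }
    c(num, den)
  }
  r <- side(key, response)
  p <- side(response, key)
  flags <- character(0)
  if (r[2] == 0) flags <- c(flags, "no-key-links")
  if (p[2] == 0) flags <- c(flags, "no-response-links")
  coref_score(r[1], r[2], p[1], p[2], "MUC", flags)
}

#' B-cubed score
#'
#' Per-mention precision and recall (overlap of the mention's key and
#' response chains over the response resp. key chain size), averaged
#' uniformly over mentions. Response mentions absent from the key count for
#' precision only, and vice versa (the absent side treats the mention as a
#' singleton).
#'
#' @param key,response [mention_partition()] objects.
#' @return A `coref_score`.
#' @export
b_cubed_score <- function(key, response) {
  if (!length(key$mentions)) stop("empty key mention set", call. = FALSE)
  side_sum <- function(a, b) {
    # sum over a's mentions m of |A(m) /\ B(m)| / |A(m)|; grouping the
    # mentions of a chain A by their b-chain, each group of size g
    # contributes g * g / |A| (mentions absent from b are singletons there)
    b_of <- chain_id_of(b)
    total <- 0
    for (A in a$chains) {
      ids <- b_of[A]
      ids[is.na(ids)] <- paste0("twinless-", A[is.na(ids)])
      total <- total + sum(tabulate(match(ids, unique(ids)))^2) / length(A)
    }
    total
  }
  coref_score(side_sum(key, response), length(key$mentions),
              side_sum(response, key), length(response$mentions), "B3")
}

#' CEAF score (mention- or entity-based)
#'
#' Chains of the key and response are aligned one-to-one so as to maximize
#' total similarity (the optimal alignment of the Kuhn-Munkres assignment
#' problem, solved via maximum-weight bipartite matching). The mention
#' variant uses `phi(K,R) = |K /\ R|`; the entity variant
#' `phi4(K,R) = 2|K /\ R| / (|K| + |R|)`. Recall divides the total by the
#' key self-similarity, precision by the response self-similarity.
#'
#' @param key,response [mention_partition()] objects.
#' @param variant `"mention"` (CEAF-M) or `"entity"` (CEAF-E).
#' @return A `coref_score`.
#' @export
ceaf_score <- function(key, response, variant = c("mention", "entity")) {
  variant <- match.arg(variant)
  phi <- if (variant == "mention") {
    function(K, R) length(intersect(K, R))
  } else {
    function(K, R) 2 * length(intersect(K, R)) / (length(K) + length(R))
  }
  nk <- length(key$chains); nr <- length(response$chains)
  total <- 0
  if (nk && nr) {
    w <- numeric(0); edges <- integer(0)
    for (i in seq_len(nk)) {
      for (j in seq_len(nr)) {
        s <- phi(key$chains[[i]], response$chains[[j]])
        if (s > 0) {
          edges <- c(edges, i, nk + j)
          w <- c(w, s)
        }
      }
    }
    if (length(w)) {
      g <- igraph::make_bipartite_graph(
        types = c(rep(FALSE, nk), rep(TRUE, nr)), edges = edges)
      m <- igraph::max_bipartite_match(g, weights = w)
      matched <- m$matching[seq_len(nk)]
      for (i in seq_len(nk)) {
        if (!is.na(matched[i])) {
          total <- total + phi(key$chains[[i]],
                               response$chains[[as.integer(matched[i]) - nk]])
        }
      }
    }
  }
  self_k <- sum(vapply(key$chains, function(K) phi(K, K), numeric(1)))
  self_r <- sum(vapply(response$chains, function(R) phi(R, R), numeric(1)))
  coref_score(total, self_k, total, self_r,
              if (variant == "mention") "CEAF-M" else "CEAF-E")
}

#' BLANC score
#'
#' Rand-index style metric: precision/recall/F are computed separately over
#' coreferent mention pairs and non-coreferent mention pairs (over the union
#' mention universe; mentions absent from a partition count as singletons
#' there), and the BLANC values are the arithmetic means of the two sides.
#' When the key has no coreferent (or no non-coreferent) pair, only the
#' defined side is meaningful; the undefined side is reported as 0 and
#' flagged.
#'
#' @param key,response [mention_partition()] objects.
#' @return A `coref_score` whose `counts` carry both sides.
#' @export
blanc_score <- function(key, response) {
  universe <- union(key$mentions, response$mentions)
  n <- length(universe)
  # chain assignment per mention; mentions absent from a partition are
  # singletons there (unique labels)
  assign_in <- function(partition) {
    v <- stats::setNames(paste0("s", seq_len(n)), universe)
    ids <- chain_id_of(partition)
    v[names(ids)] <- ids
    v
  }
  kc <- 0; krc <- 0; rc <- 0   # key-coref, both-coref, response-coref counts
  kn <- 0; krn <- 0; rn <- 0
  if (n >= 2) {
    ka <- assign_in(key); ra <- assign_in(response)
    pairs <- utils::combn(n, 2L)
    in_k <- ka[pairs[1, ]] == ka[pairs[2, ]]
    in_r <- ra[pairs[1, ]] == ra[pairs[2, ]]
    kc <- sum(in_k); kn <- sum(!in_k)
    rc <- sum(in_r); rn <- sum(!in_r)
    krc <- sum(in_k & in_r); krn <- sum(!in_k & !in_r)
  }
  rate <- function(num, den) if (den > 0) num / den else 0
  r_c <- rate(krc, kc); p_c <- rate(krc, rc)
  r_n <- rate(krn, kn); p_n <- rate(krn, rn)
  f_c <- if (p_c + r_c > 0) 2 * p_c * r_c / (p_c + r_c) else 0
  f_n <- if (p_n + r_n > 0) 2 * p_n * r_n / (p_n + r_n) else 0
  flags <- character(0)
  if (kc == 0) flags <- c(flags, "no-coref-pairs-in-key")
  if (kn == 0) flags <- c(flags, "no-noncoref-pairs-in-key")
  out <- coref_score(krc + krn, 1, krc + krn, 1, "BLANC", flags)
  out$recall <- (r_c + r_n) / 2
  out$precision <- (p_c + p_n) / 2
  out$f_score <- (f_c + f_n) / 2
  out$counts <- list(coref = c(correct = krc, key = kc, response = rc),
                     noncoref = c(correct = krn, key = kn, response = rn))
  out
}
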