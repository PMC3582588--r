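# Independent brute-force scorer oracles and set-partition enumeration,
# used to verify the coreference metrics on every small partition pair.

part <- function(...) mention_partition(list(...))

# all set partitions of `items` (list of lists of character vectors)
enumerate_partitions <- function(items) {
  if (length(items) == 0) return(list(list()))
  first <- items[1]
  rest <- enumerate_partitions(items[-1])
  out <- list()
  for (p in rest) {
    # add `first` to each existing block, or as a new block
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], first)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(first))
  }
  out
}

.perm_cache <- new.env(parent = emptyenv())
perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- if (n == 1) matrix(1L) else {
    sub <- perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      unname(cbind(i, sub + (sub >= i)))
    }))
  }
  .perm_cache[[key]] <- out
  out
}

# MUC oracle: count recovered spanning links by partition refinement
oracle_muc <- function(key, response) {
  assign_of <- function(p, universe) {
    v <- stats::setNames(paste0("s", seq_along(universe)), universe)
    for (i in seq_along(p$chains)) v[p$chains[[i]]] <- paste0("c", i)
    v
  }
  side <- function(a, b) {
    uni <- union(a$mentions, b$mentions)
    bv <- assign_of(b, uni)
    num <- 0L; den <- 0L
    for (S in a$chains) {
      den <- den + length(S) - 1L
      num <- num + length(S) - length(unique(bv[S]))
    }
    c(num = num, den = den)
  }
  r <- side(key, response); p <- side(response, key)
  rr <- if (r["den"] > 0) r["num"] / r["den"] else 0
  pp <- if (p["den"] > 0) p["num"] / p["den"] else 0
  ff <- if (rr + pp > 0) 2 * rr * pp / (rr + pp) else 0
  c(recall = unname(rr), precision = unname(pp), f = unname(ff))
}

# B-cubed oracle via the pair-counting formulation
oracle_b3 <- function(key, response) {
  same <- function(p, m1, m2) {
    for (ch in p$chains) if (m1 %in% ch) return(m2 %in% ch)
    FALSE
  }
  side <- function(a, b) {
    tot <- 0
    for (m in a$mentions) {
      A <- a$mentions[vapply(a$mentions, function(x) same(a, m, x), logical(1))]
      hits <- sum(vapply(A, function(x) x == m || same(b, m, x), logical(1)))
      tot <- tot + hits / length(A)
    }
    tot / length(a$mentions)
  }
  rr <- side(key, response); pp <- side(response, key)
  ff <- if (rr + pp > 0) 2 * rr * pp / (rr + pp) else 0
  c(recall = rr, precision = pp, f = ff)
}

# CEAF oracle: exhaustive search over chain injections
oracle_ceaf <- function(key, response, variant) {
  phi <- if (variant == "mention") {
    function(K, R) length(intersect(K, R))
  } else {
    function(K, R) 2 * length(intersect(K, R)) / (length(K) + length(R))
  }
  kc <- key$chains; rc <- response$chains
  small <- if (length(kc) <= length(rc)) kc else rc
  large <- if (length(kc) <= length(rc)) rc else kc
  best <- 0
  if (length(small)) {
    phimat <- outer(seq_along(small), seq_along(large),
                    Vectorize(function(i, j) phi(small[[i]], large[[j]])))
    pm <- perms(length(large))
    tot <- numeric(nrow(pm))
    for (i in seq_along(small)) tot <- tot + phimat[i, pm[, i]]
    best <- max(tot)
  }
  self_k <- sum(vapply(kc, function(K) phi(K, K), numeric(1)))
  self_r <- sum(vapply(rc, function(R) phi(R, R), numeric(1)))
  rr <- if (self_k > 0) best / self_k else 0
  pp <- if (self_r > 0) best / self_r else 0
  ff <- if (rr + pp > 0) 2 * rr * pp / (rr + pp) else 0
  c(recall = rr, precision = pp, f = ff)
}

# BLANC oracle via the contingency-table closed form
oracle_blanc <- function(key, response) {
  uni <- union(key$mentions, response$mentions)
  assign_of <- function(p) {
    v <- stats::setNames(paste0("s", seq_along(uni)), uni)
    for (i in seq_along(p$chains)) v[p$chains[[i]]] <- paste0("c", i)
    v
  }
  ka <- assign_of(key); ra <- assign_of(response)
  ch2 <- function(x) x * (x - 1) / 2
  n <- length(uni)
  tab <- table(ka, ra)
  bothc <- sum(ch2(tab))
  keyc <- sum(ch2(table(ka)))
  respc <- sum(ch2(table(ra)))
  total <- ch2(n)
  bothn <- total - keyc - respc + bothc
  keyn <- total - keyc; respn <- total - respc
  rate <- function(a, b) if (b > 0) a / b else 0
  r_c <- rate(bothc, keyc); p_c <- rate(bothc, respc)
  r_n <- rate(bothn, keyn); p_n <- rate(bothn, respn)
  f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  c(recall = (r_c + r_n) / 2, precision = (p_c + p_n) / 2,
    f = (f1(p_c, r_c) + f1(p_n, r_n)) / 2)
}

score_vec <- function(sc) {
  c(recall = sc$recall, precision = sc$precision, f = sc$f_score)
}
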