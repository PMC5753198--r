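# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and phyper where enumeration is feasible).

# P(X >= k) by literally enumerating all C(N, n) draws of n items from a
# population with K successes. Feasible only for tiny N.
oracle_tail_enumerate <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # items 1..K are the successes
  mean(hits >= k)
}

# P(X >= k) as an exact combinatorial sum over the support (independent
# closed form; choose() is exact in double for these magnitudes).
oracle_tail_sum <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- max(k, max(0, n - (N - K))):hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# BH step-up re-implementation: sort ascending, scale by m/rank, running
# minimum from the top, restore order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Triangles among `members` by triple enumeration over an edge lookup.
oracle_triangles <- function(members, net, min_conf = 0) {
  e <- net$edges[net$edges$confidence >= min_conf, , drop = FALSE]
  has <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(e))) {
    a <- sort(c(e$from[i], e$to[i]))
    assign(paste(a, collapse = "|"), TRUE, envir = has)
  }
  pair_in <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    exists(key, envir = has)
  }
  members <- sort(members)
  m <- length(members)
  if (m < 3) return(0L)
  cnt <- 0L
  for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (l in (j + 1):m) {
    if (pair_in(members[i], members[j]) &&
        pair_in(members[i], members[l]) &&
        pair_in(members[j], members[l])) cnt <- cnt + 1L
  }
  cnt
}

# Within-set edge count by double loop over member pairs.
oracle_pairs <- function(members, net, min_conf = 0) {
  e <- net$edges[net$edges$confidence >= min_conf, , drop = FALSE]
  cnt <- 0L
  members <- sort(members)
  m <- length(members)
  if (m < 2) return(0L)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    hit <- (e$from == members[i] & e$to == members[j]) |
      (e$from == members[j] & e$to == members[i])
    if (any(hit)) cnt <- cnt + 1L
  }
  cnt
}

# All-pairs m-type edge list recomputed from first principles.
oracle_m_type <- function(corpus, pmf_thr, tail_thr) {
  ids <- names(corpus$sets)
  N <- length(corpus$universe)
  out <- data.frame(source_id = character(0), target_id = character(0))
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    A <- corpus$sets[[a]]$members
    B <- corpus$sets[[b]]$members
    k <- length(intersect(A, B))
    if (k == 0) next
    v1 <- -log10(max(dhyper(k, length(A), N - length(A), length(B)), 1e-320))
    v2 <- -log10(max(phyper(k - 1, length(A), N - length(A), length(B),
                            lower.tail = FALSE), 1e-320))
    if (v1 > pmf_thr && v2 > tail_thr) {
      s <- sort(c(ids[a], ids[b]))
      out <- rbind(out, data.frame(source_id = s[1], target_id = s[2],
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$source_id, out$target_id), , drop = FALSE]
}

# All ordered-pairs r-type edge list recomputed from first principles.
oracle_r_type <- function(corpus, reg, pmf_alpha, tail_alpha) {
  ids <- names(corpus$sets)
  N <- length(corpus$universe)
  e <- reg$edges
  e <- e[e$from %in% corpus$universe & e$to %in% corpus$universe, ]
  E <- nrow(e)
  total <- as.numeric(N) * (N - 1)
  out <- data.frame(source_id = character(0), target_id = character(0),
                    k = integer(0))
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a == b) next
    A <- setdiff(corpus$sets[[a]]$members, corpus$sets[[b]]$members)
    B <- setdiff(corpus$sets[[b]]$members, corpus$sets[[a]]$members)
    k <- sum(e$from %in% A & e$to %in% B)
    if (k < 1) next
    draws <- as.numeric(length(A)) * length(B)
    pmf <- dhyper(k, E, total - E, draws)
    tail <- phyper(k - 1, E, total - E, draws, lower.tail = FALSE)
    if (pmf < pmf_alpha && tail < tail_alpha) {
      out <- rbind(out, data.frame(source_id = ids[a], target_id = ids[b],
                                   k = k, stringsAsFactors = FALSE))
    }
  }
  out[order(out$source_id, out$target_id), , drop = FALSE]
}

# RWR fixed point by dense linear solve: p = (1-r) W p + r u.
oracle_rwr <- function(members, net, restart, min_conf = 0) {
  m <- length(members)
  W <- matrix(0, m, m, dimnames = list(members, members))
  e <- net$edges[net$edges$confidence >= min_conf &
                   net$edges$confidence > 0, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    a <- e$from[i]; b <- e$to[i]
    if (a %in% members && b %in% members) {
      W[a, b] <- W[a, b] + e$confidence[i]
      W[b, a] <- W[b, a] + e$confidence[i]
    }
  }
  cs <- colSums(W)
  for (j in seq_len(m)) if (cs[j] > 0) W[, j] <- W[, j] / cs[j]
  u <- rep(1 / m, m)
  p <- solve(diag(m) - (1 - restart) * W, restart * u)
  stats::setNames(p / sum(p), members)
}
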