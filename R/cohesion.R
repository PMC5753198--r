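#' Theoretical number of gene pairs in a set of size n
#'
#' The denominator of pair coverage: a set of n genes contains
#' n(n-1)/2 unordered pairs (e.g. 6 genes -> 15 pairs, 101 genes -> 5050).
#'
#' @param n Non-negative integer set size (vectorized).
#' @return n(n-1)/2 as a double (exact for all practical sizes).
#' @export
theoretical_pairs <- function(n) {
  if (any(n < 0)) stop("set size must be non-negative")
  n * (n - 1) / 2
}

#' Theoretical number of gene trios in a set of size n
#' @param n Non-negative integer set size (vectorized).
#' @return n(n-1)(n-2)/6.
#' @export
theoretical_trios <- function(n) {
  if (any(n < 0)) stop("set size must be non-negative")
  n * (n - 1) * (n - 2) / 6
}

#' Count within-set PPI edges (observed pairs)
#'
#' Number of network edges whose two endpoints both belong to the set and
#' whose confidence passes the cutoff.
#'
#' @param set A \code{gene_set}.
#' @param ppi An undirected \code{gene_network}.
#' @param min_confidence Confidence cutoff in [0,1]; edges below it are
#'   ignored (default 0: use every edge).
#' @return Integer edge count.
#' @export
observed_pairs <- function(set, ppi, min_confidence = 0) {
  stopifnot(min_confidence >= 0, min_confidence <= 1)
  e <- ppi$edges
  sum(e$from %in% set$members & e$to %in% set$members &
        e$confidence >= min_confidence)
}

#' Count within-set PPI triangles (observed trios)
#'
#' A trio is counted when all three pairwise edges among three members pass
#' the confidence cutoff, i.e. triangles of the induced subgraph. Connected
#'-but-open triples do not count.
#'
#' @inheritParams observed_pairs
#' @return Integer triangle count.
#' @export
observed_trios <- function(set, ppi, min_confidence = 0) {
  stopifnot(min_confidence >= 0, min_confidence <= 1)
  g <- induced_member_graph(set, ppi, min_confidence)
  as.integer(sum(igraph::count_triangles(g)) / 3)
}

#' Summarize a background network for cohesion scoring
#'
#' Precomputes the null-model quantities shared by every set's CoCo score:
#' the universe size N, the number of background edges E among C(N,2)
#' possible pairs, and the number of background triangles T among C(N,3)
#' possible triples (all restricted to edges passing the confidence cutoff
#' and, when a universe is given, to endpoints inside it).
#'
#' @param ppi An undirected \code{gene_network}.
#' @param universe Character vector of background genes; defaults to the
#'   union of network endpoints.
#' @param min_confidence Confidence cutoff in [0,1].
#' @return A \code{cohesion_background} list with fields \code{n_genes},
#'   \code{total_pairs}, \code{edges}, \code{total_triples},
#'   \code{triangles}, \code{min_confidence}.
#' @export
cohesion_background <- function(ppi, universe = NULL, min_confidence = 0) {
  e <- ppi$edges
  e <- e[e$confidence >= min_confidence, , drop = FALSE]
  if (is.null(universe)) {
    universe <- unique(c(e$from, e$to))
  } else {
    universe <- normalize_symbols(universe)
    e <- e[e$from %in% universe & e$to %in% universe, , drop = FALSE]
  }
  n <- length(universe)
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = universe, stringsAsFactors = FALSE)
  )
  structure(list(
    n_genes = n,
    total_pairs = theoretical_pairs(n),
    edges = nrow(e),
    total_triples = theoretical_trios(n),
    triangles = sum(igraph::count_triangles(g)) / 3,
    min_confidence = min_confidence
  ), class = "cohesion_background")
}

# -log10 of the hypergeometric upper tail P(X >= k), floored so the log
# never overflows: draws `draws` from a population of `total` containing
# `good` successes.
neg_log10_tail <- function(k, good, total, draws) {
  p <- hypergeom_upper_tail(k, good, draws, total)
  -log10(max(p, 1e-320))
}

#' Cohesion coefficient (CoCo) of a gene set
#'
#' CoCo = S2 + lambda * S3, where S2 is the -log10 upper-tail
#' hypergeometric probability of covering at least the observed number of
#' within-set edges when n(n-1)/2 pairs are sampled from the C(N,2)
#' background pairs of which E are edges, and S3 is the analogous trio
#' statistic over background triangles T among C(N,3) triples. Larger CoCo
#' means the set's members are more densely functionally connected than
#' chance. Tail probabilities are floored at 1e-320 before taking logs.
#'
#' @param set A \code{gene_set} with at least 2 members.
#' @param ppi An undirected \code{gene_network}.
#' @param background A \code{cohesion_background}; computed from \code{ppi}
#'   when omitted (expensive for repeated calls: precompute it).
#' @param lambda Weight of the trio term (default 1).
#' @param min_confidence Confidence cutoff applied to the set's observed
#'   coverage. Normally matched with the background's cutoff (as
#'   \code{\link{cohesion_records}} does); with the background held fixed,
#'   raising it can only lower the score.
#' @return Non-negative CoCo score.
#' @export
coco_score <- function(set, ppi, background = NULL, lambda = 1,
                       min_confidence = 0) {
  n <- set_size(set)
  if (n < 2L) stop("cohesion undefined for singleton set '", set$id, "'")
  if (is.null(background)) {
    background <- cohesion_background(ppi, min_confidence = min_confidence)
  }
  if (background$edges == 0) return(0)
  op <- observed_pairs(set, ppi, min_confidence)
  s2 <- neg_log10_tail(op, background$edges, background$total_pairs,
                       theoretical_pairs(n))
  s3 <- 0
  if (n >= 3L && background$triangles > 0) {
    ot <- observed_trios(set, ppi, min_confidence)
    s3 <- neg_log10_tail(ot, background$triangles, background$total_triples,
                         theoretical_trios(n))
  }
  max(s2 + lambda * s3, 0)
}

#' Cohesion records for every set in a corpus
#'
#' Computes per-set pair/trio coverage and CoCo against one shared
#' background summary. Singletons get NA coverage and CoCo 0 (a single gene
#' carries no cohesion).
#'
#' @param corpus A \code{pag_corpus}.
#' @param ppi An undirected \code{gene_network}.
#' @param lambda Trio weight passed to \code{\link{coco_score}}.
#' @param min_confidence Confidence cutoff in [0,1].
#' @param background Optional precomputed \code{cohesion_background}; by
#'   default built from \code{ppi} restricted to the corpus universe.
#' @return data.frame with columns set_id, n, theoretical_pairs,
#'   observed_pairs, theoretical_trios, observed_trios, coco, ncoco
#'   (ncoco is NA until \code{\link{apply_normalizer}} fills it).
#' @export
cohesion_records <- function(corpus, ppi, lambda = 1, min_confidence = 0,
                             background = NULL) {
  if (is.null(background)) {
    background <- cohesion_background(ppi, universe = corpus$universe,
                                      min_confidence = min_confidence)
  }
  sets <- corpus$sets
  n <- corpus_sizes(corpus)
  rec <- data.frame(
    set_id = names(sets),
    n = as.integer(n),
    theoretical_pairs = theoretical_pairs(n),
    observed_pairs = NA_integer_,
    theoretical_trios = theoretical_trios(n),
    observed_trios = NA_integer_,
    coco = 0,
    ncoco = NA_real_,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  for (i in seq_along(sets)) {
    if (n[i] < 2L) next
    rec$observed_pairs[i] <- observed_pairs(sets[[i]], ppi, min_confidence)
    rec$observed_trios[i] <-
      if (n[i] >= 3L) observed_trios(sets[[i]], ppi, min_confidence) else 0L
    rec$coco[i] <- coco_score(sets[[i]], ppi, background, lambda,
                              min_confidence)
  }
  rec
}

#' Fit the corpus-wide CoCo-vs-size trend
#'
#' Raw CoCo grows with set size simply because larger sets test more pairs.
#' The normalizer captures that trend by ordinary least squares of
#' log2(CoCo) on a polynomial in log2(size), fitted over the records with
#' CoCo > 0 and size >= 2 (log of zero is undefined; Table-style reports
#' keep those sets with nCoCo = 0). The log-log space matches how set-size
#' and score distributions are conventionally binned in powers of 2.
#'
#' @param records data.frame with columns \code{n} and \code{coco} (e.g.
#'   from \code{\link{cohesion_records}}).
#' @param degree Polynomial degree >= 0 (default 3: flexible enough for a
#'   smooth trend over three decades of sizes without overfitting).
#' @return A \code{size_normalizer}: degree, coefficients (increasing
#'   powers), reference_level (mean fitted value over the fitting records),
#'   n_fit.
#' @export
fit_size_normalizer <- function(records, degree = 3) {
  stopifnot(degree >= 0, degree == round(degree))
  keep <- records$coco > 0 & records$n >= 2
  x <- log2(records$n[keep])
  y <- log2(records$coco[keep])
  if (length(x) < degree + 2) {
    stop("need at least degree+2 = ", degree + 2,
         " records with coco > 0 to fit; got ", length(x))
  }
  if (degree >= 1 && length(unique(x)) < degree + 1) {
    stop("rank-deficient fit: only ", length(unique(x)),
         " distinct sizes for polynomial degree ", degree)
  }
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, y)
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  fitted <- as.numeric(X %*% coefs)
  structure(list(degree = as.integer(degree), coefficients = coefs,
                 reference_level = mean(fitted), n_fit = length(x)),
            class = "size_normalizer")
}

#' @export
print.size_normalizer <- function(x, ...) {
  cat(sprintf("<size_normalizer> degree=%d, reference_level=%.4f (n=%d)\n",
              x$degree, x$reference_level, x$n_fit))
  invisible(x)
}

# Evaluate the fitted trend g(log2 n).
predict_trend <- function(normalizer, n) {
  x <- log2(n)
  as.numeric(outer(x, 0:normalizer$degree, `^`) %*% normalizer$coefficients)
}

#' Size-normalized cohesion (nCoCo)
#'
#' Rescales CoCo by removing the fitted size trend:
#' nCoCo = 2^(log2(coco) - g(log2 n) + reference_level) for coco > 0, and 0
#' for coco = 0. Sets sitting exactly on the trend all map to the same
#' value 2^reference_level, so nCoCo comparisons are size-unbiased.
#'
#' @param coco Non-negative CoCo score(s).
#' @param n Set size(s) >= 2 (vectorized with \code{coco}).
#' @param normalizer A fitted \code{size_normalizer}.
#' @return Non-negative nCoCo score(s).
#' @export
ncoco_score <- function(coco, n, normalizer) {
  if (!inherits(normalizer, "size_normalizer")) {
    stop("normalizer must be a fitted size_normalizer")
  }
  stopifnot(all(coco >= 0), all(n >= 2))
  out <- numeric(length(coco))
  pos <- coco > 0
  if (any(pos)) {
    g <- predict_trend(normalizer, n[pos])
    out[pos] <- 2^(log2(coco[pos]) - g + normalizer$reference_level)
  }
  out
}

#' Fill the ncoco column of a cohesion record table
#'
#' @param records data.frame from \code{\link{cohesion_records}}.
#' @param normalizer A fitted \code{size_normalizer}; fitted from
#'   \code{records} (default degree 3) when omitted.
#' @return The records with \code{ncoco} populated (0 for coco = 0 sets and
#'   singletons).
#' @export
apply_normalizer <- function(records, normalizer = NULL) {
  if (is.null(normalizer)) normalizer <- fit_size_normalizer(records)
  records$ncoco <- 0
  ok <- records$n >= 2
  records$ncoco[ok] <- ncoco_score(records$coco[ok], records$n[ok],
                                   normalizer)
  records
}

#' Score at the 50% cumulative fraction (CP50)
#'
#' The value reached at cumulative fraction 0.50 of the score distribution
#' under the lower-interpolation convention (type-1 quantile): for scores
#' 1,2,3,4 CP50 is 2, not 2.5. Used to compare per-source set quality.
#'
#' @param scores Numeric scores.
#' @param group_labels Optional grouping vector; CP50 is computed per group.
#' @return A single value, or a named vector when grouped.
#' @export
cp50 <- function(scores, group_labels = NULL) {
  one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) stop("cp50 of an empty score list")
    unname(stats::quantile(x, probs = 0.5, type = 1))
  }
  if (is.null(group_labels)) return(one(scores))
  stopifnot(length(group_labels) == length(scores))
  vapply(split(scores, group_labels), one, numeric(1))
}

#' Persist a size normalizer as JSON
#' @param normalizer A \code{size_normalizer}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_normalizer <- function(normalizer, path) {
  jsonlite::write_json(
    list(degree = normalizer$degree,
         coefficients = normalizer$coefficients,
         reference_level = normalizer$reference_level,
         n_fit = normalizer$n_fit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a size normalizer from JSON
#' @param path Path written by \code{\link{write_normalizer}}.
#' @return A \code{size_normalizer}.
#' @export
read_normalizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(degree = as.integer(x$degree),
                 coefficients = as.numeric(x$coefficients),
                 reference_level = as.numeric(x$reference_level),
                 n_fit = as.integer(x$n_fit)),
            class = "size_normalizer")
}
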