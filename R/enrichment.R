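#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Probability of drawing at least k successes in n draws without
#' replacement from a population of N items containing K successes.
#' This inclusive upper tail is the enrichment p-value used throughout.
#'
#' @param k Observed overlap (vectorized).
#' @param K Number of successes in the population (e.g. set size).
#' @param n Number of draws (e.g. mapped query size).
#' @param N Population size (gene universe).
#' @return P(X >= k) in [0,1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(K < 0) || any(n < 0) || any(K > N) || any(n > N)) {
    stop("inconsistent hypergeometric parameters: need 0 <= K, n <= N")
  }
  if (any(k < 0)) stop("k must be non-negative")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric point mass P(X = k)
#' @inheritParams hypergeom_upper_tail
#' @return P(X = k).
#' @export
hypergeom_pmf <- function(k, K, n, N) {
  if (any(K < 0) || any(n < 0) || any(K > N) || any(n > N)) {
    stop("inconsistent hypergeometric parameters: need 0 <= K, n <= N")
  }
  stats::dhyper(k, K, N - K, n)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic step-up FDR control: sort p-values, multiply p_(i) by m/i, take
#' the running minimum from the largest rank down, cap at 1, and return in
#' the original order. Output is invariant to input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values of the same length (empty in, empty out).
#' @export
bh_fdr <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}

#' Cosine (Ochiai) similarity between a query and a gene set
#'
#' |Q intersect S| / sqrt(|Q| * |S|): 1 for identical sets, 0 iff disjoint.
#' Jaccard (|Q intersect S| / |Q union S|) is available via \code{method}.
#'
#' @param query Character vector of query gene symbols (non-empty).
#' @param set A \code{gene_set} or character vector of member symbols.
#' @param method "cosine" (default) or "jaccard".
#' @return Similarity in [0,1].
#' @export
set_similarity <- function(query, set, method = c("cosine", "jaccard")) {
  method <- match.arg(method)
  members <- if (inherits(set, "gene_set")) set$members
             else normalize_symbols(set)
  query <- normalize_symbols(query)
  if (length(query) == 0L) stop("empty query")
  if (length(members) == 0L) stop("empty set")
  k <- length(intersect(query, members))
  switch(method,
         cosine = k / sqrt(length(query) * length(members)),
         jaccard = k / length(union(query, members)))
}

#' Enrichment filter configuration
#'
#' Defaults follow the Advanced-Search screen: all three set types, sizes 2
#' to 1000, similarity >= 0.1, more than 1 overlapping gene, nCoCo >= 100
#' and FDR <= 0.05. Type and size act as pre-filters (they decide which
#' sets are tested and hence the BH denominator); the remaining thresholds
#' are applied to the test results.
#'
#' @param pag_types Subset of c("P","A","G") to test.
#' @param size_min,size_max Inclusive set-size bounds.
#' @param min_similarity Minimum similarity (inclusive).
#' @param min_overlap_exclusive Overlap must strictly exceed this count.
#' @param min_ncoco Minimum nCoCo (inclusive).
#' @param max_fdr Maximum BH-adjusted p-value (inclusive).
#' @return A \code{filter_config} list.
#' @export
filter_config <- function(pag_types = c("P", "A", "G"),
                          size_min = 2, size_max = 1000,
                          min_similarity = 0.1,
                          min_overlap_exclusive = 1,
                          min_ncoco = 100,
                          max_fdr = 0.05) {
  stopifnot(all(pag_types %in% c("P", "A", "G")),
            size_min <= size_max,
            is.finite(min_similarity), is.finite(min_ncoco),
            is.finite(max_fdr))
  structure(list(pag_types = pag_types, size_min = size_min,
                 size_max = size_max, min_similarity = min_similarity,
                 min_overlap_exclusive = min_overlap_exclusive,
                 min_ncoco = min_ncoco, max_fdr = max_fdr),
            class = "filter_config")
}

#' Hypergeometric enrichment of a query gene list against a corpus
#'
#' Each corpus set passing the type/size pre-filters is tested with the
#' inclusive upper-tail hypergeometric p-value for its overlap with the
#' query, with N = universe size, K = set size and n = the number of query
#' genes mapped to the universe. BH adjustment runs across exactly the
#' tested sets. A result passes when similarity, overlap, nCoCo and FDR all
#' clear the configured thresholds.
#'
#' @param query Character vector of query gene symbols.
#' @param corpus A \code{pag_corpus} (its universe defines N).
#' @param cohesion Optional cohesion record data.frame supplying nCoCo per
#'   set id; sets without a record get nCoCo = 0.
#' @param filters A \code{filter_config}.
#' @param similarity_method "cosine" or "jaccard".
#' @return data.frame sorted by ascending fdr, then p_value, then set_id,
#'   with columns set_id, name, pag_type, source, size, overlap,
#'   similarity, p_value, fdr, ncoco, passed; attribute \code{n_tested}
#'   records the BH denominator and \code{n_query_mapped} the mapped query
#'   size.
#' @export
enrich_query <- function(query, corpus, cohesion = NULL,
                         filters = filter_config(),
                         similarity_method = c("cosine", "jaccard")) {
  similarity_method <- match.arg(similarity_method)
  stopifnot(inherits(corpus, "pag_corpus"))
  query <- normalize_symbols(query)
  if (length(query) == 0L) stop("query is empty after symbol normalization")
  mapped <- intersect(query, corpus$universe)
  if (length(mapped) == 0L) {
    stop("no query gene maps to the corpus universe; unmapped: ",
         paste(query, collapse = ", "))
  }
  unmapped <- setdiff(query, mapped)
  if (length(unmapped) > 0L) {
    warning(length(unmapped), " query gene(s) outside the universe dropped: ",
            paste(unmapped, collapse = ", "))
  }
  N <- length(corpus$universe)
  n <- length(mapped)
  ncoco_lut <- if (!is.null(cohesion)) {
    stats::setNames(cohesion$ncoco, cohesion$set_id)
  } else NULL

  sizes <- corpus_sizes(corpus)
  types <- vapply(corpus$sets, `[[`, character(1), "pag_type")
  tested <- types %in% filters$pag_types &
    sizes >= filters$size_min & sizes <= filters$size_max
  sets <- corpus$sets[tested]
  if (length(sets) == 0L) {
    res <- data.frame(set_id = character(0), name = character(0),
                      pag_type = character(0), source = character(0),
                      size = integer(0), overlap = integer(0),
                      similarity = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), ncoco = numeric(0),
                      passed = logical(0), stringsAsFactors = FALSE)
    attr(res, "n_tested") <- 0L
    attr(res, "n_query_mapped") <- n
    return(res)
  }
  overlap <- vapply(sets, function(s) length(intersect(mapped, s$members)),
                    integer(1))
  K <- sizes[tested]
  p <- hypergeom_upper_tail(overlap, K, n, N)
  sim <- vapply(sets, function(s)
    set_similarity(mapped, s, method = similarity_method), numeric(1))
  nc <- if (is.null(ncoco_lut)) rep(0, length(sets)) else {
    v <- ncoco_lut[names(sets)]
    v[is.na(v)] <- 0
    unname(v)
  }
  fdr <- bh_fdr(p)
  res <- data.frame(
    set_id = names(sets),
    name = vapply(sets, `[[`, character(1), "name"),
    pag_type = types[tested],
    source = vapply(sets, `[[`, character(1), "source"),
    size = as.integer(K),
    overlap = as.integer(overlap),
    similarity = sim,
    p_value = p,
    fdr = fdr,
    ncoco = nc,
    passed = sim >= filters$min_similarity &
      overlap > filters$min_overlap_exclusive &
      nc >= filters$min_ncoco &
      fdr <= filters$max_fdr,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  res <- res[order(res$fdr, res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- length(sets)
  attr(res, "n_query_mapped") <- n
  res
}
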