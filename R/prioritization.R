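#' Random-walk-with-restart gene weights inside a set
#'
#' Network-propagation weight of every member of a set on the
#' confidence-weighted subgraph induced by the set's members. The walker
#' restarts with probability \code{restart} to a uniform distribution over
#' the members and otherwise steps along edges with probability
#' proportional to confidence, so the weight mixes direct and indirect
#' interaction evidence. The fixed point satisfies
#' p = (1 - r) W p + r u with W the column-stochastic transition matrix of
#' the induced subgraph; members with no passing edge contribute no outflow
#' and therefore end up with only restart mass. Weights are renormalized to
#' sum to exactly 1.
#'
#' @param set A \code{gene_set}.
#' @param ppi An undirected \code{gene_network}.
#' @param restart Restart probability in (0, 1] (default 0.7).
#' @param min_confidence Edge confidence cutoff.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1e5).
#' @return Named numeric vector of weights over the members, summing to 1.
#' @export
gene_weights <- function(set, ppi, restart = 0.7, min_confidence = 0,
                         tol = 1e-10, max_iter = 1e5) {
  stopifnot(restart > 0, restart <= 1)
  members <- set$members
  m <- length(members)
  if (m == 1L) return(stats::setNames(1, members))
  e <- ppi$edges
  keep <- e$from %in% members & e$to %in% members &
    e$confidence >= min_confidence & e$confidence > 0
  e <- e[keep, , drop = FALSE]
  u <- rep(1 / m, m)
  if (nrow(e) == 0L) return(stats::setNames(u, members))
  idx <- stats::setNames(seq_len(m), members)
  # symmetric weighted adjacency; column-normalize to a transition matrix
  W <- matrix(0, m, m)
  i <- idx[e$from]; j <- idx[e$to]
  W[cbind(i, j)] <- W[cbind(i, j)] + e$confidence
  W[cbind(j, i)] <- W[cbind(j, i)] + e$confidence
  colsum <- colSums(W)
  nz <- colsum > 0
  W[, nz] <- sweep(W[, nz, drop = FALSE], 2, colsum[nz], "/")
  p <- u
  for (it in seq_len(max_iter)) {
    p_new <- (1 - restart) * as.numeric(W %*% p) + restart * u
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new / sum(p_new)
      return(stats::setNames(p, members))
    }
    p <- p_new
  }
  stop("random walk failed to converge after ", max_iter, " iterations")
}

#' Rank genes within a set by RP-score
#'
#' RP-score combines the within-set network weight with how often the gene
#' recurs across the corpus: rp = weight * (1 + log2(frequency)) under the
#' default "boost" mode, so a gene appearing in 8 sets gets a 4x factor
#' over a corpus-unique gene of equal weight. "penalize" divides by the
#' same factor (down-weighting promiscuous genes) and "off" ignores
#' frequency. Ranks are assigned by decreasing RP-score with lexicographic
#' tie-breaking on the symbol.
#'
#' @param set A \code{gene_set}.
#' @param ppi An undirected \code{gene_network}.
#' @param corpus A \code{pag_corpus} supplying membership frequencies; a
#'   member absent from it is treated as frequency 1 with a warning.
#' @param restart Restart probability for \code{\link{gene_weights}}.
#' @param min_confidence Edge confidence cutoff.
#' @param frequency_mode "boost" (default), "penalize" or "off".
#' @return data.frame sorted by rank with columns set_id, gene, weight,
#'   frequency, rp_score, rank.
#' @export
rp_score <- function(set, ppi, corpus, restart = 0.7, min_confidence = 0,
                     frequency_mode = c("boost", "penalize", "off")) {
  frequency_mode <- match.arg(frequency_mode)
  w <- gene_weights(set, ppi, restart = restart,
                    min_confidence = min_confidence)
  freq_table <- gene_frequencies(corpus)
  freq <- freq_table[names(w)]
  missing <- is.na(freq) | freq == 0
  if (any(missing)) {
    warning(sum(missing), " gene(s) of set '", set$id,
            "' absent from the corpus; frequency treated as 1: ",
            paste(names(w)[missing], collapse = ", "))
    freq[missing] <- 1L
  }
  factor <- 1 + log2(as.numeric(freq))
  rp <- switch(frequency_mode,
               boost = w * factor,
               penalize = w / factor,
               off = unname(w) * 1)
  o <- order(-rp, names(w))
  data.frame(
    set_id = set$id,
    gene = names(w)[o],
    weight = unname(w[o]),
    frequency = as.integer(freq[o]),
    rp_score = unname(rp[o]),
    rank = seq_along(o),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
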