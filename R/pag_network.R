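#' Build the membership-overlap (m-type) set-to-set network
#'
#' For every unordered pair of sets sharing at least one gene, two
#' hypergeometric statistics of the overlap k are computed against the
#' corpus universe of N genes: V1 = -log10 of the point mass P(X = k) and
#' V2 = -log10 of the upper tail P(X >= k), with X ~
#' Hypergeometric(N, |A|, |B|). An undirected edge is emitted when V1
#' exceeds \code{pmf_threshold} AND V2 exceeds \code{tail_threshold}
#' (defaults 5 and 10). Both thresholds are checked independently even
#' though the tail bounds the point mass from above.
#'
#' @param corpus A \code{pag_corpus}; its universe defines N.
#' @param pmf_threshold Minimum -log10 PMF (exclusive), default 5.
#' @param tail_threshold Minimum -log10 upper tail (exclusive), default 10.
#' @return data.frame of edges with columns source_id, target_id (canonical
#'   source_id < target_id), kind ("m"), k, neg_log10_pmf, neg_log10_tail,
#'   directed (FALSE), sorted by (source_id, target_id).
#' @export
build_m_type <- function(corpus, pmf_threshold = 5, tail_threshold = 10) {
  stopifnot(pmf_threshold >= 0, tail_threshold >= 0)
  N <- length(corpus$universe)
  sets <- corpus$sets
  ids <- names(sets)
  ns <- length(sets)
  out <- list()
  if (ns >= 2L) {
    for (a in seq_len(ns - 1L)) {
      ma <- sets[[a]]$members
      for (b in seq((a + 1L), ns)) {
        k <- length(intersect(ma, sets[[b]]$members))
        if (k == 0L) next
        Ka <- length(ma); Kb <- length(sets[[b]]$members)
        v1 <- -log10(max(hypergeom_pmf(k, Ka, Kb, N), 1e-320))
        v2 <- -log10(max(hypergeom_upper_tail(k, Ka, Kb, N), 1e-320))
        if (v1 > pmf_threshold && v2 > tail_threshold) {
          s <- ids[a]; t <- ids[b]
          if (s > t) { tmp <- s; s <- t; t <- tmp }
          out[[length(out) + 1L]] <- list(s, t, k, v1, v2)
        }
      }
    }
  }
  edges <- set_edge_frame(out, kind = "m", directed = FALSE)
  edges <- edges[order(edges$source_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Build the regulatory (r-type) set-to-set network
#'
#' For every ordered pair of sets (A, B), k counts regulation edges running
#' from an exclusive member of A (A minus B) to an exclusive member of B:
#' shared genes are excluded from both sides so co-membership cannot
#' masquerade as regulation. Under the null, k follows
#' Hypergeometric(N(N-1), E, |A\\B| * |B\\A|) where N(N-1) is the number of
#' ordered gene pairs in the universe and E the total number of regulation
#' edges inside it. A directed edge A -> B ("A upstream of B") is emitted
#' when k >= 1, P(X = k) < \code{pmf_alpha} and P(X >= k) <
#' \code{tail_alpha} (defaults 0.05/0.05); the edge weight is
#' -log10 P(X >= k).
#'
#' @param corpus A \code{pag_corpus}.
#' @param reg A directed \code{gene_network} of regulator -> target edges.
#' @param pmf_alpha Point-mass significance level in (0,1).
#' @param tail_alpha Upper-tail significance level in (0,1).
#' @return data.frame of directed edges (columns as in
#'   \code{\link{build_m_type}}, kind "r", directed TRUE), sorted by
#'   (source_id, target_id).
#' @export
build_r_type <- function(corpus, reg, pmf_alpha = 0.05, tail_alpha = 0.05) {
  stopifnot(pmf_alpha > 0, pmf_alpha < 1, tail_alpha > 0, tail_alpha < 1)
  if (!reg$directed) stop("regulation network must be directed")
  N <- length(corpus$universe)
  e <- reg$edges
  e <- e[e$from %in% corpus$universe & e$to %in% corpus$universe, ,
         drop = FALSE]
  E <- nrow(e)
  out <- list()
  if (E > 0L) {
    total_ordered_pairs <- as.numeric(N) * (N - 1)
    sets <- corpus$sets
    ids <- names(sets)
    for (a in seq_along(sets)) {
      ma <- sets[[a]]$members
      reg_from_a <- e[e$from %in% ma, , drop = FALSE]
      for (b in seq_along(sets)) {
        if (a == b) next
        mb <- sets[[b]]$members
        a_excl <- setdiff(ma, mb)
        b_excl <- setdiff(mb, ma)
        draws <- as.numeric(length(a_excl)) * length(b_excl)
        if (draws == 0) next
        k <- sum(reg_from_a$from %in% a_excl & reg_from_a$to %in% b_excl)
        if (k == 0L) next
        pmf <- hypergeom_pmf(k, E, draws, total_ordered_pairs)
        tail <- hypergeom_upper_tail(k, E, draws, total_ordered_pairs)
        if (pmf < pmf_alpha && tail < tail_alpha) {
          out[[length(out) + 1L]] <- list(ids[a], ids[b], k,
                                          -log10(max(pmf, 1e-320)),
                                          -log10(max(tail, 1e-320)))
        }
      }
    }
  }
  edges <- set_edge_frame(out, kind = "r", directed = TRUE)
  edges <- edges[order(edges$source_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

set_edge_frame <- function(rows, kind, directed) {
  if (length(rows) == 0L) {
    return(data.frame(source_id = character(0), target_id = character(0),
                      kind = character(0), k = integer(0),
                      neg_log10_pmf = numeric(0),
                      neg_log10_tail = numeric(0),
                      directed = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(
    source_id = vapply(rows, `[[`, character(1), 1L),
    target_id = vapply(rows, `[[`, character(1), 2L),
    kind = kind,
    k = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    neg_log10_pmf = vapply(rows, `[[`, numeric(1), 4L),
    neg_log10_tail = vapply(rows, `[[`, numeric(1), 5L),
    directed = directed,
    stringsAsFactors = FALSE
  )
}

#' Classify edge endpoints as singleton (sPAG) or multi-gene (mPAG)
#' and tally edges per category
#'
#' @param edges Edge data.frame from \code{\link{build_r_type}} (or
#'   \code{\link{build_m_type}}).
#' @param corpus A \code{pag_corpus} containing every edge endpoint.
#' @return Named integer vector with counts \code{s_to_m}, \code{m_to_m},
#'   \code{m_to_s} and \code{s_to_s}.
#' @export
classify_and_count <- function(edges, corpus) {
  counts <- c(s_to_m = 0L, m_to_m = 0L, m_to_s = 0L, s_to_s = 0L)
  if (nrow(edges) == 0L) return(counts)
  sizes <- corpus_sizes(corpus)
  dangling <- setdiff(c(edges$source_id, edges$target_id), names(sizes))
  if (length(dangling) > 0L) {
    stop("edge endpoint(s) absent from corpus: ",
         paste(dangling, collapse = ", "))
  }
  klass <- ifelse(sizes == 1L, "s", "m")
  key <- paste(klass[edges$source_id], klass[edges$target_id], sep = "_to_")
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Export a set-to-set network as GraphML or SIF
#'
#' Nodes carry attributes pag_type, size, degree and (optionally) a per-set
#' score such as -log2(FDR); edges carry kind, k and the two -log10
#' hypergeometric scores. Node and edge order is deterministic (sorted), so
#' identical inputs yield byte-identical files.
#'
#' @param edges Edge data.frame from the builders.
#' @param corpus A \code{pag_corpus} supplying node attributes.
#' @param path Output path.
#' @param format "graphml" or "sif".
#' @param node_scores Optional named numeric vector (e.g. -log2 FDR) by
#'   set id, written as node attribute "score".
#' @return The path, invisibly.
#' @export
export_graph <- function(edges, corpus, path,
                         format = c("graphml", "sif"), node_scores = NULL) {
  format <- match.arg(format)
  node_ids <- sort(unique(c(edges$source_id, edges$target_id)))
  if (format == "sif") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (nrow(edges)) {
      writeLines(sprintf("%s\t%s\t%s", edges$source_id, edges$kind,
                         edges$target_id), con, sep = "\n")
    }
    return(invisible(path))
  }
  sizes <- corpus_sizes(corpus)
  types <- vapply(corpus$sets, `[[`, character(1), "pag_type")
  deg <- stats::setNames(integer(length(node_ids)), node_ids)
  for (v in c(edges$source_id, edges$target_id)) deg[v] <- deg[v] + 1L
  xml_esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="node" attr.name="pag_type" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="size" attr.type="int"/>',
    '  <key id="d2" for="node" attr.name="degree" attr.type="int"/>',
    '  <key id="d3" for="node" attr.name="score" attr.type="double"/>',
    '  <key id="e0" for="edge" attr.name="kind" attr.type="string"/>',
    '  <key id="e1" for="edge" attr.name="k" attr.type="int"/>',
    '  <key id="e2" for="edge" attr.name="neg_log10_pmf" attr.type="double"/>',
    '  <key id="e3" for="edge" attr.name="neg_log10_tail" attr.type="double"/>',
    sprintf('  <graph edgedefault="%s">',
            if (nrow(edges) && all(edges$directed)) "directed"
            else "undirected")
  )
  for (v in node_ids) {
    node <- c(sprintf('    <node id="%s">', xml_esc(v)),
              sprintf('      <data key="d0">%s</data>',
                      if (v %in% names(types)) types[[v]] else "G"),
              sprintf('      <data key="d1">%d</data>',
                      if (v %in% names(sizes)) sizes[[v]] else 0L),
              sprintf('      <data key="d2">%d</data>', deg[[v]]))
    if (!is.null(node_scores) && v %in% names(node_scores)) {
      node <- c(node, sprintf('      <data key="d3">%.10g</data>',
                              node_scores[[v]]))
    }
    lines <- c(lines, node, "    </node>")
  }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      lines <- c(lines,
        sprintf('    <edge source="%s" target="%s">',
                xml_esc(edges$source_id[i]), xml_esc(edges$target_id[i])),
        sprintf('      <data key="e0">%s</data>', edges$kind[i]),
        sprintf('      <data key="e1">%d</data>', edges$k[i]),
        sprintf('      <data key="e2">%.10g</data>', edges$neg_log10_pmf[i]),
        sprintf('      <data key="e3">%.10g</data>', edges$neg_log10_tail[i]),
        "    </edge>")
    }
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a set-to-set edge list as TSV
#' @param edges Edge data.frame from the builders.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_set_edges <- function(edges, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("source_id", "target_id", "kind", "k",
                     "neg_log10_pmf", "neg_log10_tail"), collapse = "\t"),
             con, sep = "\n")
  if (nrow(edges)) {
    writeLines(sprintf("%s\t%s\t%s\t%d\t%.10g\t%.10g",
                       edges$source_id, edges$target_id, edges$kind,
                       edges$k, edges$neg_log10_pmf, edges$neg_log10_tail),
               con, sep = "\n")
  }
  invisible(path)
}
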