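test_that("m-type edges: disjoint sets, duplicate sets, canonical order", {
  genes <- sprintf("G%04d", 1:2000)
  dup <- genes[1:50]
  corpus <- pag_corpus(list(
    gene_set("ZDUP", dup), gene_set("ADUP", dup),
    gene_set("OTHER", genes[100:140]),
    gene_set("LONER", genes[500:520])
  ), background = genes)
  edges <- build_m_type(corpus)
  # identical 50-gene sets in a 2000-gene universe clear (5, 10) easily
  expect_true(any(edges$source_id == "ADUP" & edges$target_id == "ZDUP"))
  expect_true(all(edges$source_id < edges$target_id))
  expect_false(any(edges$source_id == "LONER" | edges$target_id == "LONER"))
  # duplicate pair has the maximal tail statistic
  i <- which(edges$source_id == "ADUP" & edges$target_id == "ZDUP")
  expect_equal(edges$neg_log10_tail[i], max(edges$neg_log10_tail))
})

test_that("m-type matches the brute-force oracle and is corpus-order invariant", {
  corpus <- random_corpus(111, n_genes = 40, n_sets = 10,
                          size_range = c(2, 12))
  for (thr in list(c(1, 2), c(3, 5))) {
    got <- build_m_type(corpus, thr[1], thr[2])
    want <- oracle_m_type(corpus, thr[1], thr[2])
    expect_equal(got[, c("source_id", "target_id")],
                 want, ignore_attr = TRUE)
  }
  # permuting set order changes nothing
  perm <- pag_corpus(unname(corpus$sets[rev(names(corpus$sets))]),
                     background = corpus$universe)
  expect_equal(build_m_type(perm, 1, 2), build_m_type(corpus, 1, 2))
  # tightening thresholds never adds edges
  e_loose <- build_m_type(corpus, 1, 2)
  e_tight <- build_m_type(corpus, 2, 4)
  key <- function(e) paste(e$source_id, e$target_id)
  expect_true(all(key(e_tight) %in% key(e_loose)))
})

test_that("r-type edges: planted direction recovered, oracle equivalence", {
  genes <- sprintf("G%04d", 1:1000)
  A <- genes[1:20]; B <- genes[21:40]
  corpus <- pag_corpus(list(
    gene_set("A", A), gene_set("B", B),
    gene_set("C", genes[41:60])
  ), background = genes)
  # no cross-set regulation -> no edges
  none <- gene_network(genes[100], genes[101], directed = TRUE)
  expect_equal(nrow(build_r_type(corpus, none)), 0)
  # dense planted A -> B regulation: edge emitted, reverse absent
  dense <- expand.grid(from = A, to = B, stringsAsFactors = FALSE)
  reg <- gene_network(dense$from, dense$to, directed = TRUE)
  edges <- build_r_type(corpus, reg)
  expect_true(any(edges$source_id == "A" & edges$target_id == "B"))
  expect_false(any(edges$source_id == "B" & edges$target_id == "A"))
  expect_error(build_r_type(corpus, gene_network("A", "B", directed = FALSE)),
               "directed")
})

test_that("r-type matches the brute-force oracle on a toy corpus", {
  set.seed(222)
  genes <- sprintf("G%03d", 1:120)
  sets <- lapply(1:6, function(i)
    gene_set(paste0("S", i), sample(genes, sample(4:15, 1))))
  corpus <- pag_corpus(sets, background = genes)
  reg <- gene_network(sample(genes, 300, TRUE), sample(genes, 300, TRUE),
                      directed = TRUE)
  for (alpha in list(c(0.05, 0.05), c(0.01, 0.01))) {
    got <- build_r_type(corpus, reg, alpha[1], alpha[2])
    want <- oracle_r_type(corpus, reg, alpha[1], alpha[2])
    expect_equal(got[, c("source_id", "target_id", "k")], want,
                 ignore_attr = TRUE)
  }
})

test_that("endpoint classification tallies r-type categories", {
  corpus <- pag_corpus(list(
    gene_set("SINGLE", "A"), gene_set("PAIR", c("B", "C")),
    gene_set("TRIO", c("D", "E", "F"))
  ))
  mk <- function(s, t) data.frame(source_id = s, target_id = t, kind = "r",
                                  k = 1L, neg_log10_pmf = 1,
                                  neg_log10_tail = 1, directed = TRUE,
                                  stringsAsFactors = FALSE)
  expect_equal(classify_and_count(mk("SINGLE", "PAIR"), corpus),
               c(s_to_m = 1L, m_to_m = 0L, m_to_s = 0L, s_to_s = 0L))
  empty <- mk("SINGLE", "PAIR")[0, ]
  expect_equal(sum(classify_and_count(empty, corpus)), 0L)
  edges <- rbind(mk("SINGLE", "PAIR"), mk("PAIR", "TRIO"),
                 mk("TRIO", "SINGLE"), mk("SINGLE", "SINGLE"))
  counts <- classify_and_count(edges, corpus)
  expect_equal(unname(counts), c(1L, 1L, 1L, 1L))
  # category counts sum to the total edge count
  expect_equal(sum(counts), nrow(edges))
  expect_error(classify_and_count(mk("GHOST", "PAIR"), corpus), "GHOST")
})

test_that("hand-tallied 50-edge classification matches", {
  set.seed(333)
  sizes <- sample(c(1L, 1L, 3L, 8L), 12, replace = TRUE)
  genes <- sprintf("G%03d", 1:200)
  sets <- lapply(seq_along(sizes), function(i)
    gene_set(sprintf("T%02d", i), sample(genes, sizes[i])))
  corpus <- pag_corpus(sets)
  ids <- names(corpus$sets)
  src <- sample(ids, 50, TRUE); tgt <- sample(ids, 50, TRUE)
  keep <- src != tgt
  edges <- data.frame(source_id = src[keep], target_id = tgt[keep],
                      kind = "r", k = 1L, neg_log10_pmf = 1,
                      neg_log10_tail = 1, directed = TRUE,
                      stringsAsFactors = FALSE)
  counts <- classify_and_count(edges, corpus)
  cls <- ifelse(sizes == 1L, "s", "m")
  names(cls) <- ids
  hand <- table(factor(paste0(cls[edges$source_id], "_to_",
                              cls[edges$target_id]),
                       levels = c("s_to_m", "m_to_m", "m_to_s", "s_to_s")))
  expect_equal(unname(counts), as.integer(hand))
})

test_that("graph export: SIF lines, GraphML round-trip, empty graph", {
  corpus <- pag_corpus(list(gene_set("N1", c("A", "B")),
                            gene_set("N2", c("C", "D")),
                            gene_set("N3", "E")))
  edges <- data.frame(source_id = c("N1", "N2"), target_id = c("N2", "N3"),
                      kind = "r", k = c(2L, 1L),
                      neg_log10_pmf = c(3.5, 2.0),
                      neg_log10_tail = c(3.0, 1.5), directed = TRUE,
                      stringsAsFactors = FALSE)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(edges[1, ], corpus, sif, format = "sif")
  expect_equal(readLines(sif), "N1\tr\tN2")

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(edges, corpus, gml, format = "graphml",
               node_scores = c(N1 = 12.5))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::is_directed(g))
  expect_setequal(igraph::vertex_attr(g, "size"), c(2, 2, 1))

  # empty graph is still a valid document
  empty <- edges[0, ]
  export_graph(empty, corpus, gml, format = "graphml")
  g0 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g0), 0)
  expect_error(export_graph(edges, corpus, gml, format = "dot"), "arg")

  # deterministic bytes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  export_graph(edges, corpus, f1, format = "graphml")
  export_graph(edges, corpus, f2, format = "graphml")
  expect_identical(readLines(f1), readLines(f2))

  # TSV edge list round-trips through read.delim
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_set_edges(edges, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$source_id, edges$source_id)
  expect_equal(back$k, edges$k)
})
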