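# Small fixtures built in code, shared across test files.

toy_corpus <- function() {
  pag_corpus(list(
    gene_set("S1", c("A", "B", "C", "D"), pag_type = "P"),
    gene_set("S2", c("C", "D", "E"), pag_type = "A"),
    gene_set("S3", c("F", "G"), pag_type = "G"),
    gene_set("S4", "H", pag_type = "G")
  ))
}

# K4 on A-D plus a pendant edge to E
toy_ppi <- function() {
  gene_network(
    from = c("A", "A", "A", "B", "B", "C", "D"),
    to = c("B", "C", "D", "C", "D", "D", "E"),
    confidence = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 1.0)
  )
}

random_corpus <- function(seed, n_genes = 60, n_sets = 8,
                          size_range = c(2, 15)) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  sets <- lapply(seq_len(n_sets), function(i) {
    gene_set(sprintf("R%02d", i),
             sample(genes, sample(size_range[1]:size_range[2], 1)),
             pag_type = sample(c("P", "A", "G"), 1))
  })
  pag_corpus(sets, background = genes)
}

random_ppi <- function(seed, genes, n_edges = 150) {
  set.seed(seed)
  from <- sample(genes, n_edges, replace = TRUE)
  to <- sample(genes, n_edges, replace = TRUE)
  gene_network(from, to, runif(n_edges))
}
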