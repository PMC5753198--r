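# A constructed world reproducing the published coverage profiles of the
# two example sets: a 6-gene set with 13 of its 15 pairs covered by PPI
# edges, and a 101-gene set with 612 of its 5050 pairs covered. Both live
# in a shared background: a size-spanning corpus of moderate-density
# (0.15) modules plus uniform noise edges, from which the size normalizer
# is fitted. Anchor members are reserved genes so their coverage is exact.
build_anchor_world <- function(seed = 2020, n_genes = 5000, n_trend = 100) {
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  anchor_pool <- genes[1:107]
  rest <- genes[108:n_genes]

  a6 <- gene_set("ANCHOR6", anchor_pool[1:6])
  a101 <- gene_set("ANCHOR101", anchor_pool[7:107])
  pick_pairs <- function(members, k) {
    pairs <- utils::combn(sort(members), 2)
    pairs[, sample.int(ncol(pairs), k), drop = FALSE]
  }
  p6 <- pick_pairs(a6$members, 13)     # 13 / 15
  p101 <- pick_pairs(a101$members, 612) # 612 / 5050

  trend_sets <- vector("list", n_trend)
  from <- c(p6[1, ], p101[1, ])
  to <- c(p6[2, ], p101[2, ])
  sizes <- round(2^stats::runif(n_trend, 2, log2(300)))
  for (i in seq_len(n_trend)) {
    members <- sample(rest, sizes[i])
    trend_sets[[i]] <- gene_set(sprintf("TREND%03d", i), members)
    pp <- pick_pairs(members, ceiling(0.15 * choose(sizes[i], 2)))
    from <- c(from, pp[1, ])
    to <- c(to, pp[2, ])
  }
  noise_a <- sample(rest, 5000, replace = TRUE)
  noise_b <- sample(rest, 5000, replace = TRUE)
  ppi <- gene_network(c(from, noise_a), c(to, noise_b), 1)

  corpus <- pag_corpus(c(list(a6, a101), trend_sets), background = genes)
  list(corpus = corpus, ppi = ppi, a6 = a6, a101 = a101)
}
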