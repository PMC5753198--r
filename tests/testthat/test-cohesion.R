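test_that("theoretical pair and trio counts", {
  expect_equal(theoretical_pairs(6), 15)
  expect_equal(theoretical_pairs(101), 5050)
  expect_equal(theoretical_pairs(1), 0)
  expect_equal(theoretical_trios(c(2, 3, 4, 6)), c(0, 1, 4, 20))
  expect_error(theoretical_pairs(-1), "non-negative")
})

test_that("observed pairs and trios match brute-force enumeration", {
  ppi <- toy_ppi()
  k4 <- gene_set("K4", c("A", "B", "C", "D"))
  expect_equal(observed_pairs(k4, ppi), 6)
  expect_equal(observed_trios(k4, ppi), 4)   # C(4,3) triangles in K4
  path3 <- gene_set("P3", c("C", "D", "E")) # C-D edge, D-E edge: open triple
  expect_equal(observed_trios(path3, ppi), 0)
  none <- gene_set("N0", c("X1", "X2", "X3"))
  expect_equal(observed_pairs(none, ppi), 0)

  # randomized sets against the double/triple-loop oracles
  genes <- sprintf("G%03d", 1:40)
  net <- random_ppi(101, genes, 200)
  set.seed(202)
  for (i in 1:5) {
    s <- gene_set("R", sample(genes, 20))
    cutoff <- runif(1)
    expect_equal(observed_pairs(s, net, cutoff),
                 oracle_pairs(s$members, net, cutoff))
    expect_equal(observed_trios(s, net, cutoff),
                 oracle_triangles(s$members, net, cutoff))
  }
})

test_that("raising min_confidence never increases coverage or CoCo", {
  genes <- sprintf("G%03d", 1:30)
  net <- random_ppi(303, genes, 120)
  set.seed(304)
  s <- gene_set("S", sample(genes, 12))
  cuts <- seq(0, 1, by = 0.2)
  op <- sapply(cuts, function(ct) observed_pairs(s, net, ct))
  ot <- sapply(cuts, function(ct) observed_trios(s, net, ct))
  # with the null background held fixed, less coverage can only mean a
  # larger tail probability, hence a smaller CoCo
  bg0 <- cohesion_background(net, genes)
  cc <- sapply(cuts, function(ct)
    coco_score(s, net, bg0, min_confidence = ct))
  expect_true(all(diff(op) <= 0))
  expect_true(all(diff(ot) <= 0))
  expect_true(all(diff(cc) <= 1e-9))
  expect_true(all(op <= theoretical_pairs(12)))
  expect_true(all(ot <= theoretical_trios(12)))
})

test_that("CoCo tail terms agree with combinatorial-sum oracle on <= 12 genes", {
  genes <- LETTERS[1:12]
  set.seed(55)
  net <- random_ppi(55, genes, 25)
  bg <- cohesion_background(net, genes)
  for (i in 1:4) {
    s <- gene_set("S", sample(genes, sample(3:6, 1)))
    n <- set_size(s)
    s2 <- -log10(max(oracle_tail_sum(observed_pairs(s, net), bg$edges,
                                     theoretical_pairs(n), bg$total_pairs),
                     1e-320))
    s3 <- -log10(max(oracle_tail_sum(observed_trios(s, net), bg$triangles,
                                     theoretical_trios(n), bg$total_triples),
                     1e-320))
    expect_equal(coco_score(s, net, bg), s2 + s3, tolerance = 1e-9)
  }
})

test_that("CoCo basics: zero coverage, monotone in coverage, edge cases", {
  genes <- sprintf("G%02d", 1:20)
  # empty network -> CoCo 0
  empty <- gene_network(character(0), character(0))
  s <- gene_set("S", genes[1:5])
  expect_equal(coco_score(s, empty), 0)
  expect_error(coco_score(gene_set("X", "G01"), empty), "singleton")

  # no within-set coverage -> tail probability 1 -> CoCo ~ 0
  net <- gene_network(c("G10", "G12"), c("G11", "G13"))
  expect_lt(coco_score(gene_set("S", genes[1:4]), net,
                       cohesion_background(net, genes)), 1e-9)

  # adding within-set edges (background edge count held fixed) never
  # decreases CoCo: swap a far-away edge for a within-set one each step
  far <- list(c("G10", "G11"), c("G12", "G13"), c("G14", "G15"))
  inside <- list(c("G01", "G02"), c("G01", "G03"), c("G02", "G03"))
  prev <- -Inf
  for (k in 0:3) {
    pairs <- c(inside[seq_len(k)], far[seq_len(3 - k)])
    net <- gene_network(vapply(pairs, `[[`, "", 1),
                        vapply(pairs, `[[`, "", 2))
    val <- coco_score(gene_set("S", genes[1:4]), net,
                      cohesion_background(net, genes))
    expect_gte(val, prev - 1e-12)
    prev <- val
  }
})

test_that("size normalizer recovers exact and noisy polynomial trends", {
  # exact quadratic trend: log2(coco) = 2 * log2(n)
  n <- c(2, 4, 8, 16, 32, 64)
  rec <- data.frame(n = n, coco = n^2)
  norm <- fit_size_normalizer(rec, degree = 1)
  expect_equal(norm$coefficients, c(0, 2), tolerance = 1e-9)

  # degree 0 -> intercept is the mean of log2(coco)
  norm0 <- fit_size_normalizer(rec, degree = 0)
  expect_equal(norm0$coefficients, mean(log2(rec$coco)), tolerance = 1e-12)

  # error paths
  expect_error(fit_size_normalizer(rec[1:2, ], degree = 3), "at least")
  same <- data.frame(n = rep(8, 10), coco = 2^rnorm(10, 4))
  expect_error(fit_size_normalizer(same, degree = 1), "rank-deficient")

  # noisy cubic recovery within 3 standard errors
  set.seed(77)
  nn <- round(2^runif(2000, 1, 10))
  beta <- c(0.5, 0.2, 0.15, 0.02)
  x <- log2(nn)
  y <- beta[1] + beta[2] * x + beta[3] * x^2 + beta[4] * x^3 +
    rnorm(2000, 0, 0.1)
  recs <- data.frame(n = nn, coco = 2^y)
  fit <- fit_size_normalizer(recs, degree = 3)
  lmfit <- lm(y ~ x + I(x^2) + I(x^3))
  se <- summary(lmfit)$coefficients[, "Std. Error"]
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
})

test_that("nCoCo collapses the fitted trend to a constant", {
  n <- round(2^seq(1, 9, by = 0.5))
  rec <- data.frame(n = n, coco = 3 * n^1.7)
  norm <- fit_size_normalizer(rec, degree = 2)
  nc <- ncoco_score(rec$coco, rec$n, norm)
  expect_equal(nc, rep(2^norm$reference_level, length(n)), tolerance = 1e-6)

  # degree-0 normalizer on constant coco is the identity
  recc <- data.frame(n = c(2, 5, 9, 40), coco = rep(7, 4))
  norm0 <- fit_size_normalizer(recc, degree = 0)
  expect_equal(ncoco_score(recc$coco, recc$n, norm0), rep(7, 4),
               tolerance = 1e-9)

  # coco = 0 stays 0; unfitted normalizer rejected
  expect_equal(ncoco_score(0, 5, norm), 0)
  expect_error(ncoco_score(1, 5, list(degree = 1)), "normalizer")
})

test_that("nCoCo removes planted size bias (decorrelation property)", {
  set.seed(99)
  n <- pmax(2, round(2^runif(800, 1, log2(1000))))
  coco <- n^1.5 * 2^rnorm(800, 0, 0.5)
  rec <- data.frame(n = n, coco = coco)
  expect_gt(abs(cor(rec$coco, rec$n, method = "spearman")), 0.6)
  rec <- apply_normalizer(rec, fit_size_normalizer(rec, degree = 3))
  expect_lt(abs(cor(rec$ncoco, rec$n, method = "spearman")), 0.1)
})

test_that("cp50 uses the lower-interpolation convention", {
  expect_equal(cp50(c(1, 2, 3)), 2)
  expect_equal(cp50(c(1, 2, 3, 4)), 2)
  expect_error(cp50(numeric(0)), "empty")
  # grouped
  g <- cp50(c(1, 2, 3, 10, 20), c("a", "a", "a", "b", "b"))
  expect_equal(unname(g), c(2, 10))
  # matches the sort-and-index oracle on random draws
  set.seed(5)
  x <- runif(1000)
  expect_identical(cp50(x), sort(x)[ceiling(0.5 * 1000)])
  x <- runif(999)
  expect_identical(cp50(x), sort(x)[ceiling(0.5 * 999)])
})

test_that("cohesion records cover a corpus and normalizer persists to JSON", {
  corpus <- random_corpus(404, n_genes = 50, n_sets = 10)
  net <- random_ppi(405, corpus$universe, 300)
  rec <- cohesion_records(corpus, net)
  expect_equal(nrow(rec), 10)
  expect_true(all(rec$observed_pairs <= rec$theoretical_pairs, na.rm = TRUE))
  expect_true(all(rec$observed_trios <= rec$theoretical_trios, na.rm = TRUE))
  expect_true(all(rec$coco >= 0))
  norm <- fit_size_normalizer(rec, degree = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_normalizer(norm, f)
  back <- read_normalizer(f)
  expect_equal(back$coefficients, norm$coefficients)
  expect_equal(back$reference_level, norm$reference_level)
  expect_equal(ncoco_score(5, 10, back), ncoco_score(5, 10, norm))
})
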