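#' Configuration for the synthetic-data generator
#'
#' Describes the simulated world: a corpus of gene sets with log-uniform
#' sizes (optionally spiked at 200, mimicking curated signature collections
#' that standardize on 200-gene signatures), a scale-free-ish PPI network
#' grown by preferential attachment with uniform confidences, a fraction of
#' sets planted as cohesive modules (their induced subgraph is filled to a
#' target edge density), a background of random directed regulation edges
#' and planted dense regulation between chosen set pairs.
#'
#' @param seed Integer seed; fixes every output byte-identically.
#' @param n_genes Universe size (default 2000).
#' @param n_sets Number of gene sets (default 150).
#' @param size_min,size_max Bounds of the log-uniform size distribution
#'   (defaults 1 and min(1000, n_genes); singletons included).
#' @param size_spike_at,size_spike_prob Optional size spike: with this
#'   probability a set gets exactly \code{size_spike_at} members
#'   (defaults 200 and 0.05).
#' @param ppi_m Preferential-attachment edges per new vertex (default 3).
#' @param confidence_range Uniform confidence range for PPI edges
#'   (default c(0.5, 1)).
#' @param planted_module_fraction Fraction of eligible (size >= 3) sets
#'   planted as cohesive modules (default 0.2).
#' @param planted_density Target within-set edge density of planted modules
#'   in (0, 1] (default 0.8).
#' @param regulation_edges Number of random background regulation edges
#'   (default 2000).
#' @param planted_regulation_pairs List of length-2 integer vectors
#'   (source set index -> target set index) receiving planted regulation.
#' @param planted_regulation_auto Number of regulation pairs to plant
#'   automatically between the largest eligible sets (>= 5 exclusive
#'   members each), chosen deterministically; alternative to giving
#'   explicit indices (default 0).
#' @param planted_regulation_density Fraction of cross-set ordered gene
#'   pairs wired for each planted regulation pair (default 0.3).
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed = 1L, n_genes = 2000L, n_sets = 150L,
                         size_min = 1L, size_max = NULL,
                         size_spike_at = 200L, size_spike_prob = 0.05,
                         ppi_m = 3L, confidence_range = c(0.5, 1),
                         planted_module_fraction = 0.2,
                         planted_density = 0.8,
                         regulation_edges = 2000L,
                         planted_regulation_pairs = list(),
                         planted_regulation_auto = 0L,
                         planted_regulation_density = 0.3) {
  size_max <- as.integer(size_max %||% min(1000L, n_genes))
  stopifnot(n_genes >= 10, n_sets >= 1, size_min >= 1,
            size_max >= size_min, size_max <= n_genes,
            planted_module_fraction >= 0, planted_module_fraction <= 1,
            planted_density > 0, planted_density <= 1,
            planted_regulation_density > 0,
            planted_regulation_density <= 1,
            regulation_edges >= 0, planted_regulation_auto >= 0,
            length(confidence_range) == 2,
            all(confidence_range >= 0), all(confidence_range <= 1))
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_sets = as.integer(n_sets), size_min = as.integer(size_min),
    size_max = as.integer(size_max),
    size_spike_at = as.integer(size_spike_at),
    size_spike_prob = size_spike_prob,
    ppi_m = as.integer(ppi_m), confidence_range = confidence_range,
    planted_module_fraction = planted_module_fraction,
    planted_density = planted_density,
    regulation_edges = as.integer(regulation_edges),
    planted_regulation_pairs = planted_regulation_pairs,
    planted_regulation_auto = as.integer(planted_regulation_auto),
    planted_regulation_density = planted_regulation_density
  ), class = "synth_config")
}

#' Generate a synthetic corpus, PPI network, regulation network and truth
#'
#' Fully deterministic under the config seed. Planted cohesive sets are
#' guaranteed an induced edge density of at least
#' \code{planted_density}; planted regulation pairs receive
#' \code{planted_regulation_density} of their cross-set ordered gene pairs
#' as regulation edges. Truth labels record which sets and which set pairs
#' were planted.
#'
#' @param config A \code{synth_config}.
#' @return List with elements \code{corpus} (\code{pag_corpus}), \code{ppi}
#'   (undirected \code{gene_network}), \code{regulation} (directed
#'   \code{gene_network}) and \code{truth} (list: planted_sets,
#'   planted_regulation data.frame, config echo).
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  genes <- sprintf("G%05d", seq_len(config$n_genes))

  # --- set sizes: log-uniform with optional spike -------------------------
  spike <- stats::runif(config$n_sets) < config$size_spike_prob
  sizes <- pmin(
    pmax(round(2^stats::runif(config$n_sets,
                              log2(config$size_min),
                              log2(config$size_max))),
         config$size_min),
    config$size_max)
  sizes[spike] <- min(config$size_spike_at, config$size_max)

  sets <- vector("list", config$n_sets)
  types <- c("P", "A", "G")
  for (i in seq_len(config$n_sets)) {
    sets[[i]] <- gene_set(
      id = sprintf("SET%04d", i),
      members = sample(genes, sizes[i]),
      pag_type = types[1 + (i - 1) %% 3],
      source = "synthetic",
      description = sprintf("synthetic set %d", i)
    )
  }
  corpus <- pag_corpus(sets, background = genes)

  # --- PPI: preferential attachment + planted dense modules ---------------
  g <- igraph::sample_pa(config$n_genes, m = config$ppi_m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- genes[el[, 1]]
  to <- genes[el[, 2]]

  eligible <- which(sizes >= 3)
  n_plant <- floor(config$planted_module_fraction * length(eligible))
  planted_idx <- if (n_plant > 0) sort(sample(eligible, n_plant)) else
    integer(0)
  for (i in planted_idx) {
    mem <- sets[[i]]$members
    pairs <- utils::combn(sort(mem), 2)
    need <- ceiling(config$planted_density * ncol(pairs))
    if (need > ncol(pairs)) stop("infeasible planted density for set size ",
                                 length(mem))
    pick <- sample.int(ncol(pairs), need)
    from <- c(from, pairs[1, pick])
    to <- c(to, pairs[2, pick])
  }
  conf <- stats::runif(length(from), config$confidence_range[1],
                       config$confidence_range[2])
  ppi <- gene_network(from, to, conf, directed = FALSE)

  # --- regulation: random background + planted cross-set wiring -----------
  r_from <- character(0); r_to <- character(0)
  if (config$regulation_edges > 0) {
    a <- sample(genes, config$regulation_edges, replace = TRUE)
    b <- sample(genes, config$regulation_edges, replace = TRUE)
    ok <- a != b
    r_from <- a[ok]; r_to <- b[ok]
  }
  planted_reg <- data.frame(source_id = character(0),
                            target_id = character(0),
                            stringsAsFactors = FALSE)
  reg_pairs <- config$planted_regulation_pairs
  if (config$planted_regulation_auto > 0L) {
    # pair the largest sets off deterministically; "eligible" means both
    # sides keep >= 5 exclusive members so the planted signal is testable
    ord <- order(-sizes, seq_along(sizes))
    elig <- ord[sizes[ord] >= 10]
    need <- 2L * config$planted_regulation_auto
    if (length(elig) < need) {
      stop("not enough sets of size >= 10 for ",
           config$planted_regulation_auto, " auto regulation pairs")
    }
    for (j in seq_len(config$planted_regulation_auto)) {
      reg_pairs <- c(reg_pairs, list(c(elig[2L * j - 1L], elig[2L * j])))
    }
  }
  for (pr in reg_pairs) {
    stopifnot(length(pr) == 2, all(pr >= 1), all(pr <= config$n_sets))
    ma <- setdiff(sets[[pr[1]]]$members, sets[[pr[2]]]$members)
    mb <- setdiff(sets[[pr[2]]]$members, sets[[pr[1]]]$members)
    if (length(ma) == 0 || length(mb) == 0) {
      stop("planted regulation pair (", pr[1], ",", pr[2],
           ") has no exclusive members")
    }
    all_pairs <- expand.grid(from = ma, to = mb, stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)
    need <- ceiling(config$planted_regulation_density * nrow(all_pairs))
    pick <- sample.int(nrow(all_pairs), need)
    r_from <- c(r_from, all_pairs$from[pick])
    r_to <- c(r_to, all_pairs$to[pick])
    planted_reg <- rbind(planted_reg, data.frame(
      source_id = sets[[pr[1]]]$id, target_id = sets[[pr[2]]]$id,
      stringsAsFactors = FALSE))
  }
  regulation <- gene_network(r_from, r_to, 1, directed = TRUE)

  list(
    corpus = corpus,
    ppi = ppi,
    regulation = regulation,
    truth = list(
      planted_sets = vapply(sets[planted_idx], `[[`, character(1), "id"),
      planted_regulation = planted_reg,
      seed = config$seed
    )
  )
}

#' Write a synthetic dataset to disk as plain-text fixtures
#'
#' Writes corpus.gmt, ppi.tsv, regulation.tsv and truth.json into a
#' directory. Same seed, same bytes.
#'
#' @param sim Result of \code{\link{generate_synthetic}}.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gmt(sim$corpus, file.path(dir, "corpus.gmt"))
  write_network(sim$ppi, file.path(dir, "ppi.tsv"))
  write_network(sim$regulation, file.path(dir, "regulation.tsv"))
  jsonlite::write_json(
    list(planted_sets = sim$truth$planted_sets,
         planted_regulation = sim$truth$planted_regulation,
         seed = sim$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
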