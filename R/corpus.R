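#' Construct a gene set (PAG)
#'
#' A PAG (Pathway, Annotated-list or Gene-signature) is the basic unit of a
#' corpus: an identifier, a human-readable name/description, a type code and
#' a set of member gene symbols. Symbols are whitespace-trimmed and
#' uppercased so that all downstream overlap arithmetic is symbol-exact.
#'
#' @param id Unique set identifier (opaque string).
#' @param members Character vector of gene symbols; duplicates are removed
#'   after normalization.
#' @param name Display name; defaults to the id.
#' @param pag_type One of "P" (pathway), "A" (annotated list) or
#'   "G" (gene signature).
#' @param source Free-text provenance label.
#' @param description Free-text description.
#' @return An object of class \code{gene_set}.
#' @export
gene_set <- function(id, members, name = id, pag_type = "G",
                     source = "unknown", description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!pag_type %in% c("P", "A", "G")) {
    stop("pag_type must be one of 'P', 'A', 'G', got: ", pag_type)
  }
  members <- normalize_symbols(members)
  if (length(members) == 0L) {
    stop("gene set '", id, "' has no members after normalization")
  }
  structure(
    list(id = id, name = name, pag_type = pag_type, source = source,
         description = description, members = members),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s] size=%d\n", x$id, x$pag_type,
              length(x$members)))
  invisible(x)
}

#' Size of a gene set
#' @param set A \code{gene_set}.
#' @return Integer number of members.
#' @export
set_size <- function(set) length(set$members)

# Trim, drop empties, uppercase, deduplicate preserving first occurrence.
normalize_symbols <- function(x) {
  x <- trimws(as.character(x))
  x <- x[nzchar(x)]
  unique(toupper(x))
}

#' Construct a corpus of gene sets
#'
#' A corpus bundles a list of gene sets with the gene universe used as the
#' background population (N) by every hypergeometric computation. When no
#' background is declared the universe is the union of all members.
#'
#' @param sets List of \code{gene_set} objects with unique ids.
#' @param background Optional character vector of background gene symbols;
#'   the universe becomes the union of members and background.
#' @return An object of class \code{pag_corpus}.
#' @export
pag_corpus <- function(sets, background = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0L) {
    ok <- vapply(sets, inherits, logical(1), what = "gene_set")
    if (!all(ok)) stop("all elements of 'sets' must be gene_set objects")
  }
  ids <- vapply(sets, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate set ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(sets) <- ids
  universe <- unique(c(unlist(lapply(sets, `[[`, "members"),
                              use.names = FALSE),
                       normalize_symbols(background %||% character(0))))
  structure(list(sets = sets, universe = universe), class = "pag_corpus")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pag_corpus <- function(x, ...) {
  cat(sprintf("<pag_corpus> %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' @export
length.pag_corpus <- function(x) length(x$sets)

#' Sizes of all sets in a corpus
#' @param corpus A \code{pag_corpus}.
#' @return Named integer vector of set sizes.
#' @export
corpus_sizes <- function(corpus) {
  vapply(corpus$sets, function(s) length(s$members), integer(1))
}

#' Membership frequency of genes across a corpus
#'
#' Counts, for every gene in the universe, the number of sets that contain
#' it. Used by the RP-score to reward (or penalize) genes recurring across
#' many sets.
#'
#' @param corpus A \code{pag_corpus}.
#' @return Named integer vector over the corpus universe (0 for background
#'   genes that belong to no set).
#' @export
gene_frequencies <- function(corpus) {
  freq <- integer(length(corpus$universe))
  names(freq) <- corpus$universe
  for (s in corpus$sets) freq[s$members] <- freq[s$members] + 1L
  freq
}

#' Read a corpus from a GMT file
#'
#' One set per line: \code{id<TAB>description<TAB>gene1<TAB>gene2...}.
#' Because standard GMT has no type column, the set type may be encoded as
#' a \code{type=P|A|G} token anywhere in the description field (a
#' \code{source=...} token is honored the same way); absent a token the
#' type defaults to "G". Duplicate genes on a line are deduplicated and
#' symbols are uppercased.
#'
#' @param path Path to a GMT file (UTF-8, LF).
#' @param background Optional path to a background gene list (one symbol
#'   per line, '#' comments skipped) extending the universe.
#' @return A \code{pag_corpus}.
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d of '%s': %d field(s), need >= 3",
                   i, path, length(fields)))
    }
    desc <- fields[2]
    meta <- parse_description_tokens(desc)
    sets[[i]] <- gene_set(
      id = fields[1], members = fields[-(1:2)],
      name = meta$name %||% fields[1],
      pag_type = meta$type %||% "G",
      source = meta$source %||% "unknown",
      description = desc
    )
  }
  bg <- if (!is.null(background)) read_gene_list(background) else NULL
  pag_corpus(sets, background = bg)
}

# Pull optional "type=P", "source=XYZ", "name=..." tokens out of a GMT
# description field. Tokens are space-separated key=value pairs.
parse_description_tokens <- function(desc) {
  out <- list(type = NULL, source = NULL, name = NULL)
  for (tok in strsplit(desc, " ", fixed = TRUE)[[1]]) {
    if (grepl("^type=[PAG]$", tok)) out$type <- sub("^type=", "", tok)
    if (grepl("^source=", tok)) out$source <- sub("^source=", "", tok)
    if (grepl("^name=", tok)) out$name <- sub("^name=", "", tok)
  }
  out
}

#' Write a corpus to a GMT file
#'
#' One tab-separated line per set with members in sorted order, so the
#' output is a canonical form: read -> write -> read is the identity.
#' Set type and source are embedded as \code{type=}/\code{source=} tokens
#' in the description field so they survive a round trip.
#'
#' @param corpus A \code{pag_corpus}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(corpus, path) {
  stopifnot(inherits(corpus, "pag_corpus"))
  lines <- vapply(corpus$sets, function(s) {
    desc <- sprintf("type=%s source=%s", s$pag_type, s$source)
    paste(c(s$id, desc, sort(s$members)), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(unname(lines), con, sep = "\n")
  invisible(path)
}

#' Construct an interaction or regulation network
#'
#' @param from,to Character vectors of endpoint gene symbols.
#' @param confidence Numeric confidences in [0,1]; recycled; defaults to 1.
#' @param directed FALSE for a protein-protein interaction network,
#'   TRUE for a gene-regulation network (from regulates to).
#' @return A \code{gene_network}: a data.frame of edges plus attributes.
#'   Undirected duplicates (a,b)/(b,a) are collapsed keeping the maximum
#'   confidence; self-loops are dropped (count recorded in attribute
#'   \code{dropped_self_loops}).
#' @export
gene_network <- function(from, to, confidence = 1, directed = FALSE) {
  from <- normalize_endpoint(from)
  to <- normalize_endpoint(to)
  stopifnot(length(from) == length(to))
  confidence <- rep_len(as.numeric(confidence), length(from))
  if (any(!is.finite(confidence)) ||
      any(confidence < 0) || any(confidence > 1)) {
    stop("edge confidence must be within [0,1]")
  }
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]; confidence <- confidence[!self]
  if (!directed) {
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    conf <- tapply(confidence, key, max)
    parts <- strsplit(names(conf), "\r", fixed = TRUE)
    from <- vapply(parts, `[[`, character(1), 1L)
    to <- vapply(parts, `[[`, character(1), 2L)
    confidence <- as.numeric(conf)
  }
  o <- order(from, to)
  edges <- data.frame(from = from[o], to = to[o],
                      confidence = confidence[o],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, directed = directed,
                 dropped_self_loops = n_self),
            class = "gene_network")
}

normalize_endpoint <- function(x) toupper(trimws(as.character(x)))

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %s, %d edges\n",
              if (x$directed) "directed" else "undirected",
              nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a network
#' @param network A \code{gene_network}.
#' @return Integer edge count.
#' @export
n_edges <- function(network) nrow(network$edges)

#' Read a PPI or regulation network from a TSV edge list
#'
#' Expects 2 or 3 tab-separated columns: geneA, geneB and an optional
#' confidence in [0,1] (missing confidence defaults to 1.0). Lines starting
#' with '#' are skipped; a header line is detected when the third column of
#' the first data line is non-numeric. In undirected mode (a,b) and (b,a)
#' rows collapse into one edge keeping the maximum confidence. Self-loops
#' are dropped with a message reporting the count.
#'
#' @param path Path to the TSV file.
#' @param directed TRUE for a regulation network.
#' @return A \code{gene_network}.
#' @export
read_network <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(gene_network(character(0), character(0), directed = directed))
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < 2L)) {
    stop(sprintf("network parse error at line %d: fewer than 2 columns",
                 which(nf < 2L)[1]))
  }
  # header detection: first row has a non-numeric 3rd column, or 2 columns
  # whose values recur as numeric in no row at all -- keep it simple and
  # only treat row 1 as header when its confidence field is non-numeric.
  if (nf[1] >= 3L && is.na(suppressWarnings(as.numeric(rows[[1]][3])))) {
    rows <- rows[-1]
    if (length(rows) == 0L) {
      return(gene_network(character(0), character(0), directed = directed))
    }
  }
  from <- vapply(rows, `[[`, character(1), 1L)
  to <- vapply(rows, `[[`, character(1), 2L)
  conf <- vapply(rows, function(r) {
    if (length(r) >= 3L && nzchar(r[3])) suppressWarnings(as.numeric(r[3]))
    else 1.0
  }, numeric(1))
  if (anyNA(conf)) {
    stop("non-numeric confidence at line ", which(is.na(conf))[1])
  }
  net <- gene_network(from, to, conf, directed = directed)
  if (net$dropped_self_loops > 0L) {
    message("read_network: dropped ", net$dropped_self_loops, " self-loop(s)")
  }
  net
}

#' Write a network to a TSV edge list
#' @param network A \code{gene_network}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  e <- network$edges
  if (nrow(e)) {
    writeLines(sprintf("%s\t%s\t%s", e$from, e$to,
                       format(e$confidence, trim = TRUE, digits = 15)),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#' @param path File path; '#' comments and blank lines skipped.
#' @return Character vector of normalized unique symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  normalize_symbols(lines)
}

# igraph view of a network restricted to a member set; vertices are the
# set members (isolated members kept), edges those passing min_confidence.
induced_member_graph <- function(set, network, min_confidence = 0) {
  e <- network$edges
  keep <- e$from %in% set$members & e$to %in% set$members &
    e$confidence >= min_confidence
  e <- e[keep, , drop = FALSE]
  igraph::graph_from_data_frame(
    e, directed = network$directed,
    vertices = data.frame(name = set$members, stringsAsFactors = FALSE)
  )
}
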