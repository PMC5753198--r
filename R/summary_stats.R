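#' Fold change with two-decimal truncation
#'
#' new/old truncated (not rounded) to two decimals, the convention used in
#' database release notes: 57076/18607 = 3.0674... prints as 3.06.
#'
#' @param new,old Non-negative counts (old > 0); vectorized.
#' @return Truncated fold change.
#' @export
fold_change <- function(new, old) {
  if (any(old <= 0)) stop("fold change undefined for old <= 0")
  trunc(100 * new / old) / 100
}

#' Percent increase ratio with integer truncation
#'
#' floor(100 * new / old): 579037/93713 prints as 617 (percent).
#'
#' @param new,old Non-negative counts (old > 0); vectorized.
#' @return Integer percentage.
#' @export
increase_pct <- function(new, old) {
  if (any(old <= 0)) stop("increase ratio undefined for old <= 0")
  as.integer(floor(100 * new / old))
}

#' Corpus summary report
#'
#' Release-notes-style tallies of a corpus and its derived artifacts:
#' gene and set counts, the singleton/regular split, sets passing the
#' cohesion filters (CoCo > 0, CoCo >= 1 and the nCoCo analogues), set-set
#' edge counts and the singleton/multi-gene endpoint classification of the
#' directed edges.
#'
#' @param corpus A \code{pag_corpus}.
#' @param cohesion Optional cohesion record data.frame.
#' @param m_edges,r_edges Optional edge data.frames from the builders.
#' @return Named list of counts.
#' @export
corpus_summary <- function(corpus, cohesion = NULL, m_edges = NULL,
                           r_edges = NULL) {
  sizes <- corpus_sizes(corpus)
  out <- list(
    genes = length(corpus$universe),
    sets = length(corpus$sets),
    singleton_sets = sum(sizes == 1L),
    regular_sets = sum(sizes > 1L)
  )
  if (!is.null(cohesion)) {
    out$sets_with_coco <- sum(cohesion$coco > 0)
    out$sets_coco_ge_1 <- sum(cohesion$coco >= 1)
    if (!all(is.na(cohesion$ncoco))) {
      out$sets_with_ncoco <- sum(cohesion$ncoco > 0, na.rm = TRUE)
      out$sets_ncoco_gt_1 <- sum(cohesion$ncoco > 1, na.rm = TRUE)
    }
  }
  if (!is.null(m_edges)) out$m_type_edges <- nrow(m_edges)
  if (!is.null(r_edges)) {
    out$r_type_edges <- nrow(r_edges)
    out <- c(out, as.list(classify_and_count(r_edges, corpus)))
  }
  out
}

#' Compare two corpus summaries
#'
#' Builds the comparison table (old count, new count, truncated fold change
#' and floored percent increase) for every category present in both
#' summaries.
#'
#' @param old_summary,new_summary Lists from \code{\link{corpus_summary}}.
#' @return data.frame with columns category, count_old, count_new,
#'   fold_change, increase_pct (NA where the old count is zero).
#' @export
compare_summaries <- function(old_summary, new_summary) {
  cats <- intersect(names(old_summary), names(new_summary))
  old_n <- vapply(old_summary[cats], as.numeric, numeric(1))
  new_n <- vapply(new_summary[cats], as.numeric, numeric(1))
  ok <- old_n > 0
  data.frame(
    category = cats,
    count_old = old_n,
    count_new = new_n,
    fold_change = ifelse(ok, ifelse(ok, trunc(100 * new_n / old_n) / 100, NA),
                         NA_real_),
    increase_pct = ifelse(ok, floor(100 * new_n / old_n), NA_real_),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
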