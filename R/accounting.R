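READ_CLASSES <- c("SSU", "LSU", "mRNA", "other")

#' Per-library read-class tallies
#'
#' Sums counts by read class (SSU rRNA, LSU rRNA, mRNA, other non-rRNA) for
#' each library in the table and expresses them as percentages of the
#' library total — the accounting behind a reads-per-library summary table.
#'
#' @param table a `library_table` (may contain several libraries).
#' @return A `class_tally` data frame, one row per library: total reads,
#'   per-class counts `n_<class>` and percentages `pct_<class>`.
#' @export
class_tallies <- function(table) {
  table <- validate_library_table(table, "class_tallies")
  out <- do.call(rbind, lapply(split(table, table$library_id), function(tab) {
    n <- vapply(READ_CLASSES, function(cl) sum(tab$count[tab$class == cl]), 0)
    total <- sum(n)
    row <- data.frame(library_id = tab$library_id[1], pool_label = tab$pool_label[1],
                      amplified = tab$amplified[1], total_reads = total,
                      stringsAsFactors = FALSE)
    for (cl in READ_CLASSES) row[[paste0("n_", cl)]] <- n[[cl]]
    for (cl in READ_CLASSES) row[[paste0("pct_", cl)]] <- 100 * n[[cl]] / total
    row
  }))
  rownames(out) <- NULL
  class(out) <- c("class_tally", class(out))
  out
}

#' Count-weighted mean GC content of one read class
#'
#' @param table a `library_table` for a single library.
#' @param class one of `"SSU"`, `"LSU"`, `"mRNA"`, `"other"`.
#' @return Mean GC percent, weighted by read counts over the features of
#'   that class.
#' @export
mean_gc_by_class <- function(table, class) {
  table <- validate_library_table(table, "mean_gc_by_class")
  stopifnot(length(class) == 1)
  rows <- table[table$class == class & table$count > 0, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_sipef("sipef_missing_class", "class %s absent from the library", class)
  }
  sum(rows$gc_percent * rows$count) / sum(rows$count)
}

#' Paired two-tailed Student's t-test on a vector of paired differences
#'
#' Thin wrapper around [stats::t.test()] with the degenerate cases made
#' explicit: identical pairs (all differences zero) give `t = 0, p = 1`;
#' zero variance with a nonzero mean is reported as `p = 0` with infinite t.
#'
#' @param d numeric vector of paired differences (length >= 2).
#' @return List with elements `t`, `df` and `p`.
#' @export
#' @examples
#' paired_two_tailed_t(c(1, 2, 3))  # t = 2*sqrt(3), df = 2
paired_two_tailed_t <- function(d) {
  if (length(d) < 2) {
    stop_sipef("sipef_insufficient_data", "need >= 2 paired differences (got %d)",
               length(d))
  }
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0))
  }
  tt <- stats::t.test(d, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Number of rare mRNA features in a library set
#'
#' Counts mRNA features whose summed reads (across the libraries in
#' `table`) fall below `max_count` — used to compare the prevalence of rare
#' transcripts between amplified and unamplified libraries.
#'
#' @param table a `library_table`.
#' @param max_count threshold (>= 1); features with total reads strictly
#'   below it are counted.
#' @return Integer count of rare mRNA features.
#' @export
rare_feature_frequency <- function(table, max_count) {
  table <- validate_library_table(table, "rare_feature_frequency")
  if (max_count < 1) abort_invalid("max_count must be >= 1")
  rows <- table[table$class == "mRNA", , drop = FALSE]
  if (nrow(rows) == 0) return(0L)
  totals <- tapply(rows$count, rows$feature_id, sum)
  sum(totals < max_count)
}
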