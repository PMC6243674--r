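library_table_columns <- c("library_id", "pool_label", "amplified", "feature_id",
                           "feature_kind", "class", "lineage", "gc_percent", "count")

validate_library_table <- function(tab, context = "library table") {
  tab <- as.data.frame(tab)
  missing <- setdiff(library_table_columns, names(tab))
  if (length(missing)) {
    stop_sipef("sipef_format", "%s: missing columns %s", context,
               paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    stop_sipef("sipef_insufficient_data", "%s: no rows", context)
  }
  bad <- which(tab$count < 0)
  if (length(bad)) {
    stop_sipef("sipef_validation", "%s: negative count at row(s) %s", context,
               paste(bad, collapse = ", "))
  }
  if (sum(tab$count) <= 0) {
    stop_sipef("sipef_insufficient_data", "%s: total count is zero", context)
  }
  if (!all(tab$class %in% c("SSU", "LSU", "mRNA", "other"))) {
    stop_sipef("sipef_format", "%s: class must be SSU, LSU, mRNA or other", context)
  }
  key <- paste(tab$library_id, tab$feature_id, tab$class)
  if (anyDuplicated(key)) {
    stop_sipef("sipef_validation", "%s: duplicate (feature_id, class) within a library",
               context)
  }
  class(tab) <- unique(c("library_table", class(tab)))
  tab
}

#' Sample a sequencing library from a pooled set of gradient fractions
#'
#' Draws `depth` reads multinomially. A feature's probability is proportional
#' to its RNA mass summed over the pool's member fractions, times the
#' community's read-class mix, and (for mRNA) the transcript's expression
#' weight within its host taxon. Transcripts shared between taxa are summed
#' into one row per (function, class). This stands in for sequencing plus
#' read classification: the output is the count table a classifier would
#' produce, with lineage and GC metadata per feature. Zero-count features are
#' dropped (count tables list observed features only).
#'
#' @param pool a `pool_spec` from [select_pools()].
#' @param profiles list of simulator `gradient_profile`s covering the pool's
#'   member gradients (must carry per-taxon mass matrices).
#' @param community the [make_community()] ground truth.
#' @param depth total reads to draw (>= 1).
#' @param seed integer seed.
#' @param amplified logical flag recorded in the table.
#' @return A `library_table` data frame with columns
#'   `library_id, pool_label, amplified, feature_id, feature_kind, class,
#'   lineage, gc_percent, count`.
#' @export
sample_reads <- function(pool, profiles, community, depth = 1e5, seed = 1L,
                         amplified = FALSE) {
  stopifnot(inherits(pool, "pool_spec"), inherits(community, "sip_community"))
  if (inherits(profiles, "gradient_profile")) profiles <- list(profiles)
  names(profiles) <- vapply(profiles, `[[`, "", "gradient_id")

  taxa <- community$taxa
  taxon_mass <- numeric(nrow(taxa))
  for (i in seq_len(nrow(pool$members))) {
    g <- pool$members$gradient_id[i]
    f <- pool$members$fraction_index[i]
    p <- profiles[[g]]
    if (is.null(p) || is.null(p$mass)) {
      abort_invalid("no mass matrix available for gradient %s", g)
    }
    taxon_mass <- taxon_mass + p$mass[, f]
  }
  if (sum(taxon_mass) <= 0) {
    stop_sipef("sipef_empty_pool", "pool %s has zero total RNA mass", pool$pool_label)
  }
  w <- taxon_mass / sum(taxon_mass)
  mix <- community$class_mix

  rrna <- do.call(rbind, lapply(c("SSU", "LSU", "other"), function(cl) {
    data.frame(feature_id = taxa$taxon_id, feature_kind = "taxon", class = cl,
               lineage = taxon_lineage_strings(taxa), gc_percent = taxa$gc_percent,
               prob = w * mix[[cl]], stringsAsFactors = FALSE)
  }))

  tr <- community$transcripts
  tr_prob <- w[match(tr$taxon_id, taxa$taxon_id)] * mix[["mRNA"]] * tr$expr_weight
  mrna <- data.frame(feature_id = tr$function_id, feature_kind = "transcript",
                     class = "mRNA", lineage = transcript_lineage_strings(tr),
                     gc_percent = tr$gc_percent, prob = tr_prob,
                     stringsAsFactors = FALSE)
  # one row per function: sum expression over host taxa
  mrna <- stats::aggregate(prob ~ feature_id + feature_kind + class + lineage + gc_percent,
                           data = mrna, FUN = sum)

  rows <- rbind(rrna, mrna)
  counts <- with_seed(derive_seed(seed, paste0("reads:", pool$pool_label,
                                               if (amplified) ":amp" else "")),
                      stats::rmultinom(1, size = depth, prob = rows$prob)[, 1])
  rows$count <- counts
  rows <- rows[rows$count > 0, setdiff(names(rows), "prob"), drop = FALSE]
  rows <- cbind(
    library_id = paste0(pool$pool_label, if (amplified) "_amp" else "_unamp"),
    pool_label = pool$pool_label, amplified = amplified, rows,
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  validate_library_table(rows, paste0("sample_reads(", pool$pool_label, ")"))
}

#' Apply a GC-lowering linear-amplification bias to a library
#'
#' In-vitro transcription amplification preferentially amplifies low-GC
#' templates. mRNA counts are resampled multinomially with per-feature
#' weights `w = exp(-kappa * (gc - 50))` applied to the observed proportions
#' and renormalized; rRNA classes (SSU, LSU, other) are left untouched, as
#' amplification does not measurably shift rRNA GC. The total mRNA read count
#' is preserved; the >= 300-fold RNA mass gain of amplification affects mass,
#' not counts, and is recorded as the `amp_gain` attribute only.
#' `kappa = 0` returns the table unchanged.
#'
#' @param table a `library_table`.
#' @param kappa bias strength per GC percentage point (>= 0).
#' @param seed integer seed.
#' @param amp_gain fold mass gain recorded as an attribute (metadata only).
#' @return The amplified `library_table` (`amplified = TRUE`,
#'   `library_id` suffixed `_amp`).
#' @export
apply_amplification_bias <- function(table, kappa, seed = 1L, amp_gain = 300) {
  table <- validate_library_table(table, "apply_amplification_bias")
  if (kappa < 0) abort_invalid("kappa must be >= 0")
  out <- table
  out$amplified <- TRUE
  out$library_id <- paste0(sub("_unamp$", "", out$library_id), "_amp")
  if (kappa > 0) {
    m <- which(out$class == "mRNA")
    if (length(m) > 0) {
      wts <- out$count[m] * exp(-kappa * (out$gc_percent[m] - 50))
      total <- sum(out$count[m])
      counts <- with_seed(derive_seed(seed, paste0("amp:", table$pool_label[1])),
                          stats::rmultinom(1, size = total, prob = wts)[, 1])
      out$count[m] <- counts
      out <- out[out$count > 0, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "amp_gain") <- amp_gain
  validate_library_table(out, "apply_amplification_bias")
}
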