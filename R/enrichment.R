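level_info <- function(feature_kind, level) {
  levels <- switch(feature_kind, taxon = TAXON_LEVELS, transcript = TRANSCRIPT_LEVELS,
                   abort_invalid("feature_kind must be 'taxon' or 'transcript'"))
  depth <- match(level, levels)
  if (is.na(depth)) {
    abort_invalid("level '%s' unknown for %s (use one of: %s)", level, feature_kind,
                  paste(levels, collapse = ", "))
  }
  list(levels = levels, depth = depth)
}

#' Relative abundances at a taxonomic or functional level
#'
#' Aggregates a library's counts to the requested lineage level and divides
#' by the library's total count of the basis read class: SSU rRNA for taxa,
#' mRNA for transcripts (rRNA and mRNA relative abundances are formed
#' separately, against their own sequencing basis). Reads whose lineage is
#' missing or blank at the requested level are collected into an
#' `"unclassified"` bucket, which is part of the denominator, so proportions
#' sum to 1 at every level.
#'
#' @param table a `library_table` for a single library.
#' @param feature_kind `"taxon"` or `"transcript"`.
#' @param level lineage level: one of `TAXON_LEVELS` for taxa
#'   (phylum...genus) or `TRANSCRIPT_LEVELS` (category, pathway, gene) for
#'   transcripts.
#' @param basis_class read class forming the denominator; defaults to
#'   `"SSU"` for taxa and `"mRNA"` for transcripts.
#' @param classified_only if `TRUE`, the denominator is restricted to reads
#'   classified at the requested level (the unclassified bucket is dropped).
#' @return Data frame with `feature` (label at the level), `parent` (label
#'   one level up, `NA` at the top level), `count` and `proportion`.
#' @export
relative_abundance <- function(table, feature_kind = c("taxon", "transcript"),
                               level, basis_class = NULL,
                               classified_only = FALSE) {
  feature_kind <- match.arg(feature_kind)
  table <- validate_library_table(table, "relative_abundance")
  if (length(unique(table$library_id)) != 1) {
    abort_invalid("relative_abundance works on a single library; split first")
  }
  info <- level_info(feature_kind, level)
  if (is.null(basis_class)) basis_class <- if (feature_kind == "taxon") "SSU" else "mRNA"

  rows <- table[table$class == basis_class, , drop = FALSE]
  basis_total <- sum(rows$count)
  if (basis_total <= 0) {
    stop_sipef("sipef_missing_class", "library has no %s reads to normalize against",
               basis_class)
  }
  rows <- rows[rows$feature_kind == feature_kind, , drop = FALSE]

  parts <- lineage_split(rows$lineage)
  lab <- vapply(parts, function(p) if (length(p) >= info$depth) p[info$depth] else NA_character_, "")
  par <- if (info$depth > 1) {
    vapply(parts, function(p) if (length(p) >= info$depth - 1) p[info$depth - 1] else NA_character_, "")
  } else rep(NA_character_, length(parts))
  unclass <- is.na(lab) | lab == "" | lab == "unclassified"
  lab[unclass] <- "unclassified"
  par[unclass] <- NA_character_

  agg <- stats::aggregate(rows$count, by = list(feature = lab, parent = ifelse(is.na(par), "", par)),
                          FUN = sum)
  names(agg)[3] <- "count"
  agg$parent[agg$parent == ""] <- NA_character_
  # reads of the basis class belonging to the other feature kind are part of
  # the denominator but not classifiable at this level
  other_kind <- basis_total - sum(rows$count)
  if (other_kind > 0 || !classified_only) {
    if (!"unclassified" %in% agg$feature && (other_kind > 0)) {
      agg <- rbind(agg, data.frame(feature = "unclassified", parent = NA_character_,
                                   count = 0))
    }
    if ("unclassified" %in% agg$feature) {
      agg$count[agg$feature == "unclassified"] <-
        agg$count[agg$feature == "unclassified"] + other_kind
    }
  }
  denom <- if (classified_only) sum(agg$count[agg$feature != "unclassified"]) else basis_total
  if (classified_only) agg <- agg[agg$feature != "unclassified", , drop = FALSE]
  if (denom <= 0) {
    stop_sipef("sipef_missing_class", "no classified %s reads at level %s",
               basis_class, level)
  }
  agg$proportion <- agg$count / denom
  agg <- agg[order(-agg$proportion, agg$feature), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Enrichment factor of a feature from its four pool abundances
#'
#' The core SIP statistic: with `h13, l13` the feature's relative abundance
#' in the heavy and light pools of the 13C gradient and `h12, l12` the same
#' for the 12C control,
#'
#' \deqn{EF = \frac{h_{13C}}{l_{13C}} - \frac{h_{12C}}{l_{12C}}}
#'
#' A positive EF indicates isotopic labeling (the feature shifted toward the
#' heavy fractions beyond what its physical properties cause in the
#' control); a negative EF indicates more frequent detection in the light
#' fraction. A pseudo-abundance added to all four terms keeps ratios finite
#' when a feature is absent from a light pool; with `pseudo = 0` a zero
#' light abundance is an error (`on_zero = "error"`) or `NA`
#' (`on_zero = "na"`, reported as undefined rather than infinite).
#'
#' @param heavy13,light13,heavy12,light12 relative abundances in \[0, 1\].
#'   Vectorized.
#' @param pseudo pseudo-abundance (>= 0) added to every term.
#' @param on_zero behavior when a light abundance is 0 with `pseudo = 0`.
#' @return Dimensionless EF value(s).
#' @export
#' @examples
#' enrichment_factor(0.30, 0.10, 0.12, 0.10)  # 3.0 - 1.2 = 1.8
enrichment_factor <- function(heavy13, light13, heavy12, light12, pseudo = 0,
                              on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  if (pseudo < 0) abort_invalid("pseudo must be >= 0")
  ab <- cbind(heavy13, light13, heavy12, light12)
  if (any(ab < 0 | ab > 1)) abort_invalid("abundances must lie in [0, 1]")
  l13 <- light13 + pseudo
  l12 <- light12 + pseudo
  zero <- l13 == 0 | l12 == 0
  if (any(zero) && on_zero == "error") {
    stop_sipef("sipef_division_undefined",
               "light abundance 0 with pseudo = 0; set a pseudo-abundance or drop the feature")
  }
  ef <- (heavy13 + pseudo) / l13 - (heavy12 + pseudo) / l12
  ef[zero] <- NA_real_
  ef
}

# join per-library abundance tables into a feature x library proportion grid
abundance_quartet <- function(libs, feature_kind, level, classified_only) {
  ra <- lapply(libs, relative_abundance, feature_kind = feature_kind,
               level = level, classified_only = classified_only)
  feats <- unique(unlist(lapply(ra, `[[`, "feature")))
  parent <- rep(NA_character_, length(feats))
  for (r in ra) {
    m <- match(r$feature, feats)
    parent[m[!is.na(r$parent)]] <- r$parent[!is.na(r$parent)]
  }
  prop <- vapply(ra, function(r) {
    p <- r$proportion[match(feats, r$feature)]
    ifelse(is.na(p), 0, p)
  }, numeric(length(feats)))
  cnt <- vapply(ra, function(r) {
    k <- r$count[match(feats, r$feature)]
    ifelse(is.na(k), 0, k)
  }, numeric(length(feats)))
  colnames(prop) <- colnames(cnt) <- names(libs)
  list(feature = feats, parent = parent, prop = prop, count = cnt)
}

split_pool_libraries <- function(libraries, context) {
  if (is.data.frame(libraries)) {
    libraries <- split(as.data.frame(libraries), libraries$library_id)
  }
  libraries <- lapply(libraries, validate_library_table, context)
  labels <- vapply(libraries, function(l) l$pool_label[1], "")
  if (!setequal(labels, POOL_LABELS) || length(labels) != 4) {
    stop_sipef("sipef_incomplete_design",
               "%s: need exactly the four pools (%s); got: %s", context,
               paste(POOL_LABELS, collapse = ", "), paste(labels, collapse = ", "))
  }
  amp <- vapply(libraries, function(l) l$amplified[1], NA)
  if (length(unique(amp)) != 1) {
    stop_sipef("sipef_design_mixing",
               "%s: amplified and unamplified libraries must not be mixed", context)
  }
  names(libraries) <- labels
  libraries[POOL_LABELS]
}

#' Ranked enrichment factors at one lineage level
#'
#' Computes, for every feature at the requested level, the EF from its
#' quartet of relative abundances across the four pools, with the standard
#' reporting filters: taxa are kept when their mean relative abundance over
#' the four libraries exceeds `min_mean_abundance` (strictly, mirroring a
#' "> 1%" cut) and transcripts when their summed reads reach
#' `min_total_reads` ("\eqn{\ge} 20 total reads"). The unclassified bucket
#' takes part in every denominator but is never ranked. Features absent from
#' a light pool are handled by the pseudo-abundance rule (default: half the
#' smallest nonzero proportion across the four libraries).
#'
#' @param libraries the four pool libraries: a list of `library_table`s or
#'   one data frame carrying four `library_id`s. All must be unamplified or
#'   all amplified.
#' @param feature_kind `"taxon"` or `"transcript"`.
#' @param level lineage level to aggregate to.
#' @param min_mean_abundance abundance filter (strict >); default 0.01 for
#'   taxa, 0 for transcripts.
#' @param min_total_reads total-read filter (>=); default 20 for
#'   transcripts, 0 for taxa.
#' @param pseudo `"auto"` (half the smallest nonzero proportion), or a
#'   nonnegative number; `0` reports light-zero features as undefined (`NA`).
#' @param parent optional parent label one level up; restricts the ranking
#'   to features within that clade or category.
#' @param classified_only denominator choice, see [relative_abundance()].
#' @return An `ef_table` data frame sorted by descending EF: `feature_id`,
#'   `level`, `parent`, `ef`, `mean_rel_abundance`, `total_reads`,
#'   `n_libraries`, `interpretation` (`"labeled"` iff `ef > 0`, else
#'   `"unlabeled/light-shifted"`, `"undefined"` for `NA`).
#' @export
ef_ranking <- function(libraries, feature_kind = c("taxon", "transcript"), level,
                       min_mean_abundance = NULL, min_total_reads = NULL,
                       pseudo = "auto", parent = NULL, classified_only = FALSE) {
  feature_kind <- match.arg(feature_kind)
  libs <- split_pool_libraries(libraries, "ef_ranking")
  if (is.null(min_mean_abundance)) {
    min_mean_abundance <- if (feature_kind == "taxon") 0.01 else 0
  }
  if (is.null(min_total_reads)) {
    min_total_reads <- if (feature_kind == "transcript") 20 else 0
  }

  q <- abundance_quartet(libs, feature_kind, level, classified_only)
  if (!is.null(parent)) {
    info <- level_info(feature_kind, level)
    if (info$depth == 1) abort_invalid("top level has no parent to drill into")
    if (!parent %in% q$parent) {
      stop_sipef("sipef_missing_lineage", "no %s features under parent '%s'",
                 feature_kind, parent)
    }
  }

  ps <- if (identical(pseudo, "auto")) {
    nz <- q$prop[q$prop > 0]
    if (length(nz) == 0) 0 else min(nz) / 2
  } else {
    if (!is.numeric(pseudo) || pseudo < 0) abort_invalid("pseudo must be 'auto' or >= 0")
    pseudo
  }

  ef <- enrichment_factor(q$prop[, "13C-heavy"], q$prop[, "13C-light"],
                          q$prop[, "12C-heavy"], q$prop[, "12C-light"],
                          pseudo = ps, on_zero = "na")
  out <- data.frame(
    feature_id = q$feature, level = level, parent = q$parent, ef = ef,
    mean_rel_abundance = rowMeans(q$prop), total_reads = rowSums(q$count),
    n_libraries = rowSums(q$count > 0),
    stringsAsFactors = FALSE
  )
  out$interpretation <- ifelse(is.na(out$ef), "undefined",
                               ifelse(out$ef > 0, "labeled", "unlabeled/light-shifted"))
  out <- out[out$feature_id != "unclassified", , drop = FALSE]
  if (!is.null(parent)) out <- out[!is.na(out$parent) & out$parent == parent, , drop = FALSE]
  if (feature_kind == "taxon") {
    out <- out[out$mean_rel_abundance > min_mean_abundance, , drop = FALSE]
    if (min_total_reads > 0) out <- out[out$total_reads >= min_total_reads, , drop = FALSE]
  } else {
    out <- out[out$total_reads >= min_total_reads, , drop = FALSE]
    if (min_mean_abundance > 0) {
      out <- out[out$mean_rel_abundance > min_mean_abundance, , drop = FALSE]
    }
  }
  out <- out[order(-ifelse(is.na(out$ef), -Inf, out$ef), out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pseudo") <- ps
  class(out) <- c("ef_table", class(out))
  out
}

#' @export
print.ef_table <- function(x, n = 10, ...) {
  cat(sprintf("Enrichment factors at level '%s' (%d features; pseudo = %.3g)\n",
              x$level[1], nrow(x), attr(x, "pseudo")))
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 3)
  if (nrow(x) > n) cat(sprintf("... and %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Nested enrichment-factor tables across lineage levels
#'
#' One EF table per requested level, each recomputed from counts aggregated
#' at that level (EFs are ratios and must not be averaged across children;
#' a family's EF comes from its summed counts). Optionally drills into a
#' named parent clade or category at each level below the first.
#'
#' @inheritParams ef_ranking
#' @param levels character vector of levels, ordered top-down.
#' @param parents optional named character vector: for a level present in
#'   the names, restrict that level's table to children of the given parent
#'   label.
#' @return Named list of `ef_table`s, one per level.
#' @export
ef_hierarchy <- function(libraries, feature_kind = c("taxon", "transcript"),
                         levels, parents = NULL, ...) {
  feature_kind <- match.arg(feature_kind)
  out <- lapply(levels, function(lv) {
    ef_ranking(libraries, feature_kind, lv,
               parent = if (!is.null(parents) && lv %in% names(parents)) parents[[lv]] else NULL,
               ...)
  })
  names(out) <- levels
  out
}
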