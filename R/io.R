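# All tables are written as UTF-8 TSV with a header row, '.' decimal and a
# leading provenance comment line: "# sipef <what> seed=<seed> config=<hash>".

write_stamped_tsv <- function(df, path, what, seed, hash) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cat(sprintf("# sipef %s seed=%s config=%s\n", what, seed, hash), file = con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

count_leading_comments <- function(path) {
  head <- readLines(path, n = 100, warn = FALSE)
  cum <- cumsum(startsWith(head, "#"))
  sum(cum == seq_along(head) & startsWith(head, "#"))
}

read_stamped_tsv <- function(path) {
  if (!file.exists(path)) stop_sipef("sipef_format", "file not found: %s", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Write / read the community ground-truth table
#'
#' Columns: `taxon_id`, `lineage` (semicolon-separated, depth 5),
#' `rel_abundance`, `gc_percent`, `alpha13C`.
#'
#' @param community a `sip_community`.
#' @param path output TSV path.
#' @param seed,hash provenance fields for the header comment.
#' @return The path, invisibly.
#' @export
write_community_tsv <- function(community, path, seed = community$seed, hash = "") {
  df <- data.frame(
    taxon_id = community$taxa$taxon_id,
    lineage = taxon_lineage_strings(community$taxa),
    rel_abundance = community$taxa$rel_abundance,
    gc_percent = community$taxa$gc_percent,
    alpha13C = community$taxa$alpha13C,
    stringsAsFactors = FALSE
  )
  write_stamped_tsv(df, path, "community", seed, hash)
}

#' Write / read gradient fraction tables
#'
#' Columns: `gradient_id`, `isotope`, `fraction_index`, `density_g_ml`,
#' `true_mass`, `measured_copies`.
#'
#' @param profiles a `gradient_profile` or list of them.
#' @param path TSV path.
#' @param seed,hash provenance fields.
#' @return `write_fraction_tsv`: the path, invisibly. `read_fraction_tsv`:
#'   a list of `gradient_profile`s, one per `gradient_id`.
#' @export
write_fraction_tsv <- function(profiles, path, seed = "", hash = "") {
  if (inherits(profiles, "gradient_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(gradient_id = p$fractions$gradient_id, isotope = p$isotope,
               fraction_index = p$fractions$fraction_index,
               density_g_ml = p$fractions$density,
               true_mass = if ("true_mass" %in% names(p$fractions))
                 p$fractions$true_mass else NA_real_,
               measured_copies = p$fractions$measured_copies,
               stringsAsFactors = FALSE)
  }))
  write_stamped_tsv(df, path, "fractions", seed, hash)
}

#' @rdname write_fraction_tsv
#' @export
read_fraction_tsv <- function(path) {
  df <- read_stamped_tsv(path)
  need <- c("gradient_id", "isotope", "fraction_index", "density_g_ml")
  if (!all(need %in% names(df))) {
    stop_sipef("sipef_format", "fraction TSV must have columns %s",
               paste(need, collapse = ", "))
  }
  names(df)[names(df) == "density_g_ml"] <- "density"
  lapply(split(df, df$gradient_id), function(g) {
    build_profile(g, isotope = g$isotope[1])
  })
}

#' Write / read library count tables
#'
#' Columns: `library_id`, `pool_label`, `amplified`, `feature_id`,
#' `feature_kind`, `class`, `lineage`, `gc_percent`, `count`. On reading,
#' rows are validated (schema, negative counts reported with file line
#' numbers) and split into one `library_table` per `library_id`.
#'
#' @param libraries a `library_table` or list of them.
#' @param path TSV path.
#' @param seed,hash provenance fields.
#' @return `write_library_tsv`: the path, invisibly. `read_library_tsv`:
#'   named list of validated `library_table`s.
#' @export
write_library_tsv <- function(libraries, path, seed = "", hash = "") {
  if (is.data.frame(libraries)) libraries <- list(libraries)
  df <- do.call(rbind, lapply(libraries, function(l) {
    as.data.frame(l)[, library_table_columns, drop = FALSE]
  }))
  rownames(df) <- NULL
  write_stamped_tsv(df, path, "libraries", seed, hash)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  df <- read_stamped_tsv(path)
  missing <- setdiff(library_table_columns, names(df))
  if (length(missing)) {
    stop_sipef("sipef_format", "%s: missing columns %s", path,
               paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    stop_sipef("sipef_insufficient_data", "%s: table is empty (header only)", path)
  }
  offset <- count_leading_comments(path) + 1L  # comments + header row
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad)) {
    stop_sipef("sipef_validation", "%s: invalid count at line(s) %s", path,
               paste(bad + offset, collapse = ", "))
  }
  if (!all(df$class %in% READ_CLASSES)) {
    bad <- which(!df$class %in% READ_CLASSES)
    stop_sipef("sipef_format", "%s: unknown read class at line(s) %s", path,
               paste(bad + offset, collapse = ", "))
  }
  lapply(split(df, df$library_id), validate_library_table, context = path)
}

#' Write pool assignments
#'
#' Columns: `pool_label`, `gradient_id`, `fraction_index`, `density`,
#' `mass`, plus the realized window bounds.
#'
#' @param pools list of `pool_spec` from [select_pools()].
#' @param path TSV path.
#' @param seed,hash provenance fields.
#' @export
write_pool_tsv <- function(pools, path, seed = "", hash = "") {
  df <- do.call(rbind, lapply(pools, function(p) {
    cbind(pool_label = p$pool_label, p$members,
          window_low = p$density_window[1], window_high = p$density_window[2],
          stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  write_stamped_tsv(df, path, "pools", seed, hash)
}

#' Write an EF table or a diversity summary
#'
#' @param ef an `ef_table` from [ef_ranking()].
#' @param path TSV path.
#' @param seed,hash provenance fields.
#' @export
write_ef_tsv <- function(ef, path, seed = "", hash = "") {
  write_stamped_tsv(as.data.frame(ef), path, paste0("ef:", ef$level[1]), seed, hash)
}

#' @rdname write_ef_tsv
#' @param div result of [heavy_light_diversity()].
#' @export
write_diversity_tsv <- function(div, path, seed = "", hash = "") {
  write_stamped_tsv(div$summaries, path, "diversity", seed, hash)
}
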