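# Independent quadrature oracle for Gaussian band integrals: composite
# trapezoid rule on a fine grid, deliberately avoiding pnorm.
trapezoid_band_mass <- function(lo, hi, mu, sigma, n = 1e4) {
  x <- seq(lo, hi, length.out = n)
  y <- exp(-(x - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}

# Minimal hand-built library table; rows = list of c(feature, kind, class,
# lineage, gc, count)
toy_library <- function(library_id, pool_label, rows, amplified = FALSE) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(feature_id = r[[1]], feature_kind = r[[2]], class = r[[3]],
               lineage = r[[4]], gc_percent = as.numeric(r[[5]]),
               count = as.numeric(r[[6]]), stringsAsFactors = FALSE)
  }))
  cbind(library_id = library_id, pool_label = pool_label, amplified = amplified,
        df, stringsAsFactors = FALSE)
}

taxon_row <- function(feature, genus_lineage, count, gc = 55, class = "SSU") {
  list(feature, "taxon", class, genus_lineage, gc, count)
}

transcript_row <- function(feature, lineage, count, gc = 55) {
  list(feature, "transcript", "mRNA", lineage, gc, count)
}

lin5 <- function(genus, family = "FamA", order = "OrdA", class = "ClsA",
                 phylum = "PhyA") {
  paste(phylum, class, order, family, genus, sep = ";")
}

lin3 <- function(gene, pathway = "PathA", category = "CatA") {
  paste(category, pathway, gene, sep = ";")
}

# Four-pool toy design: per-pool SSU counts for named genera, padded with a
# filler genus to a fixed basis total so proportions are counts/basis.
toy_pool_set <- function(counts, basis = 100, lineages = NULL, amplified = FALSE) {
  stopifnot(all(POOL_LABELS %in% colnames(counts)))
  if (is.null(lineages)) {
    lineages <- setNames(vapply(rownames(counts), lin5, ""), rownames(counts))
  }
  lapply(setNames(POOL_LABELS, POOL_LABELS), function(lab) {
    rows <- lapply(rownames(counts), function(f) {
      taxon_row(f, lineages[[f]], counts[f, lab])
    })
    filler <- basis - sum(counts[, lab])
    stopifnot(filler >= 0)
    if (filler > 0) {
      rows <- c(rows, list(taxon_row("Filler", lin5("Filler", family = "FamZ",
                                                    order = "OrdZ", class = "ClsZ",
                                                    phylum = "PhyZ"), filler)))
    }
    toy_library(paste0(lab, if (amplified) "_amp" else "_unamp"), lab, rows,
                amplified = amplified)
  })
}

# Hand-specifiable gradient profile for pool-selection tests
profile_from_masses <- function(masses, gradient_id = "g1", isotope = "12C",
                                span = c(1.750, 1.855)) {
  n <- length(masses)
  b <- seq(span[2], span[1], length.out = n + 1)
  build_profile(data.frame(
    gradient_id = gradient_id, fraction_index = seq_len(n),
    density = (b[-1] + b[-length(b)]) / 2,
    measured_copies = masses
  ), isotope = isotope)
}
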