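# Built-in lineage pools for the synthetic community. Families (with their
# fixed upper lineage) echo the kinds of taxa seen in hydrocarbon-degrading
# aquifer communities; genus labels are fabricated and unique per taxon.
.family_pool <- data.frame(
  phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Bacteroidetes", "Actinobacteria"),
  class  = c("Betaproteobacteria", "Betaproteobacteria", "Gammaproteobacteria",
             "Gammaproteobacteria", "Gammaproteobacteria", "Alphaproteobacteria",
             "Flavobacteriia", "Actinomycetia"),
  order  = c("Rhodocyclales", "Burkholderiales", "Pseudomonadales",
             "Pseudomonadales", "Xanthomonadales", "Sphingomonadales",
             "Flavobacteriales", "Micrococcales"),
  family = c("Rhodocyclaceae", "Comamonadaceae", "Pseudomonadaceae",
             "Moraxellaceae", "Xanthomonadaceae", "Sphingomonadaceae",
             "Flavobacteriaceae", "Microbacteriaceae"),
  stringsAsFactors = FALSE
)

# Functional lineage pool (category -> pathway); genes get K-number-like ids.
.function_pool <- data.frame(
  category = c(rep("Xenobiotics biodegradation and metabolism", 3),
               rep("Carbohydrate metabolism", 2),
               rep("Energy metabolism", 2),
               "Amino acid metabolism", "Cellular processes",
               "Metabolism of terpenoids and polyketides"),
  pathway = c("Toluene degradation", "Xylene degradation", "Benzoate degradation",
              "Glycolysis / Gluconeogenesis", "Citrate cycle (TCA cycle)",
              "Oxidative phosphorylation", "Nitrogen metabolism",
              "Glycine, serine and threonine metabolism", "Flagellar assembly",
              "Biosynthesis of siderophores"),
  stringsAsFactors = FALSE
)

rdirichlet1 <- function(n, conc) {
  g <- stats::rgamma(n, shape = conc, rate = 1)
  g / sum(g)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lo | x >= hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a SIP study community with known labeling ground truth
#'
#' Draws a bacterial community of `n_taxa` members, of which exactly
#' `n_labeled` are fully 13C-labeled (atom fraction 1) and the rest are
#' unlabeled (atom fraction 0) -- emulating an incubation on a fully labeled
#' substrate where active degraders incorporate the heavy isotope. Relative
#' RNA-mass abundances follow a symmetric Dirichlet with concentration
#' `conc` (default 0.5: heavy-tailed, a few families dominate). Each taxon
#' expresses 3-6 functional transcripts drawn from a shared pool (so
#' pathways are expressed by several taxa), with Dirichlet expression
#' weights summing to 1 within the taxon.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param n_labeled number of fully labeled taxa, `0 <= n_labeled <= n_taxa`.
#' @param seed integer seed; communities are pure functions of it.
#' @param conc Dirichlet concentration for abundances.
#' @param class_mix named proportions of read classes
#'   (`SSU`, `LSU`, `mRNA`, `other`), summing to 1. The default
#'   (0.35, 0.64, 0.009, 0.001) reflects a total RNA-seq library in which
#'   rRNA dominates and about 1% of reads are non-ribosomal.
#' @param n_functions size of the shared transcript pool; default scales
#'   with `n_taxa`.
#' @return A `sip_community`: list with `taxa` (taxon_id, lineage columns,
#'   rel_abundance, gc_percent, alpha13C), `transcripts` (taxon_id,
#'   function_id, function lineage columns, gc_percent, expr_weight) and
#'   `class_mix`.
#' @export
#' @examples
#' com <- make_community(10, 3, seed = 7)
#' sum(com$taxa$rel_abundance)          # 1
#' sum(com$taxa$alpha13C == 1)          # 3
make_community <- function(n_taxa, n_labeled, seed,
                           conc = 0.5,
                           class_mix = c(SSU = 0.35, LSU = 0.64,
                                         mRNA = 0.009, other = 0.001),
                           n_functions = max(30L, 2L * n_taxa)) {
  if (n_taxa < 1) abort_invalid("n_taxa must be >= 1 (got %d)", n_taxa)
  if (n_labeled < 0 || n_labeled > n_taxa) {
    abort_invalid("n_labeled must lie in [0, n_taxa] (got %d with n_taxa = %d)",
                  n_labeled, n_taxa)
  }
  if (abs(sum(class_mix) - 1) > 1e-9) abort_invalid("class_mix must sum to 1")
  if (!all(c("SSU", "LSU", "mRNA", "other") %in% names(class_mix))) {
    abort_invalid("class_mix must name SSU, LSU, mRNA and other")
  }

  with_seed(derive_seed(seed, "community"), {
    fam_w <- rdirichlet1(nrow(.family_pool), 0.8)
    fam_i <- sample.int(nrow(.family_pool), n_taxa, replace = TRUE, prob = fam_w)
    fams <- .family_pool[fam_i, , drop = FALSE]
    genus <- sprintf("%s_g%02d", sub("aceae$", "", fams$family), seq_len(n_taxa))
    labeled <- rep(0, n_taxa)
    if (n_labeled > 0) labeled[sample.int(n_taxa, n_labeled)] <- 1

    taxa <- data.frame(
      taxon_id = sprintf("T%03d", seq_len(n_taxa)),
      phylum = fams$phylum, class = fams$class, order = fams$order,
      family = fams$family, genus = genus,
      rel_abundance = if (n_taxa == 1) 1 else rdirichlet1(n_taxa, conc),
      gc_percent = rnorm_trunc(n_taxa, 55, 2, 45, 65),
      alpha13C = labeled,
      stringsAsFactors = FALSE
    )

    # shared functional pool: pathway from the fixed table, unique K-number
    fp_i <- sample.int(nrow(.function_pool), n_functions, replace = TRUE)
    functions <- data.frame(
      function_id = sprintf("K%05d", sample.int(20000L, n_functions)),
      category = .function_pool$category[fp_i],
      pathway = .function_pool$pathway[fp_i],
      gc_percent = rnorm_trunc(n_functions, 55, 5, 40, 70),
      stringsAsFactors = FALSE
    )
    functions$gene <- functions$function_id

    tr <- do.call(rbind, lapply(seq_len(n_taxa), function(i) {
      k <- sample(3:min(6, n_functions), 1)
      pick <- sample.int(n_functions, k)
      data.frame(
        taxon_id = taxa$taxon_id[i],
        functions[pick, c("function_id", "category", "pathway", "gene", "gc_percent")],
        expr_weight = rdirichlet1(k, 0.7),
        stringsAsFactors = FALSE
      )
    }))
    rownames(tr) <- NULL

    structure(
      list(taxa = taxa, transcripts = tr, class_mix = class_mix, seed = seed),
      class = "sip_community"
    )
  })
}

#' @export
print.sip_community <- function(x, ...) {
  cat(sprintf("SIP community: %d taxa (%d fully 13C-labeled), %d transcript entries\n",
              nrow(x$taxa), sum(x$taxa$alpha13C == 1), nrow(x$transcripts)))
  cat(sprintf("  class mix: %s\n",
              paste(sprintf("%s %.1f%%", names(x$class_mix), 100 * x$class_mix),
                    collapse = ", ")))
  top <- x$taxa[order(-x$taxa$rel_abundance), ][seq_len(min(3, nrow(x$taxa))), ]
  cat("  dominant: ",
      paste(sprintf("%s (%s, %.1f%%)", top$genus, top$family,
                    100 * top$rel_abundance), collapse = "; "), "\n", sep = "")
  invisible(x)
}

taxon_lineage_strings <- function(taxa) {
  lineage_collapse(taxa$phylum, taxa$class, taxa$order, taxa$family, taxa$genus)
}

transcript_lineage_strings <- function(tr) {
  lineage_collapse(tr$category, tr$pathway, tr$gene)
}
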