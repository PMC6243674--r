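test_that("relative abundance aggregates lineages against the class basis", {
  lib <- toy_library("L1_unamp", "12C-light", list(
    taxon_row("T1", lin5("GenA", family = "FamA", order = "OrdA"), 30),
    taxon_row("T2", lin5("GenB", family = "FamB", order = "OrdA"), 20),
    taxon_row("T3", lin5("GenC", family = "FamC", order = "OrdB"), 50)
  ))
  ra <- relative_abundance(lib, "taxon", "order")
  expect_equal(ra$proportion[ra$feature == "OrdA"], 0.5)
  expect_equal(sum(ra$proportion), 1, tolerance = 1e-9)
  for (lv in TAXON_LEVELS) {
    expect_equal(sum(relative_abundance(lib, "taxon", lv)$proportion), 1,
                 tolerance = 1e-9)
  }
  one <- toy_library("L1_unamp", "12C-light", list(taxon_row("T1", lin5("GenA"), 9)))
  expect_equal(relative_abundance(one, "taxon", "genus")$proportion, 1)
  expect_error(relative_abundance(one, "transcript", "gene"),
               class = "sipef_missing_class")
})

test_that("blank lineage components fall into the unclassified bucket but keep the denominator", {
  lib <- toy_library("L1_unamp", "12C-light", list(
    taxon_row("T1", lin5("GenA"), 40),
    taxon_row("T2", "PhyA;ClsA;;;", 60)  # unresolved below class level
  ))
  ra <- relative_abundance(lib, "taxon", "genus")
  expect_equal(ra$proportion[ra$feature == "unclassified"], 0.6)
  expect_equal(ra$proportion[ra$feature == "GenA"], 0.4)
  ra2 <- relative_abundance(lib, "taxon", "genus", classified_only = TRUE)
  expect_equal(ra2$proportion[ra2$feature == "GenA"], 1)
})

test_that("the enrichment factor follows its defining formula", {
  expect_equal(enrichment_factor(0.2, 0.2, 0.1, 0.1), 0)
  expect_equal(enrichment_factor(0.30, 0.10, 0.12, 0.10), 1.8)
  # negative EF: more frequent detection in the light fraction
  expect_equal(enrichment_factor(0.05, 0.10, 0.10, 0.10), -0.5)
  # zero whenever the two heavy/light ratios agree, at any scale
  for (s in c(0.01, 0.2, 0.9)) {
    expect_equal(enrichment_factor(0.3 * s, 0.1 * s, 0.6 * s, 0.2 * s), 0,
                 tolerance = 1e-12)
  }
  expect_error(enrichment_factor(0.1, 0, 0.1, 0.1), class = "sipef_division_undefined")
  expect_true(is.na(enrichment_factor(0.1, 0, 0.1, 0.1, on_zero = "na")))
  expect_error(enrichment_factor(0.1, 0.2, 0.3, 1.2), class = "sipef_invalid_argument")
})

test_that("EF is monotone in each abundance as the formula dictates", {
  base <- c(heavy13 = 0.3, light13 = 0.2, heavy12 = 0.25, light12 = 0.2)
  ef0 <- enrichment_factor(base[1], base[2], base[3], base[4])
  expect_gt(enrichment_factor(base[1] + 0.1, base[2], base[3], base[4]), ef0)
  expect_lt(enrichment_factor(base[1], base[2] + 0.1, base[3], base[4]), ef0)
  expect_lt(enrichment_factor(base[1], base[2], base[3] + 0.1, base[4]), ef0)
})

ranking_counts <- function() {
  m <- rbind(
    X = c(30, 10, 12, 10),
    Y = c(10, 10, 10, 10)
  )
  colnames(m) <- c("13C-heavy", "13C-light", "12C-heavy", "12C-light")
  m
}

test_that("ef_ranking ranks by EF with the quartet of proportions", {
  libs <- toy_pool_set(ranking_counts(), basis = 100)
  ef <- ef_ranking(libs, "taxon", "genus", min_mean_abundance = 0, pseudo = 0)
  expect_equal(ef$feature_id[1:2], c("X", "Y"))
  expect_equal(ef$ef[ef$feature_id == "X"], 1.8)
  expect_equal(ef$ef[ef$feature_id == "Y"], 0)
  expect_equal(ef$total_reads[ef$feature_id == "X"], 62)
  expect_equal(ef$mean_rel_abundance[ef$feature_id == "X"], mean(c(0.3, 0.1, 0.12, 0.1)))
  expect_equal(ef$interpretation[ef$feature_id == "X"], "labeled")
  # the filler (denominator ballast) is ranked too, with negative-or-zero EF
  expect_true(all(c("X", "Y", "Filler") %in% ef$feature_id))
})

test_that("ranking filters mirror the figure captions exactly", {
  # transcripts: >= 20 total reads keeps 20 and drops 19
  counts <- rbind(K20 = c(5, 5, 5, 5), K19 = c(5, 5, 5, 4), pad = c(80, 80, 80, 80))
  colnames(counts) <- c("12C-light", "12C-heavy", "13C-light", "13C-heavy")
  libs <- lapply(setNames(POOL_LABELS, POOL_LABELS), function(lab) {
    toy_library(paste0(lab, "_unamp"), lab, list(
      transcript_row("K20", lin3("K20"), counts["K20", lab]),
      transcript_row("K19", lin3("K19"), counts["K19", lab]),
      transcript_row("Kpad", lin3("Kpad"), counts["pad", lab])
    ))
  })
  ef <- ef_ranking(libs, "transcript", "gene", min_total_reads = 20, pseudo = 0)
  expect_true("K20" %in% ef$feature_id)
  expect_false("K19" %in% ef$feature_id)
  # taxa: > 1% mean abundance keeps 1.01% and drops exactly 1%
  m <- rbind(A = c(1, 1, 1, 1), B = c(1.04, 1, 1, 1), C = c(50, 50, 50, 50))
  colnames(m) <- POOL_LABELS
  libs2 <- toy_pool_set(m * 1, basis = 100)
  ef2 <- ef_ranking(libs2, "taxon", "genus", min_mean_abundance = 0.01, pseudo = 0)
  expect_false("A" %in% ef2$feature_id)   # exactly 1%
  expect_true("B" %in% ef2$feature_id)    # 1.01%
})

test_that("hierarchical EFs re-aggregate counts rather than averaging children", {
  m <- rbind(
    X = c(30, 10, 12, 10),   # EF 1.8
    Y = c(20, 20, 12, 20)    # EF 1 - 0.6 = 0.4
  )
  colnames(m) <- c("13C-heavy", "13C-light", "12C-heavy", "12C-light")
  lins <- c(X = lin5("GenX", family = "FamShared"),
            Y = lin5("GenY", family = "FamShared"))
  libs <- toy_pool_set(m, basis = 100, lineages = lins)
  h <- ef_hierarchy(libs, "taxon", c("family", "genus"),
                    min_mean_abundance = 0, pseudo = 0)
  ef_gen <- h$genus
  expect_equal(ef_gen$ef[ef_gen$feature_id == "GenX"], 1.8)
  expect_equal(ef_gen$ef[ef_gen$feature_id == "GenY"], 0.4)
  fam <- h$family
  # family EF from summed counts: (50/30) - (24/30)
  expect_equal(fam$ef[fam$feature_id == "FamShared"], 50 / 30 - 24 / 30,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fam$ef[fam$feature_id == "FamShared"],
                                mean(c(1.8, 0.4)))))
  # drill-down to a parent with one child gives a one-row table
  drill <- ef_ranking(libs, "taxon", "genus", parent = "FamZ",
                      min_mean_abundance = 0, pseudo = 0)
  expect_equal(drill$feature_id, "Filler")
  expect_error(ef_ranking(libs, "taxon", "genus", parent = "NoSuchFamily",
                          min_mean_abundance = 0, pseudo = 0),
               class = "sipef_missing_lineage")
})

test_that("the four-pool design is enforced", {
  libs <- toy_pool_set(ranking_counts(), basis = 100)
  expect_error(ef_ranking(libs[1:3], "taxon", "genus"),
               class = "sipef_incomplete_design")
  mixed <- libs
  mixed[["13C-heavy"]]$amplified <- TRUE
  expect_error(ef_ranking(mixed, "taxon", "genus"),
               class = "sipef_design_mixing")
})

test_that("auto pseudo-abundance keeps light-absent features finite and ranked", {
  m <- rbind(Hot = c(40, 0, 1, 1), Cold = c(10, 50, 40, 40))
  colnames(m) <- c("13C-heavy", "13C-light", "12C-heavy", "12C-light")
  libs <- toy_pool_set(m, basis = 100)
  ef <- ef_ranking(libs, "taxon", "genus", min_mean_abundance = 0, pseudo = "auto")
  hot <- ef[ef$feature_id == "Hot", ]
  expect_false(is.na(hot$ef))
  expect_gt(hot$ef, 0)
  expect_equal(attr(ef, "pseudo"), 0.01 / 2)  # half the smallest nonzero proportion
  # with pseudo = 0 the same feature is undefined, not infinite
  ef0 <- ef_ranking(libs, "taxon", "genus", min_mean_abundance = 0, pseudo = 0)
  expect_equal(ef0$interpretation[ef0$feature_id == "Hot"], "undefined")
})
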