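sim_pool_setup <- function(n_taxa = 6, n_labeled = 2, seed = 4) {
  com <- make_community(n_taxa, n_labeled, seed = seed)
  cfg <- sim_config(seed = seed)
  profs <- list(
    g12_1 = simulate_qpcr(fractionate(com, density_model(), cfg, "12C", "g12_1"), 0.2, seed),
    g12_2 = simulate_qpcr(fractionate(com, density_model(), cfg, "12C", "g12_2"), 0.2, seed)
  )
  pools <- select_pools(profs, profs, min_mass = 120, heavy_cutoff = NULL)
  list(com = com, profs = profs, pools = pools)
}

test_that("sample_reads conserves depth and carries full metadata", {
  s <- sim_pool_setup()
  lib <- sample_reads(s$pools[["12C-light"]], s$profs, s$com, depth = 5000, seed = 1)
  expect_s3_class(lib, "library_table")
  expect_equal(sum(lib$count), 5000)
  expect_true(all(lib$count > 0))
  expect_true(all(lib$class %in% c("SSU", "LSU", "mRNA", "other")))
  expect_true(all(lib$feature_kind[lib$class == "mRNA"] == "transcript"))
  expect_true(all(lengths(strsplit(lib$lineage[lib$class == "SSU"], ";")) == 5))
  expect_true(all(lengths(strsplit(lib$lineage[lib$class == "mRNA"], ";")) == 3))
  # seed determinism
  lib2 <- sample_reads(s$pools[["12C-light"]], s$profs, s$com, depth = 5000, seed = 1)
  expect_identical(lib, lib2)
})

test_that("a one-taxon community puts all SSU reads on that taxon", {
  com <- make_community(1, 0, seed = 2)
  cfg <- sim_config()
  prof <- simulate_qpcr(fractionate(com, density_model(), cfg, "12C", "g12_1"), 0, 1)
  pools <- select_pools(prof, prof, min_mass = 10, heavy_cutoff = NULL)
  lib <- sample_reads(pools[["12C-light"]], list(prof), com, depth = 2000, seed = 1)
  ssu <- lib[lib$class == "SSU", ]
  expect_equal(nrow(ssu), 1)
  expect_equal(ssu$feature_id, com$taxa$taxon_id)
})

test_that("feature counts track multinomial expectations across seeds", {
  s <- sim_pool_setup(n_taxa = 4, n_labeled = 0, seed = 8)
  pool <- s$pools[["12C-light"]]
  # expected SSU proportion of the most abundant taxon
  mass <- Reduce(`+`, lapply(seq_len(nrow(pool$members)), function(i) {
    s$profs[[pool$members$gradient_id[i]]]$mass[, pool$members$fraction_index[i]]
  }))
  i_top <- which.max(mass)
  p <- unname(mass[i_top] / sum(mass) * s$com$class_mix[["SSU"]])
  depth <- 20000
  hits <- vapply(1:100, function(sd) {
    lib <- sample_reads(pool, s$profs, s$com, depth = depth, seed = sd)
    obs <- lib$count[lib$class == "SSU" & lib$feature_id == s$com$taxa$taxon_id[i_top]]
    abs(obs - depth * p) <= 4 * sqrt(depth * p * (1 - p))
  }, NA)
  expect_gte(mean(hits), 0.99)
})

test_that("an empty pool is rejected", {
  s <- sim_pool_setup()
  pool <- s$pools[["12C-light"]]
  profs <- lapply(s$profs, function(p) { p$mass[] <- 0; p })
  expect_error(sample_reads(pool, profs, s$com, depth = 100, seed = 1),
               class = "sipef_empty_pool")
})

test_that("amplification bias lowers expected mRNA GC and spares rRNA", {
  s <- sim_pool_setup(n_taxa = 10, n_labeled = 0, seed = 6)
  lib <- sample_reads(s$pools[["12C-light"]], s$profs, s$com, depth = 1e5, seed = 3)
  kappa <- 0.1
  # reweighting expectation computed directly from w = exp(-kappa (gc - 50))
  m <- lib[lib$class == "mRNA", ]
  w <- m$count * exp(-kappa * (m$gc_percent - 50))
  gc_expected <- sum(m$gc_percent * w) / sum(w)
  gc_before <- sum(m$gc_percent * m$count) / sum(m$count)
  expect_lt(gc_expected, gc_before)
  amp_gc <- vapply(1:30, function(sd) {
    amp <- apply_amplification_bias(lib, kappa, seed = sd)
    mean_gc_by_class(amp, "mRNA")
  }, 0)
  expect_equal(mean(amp_gc), gc_expected, tolerance = 0.01)
  # rRNA untouched, totals preserved
  amp <- apply_amplification_bias(lib, kappa, seed = 1)
  expect_identical(amp[amp$class == "SSU", c("feature_id", "count")],
                   lib[lib$class == "SSU", c("feature_id", "count")])
  expect_equal(sum(amp$count[amp$class == "mRNA"]), sum(lib$count[lib$class == "mRNA"]))
  expect_true(all(amp$amplified))
})

test_that("kappa = 0 leaves the table unchanged; single-feature mRNA is invariant", {
  s <- sim_pool_setup()
  lib <- sample_reads(s$pools[["12C-light"]], s$profs, s$com, depth = 5000, seed = 2)
  amp0 <- apply_amplification_bias(lib, 0, seed = 1)
  expect_equal(amp0$count, lib$count)
  one <- toy_library("L_unamp", "12C-light", list(
    taxon_row("T1", lin5("GenA"), 90),
    transcript_row("K1", lin3("K1"), 10, gc = 40)
  ))
  amp1 <- apply_amplification_bias(one, 0.5, seed = 1)
  expect_equal(amp1$count[amp1$class == "mRNA"], 10)
})
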