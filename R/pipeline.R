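#' Full configuration of a synthetic SIP run
#'
#' Bundles the community, density-model, simulation, pooling and EF
#' parameters of one end-to-end experiment. Every stochastic stage derives
#' its own sub-stream from `seed`, so a config determines its outputs
#' byte-for-byte.
#'
#' @param n_taxa,n_labeled community size and number of fully labeled taxa.
#' @param seed root seed.
#' @param conc Dirichlet concentration for community abundances.
#' @param class_mix read-class proportions, see [make_community()].
#' @param model a [density_model()].
#' @param alpha_scale multiplier on the labeled taxa's 13C atom fraction
#'   (1 = fully labeled; 0.5 = half labeled; 0 = control-like).
#' @param n_fractions,gradient_span,read_depth,qpcr_cv,amp_kappa,total_rna_ng,n_gradients
#'   see [sim_config()].
#' @param min_mass,heavy_cutoff,windows,mass_source see [select_pools()].
#'   When the 13C-heavy pool is infeasible above `heavy_cutoff` (no labeled
#'   RNA reaches the heavy window, as for an unlabeled control), selection
#'   is retried without the cutoff — the "heaviest fractions from which
#'   sufficient RNA could be obtained" rule — and the relaxation is recorded.
#' @param taxon_level,transcript_level lineage levels for the EF rankings.
#' @param pseudo pseudo-abundance rule for [ef_ranking()].
#' @param ef_call EF threshold above which a feature is called labeled in
#'   the run summary (the EF itself is semi-quantitative; the call needs a
#'   margin well above counting noise).
#' @return A `run_config` object.
#' @export
run_config <- function(n_taxa = 20, n_labeled = 5, seed = 1L, conc = 0.5,
                       class_mix = c(SSU = 0.35, LSU = 0.64, mRNA = 0.009,
                                     other = 0.001),
                       model = density_model(), alpha_scale = 1,
                       n_fractions = 7L, gradient_span = c(1.750, 1.855),
                       read_depth = 1e5, qpcr_cv = 0.2, amp_kappa = 0.1,
                       total_rna_ng = 1500, n_gradients = 2L,
                       min_mass = 120, heavy_cutoff = 1.815, windows = NULL,
                       mass_source = "measured",
                       taxon_level = "genus", transcript_level = "gene",
                       pseudo = "auto", ef_call = 1) {
  sim <- sim_config(seed = seed, n_fractions = n_fractions,
                    gradient_span = gradient_span, read_depth = read_depth,
                    qpcr_cv = qpcr_cv, amp_kappa = amp_kappa,
                    total_rna_ng = total_rna_ng, n_gradients = n_gradients)
  if (alpha_scale < 0 || alpha_scale > 1) abort_invalid("alpha_scale must be in [0, 1]")
  structure(
    list(n_taxa = n_taxa, n_labeled = n_labeled, seed = as.integer(seed),
         conc = conc, class_mix = class_mix, model = model,
         alpha_scale = alpha_scale, sim = sim, min_mass = min_mass,
         heavy_cutoff = heavy_cutoff, windows = windows,
         mass_source = mass_source, taxon_level = taxon_level,
         transcript_level = transcript_level, pseudo = pseudo,
         ef_call = ef_call),
    class = "run_config"
  )
}

#' Simulate one complete SIP experiment in memory
#'
#' Runs community generation, duplicate-gradient fractionation, qPCR
#' profiling, pool selection, pooled multinomial read sampling (four
#' unamplified libraries) and linear amplification (four amplified
#' libraries), mirroring an eight-library SIP sequencing design.
#'
#' @param cfg a [run_config()].
#' @return List with `community`, `profiles` (list of gradient profiles),
#'   `pools`, `libraries` (named list of 8 `library_table`s), and `truth`
#'   (taxon_id, genus, labeled flag).
#' @export
simulate_experiment <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  com <- make_community(cfg$n_taxa, cfg$n_labeled, cfg$seed, conc = cfg$conc,
                        class_mix = cfg$class_mix)

  profiles <- list()
  for (iso in c("12C", "13C")) {
    for (r in seq_len(cfg$sim$n_gradients)) {
      gid <- sprintf("g%s_%d", iso, r)
      p <- fractionate(com, cfg$model, cfg$sim, isotope = iso, gradient_id = gid,
                       alpha_scale = cfg$alpha_scale)
      profiles[[gid]] <- simulate_qpcr(p, cfg$sim$qpcr_cv, cfg$seed)
    }
  }
  iso_of <- function(iso) profiles[grepl(paste0("^g", iso), names(profiles))]

  pools <- tryCatch(
    select_pools(iso_of("12C"), iso_of("13C"), min_mass = cfg$min_mass,
                 heavy_cutoff = cfg$heavy_cutoff, windows = cfg$windows,
                 mass_source = cfg$mass_source),
    sipef_pool_infeasible = function(e) {
      if (!grepl("13C-heavy", conditionMessage(e)) || is.null(cfg$heavy_cutoff)) {
        stop(e)
      }
      # no labeled RNA reaches the heavy window: fall back to the heaviest
      # fractions from which sufficient RNA can be obtained (control logic)
      p <- select_pools(iso_of("12C"), iso_of("13C"), min_mass = cfg$min_mass,
                        heavy_cutoff = NULL, windows = cfg$windows,
                        mass_source = cfg$mass_source)
      p[["13C-heavy"]]$cutoff_relaxed <- TRUE
      p
    }
  )

  libraries <- list()
  for (lab in POOL_LABELS) {
    unamp <- sample_reads(pools[[lab]], profiles, com, depth = cfg$sim$read_depth,
                          seed = cfg$seed, amplified = FALSE)
    libraries[[unamp$library_id[1]]] <- unamp
    amp <- apply_amplification_bias(unamp, cfg$sim$amp_kappa, seed = cfg$seed)
    libraries[[amp$library_id[1]]] <- amp
  }

  truth <- data.frame(taxon_id = com$taxa$taxon_id, genus = com$taxa$genus,
                      labeled = com$taxa$alpha13C == 1 & cfg$alpha_scale > 0,
                      stringsAsFactors = FALSE)
  list(community = com, profiles = profiles, pools = pools,
       libraries = libraries, truth = truth, cfg = cfg)
}

#' Subset a library list by amplification state
#'
#' Amplified and unamplified libraries form separate analysis sets and are
#' never mixed within one EF computation.
#'
#' @param libraries named list of `library_table`s.
#' @return The libraries with `amplified` FALSE (`unamplified()`) or TRUE
#'   (`amplified()`).
#' @export
unamplified <- function(libraries) Filter(function(l) !l$amplified[1], libraries)

#' @rdname unamplified
#' @export
amplified <- function(libraries) Filter(function(l) l$amplified[1], libraries)

#' Run the full pipeline and write all stage outputs to a directory
#'
#' Executes [simulate_experiment()], then the analysis stages — read-class
#' tallies, per-class GC means, taxon- and transcript-level EF rankings
#' (unamplified set), alpha diversity — and writes one TSV per stage plus a
#' machine-readable `summary.json`. Outputs are deterministic given the
#' config: re-running writes byte-identical files. Every file carries a
#' header comment with the root seed and a config hash.
#'
#' The summary compares the simulated ground truth with the EF calls at
#' `cfg$ef_call` (genus level, unamplified set) as confusion counts.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the experiment, the analysis tables and
#'   the summary.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (missing(out_dir)) abort_invalid("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg[setdiff(names(cfg), "seed")])
  seed <- cfg$seed
  path <- function(f) file.path(out_dir, f)

  stage <- "simulate"
  res <- tryCatch({
    exp <- simulate_experiment(cfg)

    stage <- "write-simulation"
    write_community_tsv(exp$community, path("community.tsv"), seed, hash)
    write_fraction_tsv(exp$profiles, path("fractions.tsv"), seed, hash)
    write_pool_tsv(exp$pools, path("pools.tsv"), seed, hash)
    write_library_tsv(exp$libraries, path("libraries.tsv"), seed, hash)

    stage <- "tally"
    all_libs <- do.call(rbind, lapply(exp$libraries, as.data.frame))
    rownames(all_libs) <- NULL
    tallies <- class_tallies(all_libs)
    write_stamped_tsv(as.data.frame(tallies), path("class_tallies.tsv"),
                      "tally", seed, hash)
    gc_rows <- do.call(rbind, lapply(exp$libraries, function(l) {
      cls <- intersect(READ_CLASSES, unique(l$class))
      data.frame(library_id = l$library_id[1], class = cls,
                 mean_gc = vapply(cls, function(cl) mean_gc_by_class(l, cl), 0),
                 stringsAsFactors = FALSE)
    }))
    rownames(gc_rows) <- NULL
    write_stamped_tsv(gc_rows, path("gc_by_class.tsv"), "gc", seed, hash)

    stage <- "ef"
    un <- unamplified(exp$libraries)
    ef_tax <- ef_ranking(un, "taxon", cfg$taxon_level, pseudo = cfg$pseudo)
    write_ef_tsv(ef_tax, path(sprintf("ef_taxon_%s.tsv", cfg$taxon_level)), seed, hash)
    ef_tr <- tryCatch(
      ef_ranking(un, "transcript", cfg$transcript_level, pseudo = cfg$pseudo),
      sipef_error = function(e) NULL
    )
    if (!is.null(ef_tr)) {
      write_ef_tsv(ef_tr, path(sprintf("ef_transcript_%s.tsv", cfg$transcript_level)),
                   seed, hash)
    }

    stage <- "diversity"
    div <- heavy_light_diversity(un)
    write_diversity_tsv(div, path("diversity.tsv"), seed, hash)

    stage <- "summary"
    # labeled calls use the default reporting filter (> 1% mean abundance):
    # below it, a handful of reads can produce arbitrarily noisy ratios
    ef_all <- ef_ranking(un, "taxon", "genus", pseudo = cfg$pseudo)
    called <- ef_all$feature_id[!is.na(ef_all$ef) & ef_all$ef > cfg$ef_call]
    truth_genus <- exp$truth$genus[exp$truth$labeled]
    confusion <- list(
      tp = sum(truth_genus %in% called),
      fp = sum(!(called %in% truth_genus)),
      fn = sum(!(truth_genus %in% called)),
      tn = sum(!(exp$truth$genus %in% c(called, truth_genus)))
    )
    summary <- list(
      seed = seed, config_hash = hash,
      n_taxa = cfg$n_taxa, n_labeled = cfg$n_labeled,
      alpha_scale = cfg$alpha_scale,
      n_libraries = length(exp$libraries),
      heavy_cutoff_relaxed = isTRUE(exp$pools[["13C-heavy"]]$cutoff_relaxed),
      ef_call_threshold = cfg$ef_call,
      confusion = confusion,
      shannon_heavy_minus_light_13C =
        div$differences$d_shannon[div$differences$isotope == "13C"]
    )
    jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(experiment = exp, tallies = tallies, gc = gc_rows, ef_taxon = ef_tax,
         ef_transcript = ef_tr, diversity = div, summary = summary)
  }, sipef_error = function(e) {
    stop_sipef(class(e)[1], "pipeline stage '%s' failed: %s", stage,
               conditionMessage(e))
  })
  invisible(res)
}
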