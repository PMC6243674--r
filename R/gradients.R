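#' Buoyant density from weighing a known volume
#'
#' Fraction density is determined gravimetrically: a known volume of the
#' collected fraction is weighed and density = mass / volume.
#'
#' @param mass_g mass in g (> 0). Vectorized.
#' @param volume_ml volume in ml (> 0). Vectorized.
#' @return Density in g/ml.
#' @export
#' @examples
#' density_from_weighing(0.8914, 0.5)  # 1.7828 g/ml
density_from_weighing <- function(mass_g, volume_ml) {
  if (any(mass_g <= 0)) abort_invalid("mass_g must be > 0")
  if (any(volume_ml <= 0)) abort_invalid("volume_ml must be > 0")
  mass_g / volume_ml
}

#' Assemble a validated gradient profile from fraction records
#'
#' @param records data frame with columns `gradient_id`, `fraction_index`,
#'   `density` (g/ml) and at least one of `measured_copies` (qPCR signal) or
#'   `true_mass` / `rna_mass` (ng).
#' @param isotope `"12C"` or `"13C"`.
#' @return A `gradient_profile` with fractions sorted by descending density.
#'   `fraction_index` is collection order; density governs the sort.
#' @export
build_profile <- function(records, isotope = c("13C", "12C")) {
  isotope <- match.arg(isotope)
  records <- as.data.frame(records)
  need <- c("gradient_id", "fraction_index", "density")
  if (!all(need %in% names(records))) {
    abort_invalid("records must have columns %s", paste(need, collapse = ", "))
  }
  if ("rna_mass" %in% names(records) && !"true_mass" %in% names(records)) {
    records$true_mass <- records$rna_mass
  }
  if (!any(c("measured_copies", "true_mass") %in% names(records))) {
    abort_invalid("records must carry measured_copies or true_mass/rna_mass")
  }
  if (length(unique(records$gradient_id)) != 1) {
    abort_invalid("build_profile expects fractions of a single gradient; got ids: %s",
                  paste(unique(records$gradient_id), collapse = ", "))
  }
  if (nrow(records) < 2) {
    stop_sipef("sipef_insufficient_data",
               "a gradient profile needs >= 2 fractions (got %d)", nrow(records))
  }
  key <- paste(records$gradient_id, records$fraction_index)
  if (anyDuplicated(key)) {
    stop_sipef("sipef_duplicate_record",
               "duplicate fraction keys: %s", paste(key[duplicated(key)], collapse = ", "))
  }
  if (any(records$density <= 1.0)) abort_invalid("densities must exceed 1.0 g/ml")
  if ("measured_copies" %in% names(records) &&
      any(records$measured_copies < 0, na.rm = TRUE)) {
    abort_invalid("measured_copies must be >= 0")
  }
  records <- records[order(-records$density, records$fraction_index), , drop = FALSE]
  rownames(records) <- NULL
  if (!"measured_copies" %in% names(records)) records$measured_copies <- NA_real_
  structure(
    list(gradient_id = records$gradient_id[1], isotope = isotope,
         fractions = records, mass = NULL),
    class = "gradient_profile"
  )
}

#' Density window spanned by given fraction indices
#'
#' Convenience for specifying fixed pool windows in terms of the simulator's
#' fraction layout (1 = heaviest).
#'
#' @param cfg a [sim_config()].
#' @param fraction_indices integer fraction indices.
#' @return `c(low, high)` in g/ml.
#' @export
fraction_window <- function(cfg, fraction_indices) {
  fb <- fraction_boundaries(cfg)
  fb <- fb[fb$fraction_index %in% fraction_indices, , drop = FALSE]
  if (nrow(fb) == 0) abort_invalid("no such fractions")
  c(min(fb$lower), max(fb$upper))
}

pool_fraction_table <- function(profiles, mass_source) {
  if (inherits(profiles, "gradient_profile")) profiles <- list(profiles)
  fr <- do.call(rbind, lapply(profiles, function(p) {
    f <- p$fractions
    mass <- switch(mass_source,
      measured = f$measured_copies,
      true = if ("true_mass" %in% names(f)) f$true_mass else NA_real_
    )
    if (all(is.na(mass))) {
      abort_invalid("profile %s carries no usable %s mass", p$gradient_id, mass_source)
    }
    if (!all(c("lower", "upper") %in% names(f))) {
      # infer fraction bounds from midpoints between adjacent densities
      # (edges extended by the neighbouring spacing)
      d <- sort(f$density, decreasing = TRUE)
      mids <- (d[-1] + d[-length(d)]) / 2
      up <- c(d[1] + (d[1] - mids[1]), mids)
      lo <- c(mids, d[length(d)] - (mids[length(mids)] - d[length(d)]))
      ord <- match(f$density, d)
      f$upper <- up[ord]
      f$lower <- lo[ord]
    }
    data.frame(gradient_id = f$gradient_id, fraction_index = f$fraction_index,
               density = f$density, lower = f$lower, upper = f$upper,
               mass = mass, stringsAsFactors = FALSE)
  }))
  # densest first; density ties broken by fraction index (lower = heavier)
  fr[order(-fr$density, fr$fraction_index, fr$gradient_id), , drop = FALSE]
}

greedy_pool <- function(fr, from = c("heavy", "light"), min_mass, cutoff = NULL,
                        label) {
  from <- match.arg(from)
  idx <- seq_len(nrow(fr))
  if (from == "light") idx <- rev(idx)
  if (!is.null(cutoff)) idx <- idx[fr$density[idx] >= cutoff]
  if (length(idx) == 0) {
    stop_sipef("sipef_pool_infeasible",
               "pool %s: no fractions above the heavy cutoff %.4f g/ml", label, cutoff)
  }
  cum <- cumsum(fr$mass[idx])
  k <- which(cum >= min_mass)[1]
  if (is.na(k)) {
    stop_sipef("sipef_pool_infeasible",
               "pool %s: cumulative mass %.1f never reaches min_mass %.1f",
               label, max(cum), min_mass)
  }
  idx[seq_len(k)]
}

make_pool_spec <- function(label, fr, rows, min_mass = NA, cutoff = NA,
                           cutoff_relaxed = FALSE) {
  members <- fr[rows, c("gradient_id", "fraction_index", "density", "mass")]
  rownames(members) <- NULL
  structure(
    list(pool_label = label,
         density_window = c(min(fr$lower[rows]), max(fr$upper[rows])),
         members = members,
         pooled_mass = sum(members$mass),
         min_mass = min_mass, heavy_cutoff = cutoff,
         cutoff_relaxed = cutoff_relaxed),
    class = "pool_spec"
  )
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf("Pool %s: %d fractions, window %.4f-%.4f g/ml, %.0f ng%s\n",
              x$pool_label, nrow(x$members), x$density_window[1],
              x$density_window[2], x$pooled_mass,
              if (isTRUE(x$cutoff_relaxed)) " (heavy cutoff relaxed)" else ""))
  invisible(x)
}

#' Select the four sequencing pools from 12C and 13C gradient profiles
#'
#' Implements the pooling logic of a total RNA-SIP experiment that cannot
#' rely on post-gradient amplification: each pool must accumulate at least
#' `min_mass` (~120 ng) of RNA. Pools grow greedily from a gradient end
#' inward, stopping at the first fraction where the cumulative mass reaches
#' the threshold:
#' \itemize{
#'   \item `13C-heavy`: densest contiguous run of 13C fractions at or above
#'     `heavy_cutoff`;
#'   \item `13C-light`: lightest contiguous run of 13C fractions;
#'   \item `12C-heavy`: densest contiguous run of 12C fractions (the
#'     "heaviest fractions from which sufficient RNA could be obtained" —
#'     no cutoff, since unlabeled RNA never reaches the heavy window);
#'   \item `12C-light`: lightest contiguous run of 12C fractions.
#' }
#' Duplicate gradients may be passed as a list per isotope; their fractions
#' are merged and matched by density (not by index) before selection.
#' The two pools of one isotope must be disjoint.
#'
#' Alternatively, fixed per-pool density `windows` may be given (a named list
#' of `c(low, high)`); members are then all fractions whose density lies in
#' the window, and `min_mass` is not enforced. This keeps pool composition
#' comparable across experiments (e.g. across labeling levels).
#'
#' @param profile12C,profile13C a `gradient_profile` or list of replicate
#'   profiles per isotope.
#' @param min_mass minimum pooled RNA mass, ng (> 0).
#' @param heavy_cutoff minimum density (g/ml) for 13C-heavy membership;
#'   `NULL` disables the cutoff.
#' @param windows optional named list of fixed density windows, names among
#'   `POOL_LABELS`.
#' @param mass_source `"measured"` (qPCR signal; default) or `"true"`.
#' @return Named list of four `pool_spec` objects.
#' @export
select_pools <- function(profile12C, profile13C, min_mass = 120,
                         heavy_cutoff = 1.815, windows = NULL,
                         mass_source = c("measured", "true")) {
  mass_source <- match.arg(mass_source)
  if (is.null(windows) && !(min_mass > 0)) abort_invalid("min_mass must be > 0")
  fr12 <- pool_fraction_table(profile12C, mass_source)
  fr13 <- pool_fraction_table(profile13C, mass_source)

  if (!is.null(windows)) {
    if (!all(names(windows) %in% POOL_LABELS)) {
      abort_invalid("window names must be among: %s", paste(POOL_LABELS, collapse = ", "))
    }
    pools <- lapply(POOL_LABELS, function(lab) {
      w <- windows[[lab]]
      if (is.null(w)) abort_invalid("missing window for pool %s", lab)
      if (w[1] >= w[2]) abort_invalid("pool %s window must have low < high", lab)
      fr <- if (startsWith(lab, "12C")) fr12 else fr13
      rows <- which(fr$density >= w[1] & fr$density <= w[2])
      if (length(rows) == 0) {
        stop_sipef("sipef_pool_infeasible",
                   "pool %s: no fractions inside window [%.4f, %.4f]", lab, w[1], w[2])
      }
      make_pool_spec(lab, fr, rows)
    })
    names(pools) <- POOL_LABELS
    return(pools)
  }

  h13 <- greedy_pool(fr13, "heavy", min_mass, heavy_cutoff, "13C-heavy")
  l13 <- greedy_pool(fr13, "light", min_mass, NULL, "13C-light")
  h12 <- greedy_pool(fr12, "heavy", min_mass, NULL, "12C-heavy")
  l12 <- greedy_pool(fr12, "light", min_mass, NULL, "12C-light")
  if (length(intersect(h13, l13))) {
    stop_sipef("sipef_pool_infeasible",
               "pool 13C-light: overlaps 13C-heavy; gradient cannot satisfy min_mass disjointly")
  }
  if (length(intersect(h12, l12))) {
    stop_sipef("sipef_pool_infeasible",
               "pool 12C-light: overlaps 12C-heavy; gradient cannot satisfy min_mass disjointly")
  }
  pools <- list(
    `12C-light` = make_pool_spec("12C-light", fr12, l12, min_mass),
    `12C-heavy` = make_pool_spec("12C-heavy", fr12, h12, min_mass),
    `13C-light` = make_pool_spec("13C-light", fr13, l13, min_mass),
    `13C-heavy` = make_pool_spec("13C-heavy", fr13, h13, min_mass,
                                 cutoff = if (is.null(heavy_cutoff)) NA else heavy_cutoff)
  )
  pools
}
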