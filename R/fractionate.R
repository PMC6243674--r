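#' Simulation settings for a synthetic SIP experiment
#'
#' @param seed root seed; every stochastic stage derives its own sub-stream
#'   from it (see [derive_seed()]).
#' @param n_fractions fractions collected per gradient (>= 2); 7 is the
#'   standard for 5-ml CsTFA tubes.
#' @param gradient_span density range `(low, high)` in g/ml covered by the
#'   collected fractions. The default 1.750-1.855 covers both the unlabeled
#'   and fully labeled band positions with >= 3 sigma to spare.
#' @param read_depth reads per sequenced library. Real libraries run to tens
#'   of millions; the default 1e5 preserves the same relative-abundance
#'   structure at desk scale.
#' @param qpcr_cv coefficient of variation of the multiplicative lognormal
#'   qPCR quantification noise (>= 0).
#' @param amp_kappa GC-bias strength of linear amplification, per GC
#'   percentage point; the default 0.1 yields an expected mRNA GC reduction
#'   of about 2% under the default transcript GC spread.
#' @param total_rna_ng total RNA loaded per gradient, ng.
#' @param n_gradients duplicate gradients per isotope, pooled before read
#'   sampling.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_fractions = 7L,
                       gradient_span = c(1.750, 1.855),
                       read_depth = 1e5, qpcr_cv = 0.2, amp_kappa = 0.1,
                       total_rna_ng = 1500, n_gradients = 2L) {
  if (n_fractions < 2) abort_invalid("n_fractions must be >= 2")
  if (read_depth < 1) abort_invalid("read_depth must be >= 1")
  if (qpcr_cv < 0) abort_invalid("qpcr_cv must be >= 0")
  if (amp_kappa < 0) abort_invalid("amp_kappa must be >= 0")
  if (length(gradient_span) != 2 || gradient_span[1] >= gradient_span[2]) {
    abort_invalid("gradient_span must be (low, high) with low < high")
  }
  structure(
    list(seed = as.integer(seed), n_fractions = as.integer(n_fractions),
         gradient_span = as.numeric(gradient_span),
         read_depth = as.integer(read_depth), qpcr_cv = qpcr_cv,
         amp_kappa = amp_kappa, total_rna_ng = total_rna_ng,
         n_gradients = as.integer(n_gradients)),
    class = "sim_config"
  )
}

fraction_boundaries <- function(cfg) {
  # heaviest fraction first (SIP fractions are collected densest-first)
  b <- seq(cfg$gradient_span[2], cfg$gradient_span[1], length.out = cfg$n_fractions + 1)
  data.frame(fraction_index = seq_len(cfg$n_fractions),
             upper = b[-length(b)], lower = b[-1])
}

#' Distribute a community's RNA across buoyant-density fractions
#'
#' Each taxon's RNA bands as a Gaussian centred on its [mean_density()]
#' (which depends on its 13C atom fraction and GC content) with standard
#' deviation `model$sigma`. The mass falling in each fraction is the Gaussian
#' integral over that fraction's density interval, renormalized over the
#' gradient span so the loaded mass is conserved (bands are truncated at the
#' span edges, not lost). Fractions are ordered heaviest first
#' (`fraction_index` 1 = densest).
#'
#' For a `"12C"` gradient the control incubation is emulated by setting every
#' taxon's atom fraction to 0; `"13C"` uses the community's labeling truth.
#'
#' @param community a [make_community()] result.
#' @param model a [density_model()].
#' @param cfg a [sim_config()].
#' @param isotope `"13C"` or `"12C"` (control: all taxa unlabeled).
#' @param gradient_id identifier for the gradient.
#' @param alpha_scale multiplier applied to the labeled taxa's atom fraction
#'   (partial labeling experiments); default 1.
#' @return A `gradient_profile`: `fractions` data frame (fraction_index,
#'   density midpoint, lower/upper bounds, true_mass, measured_copies = NA
#'   until [simulate_qpcr()]) plus the per-taxon mass matrix in `$mass`
#'   (taxa x fractions, ng).
#' @export
fractionate <- function(community, model = density_model(), cfg = sim_config(),
                        isotope = c("13C", "12C"), gradient_id = NULL,
                        alpha_scale = 1) {
  stopifnot(inherits(community, "sip_community"), inherits(cfg, "sim_config"))
  isotope <- match.arg(isotope)
  if (is.null(gradient_id)) gradient_id <- paste0("g", isotope)
  span <- cfg$gradient_span
  if (span[1] >= span[2]) abort_invalid("degenerate gradient span")

  alpha <- if (isotope == "12C") rep(0, nrow(community$taxa)) else
    community$taxa$alpha13C * alpha_scale
  mu <- mean_density(community$taxa$gc_percent, alpha, model)
  if (any(mu - 3 * model$sigma < span[1] | mu + 3 * model$sigma > span[2])) {
    warning("gradient span does not cover all band means +/- 3 sigma; ",
            "edge bands will be truncated and renormalized")
  }

  fb <- fraction_boundaries(cfg)
  total <- stats::pnorm(span[2], mu, model$sigma) - stats::pnorm(span[1], mu, model$sigma)
  mass <- vapply(seq_len(nrow(fb)), function(f) {
    p <- stats::pnorm(fb$upper[f], mu, model$sigma) - stats::pnorm(fb$lower[f], mu, model$sigma)
    community$taxa$rel_abundance * cfg$total_rna_ng * p / total
  }, numeric(nrow(community$taxa)))
  mass <- matrix(mass, nrow = nrow(community$taxa),
                 dimnames = list(community$taxa$taxon_id, NULL))

  fractions <- data.frame(
    gradient_id = gradient_id,
    fraction_index = fb$fraction_index,
    density = (fb$upper + fb$lower) / 2,
    lower = fb$lower, upper = fb$upper,
    true_mass = colSums(mass),
    measured_copies = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(
    list(gradient_id = gradient_id, isotope = isotope,
         fractions = fractions, mass = mass),
    class = "gradient_profile"
  )
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("Gradient %s (%s): %d fractions, %.4f-%.4f g/ml, %.0f ng RNA\n",
              x$gradient_id, x$isotope, nrow(x$fractions),
              min(x$fractions$lower), max(x$fractions$upper),
              sum(x$fractions$true_mass)))
  print(x$fractions[, c("fraction_index", "density", "true_mass", "measured_copies")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Add qPCR quantification noise to a gradient profile
#'
#' RNA recovered from fractions is quantified by RT-qPCR of SSU rRNA; the
#' measurement is modeled as the true fraction mass times multiplicative
#' lognormal noise with the given coefficient of variation, mean-unbiased
#' (`E[measured] = true`). `cv = 0` returns the truth. Measured values are on
#' the same ng scale as the true masses (a calibrated assay), so pooling
#' rules expressed in ng can act on the measured signal.
#'
#' @param profile a `gradient_profile`.
#' @param cv coefficient of variation (>= 0).
#' @param seed integer seed.
#' @return The profile with `fractions$measured_copies` filled in.
#' @export
simulate_qpcr <- function(profile, cv = 0.2, seed = 1L) {
  stopifnot(inherits(profile, "gradient_profile"))
  if (cv < 0) abort_invalid("cv must be >= 0")
  truth <- profile$fractions$true_mass
  if (cv == 0) {
    profile$fractions$measured_copies <- truth
    return(profile)
  }
  sdlog <- sqrt(log(1 + cv^2))
  noise <- with_seed(derive_seed(seed, paste0("qpcr:", profile$gradient_id)),
                     stats::rlnorm(length(truth), -sdlog^2 / 2, sdlog))
  profile$fractions$measured_copies <- truth * noise
  profile
}
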