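#' Shannon diversity (natural log)
#'
#' \eqn{H = -\sum p_i \ln p_i} over features with positive counts,
#' \eqn{p_i = n_i / N}. Reported in nats; invariant to rescaling of counts,
#' zero for a single feature and maximal (\eqn{\ln S}) for uniform counts.
#'
#' @param counts nonnegative numeric vector of feature counts.
#' @return Shannon index in nats.
#' @export
#' @examples
#' shannon(c(50, 50))  # log(2)
shannon <- function(counts) {
  if (any(counts < 0)) abort_invalid("counts must be >= 0")
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop_sipef("sipef_insufficient_data", "shannon needs at least one positive count")
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Chao1 richness estimate (bias-corrected)
#'
#' \eqn{S_{chao1} = S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, with
#' \eqn{F_1, F_2} the singleton and doubleton counts. The bias-corrected
#' form is defined even without doubletons, and reduces to the observed
#' richness when there are no singletons.
#'
#' @param counts nonnegative numeric vector of feature counts.
#' @return Estimated richness (>= observed richness).
#' @export
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), 5, 9, 10, 12))  # 10 + 4*3/6 = 12
chao1 <- function(counts) {
  if (any(counts < 0)) abort_invalid("counts must be >= 0")
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop_sipef("sipef_insufficient_data", "chao1 needs at least one positive count")
  }
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Alpha diversity of the four pools and heavy-minus-light differences
#'
#' Computes Shannon, observed richness and Chao1 per library on the counts
#' of one read class (SSU rRNA features by default), then the signed
#' heavy-minus-light difference per isotope. In a SIP experiment only part
#' of the community assimilates the labeled substrate, so diversity is
#' expected to be lower in heavy than in light fractions of the 13C
#' gradient.
#'
#' @param libraries the four pool libraries (list or single data frame), as
#'   in [ef_ranking()].
#' @param class read class whose features are counted (default `"SSU"`).
#' @return List with `summaries` (one row per library: library_id,
#'   pool_label, shannon, observed_richness, chao1, depth) and
#'   `differences` (one row per isotope: shannon/observed/chao1 heavy minus
#'   light).
#' @export
heavy_light_diversity <- function(libraries, class = "SSU") {
  libs <- split_pool_libraries(libraries, "heavy_light_diversity")
  summaries <- do.call(rbind, lapply(libs, function(tab) {
    counts <- tab$count[tab$class == class]
    data.frame(library_id = tab$library_id[1], pool_label = tab$pool_label[1],
               shannon = shannon(counts), observed_richness = sum(counts > 0),
               chao1 = chao1(counts), depth = sum(counts),
               stringsAsFactors = FALSE)
  }))
  rownames(summaries) <- NULL
  diff_of <- function(iso, col) {
    summaries[[col]][summaries$pool_label == paste0(iso, "-heavy")] -
      summaries[[col]][summaries$pool_label == paste0(iso, "-light")]
  }
  differences <- data.frame(
    isotope = c("12C", "13C"),
    d_shannon = c(diff_of("12C", "shannon"), diff_of("13C", "shannon")),
    d_observed = c(diff_of("12C", "observed_richness"), diff_of("13C", "observed_richness")),
    d_chao1 = c(diff_of("12C", "chao1"), diff_of("13C", "chao1")),
    stringsAsFactors = FALSE
  )
  list(summaries = summaries, differences = differences)
}
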