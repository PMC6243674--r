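#' @keywords internal
"_PACKAGE"

# Condition helpers: every user-facing failure mode gets a classed condition
# so callers (and tests) can dispatch on it rather than match message text.
stop_sipef <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sipef_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_invalid <- function(msg, ...) stop_sipef("sipef_invalid_argument", msg, ...)

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' All randomness in the package flows from one root seed; each stochastic
#' stage (community, qPCR per gradient, read sampling per pool, amplification)
#' draws from its own sub-stream so stages can be reproduced independently.
#' The derivation is a polynomial string hash modulo 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stage character stage label, e.g. `"reads:13C-heavy"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "qpcr:13C:g1")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage), length(stage) == 1)
  m <- 2147483647
  h <- as.double(seed %% m)
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  as.integer(h)
}

# Evaluate expr under a local RNG state; the caller's RNG is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Small non-cryptographic hash of a config for provenance headers
# (stable across sessions; only used to tag output files).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% m
  sprintf("%08x", as.integer(h))
}

# lineage strings <-> label vectors; ";"-separated, fixed depth
lineage_collapse <- function(...) paste(..., sep = ";")
lineage_split <- function(x) strsplit(x, ";", fixed = TRUE)

#' Canonical pool labels of a four-library SIP design
#' @export
POOL_LABELS <- c("12C-light", "12C-heavy", "13C-light", "13C-heavy")

#' Lineage levels for taxa and transcripts
#' @export
TAXON_LEVELS <- c("phylum", "class", "order", "family", "genus")

#' @rdname TAXON_LEVELS
#' @export
TRANSCRIPT_LEVELS <- c("category", "pathway", "gene")
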