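# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one master seed per artifact, a distinct
# 31-bit stream per (purpose, index) so regenerating one object never disturbs
# the draws of another.
derive_seed <- function(seed, purpose, index = 0L) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(seed) * 48271 + h * 1299721 + index * 2654435) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= lower) abort(sprintf("`%s` must be > %s.", name, lower))
  if (!strict && x < lower) abort(sprintf("`%s` must be >= %s.", name, lower))
  invisible(x)
}

# Haldane map function: distance d in cM -> recombination fraction, assuming
# independent crossovers (no interference).
haldane_r <- function(d_cM) {
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Convert a LOD score to the odds it represents
#'
#' A LOD score is the base-10 logarithm of the likelihood ratio of a model with
#' a QTL against the null model, so a LOD of 3 corresponds to odds of 1000:1.
#'
#' @param lod Numeric vector of LOD scores.
#' @return Numeric vector of odds, `10^lod`.
#' @examples
#' lod_to_odds(3)
#' @export
lod_to_odds <- function(lod) {
  10^lod
}

#' Map interval needed for single-gene resolution
#'
#' Given an assumed gene density (genes per centimorgan), the scan interval at
#' which, on average, one gene falls per interval is simply its reciprocal.
#' At the mouse genome's approximate density of 16 genes per cM this gives
#' 1/16 = 0.0625 cM.
#'
#' @param genes_per_cM Assumed gene density, genes per centimorgan (default 16).
#' @return Interval size in cM.
#' @examples
#' single_gene_interval_cM()
#' @export
single_gene_interval_cM <- function(genes_per_cM = 16) {
  stopifnot_scalar_number(genes_per_cM, "genes_per_cM", 0, strict = TRUE)
  1 / genes_per_cM
}
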