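# Permutation-based significance: genome-wide single-locus thresholds and the
# main/heavy/light penalties derived from two-locus scans of permuted
# phenotypes. Permutations are stratified by sex (the phenotype is shuffled
# within each sex stratum), since sex enters the scan models as a covariate.

permute_within_strata <- function(y, strata, n_perm) {
  n <- length(y)
  Y <- matrix(NA_real_, n, n_perm)
  groups <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  for (m in seq_len(n_perm)) {
    idx <- integer(n)
    for (g in groups) idx[g] <- g[sample.int(length(g))]
    Y[, m] <- y[idx]
  }
  Y
}

# Genome-wide max plain-HK LOD for many phenotype columns at once.
hk_max_lod_batch <- function(Y, Xnull, X, Z, sexvec = NULL) {
  n <- nrow(Y)
  Yr <- resid_against(Xnull, Y)
  rss0 <- colSums(Yr^2)
  Xr <- resid_against(Xnull, X)
  Zr <- resid_against(Xnull, Z)
  P <- ncol(X)
  if (is.null(sexvec)) {
    Sxx <- colSums(Xr^2); Szz <- colSums(Zr^2); Sxz <- colSums(Xr * Zr)
    Sxy <- crossprod(Xr, Yr) # P x m
    Szy <- crossprod(Zr, Yr)
    det <- Sxx * Szz - Sxz^2
    det[det <= 1e-12] <- Inf # degenerate position: no explained SS
    expl <- (Szz * Sxy^2 - 2 * Sxz * Sxy * Szy + Sxx * Szy^2) / det
    rss1 <- pmax(matrix(rss0, P, ncol(Y), byrow = TRUE) - expl, 1e-12)
    lod <- n / 2 * log10(matrix(rss0, P, ncol(Y), byrow = TRUE) / rss1)
    apply(lod, 2, max)
  } else {
    XSr <- resid_against(Xnull, X * sexvec)
    ZSr <- resid_against(Xnull, Z * sexvec)
    best <- rep(0, ncol(Y))
    for (p in seq_len(P)) {
      A <- cbind(Xr[, p], Zr[, p], XSr[, p], ZSr[, p])
      S <- crossprod(A)
      B <- crossprod(A, Yr)
      expl <- tryCatch(
        colSums(B * solve(S, B)),
        error = function(e) {
          ev <- eigen(S, symmetric = TRUE)
          keep <- ev$values > max(ev$values) * 1e-10
          U <- ev$vectors[, keep, drop = FALSE]
          colSums((t(U) %*% B)^2 / ev$values[keep])
        }
      )
      rss1 <- pmax(rss0 - expl, 1e-12)
      best <- pmax(best, n / 2 * log10(rss0 / rss1))
    }
    best
  }
}

#' Genome-wide LOD significance threshold by permutation
#'
#' Permutes the phenotype against the genotypes (within sex strata when a sex
#' covariate is present), records the genome-wide maximum LOD of each permuted
#' scan, and returns the `1 - alpha` quantile (type-7, linear interpolation).
#'
#' @param probs A `geno_probs`.
#' @param phenotype Numeric phenotype vector.
#' @param sex Optional sex covariate (1 = male, 0 = female).
#' @param n_perm Number of permutations (default 1000; 100 is a reasonable
#'   desk-scale setting).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Seed controlling the permutations.
#' @param mode Covariate scheme, as in [scan_one_ehk()].
#' @param method `"ehk"` (default, matching the scan) or `"hk"` (plain
#'   Haley-Knott, considerably faster since the permuted responses share each
#'   position's design matrix).
#' @return The LOD threshold (numeric scalar) with attributes `max_lods`
#'   (per-permutation maxima), `alpha`, `n_perm`, `method`.
#' @export
permutation_threshold <- function(probs, phenotype, sex = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = 1L,
                                  mode = c("interactive", "additive", "none"),
                                  method = c("ehk", "hk")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  if (is.null(sex)) mode <- "none"
  if (mode != "none" && length(unique(sex)) < 2) {
    mode <- "none"
    sex <- NULL
  }
  y <- phenotype
  Y <- with_seed(
    derive_seed(seed, "perms"),
    permute_within_strata(y, sex, n_perm)
  )
  sexvec <- if (mode == "interactive") sex else NULL
  Xnull <- build_null_design(length(y), sex, mode)

  if (method == "hk") {
    sc <- probs_scores(probs)
    maxl <- hk_max_lod_batch(Y, Xnull, sc$X, sc$Z, sexvec)
  } else {
    maxl <- vapply(seq_len(n_perm), function(m) {
      max(scan_one_ehk(probs, Y[, m], sex, mode = mode, method = "ehk")$lod)
    }, numeric(1))
  }
  thr <- as.numeric(quantile(maxl, 1 - alpha, type = 7))
  structure(thr, max_lods = maxl, alpha = alpha, n_perm = n_perm,
            method = method)
}

# coarse position subset (indices into the flattened score matrices) used for
# two-locus permutation scans
coarse_grid_idx <- function(pos_tbl, pair_step_cM) {
  idx <- integer(0)
  for (ch in unique(pos_tbl$chr)) {
    rows <- which(pos_tbl$chr == ch)
    p <- pos_tbl$pos_cM[rows]
    targets <- seq(0, max(p), by = pair_step_cM)
    pick <- unique(vapply(targets, function(t) rows[which.min(abs(p - t))],
                          integer(1)))
    if (length(pick) < 2) {
      abort("two-locus grid too coarse: need at least 2 positions per chromosome")
    }
    idx <- c(idx, pick)
  }
  idx
}

#' Penalties for penalized multiple-QTL model selection
#'
#' For each permutation of the phenotype, a two-locus scan over a coarse grid
#' records the maximum joint full LOD (with locus-by-locus interaction), the
#' maximum additive two-locus LOD, and the maximum single-locus LOD. The
#' penalties are `T_main` = the `1 - alpha` quantile of the single-locus
#' maxima, `T_heavy` = the same quantile of (max full - max single), and
#' `T_light` = the quantile of (max full - max additive). Plain Haley-Knott
#' regression with sex as an additive covariate is used throughout (the
#' permuted responses share each pair's design, which makes 1000-permutation
#' two-locus nulls tractable).
#'
#' @param probs A `geno_probs`.
#' @param phenotype Numeric phenotype vector.
#' @param sex Optional sex covariate.
#' @param n_perm Number of permutations (1000 for the full procedure; smaller
#'   desk-scale runs are flagged in the output).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed controlling the permutations.
#' @param pair_step_cM Grid step for the two-locus scan (default 10 cM).
#' @return An object of class `penalty_set`: list with `T_main`, `T_heavy`,
#'   `T_light`, `alpha`, `n_perm`, `pair_step_cM`, `scaled_down` (TRUE when
#'   `n_perm < 1000`).
#' @export
derive_penalties <- function(probs, phenotype, sex = NULL, n_perm = 1000,
                             alpha = 0.05, seed = 1L, pair_step_cM = 10) {
  stopifnot(inherits(probs, "geno_probs"))
  if (length(probs$chromosomes) < 2) {
    abort("penalty derivation needs at least 2 chromosomes")
  }
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  y <- phenotype
  n <- length(y)
  sc <- probs_scores(probs)
  ci <- coarse_grid_idx(sc$pos, pair_step_cM)
  Xc <- sc$X[, ci, drop = FALSE]
  Zc <- sc$Z[, ci, drop = FALSE]
  pos_c <- sc$pos[ci, ]

  Xnull <- build_null_design(n, sex, if (is.null(sex)) "none" else "additive")
  Y <- with_seed(
    derive_seed(seed, "pairperms"),
    permute_within_strata(y, sex, n_perm)
  )
  Yr <- resid_against(Xnull, Y)
  rss0 <- colSums(Yr^2)
  Xr <- resid_against(Xnull, Xc)
  Zr <- resid_against(Xnull, Zc)

  # single-locus maxima on the coarse grid
  max_single <- hk_max_lod_batch(Y, Xnull, Xc, Zc, NULL)

  expl_of <- function(A) {
    S <- crossprod(A)
    B <- crossprod(A, Yr)
    tryCatch(
      colSums(B * solve(S, B)),
      error = function(e) {
        ev <- eigen(S, symmetric = TRUE)
        keep <- ev$values > max(ev$values) * 1e-10
        U <- ev$vectors[, keep, drop = FALSE]
        colSums((t(U) %*% B)^2 / ev$values[keep])
      }
    )
  }

  Pc <- ncol(Xc)
  max_full <- rep(0, n_perm)
  max_add <- rep(0, n_perm)
  for (p in seq_len(Pc - 1)) {
    x1 <- Xc[, p]; z1 <- Zc[, p]
    for (q in seq((p + 1), Pc)) {
      same_pos <- pos_c$chr[p] == pos_c$chr[q] &&
        pos_c$pos_cM[p] == pos_c$pos_cM[q]
      if (same_pos) next
      Aadd <- cbind(Xr[, p], Zr[, p], Xr[, q], Zr[, q])
      inter <- cbind(x1 * Xc[, q], x1 * Zc[, q], z1 * Xc[, q], z1 * Zc[, q])
      Afull <- cbind(Aadd, resid_against(Xnull, inter))
      ea <- expl_of(Aadd)
      ef <- expl_of(Afull)
      max_add <- pmax(max_add, n / 2 * log10(rss0 / pmax(rss0 - ea, 1e-12)))
      max_full <- pmax(max_full, n / 2 * log10(rss0 / pmax(rss0 - ef, 1e-12)))
    }
  }

  qf <- function(v) as.numeric(quantile(v, 1 - alpha, type = 7))
  structure(
    list(
      T_main = qf(max_single),
      T_heavy = qf(max_full - max_single),
      T_light = qf(max_full - max_add),
      alpha = alpha, n_perm = n_perm, pair_step_cM = pair_step_cM,
      scaled_down = n_perm < 1000,
      max_single = max_single, max_full = max_full, max_add = max_add
    ),
    class = "penalty_set"
  )
}

#' @export
print.penalty_set <- function(x, ...) {
  cat(sprintf(
    "<penalty_set> T_main=%.2f T_heavy=%.2f T_light=%.2f (alpha=%g, %d permutations%s)\n",
    x$T_main, x$T_heavy, x$T_light, x$alpha, x$n_perm,
    if (x$scaled_down) ", scaled-down run" else ""
  ))
  invisible(x)
}

#' Broad-sense heritability from F1 and F2 cohorts
#'
#' The F1 animals of an intercross are genetically identical, so their
#' phenotypic variance estimates the environmental variance; the F2 variance
#' contains both genetic and environmental components. Broad-sense
#' heritability is estimated as `H2 = 100 * max(0, 1 - Var(F1) / Var(F2))`
#' (sample variances), in percent.
#'
#' @param values_f1,values_f2 Numeric phenotype vectors for the two cohorts
#'   (at least 2 values each).
#' @return H-squared in percent (scalar).
#' @export
estimate_heritability <- function(values_f1, values_f2) {
  if (length(values_f1) < 2 || length(values_f2) < 2) {
    abort("need at least 2 values in each cohort")
  }
  v2 <- var(values_f2)
  if (v2 == 0) abort("zero F2 variance; heritability undefined")
  100 * max(0, 1 - var(values_f1) / v2)
}

#' Screen phenotypes by broad-sense heritability
#'
#' Applies [estimate_heritability()] to each shared phenotype column and flags
#' those strictly above the criterion (the screening rule is `H2 > 40`% by
#' default, so a phenotype at exactly the criterion is not selected).
#'
#' @param pheno_f1,pheno_f2 Data frames of phenotype values (one column per
#'   phenotype) for the F1 and F2 cohorts.
#' @param criterion_percent Selection criterion in percent (default 40).
#' @return A tibble: `phenotype`, `h2_percent`, `selected`.
#' @export
select_phenotypes <- function(pheno_f1, pheno_f2, criterion_percent = 40) {
  if (is.null(pheno_f1) || nrow(as.data.frame(pheno_f1)) == 0) {
    abort("missing F1 cohort: environmental variance cannot be estimated")
  }
  f1 <- as.data.frame(pheno_f1)
  f2 <- as.data.frame(pheno_f2)
  common <- intersect(names(f1), names(f2))
  common <- common[vapply(f2[common], is.numeric, logical(1))]
  if (length(common) == 0) abort("no shared numeric phenotype columns")
  purrr::map_dfr(common, function(ph) {
    h2 <- estimate_heritability(na.omit(f1[[ph]]), na.omit(f2[[ph]]))
    tibble(phenotype = ph, h2_percent = h2,
           selected = h2 > criterion_percent)
  })
}
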