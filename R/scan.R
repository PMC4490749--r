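# Single-locus genome scans by Haley-Knott regression on genotype
# probabilities. The plain method regresses the phenotype on the conditional
# expected additive/dominance scores; the extended method additionally models
# the residual-variance inflation caused by genotype uncertainty (the variance
# of the genetic predictor under the genotype posterior) via iteratively
# reweighted least squares. LOD = log10 likelihood ratio of the full model
# over the covariates-only null.

gaussian_ll <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

# Residualise the columns of M against the column span of Xb. Fast BLAS
# projection when Xb is full rank; pivoted-QR fallback for rank-deficient
# designs (which arise when a model accumulates collinear grid positions).
resid_against <- function(Xb, M) {
  coefs <- tryCatch(solve(crossprod(Xb), crossprod(Xb, M)),
                    error = function(e) NULL)
  if (is.null(coefs)) return(qr.resid(qr(Xb), M))
  M - Xb %*% coefs
}

# RSS of y on X via least squares, robust to rank deficiency
ols_rss <- function(X, y) {
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

# Solve the normal equations RSS = syy - sy' S^-1 sy with a pseudo-inverse
# fallback for singular designs.
quad_rss <- function(S, sy, syy) {
  b <- tryCatch(solve(S, sy), error = function(e) {
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-10
    e$vectors[, keep, drop = FALSE] %*%
      ((t(e$vectors[, keep, drop = FALSE]) %*% sy) / e$values[keep])
  })
  max(syy - sum(sy * b), 0)
}

# Extended Haley-Knott log-likelihood at one position.
# Xbase: base design (intercept + covariates [+ sex]); x, z: expected scores;
# vx, vz, cxz: genotype-posterior variances/covariance; sexvec: 0/1 or NULL
# (interactive mode adds x:sex and z:sex).
ehk_loglik <- function(y, Xbase, x, z, vx, vz, cxz, sexvec = NULL,
                       tol = 1e-8, maxit = 50L) {
  n <- length(y)
  interactive <- !is.null(sexvec)
  X <- if (interactive) {
    cbind(Xbase, x, z, x * sexvec, z * sexvec)
  } else {
    cbind(Xbase, x, z)
  }
  p0 <- ncol(Xbase)
  fit <- lm.fit(X, y)
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  sigma2 <- max(sum(fit$residuals^2) / n, 1e-12)

  ll_of <- function(beta, sigma2) {
    a <- beta[p0 + 1]; d <- beta[p0 + 2]
    if (interactive) {
      a <- a + beta[p0 + 3] * sexvec
      d <- d + beta[p0 + 4] * sexvec
    }
    v <- a^2 * vx + d^2 * vz + 2 * a * d * cxz
    r <- y - as.vector(X %*% beta)
    s2v <- sigma2 + v
    list(ll = -0.5 * sum(log(2 * pi * s2v) + r^2 / s2v), v = v, r = r)
  }

  cur <- ll_of(beta, sigma2)
  best <- cur$ll
  for (it in seq_len(maxit)) {
    w <- 1 / (sigma2 + cur$v)
    sw <- sqrt(w)
    fit <- lm.fit(X * sw, y * sw)
    beta_new <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    # variance update: fixed-point of the score equation given v and residuals
    r <- y - as.vector(X %*% beta_new)
    a <- beta_new[p0 + 1]; d <- beta_new[p0 + 2]
    if (interactive) {
      a <- a + beta_new[p0 + 3] * sexvec
      d <- d + beta_new[p0 + 4] * sexvec
    }
    v <- a^2 * vx + d^2 * vz + 2 * a * d * cxz
    s2 <- sigma2
    for (k in 1:3) {
      w2 <- 1 / (s2 + v)^2
      s2 <- max(sum(w2 * (r^2 - v)) / sum(w2), 1e-12)
    }
    beta <- beta_new
    sigma2 <- s2
    new <- ll_of(beta, sigma2)
    if (new$ll > best) best <- new$ll
    if (abs(new$ll - cur$ll) < tol * (abs(cur$ll) + 1e-3)) {
      cur <- new
      break
    }
    cur <- new
  }
  best
}

build_null_design <- function(n, sexvec, mode) {
  if (mode == "none" || is.null(sexvec)) {
    matrix(1, n, 1)
  } else {
    cbind(1, sexvec)
  }
}

#' Single-locus genome scan (extended Haley-Knott)
#'
#' Scans every grid position for a QTL by comparing the full model (additive
#' and dominance regressors, plus their sex interactions in interactive mode)
#' with the covariates-only null. The default `method = "ehk"` is the extended
#' Haley-Knott fit, which weights individuals by the residual variance
#' inflation due to genotype uncertainty and is robust at poorly informed
#' positions; `method = "hk"` is plain Haley-Knott regression (identical at
#' fully typed markers).
#'
#' @param probs A `geno_probs` object.
#' @param phenotype Numeric phenotype vector (one value per individual).
#' @param sex Optional integer sex covariate (1 = male, 0 = female).
#' @param mode Covariate scheme: `"interactive"` (sex enters additively and
#'   interacts with the genotype; the study default), `"additive"`, or
#'   `"none"`.
#' @param method `"ehk"` (default) or `"hk"`.
#' @return A `qtl_scan` tibble: `chr`, `pos_cM`, `is_marker`, `lod`.
#' @export
scan_one_ehk <- function(probs, phenotype, sex = NULL,
                         mode = c("interactive", "additive", "none"),
                         method = c("ehk", "hk")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(probs, "geno_probs"))
  y <- phenotype
  if (length(y) != probs$n) abort("phenotype length does not match the cross")
  if (sd(y) == 0) abort("constant phenotype; scan undefined")
  if (is.null(sex)) mode <- "none"
  if (mode != "none" && length(unique(sex)) < 2) {
    warn(paste(
      "all individuals share one sex; the sex covariate is confounded with",
      "the intercept and is dropped (additive genotype-only model)"
    ))
    mode <- "none"
    sex <- NULL
  }
  sc <- probs_scores(probs)
  n <- length(y)
  Xnull <- build_null_design(n, sex, mode)
  sexvec <- if (mode == "interactive") sex else NULL

  P <- ncol(sc$X)
  lod <- numeric(P)
  if (method == "hk") {
    lod <- hk_scan_lods(y, Xnull, sc$X, sc$Z, sexvec)
  } else {
    rss0 <- ols_rss(Xnull, y)
    ll0 <- gaussian_ll(rss0, n)
    for (p in seq_len(P)) {
      ll1 <- ehk_loglik(y, Xnull, sc$X[, p], sc$Z[, p],
                        sc$VX[, p], sc$VZ[, p], sc$CXZ[, p], sexvec)
      lod[p] <- max(ll1 - ll0, 0) / log(10)
    }
  }

  out <- dplyr::mutate(sc$pos, lod = lod)
  class(out) <- c("qtl_scan", class(out))
  attr(out, "mode") <- mode
  attr(out, "method") <- method
  attr(out, "n") <- n
  out
}

# Plain Haley-Knott LOD at all positions, vectorised. Xnull is the null
# design; X, Z are n x P expected-score matrices; sexvec non-NULL adds the
# x:sex and z:sex columns (interactive mode).
hk_scan_lods <- function(y, Xnull, X, Z, sexvec = NULL) {
  n <- length(y)
  yr <- as.vector(resid_against(Xnull, matrix(y)))
  rss0 <- sum(yr^2)
  Xr <- resid_against(Xnull, X)
  Zr <- resid_against(Xnull, Z)
  if (is.null(sexvec)) {
    Sxx <- colSums(Xr^2); Szz <- colSums(Zr^2); Sxz <- colSums(Xr * Zr)
    Sxy <- as.vector(crossprod(Xr, yr)); Szy <- as.vector(crossprod(Zr, yr))
    det <- Sxx * Szz - Sxz^2
    expl <- ifelse(
      det > 1e-12 * pmax(Sxx * Szz, 1e-300),
      (Szz * Sxy^2 - 2 * Sxz * Sxy * Szy + Sxx * Szy^2) / det,
      ifelse(Sxx > 1e-12, Sxy^2 / Sxx, 0)
    )
    rss1 <- pmax(rss0 - expl, 1e-12)
  } else {
    XSr <- resid_against(Xnull, X * sexvec)
    ZSr <- resid_against(Xnull, Z * sexvec)
    preds <- list(Xr, Zr, XSr, ZSr)
    SS <- array(0, dim = c(4, 4, ncol(X)))
    for (i in 1:4) for (j in i:4) {
      s <- colSums(preds[[i]] * preds[[j]])
      SS[i, j, ] <- s; SS[j, i, ] <- s
    }
    Sy <- vapply(preds, function(p) as.vector(crossprod(p, yr)),
                 numeric(ncol(X)))
    rss1 <- vapply(seq_len(ncol(X)), function(p) {
      max(quad_rss(SS[, , p], Sy[p, ], rss0), 1e-12)
    }, numeric(1))
  }
  pmax(n / 2 * log10(rss0 / rss1), 0)
}

#' Peak positions of a genome scan
#'
#' @param scan A `qtl_scan`.
#' @return A one-row tibble with the genome-wide maximum (ties broken toward
#'   the smallest chromosome index, then the smallest position).
#' @export
scan_peak <- function(scan) {
  ord <- order(-scan$lod, match(scan$chr, unique(scan$chr)), scan$pos_cM)
  scan[ord[1], c("chr", "pos_cM", "lod")]
}

#' 1.5-LOD support interval on one chromosome
#'
#' The conventional approximate 95% confidence region for QTL location in an
#' intercross: the smallest closed interval containing the LOD peak, extended
#' to the outermost grid positions whose LOD is within `drop` of the maximum,
#' clipped to the chromosome ends.
#'
#' @param scan A `qtl_scan` restricted to (or filtered for) one chromosome.
#' @param chr Chromosome to use when `scan` covers several.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return A one-row tibble: `chr`, `peak_cM`, `start_cM`, `end_cM`, `lod`.
#' @export
lod_support_interval <- function(scan, chr = NULL, drop = 1.5) {
  s <- if (is.null(chr)) scan else dplyr::filter(scan, .data$chr == !!chr)
  if (nrow(s) == 0) abort("no scan positions on the requested chromosome")
  s <- dplyr::arrange(s, .data$pos_cM)
  mx <- max(s$lod)
  if (mx <= 0) {
    warn("flat zero LOD curve; support interval spans the whole chromosome")
    return(tibble(
      chr = s$chr[1], peak_cM = s$pos_cM[1],
      start_cM = min(s$pos_cM), end_cM = max(s$pos_cM), lod = mx
    ))
  }
  peak <- s$pos_cM[which.max(s$lod)]
  ok <- s$lod >= mx - drop
  tibble(
    chr = s$chr[1], peak_cM = peak,
    start_cM = min(s$pos_cM[ok]), end_cM = max(s$pos_cM[ok]), lod = mx
  )
}

#' Imputation-based single-locus scan
#'
#' Scans using posterior genotype draws rather than expected scores: at each
#' position the LOD is computed per imputed genotype assignment and combined
#' across draws on the likelihood scale (mean of 10^LOD). Provided as the
#' companion to the draws stored in [genotype_probabilities()]; the primary
#' scan method remains [scan_one_ehk()].
#'
#' @param probs A `geno_probs` with `n_draws > 0`.
#' @param phenotype Numeric phenotype vector.
#' @param sex Optional sex covariate (see [scan_one_ehk()]).
#' @param mode Covariate scheme.
#' @return A `qtl_scan` tibble.
#' @export
scan_one_imp <- function(probs, phenotype, sex = NULL,
                         mode = c("interactive", "additive", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(probs, "geno_probs"))
  if (is.null(probs$chromosomes[[1]]$draws)) {
    abort("no posterior draws present; rerun genotype_probabilities() with n_draws > 0")
  }
  y <- phenotype
  if (sd(y) == 0) abort("constant phenotype; scan undefined")
  if (is.null(sex)) mode <- "none"
  if (mode != "none" && length(unique(sex)) < 2) {
    warn(paste(
      "all individuals share one sex; the sex covariate is confounded with",
      "the intercept and is dropped (additive genotype-only model)"
    ))
    mode <- "none"
    sex <- NULL
  }
  n <- length(y)
  Xnull <- build_null_design(n, sex, mode)
  sexvec <- if (mode == "interactive") sex else NULL
  rss0 <- ols_rss(Xnull, y)

  rows <- purrr::imap_dfr(probs$chromosomes, function(cc, ch) {
    K <- length(cc$pos)
    nd <- dim(cc$draws)[3]
    lod <- numeric(K)
    for (t in seq_len(K)) {
      lods_d <- vapply(seq_len(nd), function(s) {
        g <- cc$draws[, t, s]
        x <- g - 1
        z <- (g == 1) * 1
        X <- if (!is.null(sexvec)) {
          cbind(Xnull, x, z, x * sexvec, z * sexvec)
        } else {
          cbind(Xnull, x, z)
        }
        rss1 <- max(ols_rss(X, y), 1e-12)
        n / 2 * log10(rss0 / rss1)
      }, numeric(1))
      # combine on the likelihood-ratio scale
      m <- max(lods_d)
      lod[t] <- m + log10(mean(10^(lods_d - m)))
    }
    tibble(chr = ch, pos_cM = cc$pos, is_marker = cc$is_marker,
           lod = pmax(lod, 0))
  })
  class(rows) <- c("qtl_scan", class(rows))
  attr(rows, "mode") <- mode
  attr(rows, "method") <- "imp"
  attr(rows, "n") <- n
  rows
}
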