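# Hidden Markov model for F2 genotype probabilities. The hidden chain per
# chromosome has states {AA, AB, BB} with stationary prior (1/4, 1/2, 1/4);
# transitions over a distance d cM come from the Haldane recombination
# fraction r applied independently to the two gametes; emissions allow a
# symmetric genotyping error rate, and missing genotypes are uninformative.

# 3x3 F2 transition matrix for recombination fraction r
f2_transition <- function(r) {
  matrix(c(
    (1 - r)^2, 2 * r * (1 - r), r^2,
    r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
    r^2, 2 * r * (1 - r), (1 - r)^2
  ), 3, 3, byrow = TRUE)
}

# emission matrix (n x 3) for observed codes (0/1/2/NA) at one position
f2_emission <- function(obs, n, error_rate) {
  E <- matrix(1, n, 3)
  typed <- !is.na(obs)
  if (any(typed)) {
    E[typed, ] <- error_rate / 2
    E[cbind(which(typed), obs[typed] + 1L)] <- 1 - error_rate
  }
  E
}

#' Genotype probabilities on a cM grid by forward-backward smoothing
#'
#' Runs the forward-backward algorithm over the F2 hidden Markov chain of each
#' chromosome, on a position grid that is the union of the marker positions
#' and a regular grid with the given step. Optionally draws whole-chromosome
#' genotype imputations from the joint posterior path distribution (backward
#' sampling), for imputation-based scanning.
#'
#' @param cross A `cross_data`.
#' @param step_cM Grid step in cM (default 2).
#' @param error_rate Genotyping error rate used in the emissions
#'   (default 1e-4); at a typed marker with `error_rate = 0` the observed
#'   genotype gets probability 1.
#' @param n_draws Number of posterior path draws per individual (default 0;
#'   the study convention is 128 when imputation is wanted).
#' @param seed Seed for the posterior draws.
#' @return An object of class `geno_probs`: per-chromosome lists with `pos`
#'   (cM grid), `is_marker`, `prob` (array n x positions x 3, each triple
#'   summing to 1) and `draws` (n x positions x n_draws integer array of
#'   0/1/2 codes, or `NULL`).
#' @export
genotype_probabilities <- function(cross, step_cM = 2, error_rate = 1e-4,
                                   n_draws = 0, seed = 1L) {
  stopifnot(inherits(cross, "cross_data"))
  stopifnot_scalar_number(step_cM, "step_cM", 0, strict = TRUE)
  stopifnot_scalar_number(error_rate, "error_rate", 0)
  validate_map(cross$map)
  n <- nrow(cross$geno)
  chrs <- unique(cross$map$chr)
  prior <- c(0.25, 0.5, 0.25)

  res <- list()
  for (ch in chrs) {
    sel <- cross$map$chr == ch
    mpos <- cross$map$pos_cM[sel]
    L <- max(mpos)
    grid <- sort(unique(c(mpos, seq(0, L, by = step_cM), L)))
    K <- length(grid)
    is_marker <- grid %in% mpos
    obs_at <- function(t) {
      if (!is_marker[t]) return(rep(NA_integer_, n))
      cross$geno[, which(sel)[match(grid[t], mpos)]]
    }

    Tm <- lapply(seq_len(K - 1), function(t) {
      f2_transition(haldane_r(grid[t + 1] - grid[t]))
    })
    Em <- lapply(seq_len(K), function(t) f2_emission(obs_at(t), n, error_rate))

    # forward (row-normalised, scaling factors not needed for posteriors)
    A <- vector("list", K)
    a <- matrix(prior, n, 3, byrow = TRUE) * Em[[1]]
    A[[1]] <- a / rowSums(a)
    if (K > 1) {
      for (t in seq_len(K - 1)) {
        a <- (A[[t]] %*% Tm[[t]]) * Em[[t + 1]]
        A[[t + 1]] <- a / rowSums(a)
      }
    }
    # backward
    B <- matrix(1, n, 3)
    post <- array(NA_real_, dim = c(n, K, 3))
    post[, K, ] <- A[[K]] * B / rowSums(A[[K]] * B)
    if (K > 1) {
      for (t in rev(seq_len(K - 1))) {
        B <- (Em[[t + 1]] * B) %*% t(Tm[[t]])
        B <- B / rowSums(B)
        p <- A[[t]] * B
        post[, t, ] <- p / rowSums(p)
      }
    }

    draws <- NULL
    if (n_draws > 0) {
      draws <- array(NA_integer_, dim = c(n, K, n_draws))
      with_seed(derive_seed(seed, paste0("draws_", ch)), {
        for (s in seq_len(n_draws)) {
          z <- integer(n)
          p <- A[[K]]
          u <- runif(n)
          z <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
          draws[, K, s] <- z - 1L
          if (K > 1) {
            for (t in rev(seq_len(K - 1))) {
              Tt <- Tm[[t]]
              M <- t(Tt)[z, , drop = FALSE] # row i = T[, z_i]
              p <- A[[t]] * M
              p <- p / rowSums(p)
              u <- runif(n)
              z <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
              draws[, t, s] <- z - 1L
            }
          }
        }
      })
    }

    res[[ch]] <- list(pos = grid, is_marker = is_marker, prob = post,
                      draws = draws)
  }

  structure(
    list(chromosomes = res, n = n, step_cM = step_cM, error_rate = error_rate,
         cache = new.env(parent = emptyenv())),
    class = "geno_probs"
  )
}

#' @export
print.geno_probs <- function(x, ...) {
  npos <- sum(purrr::map_int(x$chromosomes, ~ length(.x$pos)))
  cat(sprintf(
    "<geno_probs> %d individuals | %d chromosomes | %d grid positions (step %g cM)\n",
    x$n, length(x$chromosomes), npos, x$step_cM
  ))
  invisible(x)
}

# Flatten a geno_probs object into regression scores across the whole genome:
# positions table plus n x P matrices of E[x], E[z] and the genotype-posterior
# variances/covariance needed by extended Haley-Knott.
probs_scores <- function(probs) {
  stopifnot(inherits(probs, "geno_probs"))
  if (!is.null(probs$cache) && !is.null(probs$cache$scores)) {
    return(probs$cache$scores)
  }
  pos_tbl <- purrr::imap_dfr(probs$chromosomes, function(cc, ch) {
    tibble(chr = ch, pos_cM = cc$pos, is_marker = cc$is_marker)
  })
  Xl <- list(); Zl <- list(); VXl <- list(); VZl <- list(); CXZl <- list()
  for (ch in names(probs$chromosomes)) {
    p <- probs$chromosomes[[ch]]$prob
    pA <- p[, , 1]; pH <- p[, , 2]; pB <- p[, , 3]
    if (is.null(dim(pA))) { # single position chromosome
      pA <- matrix(pA, ncol = 1); pH <- matrix(pH, ncol = 1)
      pB <- matrix(pB, ncol = 1)
    }
    x <- pB - pA
    Xl[[ch]] <- x
    Zl[[ch]] <- pH
    VXl[[ch]] <- pB + pA - x^2
    VZl[[ch]] <- pH * (1 - pH)
    CXZl[[ch]] <- -x * pH
  }
  out <- list(
    pos = pos_tbl,
    X = do.call(cbind, Xl), Z = do.call(cbind, Zl),
    VX = do.call(cbind, VXl), VZ = do.call(cbind, VZl),
    CXZ = do.call(cbind, CXZl)
  )
  if (!is.null(probs$cache)) probs$cache$scores <- out
  out
}
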