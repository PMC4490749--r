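# Simulation of an F2 intercross between two inbred strains: genetic map,
# Haldane (no-interference) gamete walks, planted QTL with additive/dominance
# effects and epistatic interactions, a sex covariate, and an F1 cohort whose
# variance is purely environmental. Genotypes are coded 0 = AA, 1 = AB (het),
# 2 = BB, NA = missing; the additive score is x = g - 1 in {-1, 0, +1} and the
# dominance score z = 1 when heterozygous.

#' Build a synthetic genetic map
#'
#' A stand-in for a mouse microsatellite panel: `n_markers` markers distributed
#' over `n_chr` autosomes proportionally to chromosome length, evenly spaced
#' from 0 to the chromosome end. Defaults give 98 markers on 19 autosomes with
#' lengths declining from 100 to 50 cM.
#'
#' @param n_chr Number of autosomes (default 19).
#' @param n_markers Total marker count (default 98).
#' @param lengths_cM Chromosome lengths in cM (recycled/truncated to `n_chr`);
#'   default a linear decline from 100 to 50.
#' @return A tibble with columns `chr` (character), `marker`, `pos_cM`.
#' @export
sim_genetic_map <- function(n_chr = 19, n_markers = 98,
                            lengths_cM = round(seq(100, 50, length.out = n_chr))) {
  n_chr <- as.integer(n_chr)
  stopifnot(n_chr >= 1, n_markers >= 2 * n_chr)
  lengths_cM <- rep_len(lengths_cM, n_chr)
  # proportional allocation with largest remainder, at least 2 markers per chr
  raw <- n_markers * lengths_cM / sum(lengths_cM)
  m <- pmax(floor(raw), 2)
  rem <- n_markers - sum(m)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    m[ord[seq_len(rem)]] <- m[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(m, decreasing = TRUE)
    i <- 1
    while (rem < 0) {
      if (m[ord[i]] > 2) { m[ord[i]] <- m[ord[i]] - 1; rem <- rem + 1 }
      i <- i %% n_chr + 1
    }
  }
  purrr::map_dfr(seq_len(n_chr), function(ch) {
    pos <- seq(0, lengths_cM[ch], length.out = m[ch])
    tibble(
      chr = as.character(ch),
      marker = sprintf("M%02d_%02d", ch, seq_len(m[ch])),
      pos_cM = pos
    )
  })
}

validate_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("chr", "marker", "pos_cM") %in% names(map)))
  for (ch in unique(map$chr)) {
    p <- map$pos_cM[map$chr == ch]
    if (any(diff(p) <= 0)) {
      abort(sprintf("marker positions must be strictly increasing on chromosome %s", ch))
    }
    if (any(p < 0)) abort("marker positions must be non-negative")
  }
  invisible(map)
}

# One chromosome of F2 genotypes: Markov gamete walks under the Haldane map
# function over the given positions. Returns an n x length(pos) matrix of
# 0/1/2 genotype codes.
sim_chr_genotypes <- function(pos, n) {
  npos <- length(pos)
  g1 <- matrix(0L, n, npos)
  g2 <- matrix(0L, n, npos)
  g1[, 1] <- rbinom(n, 1, 0.5)
  g2[, 1] <- rbinom(n, 1, 0.5)
  if (npos > 1) {
    for (t in seq_len(npos - 1)) {
      r <- haldane_r(pos[t + 1] - pos[t])
      g1[, t + 1] <- ifelse(rbinom(n, 1, r) == 1L, 1L - g1[, t], g1[, t])
      g2[, t + 1] <- ifelse(rbinom(n, 1, r) == 1L, 1L - g2[, t], g2[, t])
    }
  }
  g1 + g2
}

#' Simulate F2 genotypes along a genetic map
#'
#' Each F2 individual is the union of two independent gametes; each gamete is a
#' Markov walk along the chromosome with recombination fraction
#' `r = (1 - exp(-2 d / 100)) / 2` between points `d` cM apart (Haldane, no
#' interference). Optionally also returns the true genotypes at extra
#' (off-marker) positions, e.g. planted QTL.
#'
#' @param map Genetic map tibble (`chr`, `marker`, `pos_cM`).
#' @param n Number of F2 individuals.
#' @param seed Integer seed.
#' @param missing_rate Fraction of marker genotypes masked as missing
#'   (default 0).
#' @param extra_positions Optional tibble (`chr`, `pos_cM`) of extra positions
#'   at which true genotypes are recorded (not masked).
#' @return A list: `geno` (n x markers integer matrix, 0/1/2/NA, columns named
#'   by marker) and `extra_geno` (n x extra positions, or `NULL`).
#' @export
simulate_f2_genotypes <- function(map, n, seed = 1L, missing_rate = 0,
                                  extra_positions = NULL) {
  validate_map(map)
  stopifnot(n >= 1)
  chrs <- unique(map$chr)
  geno <- matrix(NA_integer_, n, nrow(map),
                 dimnames = list(NULL, map$marker))
  extra_geno <- if (!is.null(extra_positions)) {
    matrix(NA_integer_, n, nrow(extra_positions))
  } else NULL

  with_seed(derive_seed(seed, "genotypes"), {
    for (ch in chrs) {
      mpos <- map$pos_cM[map$chr == ch]
      epos <- if (!is.null(extra_positions)) {
        extra_positions$pos_cM[extra_positions$chr == ch]
      } else numeric(0)
      allpos <- sort(unique(c(mpos, epos)))
      g <- sim_chr_genotypes(allpos, n)
      geno[, map$chr == ch] <- g[, match(mpos, allpos), drop = FALSE]
      if (length(epos)) {
        extra_geno[, which(extra_positions$chr == ch)] <-
          g[, match(epos, allpos), drop = FALSE]
      }
    }
    if (missing_rate > 0) {
      mask <- matrix(runif(length(geno)) < missing_rate, n, ncol(geno))
      geno[mask] <- NA_integer_
    }
  })
  list(geno = geno, extra_geno = extra_geno)
}

#' Simulate phenotypes from planted QTL
#'
#' Generates F2 phenotypes
#' `y = sum_q (a_q x_q + d_q z_q) + sum interactions + sex_effect * male + e`
#' with `x in {-1, 0, +1}` for AA/AB/BB, `z = 1` for heterozygotes, and
#' `e ~ N(0, env_sd^2)`; and F1 phenotypes carrying only the environmental
#' term (the F1 animals are genetically identical).
#'
#' @param qtl_geno Integer matrix (n x q) of true genotypes at the planted QTL
#'   positions (0/1/2), one column per row of `qtl`.
#' @param qtl Tibble with columns `a` and `d` (additive and dominance effects),
#'   one row per QTL; may be `NULL` / zero rows for a pure-noise phenotype.
#' @param interactions Optional tibble (`q1`, `q2`, `coef`) of epistatic terms
#'   `coef * x_q1 * x_q2` (indices into the rows of `qtl`).
#' @param sex Integer vector (1 = male, 0 = female) of length n.
#' @param sex_effect Additive male effect.
#' @param env_sd Environmental standard deviation (> 0).
#' @param n_f1 Number of F1 individuals.
#' @param seed Integer seed.
#' @return A list: `pheno_f2` (length n), `pheno_f1` (length `n_f1`).
#' @export
simulate_phenotypes <- function(qtl_geno, qtl, interactions = NULL, sex,
                                sex_effect = 0, env_sd = 1, n_f1 = 12,
                                seed = 1L) {
  stopifnot_scalar_number(env_sd, "env_sd", 0, strict = TRUE)
  n <- length(sex)
  g <- 0
  if (!is.null(qtl) && nrow(qtl) > 0) {
    stopifnot(ncol(qtl_geno) == nrow(qtl), nrow(qtl_geno) == n)
    x <- qtl_geno - 1
    z <- (qtl_geno == 1) * 1
    g <- as.vector(x %*% qtl$a + z %*% qtl$d)
    if (!is.null(interactions) && nrow(interactions) > 0) {
      for (r in seq_len(nrow(interactions))) {
        g <- g + interactions$coef[r] *
          x[, interactions$q1[r]] * x[, interactions$q2[r]]
      }
    }
  }
  with_seed(derive_seed(seed, "phenotypes"), {
    pheno_f2 <- g + sex_effect * sex + rnorm(n, 0, env_sd)
    pheno_f1 <- rnorm(n_f1, 0, env_sd)
  })
  list(pheno_f2 = pheno_f2, pheno_f1 = pheno_f1)
}

#' Simulate a complete F2 intercross study
#'
#' Joins the genotype and phenotype simulators into one `cross_data` object:
#' genetic map, F2 genotype matrix with optional missingness, sex covariate,
#' F2 phenotypes driven by planted QTL, and an F1 cohort carrying only
#' environmental variance. Defaults mirror an intercross cohort of 755
#' genotyped F2 animals and 12 F1 animals with a 47% male fraction.
#'
#' @param map Genetic map (default [sim_genetic_map()]).
#' @param n_f2,n_f1 Cohort sizes (defaults 755 and 12).
#' @param qtl Tibble (`chr`, `pos_cM`, `a`, `d`) of planted QTL, or `NULL`.
#' @param interactions Optional tibble (`q1`, `q2`, `coef`), indices into `qtl`.
#' @param sex_effect Additive male effect (default 0).
#' @param env_sd Environmental standard deviation (default 1).
#' @param p_male Probability an individual is male (default 0.47).
#' @param missing_rate Marker missingness (default 0.02).
#' @param seed Integer master seed.
#' @return An object of class `cross_data`: list with `map`, `geno`, `sex`
#'   (integer, 1 = male), `pheno_f2`, `pheno_f1`, `truth`.
#' @export
simulate_cross <- function(map = sim_genetic_map(), n_f2 = 755, n_f1 = 12,
                           qtl = NULL, interactions = NULL, sex_effect = 0,
                           env_sd = 1, p_male = 0.47, missing_rate = 0.02,
                           seed = 1L) {
  validate_map(map)
  if (!is.null(qtl) && nrow(qtl) > 0) {
    stopifnot(all(c("chr", "pos_cM", "a", "d") %in% names(qtl)))
    qtl$chr <- as.character(qtl$chr)
    for (r in seq_len(nrow(qtl))) {
      L <- max(map$pos_cM[map$chr == qtl$chr[r]])
      if (!qtl$chr[r] %in% map$chr || qtl$pos_cM[r] < 0 || qtl$pos_cM[r] > L) {
        abort("planted QTL positions must lie on the map")
      }
    }
  }
  sex <- with_seed(derive_seed(seed, "sex"), rbinom(n_f2, 1, p_male))
  sim <- simulate_f2_genotypes(
    map, n_f2, seed = seed, missing_rate = missing_rate,
    extra_positions = if (!is.null(qtl) && nrow(qtl)) qtl[, c("chr", "pos_cM")]
  )
  ph <- simulate_phenotypes(
    sim$extra_geno, qtl, interactions, sex,
    sex_effect = sex_effect, env_sd = env_sd, n_f1 = n_f1, seed = seed
  )
  structure(
    list(
      map = as_tibble(map),
      geno = sim$geno,
      sex = sex,
      pheno_f2 = ph$pheno_f2,
      pheno_f1 = ph$pheno_f1,
      truth = list(qtl = qtl, interactions = interactions,
                   sex_effect = sex_effect, env_sd = env_sd, seed = seed)
    ),
    class = "cross_data"
  )
}

#' @export
print.cross_data <- function(x, ...) {
  cat(sprintf(
    "<cross_data> %d F2 x %d markers on %d chromosomes | %d F1 | %d planted QTL\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$map$chr)),
    length(x$pheno_f1),
    if (is.null(x$truth$qtl)) 0L else nrow(x$truth$qtl)
  ))
  invisible(x)
}

GENO_CODES <- c("AA", "AB", "BB")

#' Write a cross in the intercross CSV dialect
#'
#' The de-facto intercross CSV format: phenotype and sex columns first, then
#' one column per marker; the second row carries the chromosome and the third
#' the cM position for marker columns (blank for phenotype/sex), followed by
#' one row per individual with genotype codes AA/AB/BB (missing blank).
#'
#' @param cross A `cross_data`.
#' @param path Output CSV path.
#' @param phenotype_name Column name for the phenotype (default `"pheno"`).
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(cross, path, phenotype_name = "pheno") {
  stopifnot(inherits(cross, "cross_data"))
  codes <- matrix(GENO_CODES[cross$geno + 1L], nrow(cross$geno))
  codes[is.na(codes)] <- ""
  header1 <- c(phenotype_name, "sex", cross$map$marker)
  header2 <- c("", "", cross$map$chr)
  header3 <- c("", "", sprintf("%.15g", cross$map$pos_cM))
  body <- cbind(
    sprintf("%.17g", cross$pheno_f2),
    ifelse(cross$sex == 1, "M", "F"),
    codes
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header1, collapse = ","), con)
  writeLines(paste(header2, collapse = ","), con)
  writeLines(paste(header3, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a cross from the intercross CSV dialect
#'
#' Inverse of [write_cross_csv()]. The F1 cohort and planted truth are not part
#' of the format and come back empty.
#'
#' @param path CSV path.
#' @return A `cross_data`.
#' @export
read_cross_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("cross CSV not found: %s", path))
  lines <- readLines(path)
  split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  h1 <- split_csv(lines[1])
  h2 <- split_csv(lines[2])
  h3 <- split_csv(lines[3])
  h2 <- c(h2, rep("", length(h1) - length(h2)))
  h3 <- c(h3, rep("", length(h1) - length(h3)))
  is_marker <- h2 != ""
  pheno_cols <- which(!is_marker & h1 != "sex")
  sex_col <- which(h1 == "sex")
  map <- tibble(
    chr = h2[is_marker],
    marker = h1[is_marker],
    pos_cM = as.numeric(h3[is_marker])
  )
  body <- do.call(rbind, lapply(lines[-(1:3)], function(l) {
    f <- split_csv(l)
    c(f, rep("", length(h1) - length(f)))
  }))
  geno <- matrix(
    match(body[, is_marker, drop = FALSE], GENO_CODES) - 1L,
    nrow = nrow(body), dimnames = list(NULL, map$marker)
  )
  structure(
    list(
      map = map,
      geno = geno,
      sex = as.integer(body[, sex_col] == "M"),
      pheno_f2 = as.numeric(body[, pheno_cols[1]]),
      pheno_f1 = numeric(0),
      truth = NULL
    ),
    class = "cross_data"
  )
}
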