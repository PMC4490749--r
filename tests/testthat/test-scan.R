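# Genome scans: ANOVA oracle at a fully informative marker, plain/extended
# agreement at typed markers, LOD non-negativity, covariate fallbacks,
# imputation scanning, and support intervals.

small_cross <- function(n = 300, a = 0.7, d = 0.2, seed = 5,
                        missing_rate = 0) {
  simulate_cross(
    map = sim_genetic_map(n_chr = 3, n_markers = 9), n_f2 = n,
    qtl = tibble::tibble(chr = "1", pos_cM = 0, a = a, d = d),
    missing_rate = missing_rate, env_sd = 1, seed = seed
  )
}

test_that("scan LOD at a fully typed marker equals the three-group ANOVA LOD", {
  cross <- small_cross()
  pr <- genotype_probabilities(cross, step_cM = 2, error_rate = 0)
  g <- cross$geno[, 1]
  y <- cross$pheno_f2
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(residuals(lm(y ~ factor(g)))^2)
  lod_anova <- length(y) / 2 * log10(rss0 / rss1)
  for (method in c("ehk", "hk")) {
    s <- scan_one_ehk(pr, y, sex = NULL, mode = "none", method = method)
    at <- which(s$chr == "1" & s$pos_cM == 0)
    expect_equal(s$lod[at], lod_anova, tolerance = 1e-6)
  }
})

test_that("plain and extended Haley-Knott agree at fully typed markers", {
  cross <- small_cross(missing_rate = 0)
  pr <- genotype_probabilities(cross, step_cM = 2, error_rate = 0)
  s_ehk <- scan_one_ehk(pr, cross$pheno_f2, cross$sex, mode = "interactive",
                        method = "ehk")
  s_hk <- scan_one_ehk(pr, cross$pheno_f2, cross$sex, mode = "interactive",
                       method = "hk")
  at_markers <- s_ehk$is_marker
  expect_lt(max(abs(s_ehk$lod[at_markers] - s_hk$lod[at_markers])), 1e-6)
})

test_that("LOD is non-negative over the whole genome", {
  cross <- simulate_cross(map = sim_genetic_map(n_chr = 4, n_markers = 12),
                          n_f2 = 120, missing_rate = 0.1, seed = 21)
  pr <- genotype_probabilities(cross, step_cM = 2)
  for (method in c("ehk", "hk")) {
    s <- scan_one_ehk(pr, cross$pheno_f2, cross$sex, method = method)
    expect_true(all(s$lod >= -1e-8))
  }
})

test_that("a planted QTL is detected near its true position", {
  cross <- simulate_cross(
    n_f2 = 755, qtl = tibble::tibble(chr = "7", pos_cM = 35, a = 1, d = 0),
    env_sd = 1, sex_effect = 0.3, seed = 13
  )
  pr <- genotype_probabilities(cross, step_cM = 2)
  s <- scan_one_ehk(pr, cross$pheno_f2, cross$sex)
  pk <- scan_peak(s)
  expect_equal(pk$chr, "7")
  expect_lte(abs(pk$pos_cM - 35), 10)
})

test_that("degenerate inputs are handled as contracted", {
  cross <- small_cross(n = 60)
  pr <- genotype_probabilities(cross, step_cM = 10)
  expect_error(scan_one_ehk(pr, rep(1, 60), cross$sex), "constant phenotype")
  expect_warning(
    scan_one_ehk(pr, cross$pheno_f2, rep(1L, 60), mode = "interactive",
                 method = "hk"),
    "dropped"
  )
})

test_that("imputation scan equals plain HK at fully typed markers", {
  cross <- small_cross(n = 120)
  pr <- genotype_probabilities(cross, step_cM = 25, error_rate = 0,
                               n_draws = 16, seed = 2)
  s_imp <- scan_one_imp(pr, cross$pheno_f2, sex = NULL, mode = "none")
  s_hk <- scan_one_ehk(pr, cross$pheno_f2, sex = NULL, mode = "none",
                       method = "hk")
  at <- s_imp$is_marker
  # all draws coincide with the observed genotype at typed markers
  expect_lt(max(abs(s_imp$lod[at] - s_hk$lod[at])), 1e-8)
})

test_that("support intervals follow the LOD-drop definition", {
  curve <- tibble::tibble(
    chr = "2", pos_cM = seq(0, 40, by = 1), is_marker = FALSE,
    lod = pmax(6 - abs(seq(0, 40, by = 1) - 20) * 1.5 / 8, 0)
  )
  class(curve) <- c("qtl_scan", class(curve))
  iv <- lod_support_interval(curve, drop = 1.5)
  expect_equal(iv$peak_cM, 20)
  expect_equal(iv$start_cM, 12)
  expect_equal(iv$end_cM, 28)

  # monotone curve is clipped at the chromosome end
  inc <- tibble::tibble(chr = "3", pos_cM = 0:30, is_marker = FALSE,
                        lod = seq(0, 6, length.out = 31))
  class(inc) <- c("qtl_scan", class(inc))
  iv2 <- lod_support_interval(inc, drop = 1.5)
  expect_equal(iv2$end_cM, 30)
  expect_equal(iv2$peak_cM, 30)

  # flat zero curve spans the chromosome with a warning
  flat <- tibble::tibble(chr = "4", pos_cM = 0:10, is_marker = FALSE, lod = 0)
  class(flat) <- c("qtl_scan", class(flat))
  expect_warning(iv3 <- lod_support_interval(flat), "whole chromosome")
  expect_equal(c(iv3$start_cM, iv3$end_cM), c(0, 10))
})

test_that("LOD-to-odds and single-gene interval conversions are exact", {
  expect_equal(lod_to_odds(3), 1000)
  expect_equal(single_gene_interval_cM(16), 0.0625)
})
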