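# Multiple-QTL models: variance attribution identities, effect recovery,
# stepwise behaviour on signal and null data, refinement contracts, tidiers.

fake_penalties <- function(T_main = 3.5, T_heavy = 5, T_light = 3) {
  structure(
    list(T_main = T_main, T_heavy = T_heavy, T_light = T_light,
         alpha = 0.05, n_perm = 0, pair_step_cM = 10, scaled_down = TRUE),
    class = "penalty_set"
  )
}

test_that("single-locus %var equals the marginal R-squared", {
  cross <- simulate_cross(
    map = sim_genetic_map(n_chr = 2, n_markers = 8), n_f2 = 400,
    qtl = tibble::tibble(chr = "1", pos_cM = 20, a = 0.8, d = 0.1),
    missing_rate = 0, seed = 17
  )
  pr <- genotype_probabilities(cross, step_cM = 2, error_rate = 0)
  mdl <- fit_qtl_model(pr, cross$pheno_f2, sex = NULL,
                       loci = tibble::tibble(chr = "1", pos_cM = 20))
  terms <- variance_explained(mdl, pr, cross$pheno_f2, sex = NULL)
  sc <- osteoqtl:::probs_scores(pr)
  j <- osteoqtl:::locus_col(sc$pos, "1", 20)
  r2 <- summary(lm(cross$pheno_f2 ~ sc$X[, j] + sc$Z[, j]))$r.squared
  expect_equal(terms$pct_var, 100 * r2, tolerance = 1e-9)
})

test_that("per-term %var of unlinked loci sums to the joint value", {
  cross <- simulate_cross(
    n_f2 = 900,
    qtl = tibble::tibble(chr = c("2", "12"), pos_cM = c(30, 20),
                         a = c(0.6, 0.6), d = c(0, 0)),
    env_sd = 1, missing_rate = 0, seed = 23
  )
  pr <- genotype_probabilities(cross, step_cM = 2)
  mdl <- fit_qtl_model(pr, cross$pheno_f2, sex = NULL,
                       loci = tibble::tibble(chr = c("2", "12"),
                                             pos_cM = c(30, 20)))
  terms <- variance_explained(mdl, pr, cross$pheno_f2, sex = NULL)
  joint <- 100 * (mdl$rss0 - mdl$rss) / sum((cross$pheno_f2 - mean(cross$pheno_f2))^2)
  expect_equal(sum(terms$pct_var), joint, tolerance = 0.5 / joint * 100)
})

test_that("planted additive effects are recovered with the right sign and size", {
  cross <- simulate_cross(
    n_f2 = 1000,
    qtl = tibble::tibble(chr = c("3", "8"), pos_cM = c(40, 10),
                         a = c(0.8, -0.5), d = c(0, 0.3)),
    env_sd = 1, missing_rate = 0, seed = 29
  )
  pr <- genotype_probabilities(cross, step_cM = 2)
  mdl <- fit_qtl_model(pr, cross$pheno_f2, cross$sex,
                       loci = cross$truth$qtl[, c("chr", "pos_cM")])
  expect_equal(mdl$loci$a, c(0.8, -0.5), tolerance = 0.15)
  expect_equal(sign(mdl$loci$a), c(1, -1))
})

test_that("stepwise search keeps real loci and returns empty models on noise", {
  pen <- fake_penalties()
  cross <- simulate_cross(
    n_f2 = 755,
    qtl = tibble::tibble(chr = c("3", "11"), pos_cM = c(40, 20),
                         a = c(0.8, 0.8), d = c(0, 0)),
    env_sd = 1, sex_effect = 0.5, seed = 11
  )
  pr <- genotype_probabilities(cross, step_cM = 2)
  mdl <- stepwise_model_search(pr, cross$pheno_f2, cross$sex, pen)
  expect_equal(sort(mdl$loci$chr), c("11", "3"))
  expect_lte(abs(mdl$loci$pos_cM[mdl$loci$chr == "3"] - 40), 15)
  expect_gt(mdl$plod, 0)

  null_cross <- simulate_cross(n_f2 = 400, qtl = NULL, seed = 37)
  pr0 <- genotype_probabilities(null_cross, step_cM = 4)
  m0 <- stepwise_model_search(pr0, null_cross$pheno_f2, null_cross$sex, pen,
                              max_qtl = 4)
  expect_equal(nrow(m0$loci), 0)
  expect_equal(glance(m0)$plod, 0)
})

test_that("a strong epistatic pair keeps its interaction term", {
  pen <- fake_penalties()
  cross <- simulate_cross(
    n_f2 = 755,
    qtl = tibble::tibble(chr = c("2", "9"), pos_cM = c(30, 30),
                         a = c(0.3, 0.3), d = c(0, 0)),
    interactions = tibble::tibble(q1 = 1L, q2 = 2L, coef = 1.2),
    env_sd = 1, seed = 8
  )
  pr <- genotype_probabilities(cross, step_cM = 2)
  mdl <- stepwise_model_search(pr, cross$pheno_f2, cross$sex, pen)
  expect_gte(nrow(mdl$interactions), 1)
  expect_setequal(unique(mdl$loci$chr), c("2", "9"))
})

test_that("refinement never decreases the model LOD and is near-idempotent", {
  cross <- simulate_cross(
    n_f2 = 500, qtl = tibble::tibble(chr = "5", pos_cM = 33.3, a = 0.9, d = 0),
    env_sd = 1, seed = 41
  )
  pr <- genotype_probabilities(cross, step_cM = 2)
  mdl <- fit_qtl_model(pr, cross$pheno_f2, cross$sex,
                       loci = tibble::tibble(chr = "5", pos_cM = 34),
                       penalties = fake_penalties())
  r1 <- refine_positions(mdl, cross, cross$pheno_f2, cross$sex)
  expect_gte(r1$lod + 1e-9, mdl$lod)
  r2 <- refine_positions(r1, cross, cross$pheno_f2, cross$sex)
  expect_lte(abs(r2$loci$pos_cM - r1$loci$pos_cM), 0.1)
  expect_gte(r2$lod + 1e-9, r1$lod)
  # refined position sits at the argmax of its own fine curve
  curve <- r1$refinement
  expect_equal(r1$loci$pos_cM, curve$pos_cM[which.max(curve$lod)])
})

test_that("tidy and glance summarise models in broom shape", {
  cross <- simulate_cross(
    n_f2 = 300, qtl = tibble::tibble(chr = "1", pos_cM = 50, a = 1, d = 0),
    env_sd = 1, seed = 2
  )
  pr <- genotype_probabilities(cross, step_cM = 5)
  mdl <- stepwise_model_search(pr, cross$pheno_f2, cross$sex,
                               fake_penalties(), max_qtl = 3)
  td <- tidy(mdl)
  expect_true(all(c("term", "chr", "pos_cM", "a", "d", "pct_var", "lod_drop")
                  %in% names(td)))
  gl <- glance(mdl)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_loci, nrow(mdl$loci))
  expect_true(gl$lod >= gl$plod)
})

test_that("variance attribution rejects empty models", {
  cross <- simulate_cross(n_f2 = 100, seed = 3)
  pr <- genotype_probabilities(cross, step_cM = 10)
  mdl <- fit_qtl_model(pr, cross$pheno_f2, sex = NULL,
                       loci = tibble::tibble(chr = character(),
                                             pos_cM = numeric()))
  expect_error(variance_explained(mdl, pr, cross$pheno_f2), "empty")
})
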