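ml <- two_locus_model()

test_that("genotype classes map to the penetrance vector", {
  expect_equal(penetrance_of(TRUE, 1, ml), 1.00)
  expect_equal(penetrance_of(TRUE, 2, ml), 1.00)
  expect_equal(penetrance_of(TRUE, 0, ml), 0.09)
  expect_equal(penetrance_of(FALSE, 1, ml), 0.0008)
  expect_equal(penetrance_of(FALSE, 2, ml), 0.0032)
  expect_equal(penetrance_of(FALSE, 0, ml), 0.0002)
  expect_equal(penetrance_of(c(TRUE, FALSE), c(0, 2), ml), c(0.09, 0.0032))
  expect_error(penetrance_of(TRUE, 3, ml), "dose")
  expect_error(two_locus_model(f_S = 1.2), "penetrances")
  expect_error(two_locus_model(q_B = 0), "q_B")
})

test_that("fully observed family likelihood is the penetrance product", {
  # carrier father (dose 0) and noncarrier mother unaffected, affected
  # carrier child with one risk allele: 0.91 x 0.9998 x 1.0
  tr <- make_trio(smad6 = c("D", "N", "D"), bmp2 = c(0, 0, 1),
                  validate = FALSE)   # penetrance product ignores segregation
  expect_equal(family_likelihood(tr, ml), 0.91 * 0.9998 * 1.0, tolerance = 1e-12)
  # degenerate model: all penetrances at the phenocopy rate equals the null
  flat <- two_locus_model(5e-4, 5e-4, 5e-4, 5e-4, 5e-4)
  expect_equal(family_likelihood(tr, flat), null_likelihood(tr, 5e-4),
               tolerance = 1e-12)
  # an unaffected member in a fully penetrant class kills the likelihood
  tr2 <- make_trio(smad6 = c("D", "N", "D"), bmp2 = c(1, 0, 1),
                   affected = c(FALSE, FALSE, TRUE), validate = FALSE)
  expect_equal(family_likelihood(tr2, ml), 0)
  expect_identical(family_lod(tr2, ml), -Inf)
  expect_equal(total_lod(list(tr2), ml)$flagged, "F1")
})

test_that("null likelihood is genotype-free Bernoulli", {
  tr <- make_trio()
  expect_equal(null_likelihood(tr, 0.0005), 0.0005 * 0.9995^2, tolerance = 1e-12)
  allaff <- make_trio(affected = c(TRUE, TRUE, TRUE), smad6 = c("D", "N", "D"),
                      bmp2 = c(1, 0, 1))
  expect_equal(null_likelihood(allaff, 0.3), 0.3^3, tolerance = 1e-12)
  noaff <- make_trio(affected = c(FALSE, FALSE, FALSE))
  expect_gt(null_likelihood(noaff, 1e-9), 1 - 1e-8)
  expect_error(null_likelihood(tr, 0), "prevalence")
})

test_that("lod scores are likelihood-ratio logs and add over families", {
  tr <- make_trio(smad6 = c("D", "N", "D"), bmp2 = c(0, 0, 1), validate = FALSE)
  expect_equal(family_lod(tr, ml, prevalence = 5e-4),
               log10(0.909818 / (5e-4 * 0.9995^2)), tolerance = 1e-9)
  expect_equal(family_lod(tr, ml, prevalence = 5e-4), 3.26, tolerance = 1e-3)
  flat <- two_locus_model(5e-4, 5e-4, 5e-4, 5e-4, 5e-4)
  peds <- simulate_pedigrees(6, model = ml, seed = 3)
  for (p in peds) expect_equal(family_lod(p, flat, 5e-4), 0, tolerance = 1e-12)
  # additivity: duplicating a family doubles the total
  r1 <- total_lod(list(tr), ml)
  r2 <- total_lod(list(tr, tr), ml)
  expect_equal(r2$total_lod, 2 * r1$total_lod, tolerance = 1e-12)
  expect_equal(r2$total_lod, sum(r2$per_family_lod), tolerance = 1e-12)
  # lod <-> odds conversion: the published lod 7.37 is odds 2.3e7 : 1
  expect_equal(lod_to_odds(7.37), 2.3e7, tolerance = 0.02)
  expect_equal(odds_to_lod(lod_to_odds(7.37)), 7.37, tolerance = 1e-12)
})

test_that("ascertainment correction conditions on the proband's affection", {
  tr <- make_trio(smad6 = c("D", "N", "D"), bmp2 = c(0, 1, 1))
  raw <- family_lod(tr, ml)
  cond <- family_lod(tr, ml, condition_proband = TRUE)
  # proband penetrance is 1.0 under the model, prevalence 5e-4 under the
  # null, so conditioning removes log10(1/5e-4) from the lod
  expect_equal(cond, raw - log10(1 / 5e-4), tolerance = 1e-9)
})

test_that("missing-founder marginalization equals brute-force enumeration", {
  models <- list(ml, two_locus_model(0.8, 0.2, 0.01, 0.05, 0.001, q_B = 0.5,
                                     q_S = 0.05))
  # trio with an ungenotyped mother
  t1 <- make_trio(smad6 = c("D", "N", "D"), bmp2 = c(0, 1, 1))
  t1$smad6[2] <- NA; t1$bmp2[2] <- NA
  # forced transmission: child dose 2, genotyped parent dose 1
  t2 <- make_trio(smad6 = c("N", "N", "N"), bmp2 = c(1, 1, 2),
                  affected = c(FALSE, FALSE, TRUE))
  t2$smad6[2] <- NA; t2$bmp2[2] <- NA
  # three-generation, 6 members, ungenotyped grandparents (2 missing founders)
  t3 <- pedigree(data.frame(
    fam = "G", id = c("gf", "gm", "fa", "mo", "c1", "c2"),
    father = c(NA, NA, "gf", NA, "fa", "fa"),
    mother = c(NA, NA, "gm", NA, "mo", "mo"),
    sex = c(1L, 2L, 1L, 2L, 1L, 2L),
    affected = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    proband = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    smad6 = c(NA, NA, "D", "N", "D", "N"),
    bmp2 = c(NA, NA, 1L, 0L, 1L, 0L), stringsAsFactors = FALSE))
  for (m in models) for (p in list(t1, t2, t3)) {
    expect_equal(family_likelihood(p, m), oracle_likelihood(p, m),
                 tolerance = 1e-10)
  }
  # marginalization is exercised, and fully observed pedigrees refuse it
  expect_equal(marginalize_missing_parent(t1, ml), family_likelihood(t1, ml))
  expect_error(marginalize_missing_parent(make_trio(), ml), "no missing")
  # the oracle also agrees on fully observed pedigrees (penetrance product)
  full <- make_trio(smad6 = c("D", "N", "D"), bmp2 = c(1, 0, 1),
                    affected = c(TRUE, FALSE, TRUE))
  for (m in models)
    expect_equal(family_likelihood(full, m), oracle_likelihood(full, m),
                 tolerance = 1e-12)
})

test_that("degenerate allele frequencies collapse the marginalization", {
  # q_B -> 1: every completion is dose 2, equal to the fully observed case
  m1 <- two_locus_model(q_B = 1 - 1e-12)
  t_miss <- make_trio(smad6 = c("D", "N", "D"), bmp2 = c(0, 2, 1))
  t_miss$smad6[2] <- NA; t_miss$bmp2[2] <- NA
  t_obs <- make_trio(smad6 = c("D", "N", "D"), bmp2 = c(0, 2, 1))
  t_obs$smad6[2] <- "N"
  expect_equal(family_likelihood(t_miss, m1), family_likelihood(t_obs, m1),
               tolerance = 1e-3)
  # a childless ungenotyped founder contributes its prior-averaged
  # phenotype probability
  lone <- pedigree(data.frame(
    fam = "L", id = c("fa", "mo", "ch", "aunt"),
    father = c(NA, NA, "fa", NA), mother = c(NA, NA, "mo", NA),
    sex = c(1L, 2L, 1L, 2L), affected = c(FALSE, FALSE, TRUE, FALSE),
    proband = c(FALSE, FALSE, TRUE, FALSE),
    smad6 = c("D", "N", "D", NA), bmp2 = c(0L, 1L, 1L, NA),
    stringsAsFactors = FALSE))
  base <- pedigree(lone[1:3, ])
  hwe <- c((1 - ml$q_B)^2, 2 * ml$q_B * (1 - ml$q_B), ml$q_B^2)
  f_by_state <- penetrance_of(rep(c(TRUE, FALSE), each = 3), rep(0:2, 2), ml)
  prior <- rep(c(ml$q_S, 1 - ml$q_S), each = 3) * rep(hwe, 2)
  expect_equal(family_likelihood(lone, ml),
               family_likelihood(base, ml) * sum(prior * (1 - f_by_state)),
               tolerance = 1e-12)
})

test_that("no Mendelian-consistent completion is a structured error", {
  # child dose 2 but genotyped parent dose 0: impossible for any completion
  bad <- make_trio(smad6 = c("N", "N", "N"), bmp2 = c(0, 1, 2), validate = FALSE)
  bad$smad6[2] <- NA; bad$bmp2[2] <- NA
  bad$bmp2[1] <- 0L; bad$bmp2[3] <- 2L
  expect_error(family_likelihood(bad, ml), "consistent completion")
  # more missing founders than the cap
  t3 <- make_trio(); t3$smad6[1:2] <- NA; t3$bmp2[1:2] <- NA
  expect_error(family_likelihood(t3, ml, max_missing = 1), "max_missing")
  # missing non-founder genotypes are not marginalized
  t4 <- make_trio(); t4$smad6[3] <- NA; t4$bmp2[3] <- NA
  expect_error(family_likelihood(t4, ml), "founders only")
})

test_that("grid search recovers the generating model and is deterministic", {
  peds <- simulate_pedigrees(13, model = ml, seed = 101)
  # a grid containing only the true model returns it
  fit1 <- fit_twolocus(peds, grid = list(f_both = 1, f_S = 0.09, f_B1 = 8e-4,
                                         f_B2 = 32e-4, f_0 = 2e-4))
  expect_equal(unname(coef(fit1)), c(1, 0.09, 8e-4, 32e-4, 2e-4))
  expect_equal(fit1$total_lod, total_lod(peds, ml)$total_lod, tolerance = 1e-9)
  # consistency: a large unascertained panel pins both informative
  # parameters to within one grid step of the generating values
  big <- simulate_pedigrees(120, model = ml, ascertain = "none", seed = 101)
  fit2 <- fit_twolocus(big, grid = list(f_both = c(0.25, 0.5, 1.0),
                                        f_S = penetrance_grid(),
                                        f_B1 = 8e-4, f_B2 = 32e-4, f_0 = 2e-4))
  expect_equal(unname(coef(fit2)["f_both"]), 1.0)
  expect_gte(unname(coef(fit2)["f_S"]), 0.0512)
  expect_lte(unname(coef(fit2)["f_S"]), 0.2048)
  fit2b <- fit_twolocus(big, grid = fit2$grid)
  expect_identical(coef(fit2), coef(fit2b))
  expect_error(fit_twolocus(peds, grid = list(f_S = numeric())), "empty grid")
  expect_error(fit_twolocus(peds, grid = list(bogus = 1)), "unknown grid")
  # fit object methods
  expect_s3_class(fit2, "twolocus_fit")
  expect_equal(sum(fit2$per_family_lod), fit2$total_lod, tolerance = 1e-9)
  expect_equal(attr(logLik(fit2), "nobs"), 120)
  pr <- predict(fit2, data.frame(carrier = TRUE, dose = 0))
  expect_equal(pr$penetrance, unname(coef(fit2)["f_S"]))
})

test_that("two-locus vs single-locus comparison behaves under both truths", {
  # digenic truth: the two-locus model beats the best single-locus model,
  # and the advantage grows with kindred count
  peds26 <- simulate_pedigrees(26, model = ml, seed = 7)
  r13 <- single_locus_comparison(peds26[1:13], ml)
  r26 <- single_locus_comparison(peds26, ml)
  expect_gt(r13$ratio, 1)
  expect_gt(log10(r26$ratio), log10(r13$ratio))
  # single-locus truth: no systematic two-locus advantage (median over
  # replicate panels is within overfitting noise of ratio 1)
  m_single <- two_locus_model(f_both = 0.3, f_S = 0.3, f_B1 = 2e-4,
                              f_B2 = 2e-4, f_0 = 2e-4)
  lr <- vapply(8:12, function(s) {
    peds_s <- simulate_pedigrees(13, model = m_single, seed = s,
                                 ascertain = "affected_carrier")
    fit_s <- fit_twolocus(peds_s, grid = list(f_both = c(0.15, 0.3, 0.6, 1),
                                              f_S = c(0.15, 0.3, 0.6),
                                              f_B1 = 2e-4, f_B2 = 2e-4,
                                              f_0 = 2e-4))
    log10(single_locus_comparison(peds_s, fit_s$model,
                                  m1_grid = list(f_carrier = c(0.15, 0.3, 0.6, 1)))$ratio)
  }, numeric(1))
  expect_lt(median(lr), 1)
  expect_gt(min(lr), -0.5)     # grids differ slightly; no systematic deficit
  # identical models on both sides give ratio exactly 1
  m_flat <- two_locus_model(0.3, 0.3, 0.1, 0.1, 0.1)
  peds_s <- simulate_pedigrees(13, model = m_single, seed = 8)
  r_eq <- single_locus_comparison(peds_s, m_flat,
                                  m1_grid = list(f_carrier = 0.3,
                                                 f_noncarrier = 0.1))
  expect_equal(r_eq$ratio, 1, tolerance = 1e-9)
})
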