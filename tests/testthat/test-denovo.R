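test_that("class-level Poisson burden reproduces enrichment and both tails", {
  up <- class_poisson_test(28, 14.5)
  expect_equal(up$tail, "upper")
  expect_equal(up$enrichment, 28 / 14.5, tolerance = 1e-12)
  expect_equal(up$p.value, ppois(27, 14.5, lower.tail = FALSE), tolerance = 1e-12)
  lo <- class_poisson_test(21, 40.4)
  expect_equal(lo$tail, "lower")
  # reported depletion tail is P(X < obs), the convention reproducing the
  # published synonymous-class value
  expect_equal(lo$p.value, ppois(20, 40.4), tolerance = 1e-12)
  # inclusive option gives the conservative P(X <= obs); at obs = 0 this is
  # the point mass exp(-lambda) while the exclusive tail is empty
  expect_equal(class_poisson_test(0, 5, lower_tail = "inclusive")$p.value,
               exp(-5), tolerance = 1e-12)
  expect_equal(class_poisson_test(0, 5)$p.value, 0)
  expect_error(class_poisson_test(-1, 2), "non-negative")
  expect_error(class_poisson_test(2.5, 2), "integer")
})

test_that("upper and exclusive lower tails partition the distribution", {
  for (lam in c(0.5, 3, 14.5, 40.4)) for (obs in c(1, 3, 20, 41)) {
    up <- ppois(obs - 1, lam, lower.tail = FALSE)
    lo <- ppois(obs - 1, lam)
    expect_equal(up + lo, 1, tolerance = 1e-12)
  }
})

test_that("gene-level Poisson tests match published per-gene probabilities", {
  rt <- tiny_rate_table()
  smad6 <- gene_poisson_test(rt[1, ], observed_lof = 2, observed_mis = 1)
  expect_equal(smad6$p.value[smad6$class == "LOF"],
               ppois(1, 0.00026, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(smad6$p.value[smad6$class == "LOF"], 3.38e-8, tolerance = 0.02)
  expect_equal(smad6$p.value[smad6$class == "missense"],
               ppois(0, 0.0046, lower.tail = FALSE), tolerance = 1e-12)
  spry <- gene_poisson_test(rt[2, ], observed_lof = 2)
  expect_equal(spry$p.value, 7.11e-7, tolerance = 0.01)
  # zero observed is never significant
  expect_equal(gene_poisson_test(rt[1, ], observed_lof = 0)$p.value, 1)
  # lambda = 0 with observations is flagged as an enrichment boundary
  rt0 <- rt[1, ]; rt0$lambda_lof <- 0
  z <- gene_poisson_test(rt0, observed_lof = 1)
  expect_equal(z$flag, "infinite_enrichment")
  expect_equal(z$p.value, 0)
})

test_that("Fisher's method combines de novo class evidence", {
  expect_equal(fishers_method(c(3.31e-8, 4.67e-3)), 3.6e-9, tolerance = 0.02)
  expect_equal(fishers_method(c(3.6e-9, 7.0e-16)), 1.4e-22, tolerance = 0.02)
  expect_equal(fishers_method(1.0), 1.0)
  expect_error(fishers_method(c(0.5, 0)), "0")
  expect_error(fishers_method(numeric(0)), "empty")
  # combining k copies of p < 1/e is monotone decreasing in k
  p <- 0.2
  combos <- sapply(1:6, function(k) fishers_method(rep(p, k)))
  expect_true(all(diff(combos) < 0))
})

test_that("multi-hit permutation matches the exact birthday oracle", {
  # exact oracle: P(no gene hit twice) for equiprobable genes
  birthday <- function(hits, genes)
    1 - prod((genes - seq_len(hits) + 1) / genes)
  p2 <- multihit_permutation(2, rep(1, 2), n_iter = 2e4, seed = 1)
  expect_equal(as.numeric(p2), 0.5, tolerance = 3 * attr(p2, "mc_se") / 0.5)
  p3 <- multihit_permutation(3, rep(1, 10), n_iter = 1e5, seed = 2)
  expect_equal(birthday(3, 10), 0.28)                  # frozen oracle value
  expect_lt(abs(as.numeric(p3) - 0.28), 3 * attr(p3, "mc_se") + 1e-9)
  # non-uniform probabilities: compare to direct closed form for 2 hits
  pr <- c(0.5, 0.3, 0.2)
  p2w <- multihit_permutation(2, pr, n_iter = 2e5, seed = 3)
  expect_equal(as.numeric(p2w), sum(pr^2), tolerance = 0.03)
  # reproducibility and degenerate input
  expect_identical(as.numeric(multihit_permutation(5, rep(1, 20), 1e4, seed = 9)),
                   as.numeric(multihit_permutation(5, rep(1, 20), 1e4, seed = 9)))
  expect_warning(p1 <- multihit_permutation(1, rep(1, 5), 100, seed = 1),
                 "fewer than 2")
  expect_equal(as.numeric(p1), 0)
})

test_that("attributable fraction and per-offspring rate are plain arithmetic", {
  expect_equal(attributable_fraction(123, 102.4, 132), 20.6 / 132, tolerance = 1e-12)
  expect_equal(attributable_fraction(100, 100, 132), 0)
  expect_equal(attributable_fraction(90, 100, 132), 0)   # clipped at zero
  expect_equal(attributable_fraction(144, 142.8, 132), 0.0091, tolerance = 1e-2)
  expect_error(attributable_fraction(10, 5, 0), "> 0")
  r <- per_offspring_rate(144, 132)
  expect_equal(r$per_offspring, 144 / 132, tolerance = 1e-12)
  expect_null(r$per_bp)
  expect_equal(per_offspring_rate(0, 10)$per_offspring, 0)
  # per-bp rate inverts to the implied callable target size
  bp <- 144 / (132 * 2 * 1.64e-8)
  expect_equal(per_offspring_rate(144, 132, callable_bp = bp)$per_bp, 1.64e-8,
               tolerance = 1e-12)
  expect_equal(bp, 3.33e7, tolerance = 0.01)
})
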