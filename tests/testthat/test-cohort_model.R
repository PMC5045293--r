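test_that("variant classification covers every consequence x damaging state", {
  # LOF consequences map to LOF regardless of damaging fields
  for (cons in c("nonsense", "frameshift", "splice_site"))
    expect_equal(classify_variant(cons), "LOF")
  expect_equal(classify_variant("synonymous"), "synonymous")
  # categorical missense calls
  expect_equal(classify_variant("missense", damaging_call = "D"), "D_mis")
  expect_equal(classify_variant("missense", damaging_call = "T"), "T_mis")
  # score-only calls use the strict threshold
  expect_equal(classify_variant("missense", damaging_score = 0.9), "D_mis")
  expect_equal(classify_variant("missense", damaging_score = 0.83357), "T_mis")
  expect_equal(classify_variant("missense", damaging_score = 0.5), "T_mis")
  # a categorical call wins over a conflicting score
  expect_equal(classify_variant("missense", damaging_call = "T",
                                damaging_score = 0.99), "T_mis")
  # missense with no evidence is an explicit error, never silently tolerated
  expect_error(classify_variant("missense"), "unclassifiable")
})

test_that("rarity filtering is strict, order-preserving and idempotent", {
  v <- tiny_variants()
  dom <- filter_rare(v, mode = "dominant")
  # 9.0e-6 and 9.4e-6 kept, 3.3e-5 and 2e-3 dropped; 0 (absent) kept
  expect_equal(dom$pop_af, c(0, 9.0e-6, 9.4e-6))
  expect_equal(dom$gene, c("SMAD6", "SMAD6", "SMAD6"))
  rec <- filter_rare(v, mode = "recessive")
  expect_equal(nrow(rec), 4)          # 2e-3 still excluded under 1e-3
  # boundary is strict: af exactly at the threshold is dropped
  v2 <- v; v2$pop_af[1] <- 2e-5
  expect_equal(nrow(filter_rare(v2, mode = "dominant")), 2)
  # idempotence
  expect_identical(as.data.frame(filter_rare(dom, mode = "dominant")),
                   as.data.frame(dom))
  # empty in, empty out
  expect_equal(nrow(filter_rare(v[0, ], mode = "dominant")), 0)
  v3 <- v; v3$pop_af[2] <- -1e-6
  expect_error(filter_rare(v3), "non-negative")
})

test_that("variant tables round-trip through TSV and validate fields", {
  v <- tiny_variants()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, f)
  v2 <- read_variant_table(f)
  expect_equal(as.data.frame(v2), as.data.frame(v))
  bad <- as.data.frame(v); bad$pop_af[1] <- 1.2
  expect_error(variant_table(bad), "pop_af")
  bad <- as.data.frame(v); bad$damaging_call[1] <- "D"  # on a frameshift
  expect_error(variant_table(bad), "missense")
})

test_that("rate and length tables validate, rescale and read from TSV", {
  rt <- tiny_rate_table()
  expect_equal(attr(rt, "cohort_size"), 132)
  r2 <- rescale_rate_table(rt, 264)
  expect_equal(r2$lambda_lof, rt$lambda_lof * 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(rt), f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_rate_table(f, 132)$lambda_mis, rt$lambda_mis)
  expect_error(rate_table(data.frame(gene = "g", lambda_lof = -1,
                                     lambda_mis = 0, lambda_syn = 0)), ">= 0")
  expect_error(gene_length_table(data.frame(gene = "g", coding_bp = 0)), "> 0")
})

test_that("rarity policy reads from YAML with defaults preserved", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("dominant_af_max: 1.0e-5", f)
  pol <- read_rarity_policy(f)
  expect_equal(pol$dominant_af_max, 1e-5)
  expect_equal(pol$damaging_score_min, 0.83357)
  expect_error(rarity_policy(dominant_af_max = 0.1, recessive_af_max = 1e-3))
})

test_that("pedigree files round-trip and report violations with line numbers", {
  peds <- list(make_trio("A"), make_trio("B", smad6 = c("N", "N", "D*"),
                                         bmp2 = c(0, 1, 1)))
  f <- withr::local_tempfile(fileext = ".ped")
  write_pedigree(peds, f)
  back <- read_pedigree(f)
  expect_length(back, 2)
  expect_equal(sum(is_founder(back[["A"]])), 2)
  # write(read(f)) reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".ped")
  write_pedigree(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # missing-genotype and de novo codes survive the round trip
  p3 <- make_trio("C"); p3$smad6[2] <- NA; p3$bmp2[2] <- NA
  write_pedigree(p3, f)
  expect_true(is.na(read_pedigree(f)[[1]]$bmp2[2]))
})

test_that("the pedigree reader rejects Mendelian-impossible trios and names the line", {
  lines <- c("F1 fa 0 0 1 1 0 N 0",
             "F1 mo 0 0 2 1 0 N 0",
             "F1 ch fa mo 1 2 1 N 2")   # dose 2 from 0/0 parents
  f <- withr::local_tempfile(fileext = ".ped")
  writeLines(lines, f)
  expect_error(read_pedigree(f), "Mendelian.*line 3")
  # carrier child of two noncarrier parents needs the de novo flag
  lines[3] <- "F1 ch fa mo 1 2 1 D 0"
  writeLines(lines, f)
  expect_error(read_pedigree(f), "de novo")
  lines[3] <- "F1 ch fa mo 1 2 1 D* 0"
  writeLines(lines, f)
  expect_silent(read_pedigree(f))
  # a named parent missing from the family is a structured error
  writeLines(c("F1 ch fa mo 1 2 1 N 0"), f)
  expect_error(read_pedigree(f), "missing father")
})

test_that("generated consistent trios pass validation, corrupted ones fail", {
  set.seed(11)
  doses <- function(d) switch(as.character(d), "0" = 0L, "1" = sample(0:1, 1), "2" = 1L)
  for (rep in 1:25) {
    dp <- sample(0:2, 2, replace = TRUE)
    child <- doses(dp[1]) + doses(dp[2])
    p <- make_trio("R", smad6 = c("N", "N", "N"), bmp2 = c(dp, child))
    expect_silent(validate_pedigree(p))
    # corrupt: push the child's dose outside the reachable set
    reach <- sort(unique(as.vector(outer(
      switch(as.character(dp[1]), "0" = 0L, "1" = 0:1, "2" = 1L),
      switch(as.character(dp[2]), "0" = 0L, "1" = 0:1, "2" = 1L), "+"))))
    bad_vals <- setdiff(0:2, reach)
    if (length(bad_vals)) {
      pb <- p; pb$bmp2[3] <- bad_vals[1]
      expect_error(validate_pedigree(pb), "Mendelian")
    }
  }
  # cyclic parent links are rejected
  cyc <- data.frame(fam = "C", id = c("a", "b"), father = c("b", "a"),
                    mother = c("b", "a"), sex = 1L, affected = FALSE,
                    proband = FALSE, smad6 = "N", bmp2 = 0L)
  expect_error(pedigree(cyc), "cyclic|one named parent|missing")
})
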