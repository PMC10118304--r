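test_that("U content by codon position counts sites and Us correctly", {
  pc <- u_content_by_position(cds_record("x", "AUGUUA"))
  expect_equal(pc$proportions, c(0.5, 1.0, 0.0))
  expect_equal(u_content_by_position(cds_record("u", "UUUUUU"))$proportions,
               c(1, 1, 1))
  expect_equal(u_content_by_position(cds_record("a", "ACGACG"))$proportions,
               c(0, 0, 0))
  # N counts as a site but not as U
  pcn <- u_content_by_position(cds_record("n", "NUGNUN"))
  expect_identical(pcn$site_counts, c(2L, 2L, 2L))
  expect_identical(pcn$u_counts, c(0L, 2L, 0L))
})

test_that("windowed U proportion SD uses non-overlapping windows and population SD", {
  # 30 Us then 30 non-U: two windows with proportions {1, 0}
  rec <- cds_record("x", paste0(strrep("U", 30), strrep("A", 30)))
  res <- windowed_u_sd(rec)
  expect_equal(res$overall, 0.5)
  expect_identical(res$n_windows, 2L)
  expect_equal(res$window_proportions, c(1, 0))
  # homogeneous sequence -> SD 0
  expect_equal(windowed_u_sd(cds_record("u", strrep("U", 90)))$overall, 0)
  # trailing remainder dropped with a warning; single window -> SD 0
  rec59 <- cds_record("y", paste0(strrep("U", 30), strrep("A", 29)))
  expect_warning(res59 <- windowed_u_sd(rec59), "window")
  expect_identical(res59$n_windows, 1L)
  expect_equal(res59$overall, 0)
  expect_error(windowed_u_sd(rec, window = 2), "window")
  expect_error(windowed_u_sd(cds_record("s", "ACGUA")), "shorter")
})

test_that("homogeneity test matches the df = 2 closed form", {
  eq <- homogeneity_test(c(10, 10, 10), c(30, 30, 30))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  skewed <- homogeneity_test(c(20, 10, 0), c(30, 30, 30))
  expect_equal(skewed$statistic, 20)
  expect_equal(skewed$p, exp(-10), tolerance = 1e-12)
  expect_equal(skewed$p, 4.54e-5, tolerance = 1e-3)
  # expected counts proportional to site totals, preserving the total
  uneven <- homogeneity_test(c(8, 3, 1), c(60, 30, 30))
  expect_equal(uneven$expected, 12 * c(60, 30, 30) / 120)
  expect_equal(sum(uneven$expected), sum(uneven$observed))
  # degenerate all-zero counts
  degen <- homogeneity_test(c(0, 0, 0), c(10, 10, 10))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
  # property: p == exp(-chi2/2) for df = 2, within 1e-10
  set.seed(11)
  for (i in 1:50) {
    sites <- sample(20:200, 3, replace = TRUE)
    u <- vapply(sites, function(s) sample(0:s, 1), 0L)
    if (sum(u) == 0) next
    res <- homogeneity_test(u, sites)
    expect_equal(res$p, exp(-res$statistic / 2), tolerance = 1e-10)
  }
})

test_that("species comparison is an uncorrected 2x2 chi-square with stars", {
  a <- cds_record("a", paste(c(rep("U", 48), rep("A", 52)), collapse = ""))
  b <- cds_record("b", paste(c(rep("U", 29), rep("A", 71)), collapse = ""))
  res <- species_vs_reference_test(a, b)
  # oracle: closed-form 2x2 chi-square n(ad - bc)^2 / product of marginals
  oracle <- 200 * (48 * 71 - 52 * 29)^2 / (100 * 100 * 77 * 123)
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 7.62, tolerance = 1e-3)
  expect_equal(res$p, 0.0058, tolerance = 1e-2)
  expect_identical(res$stars, "**")
  # identical sequences -> statistic 0, p 1
  same <- species_vs_reference_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # equal proportions at different scales -> statistic 0
  a10 <- cds_record("a10", strrep(a$seq, 10))
  expect_equal(species_vs_reference_test(a, a10)$statistic, 0)
  # symmetry
  rev <- species_vs_reference_test(b, a)
  expect_equal(rev$statistic, res$statistic)
  expect_equal(rev$p, res$p)
  # zero marginal is degenerate
  allu <- cds_record("u", "UUUU")
  expect_error(species_vs_reference_test(allu, cds_record("u2", "UUUU")),
               "degenerate")
})

test_that("composition report assembles per-record statistics with stars", {
  set.seed(5)
  recs <- list(random_cds(120, 1, c(A = .2, C = .1, G = .2, U = .5), id = "ed"),
               random_cds(120, 2, c(A = .3, C = .2, G = .3, U = .2), id = "ref"))
  rep <- composition_report(recs, reference_id = "ref")
  expect_identical(nrow(rep), 2L)
  expect_true(is.na(rep$vs_reference_p[rep$id == "ref"]))
  row <- rep[rep$id == "ed", ]
  direct <- species_vs_reference_test(recs[[1]], recs[[2]])
  expect_equal(row$vs_reference_chisq, direct$statistic)
  expect_identical(row$vs_reference_stars, direct$stars)
  expect_error(composition_report(recs, reference_id = "nope"), "reference")
})
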