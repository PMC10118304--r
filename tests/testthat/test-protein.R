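test_that("translation uses the protozoan mitochondrial code", {
  expect_identical(translate_cds(cds_record("a", "UUUUUA"))$seq, "FL")
  expect_identical(translate_cds(cds_record("b", "UGA"))$seq, "W")
  expect_identical(translate_cds(cds_record("c", "UANUUU"))$seq, "XF")
  # terminal stop dropped, internal stop rejected (table 4: UAA is a stop)
  expect_identical(translate_cds(cds_record("d", "AUGUUUUAA"))$seq, "MF")
  expect_error(translate_cds(cds_record("e", "AUGUAAUUU")), "internal stop")
  expect_identical(
    translate_cds(cds_record("e", "AUGUAAUUU"),
                  allow_internal_stops = TRUE)$seq, "MXF")
  # standard code differs at UGA
  expect_identical(translate_cds(cds_record("f", "UGAUUU"),
                                 code_table = "1",
                                 allow_internal_stops = TRUE)$seq, "XF")
  expect_identical(translate_cds(cds_record("g", "AUGUUU"))$source_cds_id, "g")
})

test_that("hydrophobic fraction excludes X from the denominator", {
  expect_equal(hydrophobic_fraction(protein_record("p", "FLSA")), 0.5)
  expect_equal(hydrophobic_fraction(protein_record("p", "FFFF")), 1.0)
  expect_equal(hydrophobic_fraction(protein_record("p", "SSSS")), 0.0)
  expect_equal(hydrophobic_fraction(protein_record("p", "FXSX")), 0.5)
  expect_error(hydrophobic_fraction(protein_record("p", "XXX")), "unknown")
})

test_that("survey ranking is dense, descending and tie-sharing", {
  prots <- list(protein_record("a", strrep("F", 10)),              # 1.0
                protein_record("b", paste0(strrep("F", 5), strrep("S", 5))),
                protein_record("c", paste0(strrep("L", 5), strrep("A", 5))))
  sr <- survey_rank(prots, queries = "b")
  expect_identical(sr$table$rank, c(1L, 2L, 2L))
  expect_identical(unname(sr$query_ranks["b"]), 2L)
  expect_equal(sr$mean, mean(c(1, .5, .5)))
  expect_equal(sr$sd, sd(c(1, .5, .5)))
  dup <- list(protein_record("a", "FL"), protein_record("a", "SS"))
  expect_error(survey_rank(dup), "duplicate")
  expect_error(survey_rank(prots[1]), "at least two")
  expect_error(survey_rank(prots, queries = "zz"), "not in the protein set")

  # an extreme outlier among a background near 0.48 +/- 0.03 ranks first,
  # several SD above the mean
  set.seed(42)
  bg <- lapply(1:400, function(i) {
    f <- min(max(rnorm(1, 0.48, 0.03), 0.05), 0.95)
    n_h <- round(200 * f)
    protein_record(sprintf("bg%03d", i),
                   paste(sample(c(rep("F", n_h), rep("S", 200 - n_h))),
                         collapse = ""))
  })
  extreme <- protein_record("query",
                            paste(sample(c(rep("L", 136), rep("S", 64))),
                                  collapse = ""))  # 0.68
  sr2 <- survey_rank(c(bg, list(extreme)), queries = "query")
  expect_identical(unname(sr2$query_ranks["query"]), 1L)
  expect_gt((0.68 - sr2$mean) / sr2$sd, 6)
})

test_that("class composition frequencies sum to one and respect the map", {
  map <- list(order = c("L", ORDER_DISORDER_CLASSES$order[
    ORDER_DISORDER_CLASSES$order != "L"]),
    disorder = ORDER_DISORDER_CLASSES$disorder,
    ambiguous = ORDER_DISORDER_CLASSES$ambiguous)
  ct <- composition_by_class(protein_record("p", "LLSS"))
  expect_equal(unname(ct$class_totals["order"]), 0.5)
  expect_equal(unname(ct$class_totals["disorder"]), 0.5)
  expect_equal(sum(ct$frequencies), 1)
  # C is order-promoting under the default map
  expect_equal(unname(composition_by_class(
    protein_record("p", "CCCC"))$class_totals["order"]), 1.0)
  expect_error(composition_by_class(protein_record("p", "LL"),
                                    classification = list()), "empty")
  expect_error(composition_by_class(protein_record("p", "LL"),
                                    classification = list(order = "L")),
               "cover")
  # invariance under shuffling
  p1 <- random_protein(80, 7)
  shuf <- protein_record("s", paste(sample(strsplit(p1$seq, "")[[1]]),
                                    collapse = ""))
  expect_equal(composition_by_class(p1)$frequencies,
               composition_by_class(shuf)$frequencies)
  # X reported separately
  ctx <- composition_by_class(protein_record("p", "LXSX"))
  expect_equal(ctx$x_fraction, 0.5)
  expect_equal(sum(ctx$frequencies), 1)
})

test_that("coevolving-pair summary counts close supra-threshold pairs", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.9    # L-V adjacent pair
  cs <- coevolution_pair_summary(m, protein_record("p", "LVS"))
  expect_identical(cs$n_pairs, 1L)
  expect_equal(cs$hydrophobic_pair_fraction, 1.0)
  # no qualifying pairs -> fraction undefined
  zero <- coevolution_pair_summary(matrix(0, 3, 3), protein_record("p", "LVS"))
  expect_identical(zero$n_pairs, 0L)
  expect_true(is.na(zero$hydrophobic_pair_fraction))
  expect_identical(coevolution_pair_summary(m, protein_record("p", "LVS"),
                                            threshold = 1.1)$n_pairs, 0L)
  expect_error(coevolution_pair_summary(matrix(0, 4, 4),
                                        protein_record("p", "LVS")),
               "residues")
  m2 <- m; m2[1, 2] <- 0.5
  expect_error(coevolution_pair_summary(m2, protein_record("p", "LVS")),
               "symmetric")

  # brute-force double-loop oracle on random matrices
  set.seed(9)
  for (rep in 1:5) {
    n <- 50
    prot <- random_protein(n, rep + 100)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    cs <- coevolution_pair_summary(m, prot, threshold = 0.8, max_dist = 5)
    chars <- strsplit(prot$seq, "")[[1]]
    n_pairs <- 0L; n_hh <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (j - i <= 5 && m[i, j] > 0.8) {
        n_pairs <- n_pairs + 1L
        if (chars[i] %in% HYDROPHOBIC_SET && chars[j] %in% HYDROPHOBIC_SET)
          n_hh <- n_hh + 1L
      }
    }
    expect_identical(cs$n_pairs, n_pairs)
    expect_equal(cs$hydrophobic_pair_fraction,
                 if (n_pairs) n_hh / n_pairs else NA_real_)
  }
})

test_that("score matrices round-trip through whitespace-delimited text", {
  m <- matrix(round(runif(16), 4), 4, 4)
  m <- (m + t(m)) / 2
  path <- tempfile()
  write.table(m, path, row.names = FALSE, col.names = FALSE)
  expect_equal(read_score_matrix(path), m, tolerance = 1e-12)
})
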