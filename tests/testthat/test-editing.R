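test_that("anchor alignment infers insertion and deletion runs", {
  aln <- anchor_align(cds_record("c", "GAGGG"), cds_record("e", "GUAGUUGG"))
  expect_identical(aln$total_inserted, 3L)
  expect_identical(aln$total_deleted, 0L)
  # runs: one U after the first anchor, two after the third
  ins_runs <- aln$runs[aln$runs$n_inserted > 0, ]
  expect_identical(ins_runs$n_inserted, c(1L, 2L))
  # a U-deletion pair
  del <- anchor_align(cds_record("c", "GUUA"), cds_record("e", "GUA"))
  expect_identical(del$total_inserted, 0L)
  expect_identical(del$total_deleted, 1L)
  # identity
  id <- anchor_align(cds_record("c", "GAUGC"), cds_record("e", "GAUGC"))
  expect_identical(id$total_inserted + id$total_deleted, 0L)
  # incompatible anchors are rejected with positions
  expect_error(anchor_align(cds_record("c", "GAGGG"),
                            cds_record("e", "GUAGUUGGG")),
               "editing-incompatible")
  expect_error(anchor_align(cds_record("c", "GAG"), cds_record("e", "GCG")),
               "position 2")
  # exactly one of insertion/deletion per run, by construction
  expect_true(all(aln$runs$n_inserted == 0 | aln$runs$n_deleted == 0))
})

test_that("inserted Us are assigned codon positions under both conventions", {
  aln <- anchor_align(cds_record("c", "GAGGG"), cds_record("e", "GUAGUUGG"))
  expect_identical(inserted_by_codon_position(aln, "genomic_left"),
                   c(0L, 2L, 1L))
  # no genomic Us anywhere -> placement convention cannot matter
  expect_identical(inserted_by_codon_position(aln, "genomic_right"),
                   inserted_by_codon_position(aln, "genomic_left"))
  # mixed run: crypto GU..., edited GUUU -> 2 inserted; left takes slots 3,4
  mix <- anchor_align(cds_record("c", "GUAAA"), cds_record("e", "GUUUAAA"))
  expect_identical(inserted_by_codon_position(mix, "genomic_left"),
                   c(1L, 0L, 1L))   # edited slots 3 and 4
  expect_identical(inserted_by_codon_position(mix, "genomic_right"),
                   c(0L, 1L, 1L))   # edited slots 2 and 3
  # a run with equal U counts contributes nothing
  eq <- anchor_align(cds_record("c", "GUG"), cds_record("e", "GUG"))
  expect_identical(inserted_by_codon_position(eq), c(0L, 0L, 0L))
})

test_that("inserted-U homogeneity test reproduces uniform-expectation p-values", {
  expect_equal(round(inserted_homogeneity_test(c(606, 570, 590))$p, 2), 0.58)
  expect_equal(round(inserted_homogeneity_test(c(149, 141, 123))$p, 2), 0.28)
  even <- inserted_homogeneity_test(c(5, 5, 5))
  expect_equal(even$p, 1)
  degen <- inserted_homogeneity_test(c(0, 0, 0))
  expect_true(degen$degenerate)
})

test_that("alignment recovers simulated editing events exactly", {
  for (seed in 1:150) {
    sim <- simulate_editing_pair(editing_sim_params(cds_length = 60,
                                                    seed = seed))
    aln <- anchor_align(sim$cryptogene, sim$edited)
    expect_identical(aln$total_inserted, sim$truth$total_inserted)
    expect_identical(aln$total_deleted, sim$truth$total_deleted)
    expect_identical(aln$runs$n_inserted, sim$truth$run_inserted)
    expect_identical(aln$runs$n_deleted, sim$truth$run_deleted)
    expect_identical(inserted_by_codon_position(aln, "genomic_left"),
                     sim$truth$inserted_by_position)
    # U bookkeeping: edited Us = cryptogene Us - deleted + inserted
    n_u <- function(r) sum(strsplit(r$seq, "")[[1]] == "U")
    expect_identical(n_u(sim$edited),
                     n_u(sim$cryptogene) - sim$truth$total_deleted +
                       sim$truth$total_inserted)
  }
})

test_that("editing report tabulates inserted and total Us per gene", {
  sims <- lapply(1:3, function(s)
    simulate_editing_pair(editing_sim_params(cds_length = 50, seed = s)))
  pairs <- lapply(sims, function(x)
    list(cryptogene = x$cryptogene, edited = x$edited))
  rep <- suppressWarnings(editing_report(pairs))
  expect_identical(nrow(rep), 3L)
  for (i in 1:3) {
    expect_identical(rep$total_inserted[i], sims[[i]]$truth$total_inserted)
    expect_identical(c(rep$inserted_pos1[i], rep$inserted_pos2[i],
                       rep$inserted_pos3[i]),
                     sims[[i]]$truth$inserted_by_position)
    expect_true(rep$inserted_pos1[i] <= rep$total_u_pos1[i])
  }
})
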