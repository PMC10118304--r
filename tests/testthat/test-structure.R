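test_that("PDB and mmCIF files load with element radii, skipping waters", {
  model <- make_toy_complex(6, 5, 0.4)$model
  pdb_path <- tempfile(fileext = ".pdb")
  write_structure_pdb(model, pdb_path)
  back <- read_structure(pdb_path)
  expect_identical(nrow(back$atoms), nrow(model$atoms))
  expect_equal(back$atoms$x, model$atoms$x, tolerance = 1e-3)
  expect_equal(unique(back$atoms$radius), 1.70)
  # waters are skipped by default (HETATM/HOH records)
  lines <- readLines(pdb_path)
  wat <- "HETATM   99  O   HOH A  99      50.000  50.000  50.000  1.00  0.00           O"
  writeLines(c(lines[-length(lines)], wat, "END"), pdb_path)
  expect_identical(nrow(read_structure(pdb_path)$atoms), nrow(model$atoms))
  # unknown element falls back to the default radius with a warning
  expect_warning(
    mdl <- structure_model(data.frame(chain = "A", resno = 1, resid = "ALA",
                                      elety = "FE", element = "FE",
                                      x = 0, y = 0, z = 0)),
    "not in radius table")
  expect_equal(mdl$atoms$radius, 1.70)
  expect_error(read_structure(tempfile()), "not found")
})

test_that("SASA matches analytic sphere values", {
  # isolated atom: exactly the extended-sphere area
  one <- sasa(structure_model(carbon_atoms(0)))
  R <- 1.7 + 1.4
  expect_equal(one$total, 4 * pi * R^2, tolerance = 0.01)
  # two distant atoms: both full spheres
  far <- sasa(structure_model(carbon_atoms(c(0, 100))))
  expect_equal(far$atom_sasa, rep(4 * pi * R^2, 2), tolerance = 0.01)
  # overlapping pair: spherical-cap closed form 4*pi*R^2 - 2*pi*R*(R - d/2)
  for (d in c(1.0, 2.5, 4.0, 5.5)) {
    s <- sasa(structure_model(carbon_atoms(c(0, d))))
    expected <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
    expect_equal(s$atom_sasa[1], expected, tolerance = 0.02)
    expect_equal(s$atom_sasa[2], expected, tolerance = 0.02)
  }
  # sampling error shrinks as points grow
  d <- 3.0
  expected <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  err_at <- function(np) {
    s <- sasa(structure_model(carbon_atoms(c(0, d))), n_points = np)
    abs(s$atom_sasa[1] - expected) / expected
  }
  expect_lt(err_at(4000), err_at(60) + 1e-12)
  expect_error(sasa(structure_model(carbon_atoms(0)), n_points = 5),
               "n_points")
  # residue SASA sums atom SASA
  m <- sasa(structure_model(carbon_atoms(c(0, 2, 50))))
  expect_equal(sum(m$residues$sasa), m$total)
})

test_that("exposure classification is a strict 30 percent cutoff", {
  res <- sasa(structure_model(carbon_atoms(0)))
  # single carbon sphere: 120.8 of ALA's 129 max -> exposed
  expect_true(res$residues$exposed[1])
  expect_true(classify_exposure(res))
  # boundary: exactly 0.30 is not exposed
  fake <- res
  fake$residues$rel_sasa <- c(0.30)
  expect_false(classify_exposure(fake))
  fake$residues$rel_sasa <- 0.300000001
  expect_true(classify_exposure(fake))
  # missing reference residue type errors by name
  odd <- suppressWarnings(sasa(structure_model(
    data.frame(chain = "A", resno = 1, resid = "UNK", elety = "CA",
               element = "C", x = 0, y = 0, z = 0))))
  expect_error(classify_exposure(odd), "UNK")
})

test_that("interface detection flags exactly the occluded residues", {
  toy <- make_toy_complex(30, 20, 0.3, seed = 1)
  im <- interface_sites(toy$model, "A", "B")
  expect_identical(im$A$resno[im$A$interface], toy$truth$A)
  expect_identical(im$B$resno[im$B$interface], toy$truth$B)
  # complexed SASA never exceeds isolated SASA (up to sampling tolerance)
  expect_true(all(im$A$delta_sasa > -1e-9))
  expect_true(all(im$B$delta_sasa > -1e-9))
  # chains far apart -> no interface
  apart <- structure_model(rbind(carbon_atoms(0:2 * 3.8, chain = "A"),
                                 carbon_atoms(0:2 * 3.8, y = 100,
                                              chain = "B")))
  im2 <- interface_sites(apart, "A", "B")
  expect_false(any(im2$A$interface))
  expect_false(any(im2$B$interface))
  expect_error(interface_sites(apart, "A", "A"), "must differ")
  expect_error(interface_sites(apart, "A", "C"), "not present")
})

test_that("hydrophobicity-increase comparison matches a hand-built contingency", {
  # 40 aligned sites; increases at exactly 9/20 exposed and 3/20 buried
  q_chars <- rep("S", 40)
  s_chars <- rep("S", 40)
  exposed <- rep(c(TRUE, FALSE), each = 20)
  q_chars[c(1:9, 21:23)] <- "L"   # KD(L) > KD(S): an increase
  query <- protein_record("q", paste(q_chars, collapse = ""))
  subject <- protein_record("s", paste(s_chars, collapse = ""))
  aln <- data.frame(qpos = 1:40, spos = 1:40)
  cmp <- compare_hydrophobicity(query, subject, aln, strata = exposed)
  expect_equal(unname(cmp$fractions), c(9 / 20, 3 / 20))
  # oracle: closed-form 2x2 chi-square
  tab <- rbind(c(9, 11), c(3, 17))
  n <- sum(tab)
  oracle <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab)) / prod(colSums(tab)) * 1
  expect_equal(cmp$test$statistic, oracle, tolerance = 1e-12)
  expect_identical(cmp$contingency[1, 1], 9L)
  # identical proteins: all fractions 0, test degenerate
  expect_warning(
    same <- compare_hydrophobicity(subject, subject, aln, strata = exposed),
    "skipped")
  expect_equal(unname(same$fractions), c(0, 0))
  expect_null(same$test)
  # subject uniformly more hydrophobic -> zero fractions
  subj_hi <- protein_record("s2", strrep("I", 40))
  expect_warning(
    low <- compare_hydrophobicity(subject, subj_hi, aln, strata = exposed),
    "skipped")
  expect_equal(unname(low$fractions), c(0, 0))
  # editing-by-stratum side comparison
  ed <- rep(c(TRUE, FALSE), 20)
  cmp_ed <- compare_hydrophobicity(query, subject, aln, strata = exposed,
                                   edited_flags = ed)
  expect_equal(unname(cmp_ed$editing_fractions), c(0.5, 0.5))
  expect_error(compare_hydrophobicity(query, subject, aln,
                                      strata = exposed[1:10]),
               "one flag per")
})

test_that("the helper aligner pairs homologous sites", {
  q <- protein_record("q", "MKLFVDEW")
  s <- protein_record("s", "MKFVDEW")  # L deleted
  pairs <- align_homologs(q, s)
  expect_true(all(pairs$qpos >= 1 & pairs$qpos <= 8))
  # matched flanks map to each other
  expect_true(all(c(1, 2) %in% pairs$qpos))
  expect_identical(pairs$spos[pairs$qpos == 1], 1L)
  expect_identical(pairs$spos[pairs$qpos == 8], 7L)
  # round trip through the two-column TSV
  f <- tempfile(fileext = ".tsv")
  write.table(pairs, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_identical(read_alignment_pairs(f), pairs)
})
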