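test_that("cohort generation is deterministic under seed and leaves the RNG alone", {
  c1 <- gen_ligand_cohort(n = 300, seed = 17)
  c2 <- gen_ligand_cohort(n = 300, seed = 17)
  expect_identical(c1, c2)
  set.seed(1); before <- runif(5)
  set.seed(1); invisible(gen_ligand_cohort(n = 50, seed = 99)); after <- runif(5)
  expect_identical(before, after)
  expect_identical(attr(c1, "seed"), 17)
})

test_that("cohort tuples satisfy the WHBC identity and class composition", {
  coh <- gen_ligand_cohort(n = 1500, seed = 23)
  expect_true(all(coh$WHBC == (coh$nHDon + coh$nHAcc) / coh$nSK))
  expect_true(all(coh$nSK >= 6 * coh$nAR))
  expect_true(all(coh$nHDon >= 0 & coh$nHAcc >= 0))
  # composition approximately matches the requested weights
  cd <- class_distribution(coh)
  expect_equal(cd$percent / 100,
               unname(c(1, 117, 507, 819, 570, 125) / 2139),
               tolerance = 0.35)
})

test_that("a flat planted slope yields statistically flat class means", {
  coh <- gen_ligand_cohort(n = 3000, slope = 0, intercept = 0.33, seed = 31)
  cd <- class_distribution(coh)
  cd <- cd[cd$n >= 30, ]
  overall <- sum(cd$n * cd$mean_whbc) / sum(cd$n)
  expect_true(all(abs(cd$mean_whbc - overall) <= 2.5 * cd$sem_whbc + 0.006))
})

test_that("generated SMILES reproduce their own descriptor tuples", {
  coh <- gen_ligand_cohort(n = 30, seed = 47, smiles = TRUE)
  for (i in seq_len(nrow(coh))) {
    mol <- parse_ligand(coh$smiles[i])
    expect_equal(count_aromatic_rings(mol), coh$nAR[i], info = coh$smiles[i])
    expect_equal(count_hbond_donors(mol), coh$nHDon[i], info = coh$smiles[i])
    expect_equal(count_hbond_acceptors(mol), coh$nHAcc[i], info = coh$smiles[i])
    expect_equal(nrow(mol$atoms), coh$nSK[i], info = coh$smiles[i])
  }
})

test_that("complex fixtures are deterministic and record their seed", {
  f1 <- gen_complex_fixture(seed = 12)
  f2 <- gen_complex_fixture(seed = 12)
  expect_identical(f1, f2)
  expect_true(grepl("SEED 12", f1))
  expect_false(identical(f1, gen_complex_fixture(seed = 13)))
  expect_error(gen_complex_fixture(modes = "WIBBLE"), "unknown mode")
})

test_that("clashing fixture placements are rejected", {
  expect_error(
    gen_complex_fixture(modes = "CH_PI", distances = c(CH_PI = 0.5)),
    "clash"
  )
})

test_that("synthetic ledgers validate cleanly; corruption is flagged row-exactly", {
  led <- gen_energy_ledger(n_residues = 11, seed = 6)
  expect_equal(sum(validate_ledger(led)$flagged), 0)
  corrupted <- led
  rows <- c(2, 5, 9)
  corrupted$dE_aq[rows] <- corrupted$dE_aq[rows] + 0.7
  v <- validate_ledger(corrupted)
  expect_equal(which(v$flagged), rows)
  expect_identical(gen_energy_ledger(n_residues = 5, seed = 8),
                   gen_energy_ledger(n_residues = 5, seed = 8))
})
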