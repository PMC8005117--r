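test_that("donor and acceptor counting follows the configured rules", {
  expect_equal(count_hbond_donors(parse_ligand("c1ccccc1")), 0)
  expect_equal(count_hbond_donors(parse_ligand("Oc1ccccc1")), 1)   # phenol
  expect_equal(count_hbond_acceptors(parse_ligand("CC")), 0)
  expect_equal(count_hbond_acceptors(parse_ligand("c1ccncc1")), 1) # pyridine

  caffeine <- parse_ligand("Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  expect_equal(
    count_hbond_acceptors(caffeine, descriptor_config(acceptor_rule = "all_no")),
    6
  )
  expect_lt(count_hbond_acceptors(caffeine), 6)

  # thiol counts only under the extended donor rule
  thiol <- parse_ligand("SCC")
  expect_equal(count_hbond_donors(thiol), 0)
  expect_equal(count_hbond_donors(thiol, descriptor_config(donor_rule = "nos_h")), 1)
})

test_that("sp3 fraction and WHBC arithmetic match hand counts", {
  expect_equal(fraction_sp3(parse_ligand("C1CCCCC1")), 1.0)
  expect_equal(fraction_sp3(parse_ligand("c1ccccc1")), 0.0)
  expect_equal(fraction_sp3(parse_ligand("CCCc1ccccc1")), 3 / 9)
  expect_error(fraction_sp3(parse_ligand("O=S=O")), "no carbon")

  expect_equal(weighted_hbond_count(0, 0, 10), 0)
  expect_equal(weighted_hbond_count(2, 7, 27), 9 / 27)
  expect_equal(weighted_hbond_count(5, 14, 40), 0.475)
  expect_error(weighted_hbond_count(1, 1, 0), "nSK")
})

test_that("the full descriptor set is internally consistent", {
  d <- compute_descriptors(parse_ligand("c1ccccc1", name = "benzene"))
  expect_equal(d$MW, 78.11, tolerance = 1e-3)
  expect_equal(d$nAR, 1)
  expect_equal(d$ARR, 1.0)
  expect_equal(d$Fsp3, 0)
  expect_equal(d$WHBC, 0)

  w <- compute_descriptors(parse_ligand("O", name = "water"))
  expect_equal(w$nSK, 1)
  expect_equal(w$nHDon, 1)
  expect_equal(w$WHBC, (w$nHDon + w$nHAcc) / w$nSK)

  # TPSA under Ertl fragment contributions (literature value for aspirin)
  asp <- compute_descriptors(parse_ligand("CC(=O)Oc1ccccc1C(=O)O"))
  expect_equal(asp$TPSA, 63.6, tolerance = 0.05)
})

test_that("WHBC in the descriptor set always equals its defining ratio", {
  coh <- gen_ligand_cohort(n = 25, seed = 11, smiles = TRUE)
  for (i in seq_len(nrow(coh))) {
    d <- compute_descriptors(parse_ligand(coh$smiles[i]))
    expect_identical(d$WHBC, (d$nHDon + d$nHAcc) / d$nSK)
    expect_true(d$ARR >= 0 && d$ARR <= 1)
    expect_true(d$Fsp3 >= 0 && d$Fsp3 <= 1)
    expect_gte(d$nSK, d$nC)
  }
})

test_that("donor/acceptor counts agree with brute-force atom enumeration", {
  coh <- gen_ligand_cohort(n = 100, seed = 99, smiles = TRUE)
  cfg_all <- descriptor_config(acceptor_rule = "all_no")
  for (i in seq_len(nrow(coh))) {
    mol <- parse_ligand(coh$smiles[i])
    expect_equal(count_hbond_donors(mol), brute_donors(mol), info = i)
    expect_equal(count_hbond_acceptors(mol, cfg_all), brute_acceptors_all(mol),
                 info = i)
  }
})
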