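test_that("thermodynamic-cycle arithmetic is exact", {
  expect_equal(gas_interaction(-10, -4, -5), -1)
  expect_equal(gas_interaction(0, 0, 0), 0)
  expect_equal(dehydration(-20, -12, -11), 3)
  expect_equal(aqueous_interaction(-4.1, 3.8), -0.3, tolerance = 1e-9)  # Met477
  expect_equal(aqueous_interaction(-3.0, 0.1), -2.9, tolerance = 1e-9)  # Val416
  expect_equal(aqueous_interaction(2.5, 0), 2.5)
  expect_error(gas_interaction(Inf, 0, 0), "finite")

  set.seed(8)
  for (i in 1:50) {
    v <- round(runif(3, -30, 10), 1)
    expect_equal(gas_interaction(v[1], v[2], v[3]), v[1] - v[2] - v[3],
                 tolerance = 1e-9)
    expect_equal(dehydration(v[1], v[2], v[3]), v[1] - v[2] - v[3],
                 tolerance = 1e-9)
  }
})

test_that("the shipped ibrutinib-BTK ledger reproduces the published group sums", {
  led <- ibrutinib_btk_ledger()
  expect_equal(nrow(led), 11)
  grp <- group_by_mode(led)
  hb <- grp[grp$group == "hydrogen_bonding", ]
  pi <- grp[grp$group == "nonbonded_pi", ]
  expect_equal(hb$combined_energy, -0.6, tolerance = 1e-9)
  expect_equal(hb$n_residues, 2)
  expect_true(grepl("Met477", hb$residues) && grepl("Lys481", hb$residues))
  expect_equal(pi$combined_energy, -22.5, tolerance = 1e-9)
  expect_equal(pi$n_residues, 9)
})

test_that("ledger validation flags additivity violations at the right tolerance", {
  led <- ibrutinib_btk_ledger()
  expect_equal(sum(validate_ledger(led)$flagged), 0)
  # one published row carries a 0.1 kcal/mol rounding residual
  tight <- validate_ledger(led, tol = 0.05)
  expect_equal(sum(tight$flagged), 1)
  expect_equal(led$residue[tight$flagged], "Lys430")

  bad <- led
  bad$dE_aq[3] <- bad$dE_aq[3] + 1.0
  expect_equal(sum(validate_ledger(bad)$flagged), 1)
})

test_that("mode grouping conserves energy and is order independent", {
  led <- gen_energy_ledger(n_residues = 11, seed = 14)
  grp <- group_by_mode(led)
  expect_equal(sum(grp$combined_energy), sum(led$dE_aq), tolerance = 1e-9)
  grp2 <- group_by_mode(led[sample(nrow(led)), ])
  expect_equal(grp$combined_energy, grp2$combined_energy, tolerance = 1e-9)

  single <- tibble::tibble(residue = "X1", modes = "H-bond", dE_gas = -2,
                           dE_deh = 1, dE_aq = -1)
  g1 <- group_by_mode(single)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$combined_energy, -1)

  bad <- single
  bad$modes <- "frobnication"
  expect_error(group_by_mode(bad), "unrecognised")
})

test_that("ledger CSV round-trips through read_energy_ledger", {
  tf <- tempfile(fileext = ".csv")
  led <- gen_energy_ledger(n_residues = 6, seed = 2, file = tf)
  back <- read_energy_ledger(tf)
  expect_equal(back$dE_aq, led$dE_aq)
  expect_equal(back$modes, led$modes)
  # dE_aq column is reconstructed when absent
  readr::write_csv(led[, c("residue", "modes", "dE_gas", "dE_deh")], tf)
  back2 <- read_energy_ledger(tf)
  expect_equal(back2$dE_aq, led$dE_gas + led$dE_deh, tolerance = 1e-9)
})
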