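mk_desc <- function(MW = 390.29, cLogP = 2.58, nHDon = 2, nHAcc = 7,
                    RBN = 5, TPSA = 94.06) {
  tibble::tibble(MW = MW, cLogP = cLogP, nHDon = nHDon, nHAcc = nHAcc,
                 RBN = RBN, TPSA = TPSA)
}

test_that("rule thresholds are strict at the stated boundaries", {
  # the cohort-median profile satisfies every bound
  expect_true(evaluate_compliance(mk_desc())$ro5_ok)
  expect_true(evaluate_compliance(mk_desc())$veber_ok)

  expect_false(evaluate_compliance(mk_desc(MW = 500))$mw_ok)
  expect_true(evaluate_compliance(mk_desc(MW = 499.99))$mw_ok)
  expect_false(evaluate_compliance(mk_desc(cLogP = 5))$clogp_ok)

  b <- evaluate_compliance(mk_desc(nHDon = 5, nHAcc = 7))
  expect_true(b$donors_ok)
  expect_false(b$hb_total_ok)  # 12 is not < 12

  expect_false(evaluate_compliance(mk_desc(TPSA = 140))$tpsa_ok)
  expect_true(evaluate_compliance(mk_desc(TPSA = 140), tpsa_strict = FALSE)$tpsa_ok)
  expect_true(evaluate_compliance(mk_desc(RBN = 10))$rbn_ok)
  expect_false(evaluate_compliance(mk_desc(RBN = 11))$rbn_ok)
})

test_that("cohort percentages are count-exact", {
  n <- 1000
  desc <- mk_desc(MW = c(rep(450, 854), rep(550, 146)),
                  cLogP = 2, nHDon = 2, nHAcc = 7, RBN = 5, TPSA = 90)
  s <- summarize_cohort(desc)
  expect_equal(s$pct_ro5[s$descriptor == "MW"], 100 * 854 / n)
})

test_that("cohort summaries are permutation invariant with correct spread", {
  set.seed(5)
  desc <- mk_desc(
    MW = runif(40, 200, 600), cLogP = runif(40, -1, 7),
    nHDon = sample(0:8, 40, TRUE), nHAcc = sample(1:14, 40, TRUE),
    RBN = sample(0:15, 40, TRUE), TPSA = runif(40, 20, 200)
  )
  s1 <- summarize_cohort(desc)
  s2 <- summarize_cohort(desc[sample(40), ])
  expect_equal(s1, s2)
  expect_true(all(s1$min <= s1$median & s1$median <= s1$max))
  # SEM versus SD differ by sqrt(n)
  s_sd <- summarize_cohort(desc, spread = "sd")
  expect_equal(s_sd$spread, s1$spread * sqrt(40))

  one <- summarize_cohort(mk_desc())
  expect_equal(one$min, one$max)
  expect_equal(one$spread, rep(0, nrow(one)))
  expect_error(summarize_cohort(mk_desc()[0, ]), "empty")
})
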