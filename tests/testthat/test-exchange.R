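test_that("ring-class binning follows both schemes", {
  expect_equal(as.character(assign_ring_class(3)), "3")
  expect_equal(as.character(assign_ring_class(8)), "5+")
  expect_equal(as.character(assign_ring_class(0, scheme = "histogram")), "0-1")
  expect_equal(as.character(assign_ring_class(c(0, 1, 5), "histogram")),
               c("0-1", "0-1", "5+"))
  expect_error(assign_ring_class(-1), "non-negative")
})

test_that("class distribution reproduces the published class percentages", {
  cd <- class_distribution(table3_cohort())
  expect_equal(round(cd$percent, 2), c(0.05, 5.47, 23.70, 38.29, 26.65, 5.84))
  expect_equal(cd$n, table3_counts)
  expect_equal(cd$mean_whbc, table3_means, tolerance = 1e-12)
})

test_that("class distribution conserves counts and WHBC mass", {
  coh <- gen_ligand_cohort(n = 500, seed = 21)
  cd <- class_distribution(coh)
  expect_equal(sum(cd$n), nrow(coh))
  expect_equal(sum(cd$percent), 100, tolerance = 1e-9)
  mass <- sum(cd$n * cd$mean_whbc, na.rm = TRUE)
  expect_equal(mass, sum(coh$WHBC), tolerance = 1e-9)
  # single-class cohort
  one <- class_distribution(tibble::tibble(nAR = rep(2, 5), WHBC = 1:5 / 10))
  expect_equal(one$percent[as.character(one$ring_class) == "2"], 100)
})

test_that("gaussian fits return mean/SD parameters and flag degeneracy", {
  expect_error(fit_gaussian(0.3), "at least two")
  expect_warning(g0 <- fit_gaussian(rep(0.3, 5)), "degenerate")
  expect_true(g0$degenerate)
  g <- fit_gaussian(c(0.2, 0.4))
  expect_equal(g$mu, 0.3)
  expect_equal(g$sigma, sd(c(0.2, 0.4)))
  set.seed(123)
  big <- fit_gaussian(rnorm(1e4, 0.33, 0.05))
  expect_equal(big$mu, 0.33, tolerance = 0.002 / 0.33)
  expect_equal(big$sigma, 0.05, tolerance = 0.05)
})

test_that("the exchange line matches closed-form OLS on the published means", {
  cd <- class_distribution(table3_cohort())
  fit <- fit_exchange_line(cd)   # zero-ring singleton excluded by default
  x <- 1:5
  y <- table3_means[2:6]
  expect_equal(fit$slope, ols_slope(x, y), tolerance = 1e-12)
  expect_equal(fit$intercept, ols_intercept(x, y), tolerance = 1e-12)
  expect_lt(fit$slope, 0)
  expect_equal(fit$slope, -0.0249, tolerance = 1e-3)

  # including the zero class and moving the top-class abscissa both work
  fit0 <- fit_exchange_line(cd, include_zero_class = TRUE, x_five_plus = 5.5)
  expect_equal(fit0$slope, ols_slope(c(0:4, 5.5), table3_means), tolerance = 1e-12)
})

test_that("exactly collinear class means give r-squared 1 and the planted slope", {
  tab <- tibble::tibble(
    ring_class = assign_ring_class(1:5),
    mean_whbc = 0.41 - 0.03 * (1:5),
    sem_whbc = rep(0.004, 5)
  )
  fit <- fit_exchange_line(tab)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -0.03, tolerance = 1e-12)
  # two points always fit exactly
  fit2 <- fit_exchange_line(tab[1:2, ])
  expect_equal(fit2$r_squared, 1)
  expect_error(fit_exchange_line(tab[1, ]), "two classes")
  # inverse-variance weighting on equal SEMs equals the unweighted fit
  fitw <- fit_exchange_line(tab, weighted = TRUE)
  expect_equal(fitw$slope, fit$slope, tolerance = 1e-12)
})

test_that("synthetic cohorts recover the planted slope", {
  slopes <- vapply(1:10, function(s) {
    fit_exchange_line(class_distribution(
      gen_ligand_cohort(n = 2000, seed = s)
    ))$slope
  }, numeric(1))
  expect_equal(mean(slopes), -0.025, tolerance = 0.1)
  expect_true(all(slopes < 0))
})

test_that("tidy, glance and autoplot methods work on exchange fits", {
  fit <- fit_exchange_line(class_distribution(table3_cohort()))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- generics::glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_equal(gl$n_classes, 5)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(plot_class_gaussians(gen_ligand_cohort(n = 300, seed = 2)),
                  "ggplot")
})
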