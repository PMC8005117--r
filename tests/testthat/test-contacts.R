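test_that("each mode is detected inside its window and not outside it", {
  for (mode in all_modes) {
    cx_in <- load_complex(gen_complex_fixture(modes = mode), "LIG")
    m_in <- interaction_map(cx_in)
    expect_equal(m_in$mode, mode, info = paste("inside", mode))

    cx_out <- load_complex(
      gen_complex_fixture(modes = mode, placement = "outside"), "LIG"
    )
    m_out <- interaction_map(cx_out)
    expect_equal(nrow(m_out), 0, info = paste("outside", mode))
  }
})

test_that("the all-mode fixture yields exactly the planted multiset", {
  cx <- load_complex(gen_complex_fixture(), "LIG")
  m <- interaction_map(cx)
  expect_equal(sort(m$mode), sort(all_modes))
  expect_equal(nrow(m), 8)
  # residues are sorted by number
  expect_equal(m$resno, sort(m$resno))
  # empty pocket: no protein records at all
  lonely <- gen_complex_fixture(modes = character(0))
  expect_equal(nrow(interaction_map(load_complex(lonely, "LIG"))), 0)
})

test_that("detection equals the independent all-pairs oracle on random fixtures", {
  for (s in 1:20) {
    set.seed(500 + s)
    md <- sample(all_modes, sample(2:8, 1))
    pl <- stats::setNames(sample(c("inside", "outside"), length(md), TRUE), md)
    pdb <- gen_complex_fixture(modes = md, placement = pl, seed = s)
    got <- sort(interaction_map(load_complex(pdb, "LIG"))$mode)
    expect_equal(got, oracle_fixture_contacts(pdb), info = paste("fixture", s))
  }
})

test_that("detection is invariant under rigid-body motion", {
  pdb <- gen_complex_fixture(seed = 33)
  m1 <- interaction_map(load_complex(pdb, "LIG"))
  m2 <- interaction_map(load_complex(rotate_pdb_text(pdb), "LIG"))
  expect_equal(m1$mode, m2$mode)
  expect_equal(m1$resno, m2$resno)
  # distances agree to the fixed-format coordinate precision
  expect_equal(m1$distance, m2$distance, tolerance = 1e-2)
})

test_that("every reported contact satisfies its own geometric window", {
  cx <- load_complex(gen_complex_fixture(seed = 4), "LIG")
  crit <- geometry_criteria()
  m <- interaction_map(cx, crit)
  lim <- c(HBOND = crit$hbond_dist, SALT_BRIDGE = crit$salt_bridge_dist,
           PI_PI = crit$pipi_tshape_dist, CH_PI = crit$chpi_dist,
           CATION_PI = crit$catpi_dist, NH_PI = crit$xhpi_dist,
           OH_PI = crit$xhpi_dist, SH_PI = crit$xhpi_dist)
  key <- ifelse(is.na(m$centroid_dist), m$distance, m$centroid_dist)
  expect_true(all(key <= lim[m$mode] + 1e-9))
  point_modes <- m$mode %in% c("CH_PI", "CATION_PI", "NH_PI", "OH_PI", "SH_PI")
  expect_true(all(m$height[point_modes] >= crit$pi_min_height))
})

test_that("custom geometry criteria move the detection boundary", {
  # a CH-pi probe at 4.3 is inside the default window but outside a
  # tightened one
  pdb <- gen_complex_fixture(modes = "CH_PI", distances = c(CH_PI = 4.3))
  cx <- load_complex(pdb, "LIG")
  expect_equal(nrow(interaction_map(cx)), 1)
  tight <- geometry_criteria(chpi_dist = 4.0)
  expect_equal(nrow(interaction_map(cx, tight)), 0)
  expect_error(geometry_criteria(chpi_dist = -1), "non-negative")
  expect_error(geometry_criteria(pipi_tshape_angle = c(90, 60)), "increasing")
})

test_that("interaction maps plot", {
  m <- interaction_map(load_complex(gen_complex_fixture(), "LIG"))
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
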