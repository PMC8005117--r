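test_that("generated fixtures round-trip losslessly through load_complex", {
  pdb <- gen_complex_fixture(seed = 5)
  cx <- load_complex(pdb, "LIG")
  ref <- oracle_read_pdb(pdb)
  lig_ref <- ref[ref$type == "HETATM", ]
  expect_equal(nrow(cx$ligand), nrow(lig_ref))
  expect_equal(cx$ligand$x, lig_ref$x)
  expect_equal(cx$ligand$y, lig_ref$y)
  expect_equal(cx$ligand$z, lig_ref$z)
  expect_equal(cx$ligand$elety, lig_ref$name)
  prot_ref <- ref[ref$type == "ATOM", ]
  expect_equal(nrow(cx$protein), nrow(prot_ref))
  # CONECT records drive the ligand bond graph (19 atoms, 3 rings + links)
  expect_equal(nrow(cx$lig_bonds), 21)
})

test_that("missing ligand codes produce an informative error", {
  pdb <- gen_complex_fixture(modes = "HBOND")
  expect_error(load_complex(pdb, "XYZ"), "available: LIG")
})

test_that("alternate locations resolve to one coordinate per atom", {
  txt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C1  LIG A  90       0.000   3.000   0.000  1.00  0.00           C",
    "HETATM    5  C2  LIG A  90       1.400   3.000   0.000  1.00  0.00           C",
    "END"
  )
  cx <- load_complex(paste(txt, collapse = "\n"), "LIG")
  ca <- cx$protein[cx$protein$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.0)  # altloc B has the higher occupancy
})

test_that("waters are excluded and binding-site listing matches brute force", {
  pdb <- gen_complex_fixture(seed = 9)
  cx <- load_complex(pdb, "LIG")
  site <- binding_site_residues(cx, 4.5)
  # brute-force O(n^2) oracle on the raw text
  at <- oracle_read_pdb(pdb)
  lig <- at[at$type == "HETATM", ]
  prot <- at[at$type == "ATOM", ]
  keep <- character()
  for (r in unique(prot$resno)) {
    res <- prot[prot$resno == r, ]
    mind <- Inf
    for (i in seq_len(nrow(res))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((res$x[i] - lig$x[j])^2 + (res$y[i] - lig$y[j])^2 +
                    (res$z[i] - lig$z[j])^2)
        mind <- min(mind, d)
      }
    }
    if (mind <= 4.5) keep <- c(keep, r)
  }
  expect_setequal(as.character(site$resno), keep)
})

test_that("ring perception finds ligand rings by planarity and protein rings by template", {
  pdb <- gen_complex_fixture(modes = c("PI_PI", "CATION_PI"), seed = 1)
  cx <- load_complex(pdb, "LIG")
  rings <- perceive_rings(cx)
  expect_equal(nrow(rings$ligand), 3)   # the three ligand hexagons
  expect_true(all(rings$ligand$rms < 1e-6))
  expect_equal(rings$ligand$radius, rep(1.39, 3), tolerance = 1e-3)
  expect_equal(nrow(rings$protein), 1)  # the Phe probe
  expect_equal(rings$protein$resid, "PHE")
  # normals are unit vectors
  expect_equal(sqrt(sum(rings$ligand$normal[[1]]^2)), 1, tolerance = 1e-12)
})

test_that("protein rings with missing atoms are skipped with a warning", {
  txt <- c(
    "ATOM      1  CG  PHE A   7       0.000   0.000   3.000  1.00  0.00           C",
    "ATOM      2  CD1 PHE A   7       1.200   0.700   3.000  1.00  0.00           C",
    "HETATM    3  C1  LIG A  90       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C2  LIG A  90       1.400   0.000   0.000  1.00  0.00           C",
    "END"
  )
  cx <- load_complex(paste(txt, collapse = "\n"), "LIG")
  expect_warning(rings <- perceive_rings(cx), "ring atoms missing")
  expect_equal(nrow(rings$protein), 0)
})
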