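test_that("SMILES parsing perceives aromaticity, rings and hydrogens", {
  bz <- parse_ligand("c1ccccc1", name = "benzene")
  expect_equal(nrow(bz$atoms), 6)
  expect_true(all(bz$atoms$aromatic))
  expect_length(bz$rings, 1)
  expect_true(all(bz$atoms$n_h == 1))

  ac <- parse_ligand("CC(=O)O")
  expect_equal(nrow(ac$atoms), 4)
  expect_length(ac$rings, 0)

  # fused and heteroaromatic systems
  cases <- list(
    list("c1ccc2ccccc2c1", 2),   # naphthalene
    list("n1ccc2ccccc2c1", 2),   # quinoline
    list("c1cc[nH]c1", 1),       # pyrrole
    list("c1ccoc1", 1),          # furan
    list("C1CCCCC1", 0),         # cyclohexane
    list("Cn1cnc2c1c(=O)n(C)c(=O)n2C", 2)  # caffeine
  )
  for (cs in cases) {
    expect_equal(count_aromatic_rings(parse_ligand(cs[[1]])), cs[[2]],
                 info = cs[[1]])
  }
})

test_that("ibrutinib and lenvatinib parse with the known ring counts", {
  ib <- parse_ligand(
    "C=CC(=O)N1CCC(CC1)n1nc(-c2ccc(Oc3ccccc3)cc2)c2c(N)ncnc21",
    name = "ibrutinib"
  )
  expect_equal(count_aromatic_rings(ib), 4)
  expect_equal(count_hbond_donors(ib), 1)  # the exocyclic NH2 only

  lev <- parse_ligand("COc1cc2nccc(Oc3ccc(NC(=O)NC4CC4)c(Cl)c3)c2cc1C(N)=O",
                      name = "lenvatinib")
  expect_equal(count_aromatic_rings(lev), 3)
})

test_that("parse errors name the offending record", {
  expect_error(parse_ligand("not(a(smiles"), "could not parse SMILES")
  multi <- paste0(
    ChemmineOB::convertFormat("SMI", "SDF", "CCO a\nCCC b\n")
  )
  expect_error(parse_ligand(multi, format = "sdf"), "multi-record")
})

test_that("descriptors are invariant to atom reordering of the input", {
  a <- compute_descriptors(parse_ligand("OCc1ccncc1C(N)=O"))
  b <- compute_descriptors(parse_ligand("NC(=O)c1cnccc1CO"))
  for (col in c("MW", "nHDon", "nHAcc", "nSK", "Nsp3", "RBN", "ARR",
                "nAR", "Fsp3", "WHBC", "TPSA")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-8, info = col)
  }
})

test_that("SDF input retains 3D coordinates and SMILES input does not", {
  sdf3d <- paste(
    "mol3d", " test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.1000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.2000    0.8000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.2000   -1.0000   -0.9000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6000    1.0000    1.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  2  0  0  0  0",
    "  2  4  1  0  0  0  0",
    "  1  5  1  0  0  0  0",
    "M  END",
    "$$$$", sep = "\n"
  )
  m <- parse_ligand(sdf3d, format = "sdf")
  expect_false(is.null(m$coords3d))
  expect_equal(m$coords3d[3, ], c(2.1, 1.2, 0.8))
  expect_null(parse_ligand("CCO")$coords3d)
})

test_that("read_ligands handles SMILES files with ids and multi-record SDF", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1\tbz", "CCO\teth"), tf)
  tab <- read_ligands(tf)
  expect_equal(tab$id, c("bz", "eth"))
  expect_equal(nrow(tab$mol[[1]]$atoms), 6)

  tf2 <- tempfile(fileext = ".sdf")
  writeLines(ChemmineOB::convertFormat("SMI", "SDF", "CCO a\nc1ccccc1 b\n"), tf2)
  tab2 <- read_ligands(tf2)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$id, c("a", "b"))
})
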