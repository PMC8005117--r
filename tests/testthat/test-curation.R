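mk_rec <- function(ligand_id, resolution, pdb_id = NULL) {
  n <- length(ligand_id)
  tibble::tibble(
    ligand_name = paste0("lig_", seq_len(n)),
    ligand_id = ligand_id,
    kinase_name = paste0("kinase_", seq_len(n)),
    pdb_id = pdb_id %||% sprintf("%d%s%s%s", (seq_len(n) - 1) %% 9 + 1,
      LETTERS[(seq_len(n) - 1) %% 26 + 1], LETTERS[(seq_len(n) - 1) %/% 26 %% 26 + 1],
      LETTERS[(seq_len(n) - 1) %/% 676 %% 26 + 1]),
    resolution = resolution
  )
}

test_that("resolution filtering is inclusive at the cutoff", {
  rec <- mk_rec(c("AAA", "BBB", "CCC"), c(2.49, 2.50, 2.51))
  kept <- filter_resolution(rec)
  expect_equal(kept$ligand_id, c("AAA", "BBB"))
  expect_equal(nrow(filter_resolution(rec[0, ])), 0)
})

test_that("deduplication keeps the best-resolution complex per ligand", {
  rec <- mk_rec(c("AAA", "AAA"), c(1.1, 2.0))
  expect_equal(deduplicate_ligands(rec)$resolution, 1.1)
  # ties broken by lexicographic PDB id
  tie <- mk_rec(c("AAA", "AAA"), c(1.5, 1.5), pdb_id = c("2ZZZ", "1AAA"))
  expect_equal(deduplicate_ligands(tie)$pdb_id, "1AAA")
  # all-unique input is untouched (up to ordering)
  uni <- mk_rec(c("AAA", "BBB", "CCC"), c(1, 2, 1.4))
  expect_setequal(deduplicate_ligands(uni)$ligand_id, uni$ligand_id)
})

test_that("deduplication equals a brute-force group-by minimum", {
  set.seed(77)
  rec <- mk_rec(
    sample(c("AAA", "BBB", "CCC", "DDD", "EEE"), 100, replace = TRUE),
    round(runif(100, 0.9, 3.5), 2)
  )
  got <- deduplicate_ligands(rec)
  expect_true(all(table(got$ligand_id) == 1))
  best <- tapply(rec$resolution, rec$ligand_id, min)
  expect_equal(got$resolution[order(got$ligand_id)],
               as.numeric(best[sort(names(best))]))
})

test_that("the blocklist removes non-inhibitor ligands and nothing else", {
  rec <- mk_rec(c("ATP", "GOL", "IBR"), c(1.5, 1.6, 1.7))
  expect_equal(exclude_blocklist(rec)$ligand_id, "IBR")
  expect_equal(exclude_blocklist(rec, character())$ligand_id, rec$ligand_id)
  set.seed(3)
  mixed <- mk_rec(sample(c("ATP", "MG", "XYZ", "QQQ"), 50, TRUE),
                  runif(50, 1, 2))
  got <- exclude_blocklist(mixed)
  expect_equal(nrow(got), sum(!(mixed$ligand_id %in% default_ligand_blocklist())))
})

test_that("the curation pipeline is idempotent", {
  set.seed(41)
  rec <- mk_rec(sample(c("AAA", "BBB", "ATP", "CCC", "DDD"), 60, TRUE),
                round(runif(60, 1.0, 3.4), 2))
  once <- curate_records(rec)
  twice <- curate_records(once)
  expect_equal(once, twice)
  expect_true(all(table(once$ligand_id) == 1))
  expect_true(all(once$resolution <= 2.5))
})

test_that("malformed curation tables are rejected", {
  expect_error(filter_resolution(tibble::tibble(x = 1)), "lacks column")
  bad <- mk_rec("AAA", 1.5)
  bad$pdb_id <- "ZZZZZ"
  expect_error(filter_resolution(bad), "malformed PDB accession")
  neg <- mk_rec("AAA", -1)
  expect_error(filter_resolution(neg), "positive")
})
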