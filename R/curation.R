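#' Default co-crystallisation blocklist
#'
#' Three-character chemical component codes for ligands routinely found in
#' kinase structures that are not inhibitors: nucleotides and analogues,
#' common ions, buffers and cryoprotectants.
#'
#' @return A character vector of ligand codes.
#' @export
default_ligand_blocklist <- function() {
  c(
    # nucleotides and close analogues
    "ATP", "ADP", "AMP", "ANP", "ACP", "AGS", "GTP", "GDP", "GNP", "GSP",
    "ADN", "NAD", "NAP", "FAD", "FMN", "SAM", "SAH",
    # metals and simple ions
    "MG", "MN", "ZN", "CA", "NA", "K", "CL", "BR", "IOD", "F", "NI", "CO",
    "CD", "FE", "FE2", "CU",
    # buffers, cryoprotectants, additives
    "SO4", "PO4", "GOL", "EDO", "PEG", "PG4", "PGE", "1PE", "DMS", "ACT",
    "TRS", "MPD", "BME", "DTT", "MES", "EPE", "IMD", "FMT", "ACY", "CIT",
    "TLA", "NO3", "AZI", "SCN", "CO3", "OGA", "BOG", "NAG", "MAN", "GAL",
    "GLC", "FUC", "HOH"
  )
}

.check_pki_records <- function(records) {
  need <- setdiff(
    c("ligand_name", "ligand_id", "kinase_name", "pdb_id", "resolution"),
    names(records)
  )
  if (length(need)) {
    abort(paste0("curation table lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (nrow(records)) {
    if (any(is.na(records$resolution)) || any(records$resolution <= 0)) {
      abort("resolutions must be positive and non-missing")
    }
    bad <- !grepl("^[0-9][A-Za-z0-9]{3}$", records$pdb_id)
    if (any(bad)) {
      abort(paste0("malformed PDB accession(s): ",
                   paste(unique(records$pdb_id[bad]), collapse = ", ")))
    }
  }
  invisible(records)
}

#' Filter complex records by crystallographic resolution
#'
#' Retains records solved at `cutoff` Angstrom or better (inclusive:
#' "2.5 A or better" keeps a 2.50 A structure).
#'
#' @param records A tibble with columns `ligand_name`, `ligand_id`,
#'   `kinase_name`, `pdb_id`, `resolution`.
#' @param cutoff Resolution cutoff in Angstrom (default 2.5).
#' @return The filtered tibble.
#' @export
filter_resolution <- function(records, cutoff = 2.5) {
  stopifnot(cutoff > 0)
  .check_pki_records(records)
  filter(as_tibble(records), .data$resolution <= cutoff)
}

#' Keep one kinase complex per ligand
#'
#' Where the same ligand code appears bound to multiple kinases, only the
#' record with the best (lowest) resolution is retained; ties are broken
#' by lexicographic PDB accession for determinism.
#'
#' @inheritParams filter_resolution
#' @return A tibble with exactly one row per `ligand_id`.
#' @export
deduplicate_ligands <- function(records) {
  .check_pki_records(records)
  as_tibble(records) |>
    arrange(.data$ligand_id, .data$resolution, .data$pdb_id) |>
    distinct(.data$ligand_id, .keep_all = TRUE)
}

#' Remove blocklisted ligand codes
#'
#' Drops records whose ligand code is a known non-inhibitor
#' (nucleotide/ion/buffer/cryoprotectant). How the original cohort
#' separated genuine inhibitors from co-crystallised bystander ligands
#' is not recorded anywhere; this curated blocklist is a documented,
#' deterministic stand-in, not a reconstruction of that step.
#'
#' @inheritParams filter_resolution
#' @param blocklist Character vector of ligand codes to exclude.
#' @return The filtered tibble.
#' @export
exclude_blocklist <- function(records, blocklist = default_ligand_blocklist()) {
  .check_pki_records(records)
  filter(as_tibble(records), !(toupper(.data$ligand_id) %in% toupper(blocklist)))
}

#' Run the full curation pipeline
#'
#' Resolution filter, blocklist exclusion, then one-kinase-per-ligand
#' deduplication. The pipeline is idempotent.
#'
#' @inheritParams filter_resolution
#' @inheritParams exclude_blocklist
#' @return A curated tibble.
#' @export
curate_records <- function(records, cutoff = 2.5,
                           blocklist = default_ligand_blocklist()) {
  records |>
    filter_resolution(cutoff = cutoff) |>
    exclude_blocklist(blocklist = blocklist) |>
    deduplicate_ligands()
}

#' Read a curation metadata table
#'
#' CSV with columns `ligand_name`, `ligand_id`, `kinase_name`, `pdb_id`,
#' `resolution` (Angstrom), mirroring the per-complex bookkeeping schema
#' used for kinase-inhibitor cohorts.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_pki_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  .check_pki_records(rec)
  rec
}
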