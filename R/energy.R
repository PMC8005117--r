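#' Gas-phase supermolecular interaction energy
#'
#' The interaction energy of a dimer AB is the dimer energy minus the
#' monomer energies: E_AB - E_A - E_B (kcal/mol).
#'
#' @param e_ab,e_a,e_b Gas-phase energies in kcal/mol. Vectorised.
#' @return kcal/mol.
#' @export
gas_interaction <- function(e_ab, e_a, e_b) {
  if (any(!is.finite(c(e_ab, e_a, e_b)))) abort("energies must be finite")
  e_ab - e_a - e_b
}

#' Dehydration energy of complex formation
#'
#' The solvation free energy lost on binding: dG_sol(AB) - dG_sol(A) -
#' dG_sol(B) (kcal/mol). Typically positive - both partners shed part of
#' their solvation shell.
#'
#' @param dg_ab,dg_a,dg_b Solvation free energies in kcal/mol. Vectorised.
#' @return kcal/mol.
#' @export
dehydration <- function(dg_ab, dg_a, dg_b) {
  if (any(!is.finite(c(dg_ab, dg_a, dg_b)))) abort("energies must be finite")
  dg_ab - dg_a - dg_b
}

#' Aqueous-phase interaction energy
#'
#' Thermodynamic-cycle sum: the aqueous interaction energy is the
#' gas-phase interaction energy plus the dehydration penalty.
#'
#' @param de_gas Gas-phase interaction energy (kcal/mol).
#' @param de_deh Dehydration energy (kcal/mol).
#' @return kcal/mol. Vectorised.
#' @examples
#' aqueous_interaction(-4.1, 3.8)  # -0.3
#' @export
aqueous_interaction <- function(de_gas, de_deh) {
  if (any(!is.finite(c(de_gas, de_deh)))) abort("energies must be finite")
  de_gas + de_deh
}

# recognised mode tags in ledger files (case/dash/greek tolerant)
.normalise_mode_tag <- function(tag) {
  t <- tolower(gsub("[–—]", "-", trimws(tag)))
  t <- gsub("π", "pi", t)
  map <- c(
    "h-bond" = "HBOND", "hbond" = "HBOND", "hydrogen bond" = "HBOND",
    "salt bridge" = "SALT_BRIDGE", "salt-bridge" = "SALT_BRIDGE",
    "pi-pi" = "PI_PI", "pipi" = "PI_PI",
    "ch-pi" = "CH_PI", "cation-pi" = "CATION_PI",
    "nh-pi" = "NH_PI", "oh-pi" = "OH_PI", "sh-pi" = "SH_PI"
  )
  out <- map[t]
  if (anyNA(out)) {
    abort(paste0("unrecognised interaction mode tag(s): ",
                 paste(unique(tag[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' Read a per-residue energy ledger
#'
#' CSV with columns `residue`, `modes` (comma-separated mode tags such as
#' `"H-bond, CH-pi"`), `dE_gas`, `dE_deh` and optionally `dE_aq`
#' (kcal/mol). When `dE_aq` is absent it is recomputed from the cycle sum.
#'
#' @param path CSV path.
#' @return A tibble `residue`, `modes`, `dE_gas`, `dE_deh`, `dE_aq`.
#' @export
read_energy_ledger <- function(path) {
  led <- readr::read_csv(path, show_col_types = FALSE)
  need <- setdiff(c("residue", "modes", "dE_gas", "dE_deh"), names(led))
  if (length(need)) {
    abort(paste0("energy ledger lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (!"dE_aq" %in% names(led)) {
    led$dE_aq <- aqueous_interaction(led$dE_gas, led$dE_deh)
  }
  select(led, "residue", "modes", "dE_gas", "dE_deh", "dE_aq")
}

#' The ibrutinib-BTK per-residue energy ledger
#'
#' Transcription of the published pair-wise interaction energies between
#' ibrutinib and the 11 binding-pocket residues of tyrosine kinase BTK
#' (gas-phase supermolecular energies, dehydration penalties and their
#' aqueous-phase sums, kcal/mol), shipped with the package as a worked
#' example and validation input.
#'
#' @return The ledger tibble (see [read_energy_ledger()]).
#' @export
ibrutinib_btk_ledger <- function() {
  read_energy_ledger(
    system.file("extdata", "ibrutinib_btk_ledger.csv",
                package = "pkiprofiler", mustWork = TRUE)
  )
}

#' Validate thermodynamic-cycle additivity of a ledger
#'
#' Flags rows where `dE_aq` differs from `dE_gas + dE_deh` by more than
#' `tol`. The default 0.15 kcal/mol absorbs the worst-case accumulation
#' of two addends independently rounded to one decimal.
#'
#' @param ledger A ledger tibble (see [read_energy_ledger()]).
#' @param tol Additivity tolerance in kcal/mol (default 0.15).
#' @return The ledger with `residual` and `flagged` columns appended.
#' @export
validate_ledger <- function(ledger, tol = 0.15) {
  need <- setdiff(c("residue", "dE_gas", "dE_deh", "dE_aq"), names(ledger))
  if (length(need)) {
    abort(paste0("energy ledger lacks column(s): ", paste(need, collapse = ", ")))
  }
  as_tibble(ledger) |>
    mutate(
      residual = .data$dE_aq - (.data$dE_gas + .data$dE_deh),
      flagged = abs(.data$residual) > tol + 1e-9
    )
}

#' Combine per-residue energies by interaction-mode group
#'
#' Residues whose mode tags include a hydrogen bond (or salt bridge) form
#' the polar `hydrogen_bonding` group; every remaining residue with
#' pi-originated tags (pi-pi, CH-pi, cation-pi, NH/OH/SH-pi) forms the
#' `nonbonded_pi` group. Combined energies are exact sums of the member
#' aqueous-phase energies. A residue with no recognised tag is an error.
#'
#' @param ledger A ledger tibble (see [read_energy_ledger()]).
#' @return A tibble `group`, `residues`, `n_residues`, `combined_energy`.
#' @export
group_by_mode <- function(ledger) {
  if (!nrow(ledger)) abort("cannot group an empty ledger")
  need <- setdiff(c("residue", "modes", "dE_aq"), names(ledger))
  if (length(need)) {
    abort(paste0("energy ledger lacks column(s): ", paste(need, collapse = ", ")))
  }
  tags <- map(strsplit(ledger$modes, "[,;]"), function(x) {
    x <- x[nzchar(trimws(x))]
    if (!length(x)) {
      abort("ledger row with empty mode tags")
    }
    .normalise_mode_tag(x)
  })
  polar <- map_lgl(tags, function(t) any(t %in% c("HBOND", "SALT_BRIDGE")))
  grp <- ifelse(polar, "hydrogen_bonding", "nonbonded_pi")
  as_tibble(ledger) |>
    mutate(group = factor(grp, levels = c("hydrogen_bonding", "nonbonded_pi"))) |>
    group_by(.data$group) |>
    summarise(
      residues = paste(.data$residue, collapse = ", "),
      n_residues = n(),
      combined_energy = sum(.data$dE_aq),
      .groups = "drop"
    )
}
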