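.ensure_outdir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

.log_msg <- function(verbose, ...) {
  if (verbose) message(...)
  invisible(NULL)
}

#' Profile ligands: descriptors + drug-likeness compliance
#'
#' Reads a SMILES/SDF file (or takes a parsed ligand table), computes the
#' descriptor set per ligand, evaluates Ro5/Veber compliance and writes
#' `descriptors.csv`, `compliance.csv` and `summary.csv`. Outputs are
#' deterministic: rerunning on the same input yields byte-identical files.
#'
#' @param input Path to a SMILES/SDF file, or a tibble with a `mol`
#'   list-column, or a precomputed descriptor tibble.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param config A [descriptor_config()].
#' @param tpsa_strict Passed to [evaluate_compliance()].
#' @param verbose Log a cohort summary to stderr.
#' @return Invisibly, a list with `descriptors`, `compliance`, `summary`.
#' @export
run_profile <- function(input, out_dir = NULL, config = descriptor_config(),
                        tpsa_strict = TRUE, verbose = TRUE) {
  desc <- if (is.data.frame(input) && !("mol" %in% names(input)) &&
              all(c("MW", "nHDon") %in% names(input))) {
    as_tibble(input)
  } else {
    profile_ligands(input, config)
  }
  if (!nrow(desc)) abort("no ligands to profile")
  comp <- evaluate_compliance(desc, tpsa_strict = tpsa_strict)
  summ <- summarize_cohort(desc, tpsa_strict = tpsa_strict)
  .log_msg(verbose, sprintf(
    "profiled %d ligand(s): %.1f%% Ro5-compliant, %.1f%% Veber-compliant",
    nrow(comp), 100 * mean(comp$ro5_ok), 100 * mean(comp$veber_ok)
  ))
  if (!is.null(out_dir)) {
    .ensure_outdir(out_dir)
    readr::write_csv(desc, file.path(out_dir, "descriptors.csv"))
    readr::write_csv(comp, file.path(out_dir, "compliance.csv"))
    readr::write_csv(summ, file.path(out_dir, "summary.csv"))
  }
  invisible(list(descriptors = desc, compliance = comp, summary = summ))
}

#' Ring-class table and exchange-line fit for a cohort
#'
#' Takes a per-ligand table (or CSV) with `nAR` and `WHBC` columns, bins
#' it into ring classes, fits the exchange line and writes
#' `ring_classes.csv` and `exchange_line.json` (+ `exchange_plot.pdf`
#' when `plot = TRUE`).
#'
#' @param input Data frame or CSV path with `nAR` and `WHBC` columns.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param scheme Binning scheme, see [assign_ring_class()].
#' @param x_five_plus,include_zero_class,weighted Passed to
#'   [fit_exchange_line()].
#' @param plot Also write the trend plot (default FALSE).
#' @param verbose Log the slope sign to stderr.
#' @return Invisibly, a list with `classes` and `fit`.
#' @export
run_exchange <- function(input, out_dir = NULL, scheme = "table",
                         x_five_plus = 5, include_zero_class = FALSE,
                         weighted = FALSE, plot = FALSE, verbose = TRUE) {
  dat <- if (is.character(input)) {
    readr::read_csv(input, show_col_types = FALSE)
  } else {
    as_tibble(input)
  }
  need <- setdiff(c("nAR", "WHBC"), names(dat))
  if (length(need)) {
    abort(paste0("exchange input lacks column(s): ", paste(need, collapse = ", ")))
  }
  classes <- class_distribution(dat, scheme = scheme)
  fit <- fit_exchange_line(classes, x_five_plus = x_five_plus,
                           include_zero_class = include_zero_class,
                           weighted = weighted)
  .log_msg(verbose, sprintf(
    "exchange line over %d classes: slope %+.4f WHBC/ring (%s), r^2 = %.3f",
    nrow(fit$data), fit$slope,
    if (fit$slope < 0) "inverse relationship" else "no inverse relationship",
    fit$r_squared
  ))
  if (!is.null(out_dir)) {
    .ensure_outdir(out_dir)
    readr::write_csv(classes, file.path(out_dir, "ring_classes.csv"))
    jsonlite::write_json(
      list(slope = fit$slope, intercept = fit$intercept,
           r_squared = fit$r_squared,
           class_x_values = as.list(fit$class_x_values)),
      file.path(out_dir, "exchange_line.json"),
      auto_unbox = TRUE, digits = NA
    )
    if (plot) {
      ggplot2::ggsave(file.path(out_dir, "exchange_plot.pdf"),
                      autoplot(fit), width = 5, height = 4)
    }
  }
  invisible(list(classes = classes, fit = fit))
}

#' Interaction map of a protein-ligand complex
#'
#' Loads a PDB complex, detects all non-bonded interaction modes and
#' writes `contacts.csv` and `contacts.json`.
#'
#' @param pdb PDB file path or text.
#' @param ligand_code Chemical component code of the ligand.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param chain Optional chain restriction.
#' @param crit A [geometry_criteria()].
#' @param verbose Log per-mode counts to stderr.
#' @return Invisibly, the `interaction_map` tibble.
#' @export
run_contacts <- function(pdb, ligand_code, out_dir = NULL, chain = NULL,
                         crit = geometry_criteria(), verbose = TRUE) {
  cx <- load_complex(pdb, ligand_code, chain = chain)
  res <- interaction_map(cx, crit)
  counts <- table(factor(res$mode, levels = .contact_modes))
  .log_msg(verbose, paste0(
    "contacts for ", cx$ligand_code, ": ",
    paste(sprintf("%s=%d", names(counts), counts), collapse = " ")
  ))
  if (!is.null(out_dir)) {
    .ensure_outdir(out_dir)
    readr::write_csv(res, file.path(out_dir, "contacts.csv"))
    jsonlite::write_json(res, file.path(out_dir, "contacts.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(res)
}

#' Validate and summarise an energy ledger
#'
#' Checks thermodynamic-cycle additivity per residue, aggregates
#' aqueous-phase energies by interaction-mode group and writes
#' `ledger_validation.csv` and `mode_groups.csv`.
#'
#' @param ledger Ledger tibble or CSV path (see [read_energy_ledger()]).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param tol Additivity tolerance (kcal/mol, default 0.15).
#' @param verbose Log group sums and flags to stderr.
#' @return Invisibly, a list with `validation` and `groups`.
#' @export
run_energetics <- function(ledger, out_dir = NULL, tol = 0.15,
                           verbose = TRUE) {
  led <- if (is.character(ledger)) read_energy_ledger(ledger) else as_tibble(ledger)
  val <- validate_ledger(led, tol = tol)
  grp <- group_by_mode(led)
  .log_msg(verbose, paste0(
    paste(sprintf("%s: %.1f kcal/mol (%d residues)", grp$group,
                  grp$combined_energy, grp$n_residues), collapse = "; "),
    "; ", sum(val$flagged), " additivity flag(s)"
  ))
  if (!is.null(out_dir)) {
    .ensure_outdir(out_dir)
    readr::write_csv(val, file.path(out_dir, "ledger_validation.csv"))
    readr::write_csv(grp, file.path(out_dir, "mode_groups.csv"))
  }
  invisible(list(validation = val, groups = grp))
}
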