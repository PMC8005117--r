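#' Evaluate Lipinski rule-of-five and Veber compliance
#'
#' Thresholds are strict as commonly quoted for kinase-inhibitor cohorts:
#' Ro5 requires MW < 500 Da, cLogP < 5, nHDon <= 5 and nHAcc <= 10;
#' Veber requires RBN <= 10, nHDon + nHAcc < 12 and TPSA < 140 A^2.
#' The original Veber publication used TPSA <= 140; set
#' `tpsa_strict = FALSE` to recover that reading.
#'
#' @param descriptors A tibble of per-ligand descriptors (from
#'   [profile_ligands()] or any table with columns `MW`, `cLogP`, `nHDon`,
#'   `nHAcc`, `RBN`, `TPSA`).
#' @param tpsa_strict Logical; `TRUE` (default) applies TPSA < 140.
#' @return The input with logical columns `mw_ok`, `clogp_ok`,
#'   `donors_ok`, `acceptors_ok`, `ro5_ok`, `rbn_ok`, `hb_total_ok`,
#'   `tpsa_ok`, `veber_ok` appended.
#' @examples
#' evaluate_compliance(tibble::tibble(
#'   MW = 390.29, cLogP = 2.58, nHDon = 2, nHAcc = 7, RBN = 5, TPSA = 94.06
#' ))
#' @export
evaluate_compliance <- function(descriptors, tpsa_strict = TRUE) {
  need <- c("MW", "cLogP", "nHDon", "nHAcc", "RBN", "TPSA")
  missing_cols <- setdiff(need, names(descriptors))
  if (length(missing_cols)) {
    abort(paste0("descriptor table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_tibble(descriptors) |>
    mutate(
      mw_ok = .data$MW < 500,
      clogp_ok = .data$cLogP < 5,
      donors_ok = .data$nHDon <= 5,
      acceptors_ok = .data$nHAcc <= 10,
      ro5_ok = .data$mw_ok & .data$clogp_ok & .data$donors_ok & .data$acceptors_ok,
      rbn_ok = .data$RBN <= 10,
      hb_total_ok = (.data$nHDon + .data$nHAcc) < 12,
      tpsa_ok = if (tpsa_strict) .data$TPSA < 140 else .data$TPSA <= 140,
      veber_ok = .data$rbn_ok & .data$hb_total_ok & .data$tpsa_ok
    )
}

#' Summarise a descriptor cohort
#'
#' Per-descriptor minimum, median, maximum, mean and SEM (standard error
#' of the mean; switchable to SD), plus the percentage of the cohort
#' passing the rule attached to each descriptor where one applies
#' (MW/cLogP/nHDon/nHAcc under Ro5; RBN/TPSA and the combined H-bond
#' count under Veber). Percentages are count-exact:
#' 100 x (number passing) / n.
#'
#' @param descriptors Per-ligand descriptor tibble.
#' @param spread `"sem"` (default) or `"sd"`.
#' @param tpsa_strict Passed to [evaluate_compliance()].
#' @return A tibble with one row per descriptor: `descriptor`, `min`,
#'   `median`, `max`, `mean`, `spread`, `pct_ro5`, `pct_veber`.
#' @export
summarize_cohort <- function(descriptors, spread = c("sem", "sd"),
                             tpsa_strict = TRUE) {
  spread <- match.arg(spread)
  if (!nrow(descriptors)) abort("cannot summarise an empty cohort")
  flags <- evaluate_compliance(descriptors, tpsa_strict = tpsa_strict)
  n <- nrow(flags)
  pct <- function(x) 100 * sum(x) / n

  cols <- intersect(
    c("MW", "nHDon", "nHAcc", "cLogP", "TPSA", "RBN", "ARR", "nAR",
      "Nsp3", "nSK", "Fsp3", "WHBC"),
    names(descriptors)
  )
  ro5_pct <- c(
    MW = pct(flags$mw_ok), nHDon = pct(flags$donors_ok),
    nHAcc = pct(flags$acceptors_ok), cLogP = pct(flags$clogp_ok)
  )
  veber_pct <- c(
    TPSA = pct(flags$tpsa_ok), RBN = pct(flags$rbn_ok),
    nHDon = pct(flags$hb_total_ok)
  )
  purrr::map(cols, function(cn) {
    x <- descriptors[[cn]]
    s <- if (n >= 2) stats::sd(x) else 0
    tibble(
      descriptor = cn,
      min = min(x), median = stats::median(x), max = max(x), mean = mean(x),
      spread = if (spread == "sem") s / sqrt(n) else s,
      pct_ro5 = unname(ro5_pct[cn])[1] %||% NA_real_,
      pct_veber = unname(veber_pct[cn])[1] %||% NA_real_
    )
  }) |>
    bind_rows()
}
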