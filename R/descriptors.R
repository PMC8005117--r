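#' Descriptor rule configuration
#'
#' The donor/acceptor counting rules and the aromatic-ratio definition are
#' configurable because the tools that popularised these descriptors do not
#' publish their exact perception rules. Two acceptor modes are provided:
#' `"exclusions"` (default) counts every N and O except pyrrole-type
#' aromatic N (the lone pair is part of the ring pi system), amide N and
#' nitro/aromatic O; `"all_no"` counts every N and O.
#'
#' @param donor_rule `"no_h"` (N or O bearing at least one H, default) or
#'   `"nos_h"` (also counts S-H thiols).
#' @param acceptor_rule `"exclusions"` (default) or `"all_no"`.
#' @param arr_rule `"atoms"` (aromatic heavy atoms / heavy atoms, default)
#'   or `"bonds"` (aromatic bonds / heavy-atom bonds).
#' @return A list of class `descriptor_config`.
#' @export
descriptor_config <- function(donor_rule = c("no_h", "nos_h"),
                              acceptor_rule = c("exclusions", "all_no"),
                              arr_rule = c("atoms", "bonds")) {
  structure(
    list(
      donor_rule = match.arg(donor_rule),
      acceptor_rule = match.arg(acceptor_rule),
      arr_rule = match.arg(arr_rule)
    ),
    class = "descriptor_config"
  )
}

#' Count hydrogen-bond donor atoms
#'
#' A donor is an N or O atom carrying at least one hydrogen (explicit or
#' implicit). With `donor_rule = "nos_h"`, S-H thiols count too.
#'
#' @param mol A `molecule_graph`.
#' @param config A [descriptor_config()].
#' @return Integer count.
#' @export
count_hbond_donors <- function(mol, config = descriptor_config()) {
  stopifnot(inherits(mol, "molecule_graph"))
  el <- if (config$donor_rule == "nos_h") c("N", "O", "S") else c("N", "O")
  sum(mol$atoms$element %in% el & mol$atoms$n_h >= 1)
}

#' Count hydrogen-bond acceptor atoms
#'
#' Under the default `"exclusions"` rule every N and O counts except:
#' pyrrole-type aromatic N (an aromatic N whose lone pair sits in the ring
#' pi system, i.e. an aromatic N bearing an H or with three heavy
#' neighbours), amide N (N single-bonded to a carbonyl or thiocarbonyl C),
#' nitro-group O, and aromatic O (furan-type). The `"all_no"` rule counts
#' every N and O.
#'
#' @inheritParams count_hbond_donors
#' @return Integer count.
#' @export
count_hbond_acceptors <- function(mol, config = descriptor_config()) {
  stopifnot(inherits(mol, "molecule_graph"))
  at <- mol$atoms
  is_no <- at$element %in% c("N", "O")
  if (config$acceptor_rule == "all_no") return(sum(is_no))

  n <- nrow(at)
  deg_heavy <- integer(n)
  for (b in seq_len(nrow(mol$bonds))) {
    deg_heavy[mol$bonds$a1[b]] <- deg_heavy[mol$bonds$a1[b]] + 1L
    deg_heavy[mol$bonds$a2[b]] <- deg_heavy[mol$bonds$a2[b]] + 1L
  }
  neighbours <- function(i) {
    b <- mol$bonds
    c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  }
  bond_order <- function(i, j) {
    b <- mol$bonds
    o <- b$order[(b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i)]
    if (length(o)) o[1] else 0L
  }
  is_carbonyl_c <- vapply(seq_len(n), function(i) {
    if (at$element[i] != "C") return(FALSE)
    any(vapply(neighbours(i), function(j) {
      at$element[j] %in% c("O", "S") && bond_order(i, j) == 2
    }, logical(1)))
  }, logical(1))
  is_nitro_n <- vapply(seq_len(n), function(i) {
    if (at$element[i] != "N") return(FALSE)
    nb <- neighbours(i)
    o_nb <- nb[at$element[nb] == "O"]
    length(o_nb) >= 2 && any(vapply(o_nb, function(j) bond_order(i, j) == 2, logical(1)))
  }, logical(1))

  ok <- logical(n)
  for (i in seq_len(n)) {
    e <- at$element[i]
    if (e == "N") {
      if (is_nitro_n[i]) next
      if (at$aromatic[i] && (at$n_h[i] >= 1 || deg_heavy[i] >= 3)) next  # pyrrole-type
      if (!at$aromatic[i] && any(is_carbonyl_c[neighbours(i)] &
            vapply(neighbours(i), function(j) bond_order(i, j) == 1, logical(1)))) {
        next  # amide N
      }
      ok[i] <- TRUE
    } else if (e == "O") {
      if (at$aromatic[i]) next  # furan-type O
      nb <- neighbours(i)
      if (any(is_nitro_n[nb])) next  # nitro O
      ok[i] <- TRUE
    }
  }
  sum(ok)
}

#' Count aromatic rings
#'
#' Number of SSSR rings whose atoms are all aromatic; each constituent
#' ring of a fused system counts separately.
#'
#' @param mol A `molecule_graph`.
#' @return Integer count.
#' @export
count_aromatic_rings <- function(mol) {
  stopifnot(inherits(mol, "molecule_graph"))
  sum(mol$ring_aromatic)
}

#' Fraction of sp3-hybridised carbons
#'
#' Fsp3 = Nsp3 / nC, the count of carbons with four single bonds divided
#' by the total carbon count. Low values mark "flat", aromatic-dominated
#' molecules. Always in \[0, 1\].
#'
#' @param mol A `molecule_graph`.
#' @return A double in \[0, 1\].
#' @export
fraction_sp3 <- function(mol) {
  stopifnot(inherits(mol, "molecule_graph"))
  n_c <- sum(mol$atoms$element == "C")
  if (n_c == 0) abort("fraction_sp3 is undefined for a molecule with no carbon atoms")
  .count_sp3(mol) / n_c
}

.count_sp3 <- function(mol) {
  at <- mol$atoms
  unsat <- logical(nrow(at))
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] >= 2 || mol$bonds$order[b] == 4) {
      unsat[c(mol$bonds$a1[b], mol$bonds$a2[b])] <- TRUE
    }
  }
  sum(at$element == "C" & !at$aromatic & !unsat)
}

#' Weighted hydrogen bond count
#'
#' WHBC = (nHDon + nHAcc) / nSK: combined donor and acceptor atom counts
#' normalised by the number of heavy atoms. A size-independent measure of
#' a ligand's hydrogen-bonding capacity.
#'
#' @param nHDon,nHAcc,nSK Non-negative counts; `nSK` must be >= 1.
#' @return A double >= 0. Vectorised.
#' @examples
#' weighted_hbond_count(2, 7, 27)
#' @export
weighted_hbond_count <- function(nHDon, nHAcc, nSK) {
  if (any(nSK < 1)) abort("nSK must be >= 1 to compute WHBC")
  if (any(nHDon < 0) || any(nHAcc < 0)) abort("donor/acceptor counts must be >= 0")
  (nHDon + nHAcc) / nSK
}

.count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  at <- mol$atoms
  n <- nrow(at)
  deg_heavy <- integer(n)
  for (k in seq_len(nrow(b))) {
    deg_heavy[b$a1[k]] <- deg_heavy[b$a1[k]] + 1L
    deg_heavy[b$a2[k]] <- deg_heavy[b$a2[k]] + 1L
  }
  is_carbonyl_c <- vapply(seq_len(n), function(i) {
    if (at$element[i] != "C") return(FALSE)
    any((b$a1 == i & at$element[b$a2] == "O" & b$order == 2) |
        (b$a2 == i & at$element[b$a1] == "O" & b$order == 2))
  }, logical(1))
  rot <- b$order == 1 & !b$in_ring &
    deg_heavy[b$a1] >= 2 & deg_heavy[b$a2] >= 2 &
    # amide C-N bonds are not rotatable
    !((is_carbonyl_c[b$a1] & at$element[b$a2] == "N") |
      (is_carbonyl_c[b$a2] & at$element[b$a1] == "N"))
  sum(rot)
}

.molecular_weight <- function(mol) {
  at <- mol$atoms
  w <- .atomic_weights[at$element]
  if (anyNA(w)) {
    warn(paste0(
      "unknown element(s) ", paste(unique(at$element[is.na(w)]), collapse = ", "),
      " ignored in molecular weight"
    ))
    w[is.na(w)] <- 0
  }
  sum(w) + sum(at$n_h) * .atomic_weights[["H"]]
}

#' Compute the full descriptor set for one molecule
#'
#' Returns the standard kinase-inhibitor profiling descriptor vector:
#' molecular weight (Da), H-bond donor/acceptor counts, heavy-atom count
#' (nSK), sp3-carbon count (Nsp3), carbon count (nC), rotatable-bond count
#' (RBN), aromatic ratio (ARR), cLogP (Wildman-Crippen atomic
#' contributions via OpenBabel), TPSA (Ertl fragment contributions, A^2),
#' aromatic ring count (nAR), plus the derived Fsp3 and WHBC.
#'
#' @param mol A `molecule_graph`.
#' @param config A [descriptor_config()].
#' @return A one-row tibble.
#' @export
compute_descriptors <- function(mol, config = descriptor_config()) {
  stopifnot(inherits(mol, "molecule_graph"))
  at <- mol$atoms
  nSK <- nrow(at)
  nC <- sum(at$element == "C")
  nHDon <- count_hbond_donors(mol, config)
  nHAcc <- count_hbond_acceptors(mol, config)
  nAR <- count_aromatic_rings(mol)
  Nsp3 <- .count_sp3(mol)
  arr <- if (config$arr_rule == "atoms") {
    sum(at$aromatic) / nSK
  } else {
    if (nrow(mol$bonds)) sum(mol$bonds$aromatic) / nrow(mol$bonds) else 0
  }
  ob <- .propob_one(mol)
  tibble(
    id = mol$name %||% NA_character_,
    MW = .molecular_weight(mol),
    nHDon = nHDon,
    nHAcc = nHAcc,
    nSK = nSK,
    Nsp3 = Nsp3,
    nC = nC,
    RBN = .count_rotatable_bonds(mol),
    ARR = arr,
    cLogP = ob$logP,
    TPSA = ob$TPSA,
    nAR = nAR,
    Fsp3 = if (nC > 0) Nsp3 / nC else NA_real_,
    WHBC = weighted_hbond_count(nHDon, nHAcc, nSK)
  )
}

# cLogP + TPSA through OpenBabel for one stored SDF record
.propob_one <- function(mol) {
  txt <- mol$sdf_text
  if (!grepl("\\$\\$\\$\\$", txt)) txt <- paste0(txt, "\n$$$$\n")
  p <- ChemmineOB::forEachMol("SDF", txt, function(m) ChemmineOB::prop_OB(m))[[1]]
  list(logP = p[["logP"]], TPSA = p[["TPSA"]])
}

#' Profile a ligand table
#'
#' Computes the descriptor set for every ligand in a table (as returned by
#' [read_ligands()]) or in a SMILES/SDF file. This is the tabular entry
#' point of the profiling pipeline; the per-ligand output feeds
#' [evaluate_compliance()], [summarize_cohort()] and [class_distribution()].
#'
#' @param ligands A tibble with a `mol` list-column (and optionally `id`),
#'   or a path to a SMILES/SDF file.
#' @param config A [descriptor_config()].
#' @return A tibble with one row per ligand and the columns of
#'   [compute_descriptors()].
#' @export
profile_ligands <- function(ligands, config = descriptor_config()) {
  if (is.character(ligands) && length(ligands) == 1) {
    ligands <- read_ligands(ligands)
  }
  stopifnot(is.data.frame(ligands), "mol" %in% names(ligands))
  out <- map(seq_len(nrow(ligands)), function(i) {
    d <- compute_descriptors(ligands$mol[[i]], config)
    if ("id" %in% names(ligands)) d$id <- ligands$id[i]
    d
  })
  bind_rows(out)
}
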