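#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across all_of rename distinct slice pull
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map_chr imap pmap keep
NULL

# standard atomic weights for the elements that occur in drug-like molecules
.atomic_weights <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Se = 78.971,
  Br = 79.904, I = 126.904
)

# lowest standard valence per element; S and P may expand (see .effective_valence)
.base_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Se = 2, Br = 1, I = 1
)

.effective_valence <- function(element, charge, bond_sum) {
  base <- .base_valence[[element]] %||% 0
  if (element %in% c("S", "P", "Se")) {
    # hypervalent states (sulfone, sulfoxide, phosphate)
    for (v in c(base, base + 2, base + 4)) {
      if (v >= ceiling(bond_sum - charge)) {
        base <- v
        break
      }
    }
  }
  if (element %in% c("N", "O", "P", "S", "Se")) base + charge
  else if (element == "C") base - abs(charge)
  else base
}

#' Parse a ligand structure into a molecule graph
#'
#' Accepts a SMILES string or a single V2000 SDF record and returns a
#' `molecule_graph`: the heavy-atom graph with perceived aromaticity
#' (Hueckel 4n+2 rule over the smallest set of smallest rings), attached
#' hydrogen counts (explicit hydrogens are collapsed onto their heavy
#' neighbours, implicit hydrogens filled from a standard valence model),
#' ring membership, and 3D coordinates when the SDF record carries them.
#' SMILES are converted to a kekulised SDF record with OpenBabel before
#' graph construction, so aromaticity perception always operates on
#' integer bond orders.
#'
#' @param text A SMILES string, or the text of a single SDF (V2000) record.
#' @param name Optional molecule name; defaults to the SMILES title field
#'   or the SDF header line.
#' @param format `"auto"` (default), `"smiles"` or `"sdf"`. Auto-detection
#'   treats multi-line text containing a V2000 counts line as SDF.
#' @return An object of class `molecule_graph` with elements `name`,
#'   `atoms` (tibble: `element`, `charge`, `n_h`, `aromatic`, `in_ring`),
#'   `bonds` (tibble: `a1`, `a2`, `order`, `aromatic`, `in_ring`),
#'   `rings` (list of atom-index vectors, SSSR), `ring_aromatic`
#'   (logical per ring), `coords3d` (matrix or `NULL`) and `sdf_text`.
#' @examples
#' mol <- parse_ligand("c1ccccc1", name = "benzene")
#' count_aromatic_rings(mol)
#' @export
parse_ligand <- function(text, name = NULL, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  stopifnot(is.character(text), length(text) >= 1)
  text <- paste(text, collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("V2000", text)) "sdf" else "smiles"
  }
  if (format == "smiles") {
    smi <- trimws(text)
    if (!nzchar(smi) || grepl("\n", smi)) {
      abort("expected a single SMILES record")
    }
    label <- name %||% smi
    sdf_text <- .smiles_to_sdf(smi, label)
  } else {
    n_rec <- lengths(regmatches(text, gregexpr("\\$\\$\\$\\$", text)))
    body <- sub("\\$\\$\\$\\$[[:space:]]*$", "", text)
    if (n_rec > 1 || grepl("\\$\\$\\$\\$", body)) {
      abort("multi-record SDF passed to the single-molecule parser; split it first")
    }
    sdf_text <- text
  }
  .mol_from_sdf_text(sdf_text, name = name)
}

.smiles_to_sdf <- function(smiles, label) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, " ", label, "\n")
    )),
    error = function(e) ""
  )
  if (!nzchar(out) || !grepl("V2000", out)) {
    abort(paste0("could not parse SMILES record: '", smiles, "'"))
  }
  out
}

# Build a molecule_graph from one V2000 SDF record.
.mol_from_sdf_text <- function(sdf_text, name = NULL) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  counts_idx <- grep("V2000", lines)[1]
  if (is.na(counts_idx)) abort("no V2000 counts line found in SDF record")
  n_atoms <- as.integer(substr(lines[counts_idx], 1, 3))
  n_bonds <- as.integer(substr(lines[counts_idx], 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) abort("empty or malformed SDF atom block")

  atom_lines <- lines[(counts_idx + 1):(counts_idx + n_atoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  xyz <- matrix(
    as.numeric(c(
      substr(atom_lines, 1, 10), substr(atom_lines, 11, 20),
      substr(atom_lines, 21, 30)
    )),
    ncol = 3
  )
  if (n_bonds > 0) {
    bond_lines <- lines[(counts_idx + n_atoms + 1):(counts_idx + n_atoms + n_bonds)]
    bonds <- tibble(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  if (nrow(bonds) && (any(bonds$a1 > n_atoms) || any(bonds$a2 > n_atoms))) {
    abort("SDF bond block references atoms outside the atom block")
  }

  # formal charges live on M  CHG lines (ChemmineR drops these, so read raw)
  charge <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    k <- f[1]
    for (i in seq_len(k)) {
      charge[f[2 * i]] <- f[2 * i + 1]
    }
  }

  if (is.null(name)) {
    hdr <- trimws(lines[1])
    name <- if (nzchar(hdr)) hdr else NA_character_
  }

  # collapse explicit hydrogens onto heavy neighbours
  is_h <- element == "H"
  n_h_expl <- integer(n_atoms)
  if (any(is_h)) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (is_h[a1] && !is_h[a2]) n_h_expl[a2] <- n_h_expl[a2] + 1L
      if (is_h[a2] && !is_h[a1]) n_h_expl[a1] <- n_h_expl[a1] + 1L
    }
  }
  keep_idx <- which(!is_h)
  remap <- integer(n_atoms)
  remap[keep_idx] <- seq_along(keep_idx)
  bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  element <- element[keep_idx]
  charge <- charge[keep_idx]
  n_h_expl <- n_h_expl[keep_idx]
  xyz <- xyz[keep_idx, , drop = FALSE]
  n <- length(element)

  # bond-order sum per heavy atom; order 4 (rare aromatic-typed input) as 1.5
  ord_num <- ifelse(bonds$order == 4, 1.5, as.numeric(bonds$order))
  bond_sum <- numeric(n)
  for (b in seq_len(nrow(bonds))) {
    bond_sum[bonds$a1[b]] <- bond_sum[bonds$a1[b]] + ord_num[b]
    bond_sum[bonds$a2[b]] <- bond_sum[bonds$a2[b]] + ord_num[b]
  }
  bond_sum <- bond_sum + n_h_expl

  n_h_impl <- vapply(seq_len(n), function(i) {
    v <- .effective_valence(element[i], charge[i], bond_sum[i])
    max(0, round(v - bond_sum[i]))
  }, numeric(1))
  n_h <- as.integer(n_h_expl + n_h_impl)

  rings <- .sssr(n, bonds)
  arom <- .perceive_aromaticity(element, charge, n_h, bonds, rings)

  in_ring_atom <- logical(n)
  for (r in rings) in_ring_atom[r] <- TRUE
  ring_bond <- .ring_bond_flags(bonds, rings)

  has_coords <- nrow(xyz) > 0 && any(abs(xyz[, 3]) > 1e-8)

  structure(
    list(
      name = name,
      atoms = tibble(
        element = element, charge = charge, n_h = n_h,
        aromatic = arom$atom, in_ring = in_ring_atom
      ),
      bonds = mutate(bonds, aromatic = arom$bond, in_ring = ring_bond),
      rings = rings,
      ring_aromatic = arom$ring,
      coords3d = if (has_coords) xyz else NULL,
      sdf_text = sdf_text
    ),
    class = "molecule_graph"
  )
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(
    "<molecule_graph>", if (!is.na(x$name %||% NA)) x$name else "", "\n",
    " ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds, ",
    length(x$rings), " rings (", sum(x$ring_aromatic), " aromatic)",
    if (!is.null(x$coords3d)) ", 3D coordinates" else "", "\n",
    sep = ""
  )
  invisible(x)
}

# ---- ring perception -------------------------------------------------------

# Smallest set of smallest rings: shortest cycle through every ring bond,
# greedily kept while linearly independent over GF(2) in edge space.
.sssr <- function(n_atoms, bonds) {
  m <- nrow(bonds)
  if (m == 0) return(list())
  adj <- vector("list", n_atoms)
  for (b in seq_len(m)) {
    adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], b)
    adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], b)
  }
  other_end <- function(b, a) if (bonds$a1[b] == a) bonds$a2[b] else bonds$a1[b]

  comp <- integer(n_atoms)
  cid <- 0
  for (s in seq_len(n_atoms)) {
    if (comp[s] == 0) {
      cid <- cid + 1
      queue <- s; comp[s] <- cid
      while (length(queue)) {
        a <- queue[1]; queue <- queue[-1]
        for (b in adj[[a]]) {
          nb <- other_end(b, a)
          if (comp[nb] == 0) { comp[nb] <- cid; queue <- c(queue, nb) }
        }
      }
    }
  }
  n_rings_target <- m - n_atoms + cid
  if (n_rings_target <= 0) return(list())

  # shortest cycle through each bond (BFS excluding the bond itself)
  candidates <- list()
  for (b in seq_len(m)) {
    src <- bonds$a1[b]; dst <- bonds$a2[b]
    prev_atom <- integer(n_atoms); prev_bond <- integer(n_atoms)
    seen <- logical(n_atoms); seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) && !found) {
      a <- queue[1]; queue <- queue[-1]
      for (bb in adj[[a]]) {
        if (bb == b) next
        nb <- other_end(bb, a)
        if (!seen[nb]) {
          seen[nb] <- TRUE; prev_atom[nb] <- a; prev_bond[nb] <- bb
          if (nb == dst) { found <- TRUE; break }
          queue <- c(queue, nb)
        }
      }
    }
    if (found) {
      path <- dst; eb <- integer()
      a <- dst
      while (a != src) { eb <- c(eb, prev_bond[a]); a <- prev_atom[a]; path <- c(path, a) }
      candidates[[length(candidates) + 1]] <- list(atoms = path, edges = sort(c(eb, b)))
    }
  }
  if (!length(candidates)) return(list())
  candidates <- candidates[!duplicated(map(candidates, "edges"))]
  candidates <- candidates[order(lengths(map(candidates, "atoms")))]

  basis <- matrix(FALSE, nrow = 0, ncol = m)
  rings <- list()
  for (cand in candidates) {
    v <- logical(m); v[cand$edges] <- TRUE
    w <- v
    for (r in seq_len(nrow(basis))) {
      pivot <- which(basis[r, ])[1]
      if (w[pivot]) w <- xor(w, basis[r, ])
    }
    if (any(w)) {
      basis <- rbind(basis, w)
      # keep pivot order: re-sort rows by pivot for stable elimination
      basis <- basis[order(apply(basis, 1, function(z) which(z)[1])), , drop = FALSE]
      rings[[length(rings) + 1]] <- sort(unique(cand$atoms))
    }
    if (length(rings) == n_rings_target) break
  }
  rings
}

.ring_bond_flags <- function(bonds, rings) {
  if (!nrow(bonds)) return(logical(0))
  flag <- logical(nrow(bonds))
  for (r in rings) {
    in_r <- bonds$a1 %in% r & bonds$a2 %in% r
    flag <- flag | in_r
  }
  flag
}

# ---- aromaticity -----------------------------------------------------------

# Hueckel perception on the kekulised graph: a ring is aromatic when every
# member is sp2-capable and the pi-electron count satisfies 4n+2. Pyrrole-type
# N/O/S contribute a lone pair (2 electrons); atoms in an endocyclic double
# bond contribute 1; exocyclic-double-bond atoms (e.g. ring carbonyl C)
# contribute 0. Bonds typed aromatic (order 4) on input are honoured directly.
.perceive_aromaticity <- function(element, charge, n_h, bonds, rings) {
  n <- length(element)
  m <- nrow(bonds)
  atom_arom <- logical(n)
  bond_arom <- logical(m)
  ring_arom <- logical(length(rings))
  if (!length(rings)) return(list(atom = atom_arom, bond = bond_arom, ring = ring_arom))

  bond_idx <- function(a, b) {
    which((bonds$a1 == a & bonds$a2 == b) | (bonds$a1 == b & bonds$a2 == a))
  }
  dbl_partner <- vector("list", n)
  for (b in seq_len(m)) {
    if (bonds$order[b] == 2) {
      dbl_partner[[bonds$a1[b]]] <- c(dbl_partner[[bonds$a1[b]]], bonds$a2[b])
      dbl_partner[[bonds$a2[b]]] <- c(dbl_partner[[bonds$a2[b]]], bonds$a1[b])
    }
  }
  has_triple <- logical(n)
  for (b in seq_len(m)) {
    if (bonds$order[b] >= 3) has_triple[c(bonds$a1[b], bonds$a2[b])] <- TRUE
  }

  for (ri in seq_along(rings)) {
    r <- rings[[ri]]
    if (length(r) < 5 || length(r) > 7) next
    ring_bonds <- integer(0)
    ok <- TRUE
    # collect the ring's own bonds
    for (a in r) for (b2 in r) {
      if (a < b2) ring_bonds <- c(ring_bonds, bond_idx(a, b2))
    }
    ring_bonds <- unique(ring_bonds)
    if (length(ring_bonds) && all(bonds$order[ring_bonds] == 4)) {
      ring_arom[ri] <- TRUE
      atom_arom[r] <- TRUE
      bond_arom[ring_bonds] <- TRUE
      next
    }
    all_ring_atoms <- unique(unlist(rings))
    pi_e <- 0
    for (a in r) {
      if (has_triple[a]) { ok <- FALSE; break }
      dp <- dbl_partner[[a]]
      if (length(dp) && any(dp %in% r)) {
        pi_e <- pi_e + 1
      } else if (length(dp) && any(dp %in% all_ring_atoms)) {
        # kekule double bond into a fused ring still feeds the shared pi system
        pi_e <- pi_e + 1
      } else if (length(dp)) {
        # exocyclic double bond to a non-ring atom (e.g. carbonyl): sp2, 0 pi
        pi_e <- pi_e + 0
      } else if (element[a] %in% c("N", "O", "S", "Se") ||
                 (element[a] == "C" && charge[a] == -1)) {
        pi_e <- pi_e + 2
      } else {
        ok <- FALSE; break
      }
    }
    if (ok && pi_e %% 4 == 2) {
      ring_arom[ri] <- TRUE
      atom_arom[r] <- TRUE
      bond_arom[ring_bonds] <- TRUE
    }
  }
  list(atom = atom_arom, bond = bond_arom, ring = ring_arom)
}

#' Read a ligand table from a SMILES or SDF file
#'
#' SMILES files hold one record per line, optionally followed by a
#' tab- or space-separated identifier. SDF files may hold multiple
#' records separated by `$$$$`.
#'
#' @param path Path to a `.smi`/`.smiles` or `.sdf` file.
#' @param format `"auto"`, `"smiles"` or `"sdf"`.
#' @return A tibble with columns `id` and `mol` (list-column of
#'   `molecule_graph` objects).
#' @export
read_ligands <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) abort(paste0("no records in ", path))
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    tibble(
      id = map_chr(seq_along(parts), function(i) {
        if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("mol_", i)
      }),
      mol = map(seq_along(parts), function(i) {
        id <- if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("mol_", i)
        parse_ligand(parts[[i]][1], name = id, format = "smiles")
      })
    )
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    recs <- strsplit(txt, "\\$\\$\\$\\$[[:space:]]*\n?")[[1]]
    recs <- recs[grepl("V2000", recs)]
    if (!length(recs)) abort(paste0("no SDF records in ", path))
    mols <- map(recs, .mol_from_sdf_text)
    tibble(
      id = map_chr(seq_along(mols), function(i) {
        nm <- mols[[i]]$name
        if (is.na(nm %||% NA) || !nzchar(nm)) paste0("mol_", i) else nm
      }),
      mol = mols
    )
  }
}
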