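# covalent radii (A) for distance-based bond perception of ligands
.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Se = 1.2, Br = 1.2, I = 1.39
)

#' Geometric criteria for interaction detection
#'
#' All cutoffs are in Angstrom, all angles in degrees. The defaults are
#' literature-standard windows for each mode; none of them is dictated by
#' the underlying binding-mode taxonomy, which names the modes without
#' thresholds.
#'
#' @param site_cutoff Binding-site inclusion: residues with a heavy atom
#'   within this distance of any ligand heavy atom (default 4.5).
#' @param hbond_dist Donor-acceptor heavy-atom distance (default 3.5).
#' @param hbond_angle Minimum D-H...A angle, applied only when hydrogen
#'   coordinates are present (default 120).
#' @param salt_bridge_dist Charged N/O pair distance (default 4.0).
#' @param pipi_dist Ring-centroid distance for parallel stacking
#'   (default 5.5).
#' @param pipi_parallel_angle Maximum interplanar angle for the parallel
#'   class (default 30).
#' @param pipi_offset Maximum lateral offset for the parallel class
#'   (default 2.5).
#' @param pipi_tshape_dist Centroid distance for the T-shaped class
#'   (default 6.0).
#' @param pipi_tshape_angle Interplanar angle window for the T-shaped
#'   class (default c(60, 90)).
#' @param chpi_dist C-H carbon to ring-centroid distance (default 4.5).
#' @param catpi_dist Cationic N to ring-centroid distance (default 6.0).
#' @param xhpi_dist N/O/S-H donor to ring-centroid distance (default 4.5).
#' @param pi_min_height Minimum height above the ring plane for the
#'   point-to-ring modes (default 1.5).
#' @param pi_offset_pad Maximum lateral offset for point-to-ring modes is
#'   ring radius + this pad (default 1.0).
#' @param planarity_tol Maximum RMS deviation from the fitted plane for a
#'   ligand ring to count as an aromatic pi system (default 0.1).
#' @param his_cation Treat His ring nitrogens as cationic (default FALSE;
#'   protonation states are unknown in most depositions).
#' @return A list of class `geometry_criteria`.
#' @export
geometry_criteria <- function(site_cutoff = 4.5,
                              hbond_dist = 3.5,
                              hbond_angle = 120,
                              salt_bridge_dist = 4.0,
                              pipi_dist = 5.5,
                              pipi_parallel_angle = 30,
                              pipi_offset = 2.5,
                              pipi_tshape_dist = 6.0,
                              pipi_tshape_angle = c(60, 90),
                              chpi_dist = 4.5,
                              catpi_dist = 6.0,
                              xhpi_dist = 4.5,
                              pi_min_height = 1.5,
                              pi_offset_pad = 1.0,
                              planarity_tol = 0.1,
                              his_cation = FALSE) {
  crit <- as.list(environment())
  num <- unlist(crit[vapply(crit, is.numeric, logical(1))])
  if (any(num < 0)) abort("geometry criteria must be non-negative")
  if (length(crit$pipi_tshape_angle) != 2 ||
      crit$pipi_tshape_angle[1] > crit$pipi_tshape_angle[2] ||
      crit$pipi_tshape_angle[2] > 180) {
    abort("pipi_tshape_angle must be an increasing pair within [0, 180]")
  }
  structure(crit, class = "geometry_criteria")
}

#' Load a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations
#' (highest occupancy, ties to altloc 'A'), excludes waters, extracts the
#' ligand by its 3-character chemical component code, and perceives
#' ligand bonds from CONECT records when present (falling back to
#' covalent-radius distances).
#'
#' @param pdb Path to a PDB file, or PDB-format text.
#' @param ligand_code 1-3 character chemical component code of the bound
#'   ligand (e.g. `"1E8"` for ibrutinib, `"LEV"` for lenvatinib).
#' @param chain Optional chain identifier restricting the ligand search.
#' @return An object of class `complex_structure` with tibbles `protein`
#'   and `ligand` (columns `eleno`, `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z`, `element`), a `lig_bonds` tibble (`a1`, `a2` row
#'   indices into `ligand`), and `ligand_code`.
#' @export
load_complex <- function(pdb, ligand_code, chain = NULL) {
  stopifnot(is.character(pdb), length(pdb) >= 1)
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    pdb_lines <- readLines(pdb, warn = FALSE)
    pdb_path <- pdb
  } else {
    pdb_lines <- if (length(pdb) > 1) pdb else strsplit(pdb, "\n", fixed = TRUE)[[1]]
    pdb_path <- tempfile(fileext = ".pdb")
    writeLines(pdb_lines, pdb_path)
    on.exit(unlink(pdb_path))
  }
  pdbobj <- bio3d::read.pdb(pdb_path, rm.alt = FALSE, verbose = FALSE)
  at <- as_tibble(pdbobj$atom)
  at$element <- .element_from_atom(at$elesy, at$elety)
  at <- filter(at, !(toupper(.data$resid) %in% c("HOH", "WAT", "DOD")))

  # resolve altlocs: best occupancy, ties by altloc letter
  at$alt[is.na(at$alt)] <- ""
  at <- at |>
    arrange(.data$chain, .data$resno, .data$resid, .data$elety,
            dplyr::desc(.data$o), .data$alt) |>
    distinct(.data$chain, .data$resno, .data$resid, .data$insert,
             .data$elety, .keep_all = TRUE) |>
    arrange(.data$eleno)

  lig <- filter(at, .data$type == "HETATM",
                toupper(.data$resid) == toupper(ligand_code))
  if (!is.null(chain)) lig <- filter(lig, .data$chain == !!chain)
  if (!nrow(lig)) {
    het <- unique(at$resid[at$type == "HETATM"])
    abort(paste0(
      "ligand code '", ligand_code, "' not found among HETATM records; ",
      if (length(het)) paste0("available: ", paste(het, collapse = ", "))
      else "no HETATM records present"
    ))
  }
  # a ligand code can occur in several copies; keep the first residue instance
  first_inst <- lig |> distinct(.data$chain, .data$resno) |> slice(1)
  lig <- filter(lig, .data$chain == first_inst$chain,
                .data$resno == first_inst$resno)
  prot <- filter(at, .data$type == "ATOM")

  keep_cols <- c("eleno", "elety", "resid", "chain", "resno",
                 "x", "y", "z", "element")
  lig <- select(lig, all_of(keep_cols))
  prot <- select(prot, all_of(keep_cols))
  if (any(!is.finite(c(lig$x, lig$y, lig$z, prot$x, prot$y, prot$z)))) {
    abort("non-finite coordinates in PDB input")
  }

  lig_bonds <- .ligand_bonds(pdb_lines, lig)

  structure(
    list(
      protein = prot, ligand = lig, lig_bonds = lig_bonds,
      ligand_code = toupper(ligand_code)
    ),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(
    "<complex_structure> ligand ", x$ligand_code, ": ",
    nrow(x$ligand), " atoms (", nrow(x$lig_bonds), " bonds); protein: ",
    nrow(x$protein), " atoms, ",
    nrow(distinct(x$protein, .data$chain, .data$resno)), " residues\n",
    sep = ""
  )
  invisible(x)
}

.element_from_atom <- function(elesy, elety) {
  el <- trimws(elesy %||% "")
  el[is.na(el)] <- ""
  # fall back to the first letter(s) of the atom name
  guess <- sub("^[0-9]*", "", trimws(elety))
  guess2 <- toupper(substr(guess, 1, 2))
  guess1 <- toupper(substr(guess, 1, 1))
  two_letter <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "SI")
  fixed <- ifelse(guess2 %in% two_letter, guess2, guess1)
  out <- ifelse(nzchar(el), el, fixed)
  # normalise case: first upper, rest lower
  paste0(toupper(substr(out, 1, 1)), tolower(substr(out, 2, 2)))
}

# ligand bonds from CONECT records when they cover the ligand, else from
# covalent-radius distance perception
.ligand_bonds <- function(pdb_lines, lig) {
  serial_to_row <- stats::setNames(seq_len(nrow(lig)), lig$eleno)
  con <- grep("^CONECT", pdb_lines, value = TRUE)
  bonds <- NULL
  if (length(con)) {
    pairs <- list()
    for (ln in con) {
      f <- ln
      base <- suppressWarnings(as.integer(substr(f, 7, 11)))
      if (is.na(base) || !(base %in% lig$eleno)) next
      for (st in c(12, 17, 22, 27)) {
        p <- suppressWarnings(as.integer(substr(f, st, st + 4)))
        if (!is.na(p) && p %in% lig$eleno) {
          pairs[[length(pairs) + 1]] <- sort(c(
            serial_to_row[[as.character(base)]],
            serial_to_row[[as.character(p)]]
          ))
        }
      }
    }
    if (length(pairs)) {
      m <- unique(do.call(rbind, pairs))
      bonds <- tibble(a1 = m[, 1], a2 = m[, 2])
    }
  }
  if (is.null(bonds) || nrow(bonds) < nrow(lig) - 1) {
    bonds <- .distance_bonds(lig)
  }
  bonds
}

.distance_bonds <- function(lig) {
  n <- nrow(lig)
  if (n < 2) return(tibble(a1 = integer(), a2 = integer()))
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  rad <- .covalent_radii[lig$element]
  rad[is.na(rad)] <- 0.77
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > 0.4 && d <= 1.25 * (rad[i] + rad[j])) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(tibble(a1 = integer(), a2 = integer()))
  m <- do.call(rbind, out)
  tibble(a1 = m[, 1], a2 = m[, 2])
}

#' Residues lining the ligand binding site
#'
#' Protein residues with at least one heavy atom within `cutoff` of any
#' ligand heavy atom.
#'
#' @param cx A `complex_structure`.
#' @param cutoff Distance cutoff in Angstrom (default 4.5).
#' @return A tibble `chain`, `resno`, `resid`, `min_dist`, sorted by
#'   residue number.
#' @export
binding_site_residues <- function(cx, cutoff = 4.5) {
  stopifnot(inherits(cx, "complex_structure"), cutoff > 0)
  lig <- filter(cx$ligand, .data$element != "H")
  prot <- filter(cx$protein, .data$element != "H")
  if (!nrow(prot) || !nrow(lig)) {
    return(tibble(chain = character(), resno = integer(),
                  resid = character(), min_dist = numeric()))
  }
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  # min distance of each protein atom to the ligand
  d2 <- outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") - 2 * pxyz %*% t(lxyz)
  prot$min_dist <- sqrt(pmax(0, apply(d2, 1, min)))
  prot |>
    group_by(.data$chain, .data$resno, .data$resid) |>
    summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
    filter(.data$min_dist <= cutoff) |>
    arrange(.data$resno)
}

# ---- aromatic ring perception in 3D ---------------------------------------

.ring_plane <- function(xyz) {
  centroid <- colMeans(xyz)
  centred <- sweep(xyz, 2, centroid)
  sv <- svd(centred)
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  rms <- sqrt(mean((centred %*% normal)^2))
  radius <- mean(sqrt(rowSums(centred^2)))
  list(centroid = centroid, normal = normal, rms = rms, radius = radius)
}

# side-chain ring templates for the aromatic residues
.protein_ring_templates <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(
    c("CG", "CD1", "NE1", "CE2", "CD2"),
    c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  ),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

#' Perceive aromatic rings in a complex
#'
#' Ligand rings are cycles of 5-7 C/N/O/S atoms in the perceived bond
#' graph whose fitted plane has RMS deviation below the planarity
#' tolerance (a geometric criterion, appropriate when bond orders are
#' unavailable in PDB input). Protein rings come from fixed atom-name
#' templates for Phe, Tyr, Trp (both rings) and His; rings with missing
#' atoms are skipped with a warning.
#'
#' @param cx A `complex_structure`.
#' @param crit A [geometry_criteria()].
#' @param site Optional output of [binding_site_residues()]; protein
#'   rings are restricted to these residues when given.
#' @return A list with tibbles `ligand` and `protein`; each row carries
#'   `atoms` (list of atom row indices), `atom_names`, `centroid`,
#'   `normal` (list columns), `rms` and `radius`, and for protein rings
#'   the residue identity.
#' @export
perceive_rings <- function(cx, crit = geometry_criteria(), site = NULL) {
  stopifnot(inherits(cx, "complex_structure"))
  lig <- cx$ligand
  lig_rings <- list()
  heavy_ok <- lig$element %in% c("C", "N", "O", "S")
  rings <- .sssr(nrow(lig), mutate(cx$lig_bonds, order = 1L))
  for (r in rings) {
    if (length(r) < 5 || length(r) > 7) next
    if (!all(heavy_ok[r])) next
    geo <- .ring_plane(as.matrix(lig[r, c("x", "y", "z")]))
    if (geo$rms > crit$planarity_tol) next
    lig_rings[[length(lig_rings) + 1]] <- tibble(
      ring_id = length(lig_rings) + 1L,
      atoms = list(r),
      atom_names = paste(lig$elety[r], collapse = ","),
      centroid = list(geo$centroid), normal = list(geo$normal),
      rms = geo$rms, radius = geo$radius
    )
  }
  lig_rings <- if (length(lig_rings)) bind_rows(lig_rings) else
    tibble(ring_id = integer(), atoms = list(), atom_names = character(),
           centroid = list(), normal = list(), rms = numeric(),
           radius = numeric())

  prot <- cx$protein
  if (!is.null(site)) {
    prot_res <- dplyr::semi_join(
      distinct(prot, .data$chain, .data$resno, .data$resid),
      site, by = c("chain", "resno", "resid")
    )
  } else {
    prot_res <- distinct(prot, .data$chain, .data$resno, .data$resid)
  }
  prot_res <- filter(prot_res,
                     toupper(.data$resid) %in% names(.protein_ring_templates))
  prot_rings <- list()
  for (i in seq_len(nrow(prot_res))) {
    rr <- prot_res[i, ]
    tmpls <- .protein_ring_templates[[toupper(rr$resid)]]
    res_atoms <- filter(prot, .data$chain == rr$chain,
                        .data$resno == rr$resno, .data$resid == rr$resid)
    for (tmpl in tmpls) {
      idx <- match(tmpl, res_atoms$elety)
      if (anyNA(idx)) {
        warn(paste0("ring atoms missing for ", rr$resid, rr$resno,
                    "; ring skipped"))
        next
      }
      rows <- which(prot$chain == rr$chain & prot$resno == rr$resno &
                    prot$resid == rr$resid)[idx]
      geo <- .ring_plane(as.matrix(prot[rows, c("x", "y", "z")]))
      prot_rings[[length(prot_rings) + 1]] <- tibble(
        ring_id = length(prot_rings) + 1L,
        chain = rr$chain, resno = rr$resno, resid = rr$resid,
        atoms = list(rows), atom_names = paste(tmpl, collapse = ","),
        centroid = list(geo$centroid), normal = list(geo$normal),
        rms = geo$rms, radius = geo$radius
      )
    }
  }
  prot_rings <- if (length(prot_rings)) bind_rows(prot_rings) else
    tibble(ring_id = integer(), chain = character(), resno = integer(),
           resid = character(), atoms = list(), atom_names = character(),
           centroid = list(), normal = list(), rms = numeric(),
           radius = numeric())

  list(ligand = lig_rings, protein = prot_rings)
}
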