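.contact_modes <- c("HBOND", "SALT_BRIDGE", "PI_PI", "CH_PI", "CATION_PI",
                    "NH_PI", "OH_PI", "SH_PI")

# candidate-pool radius: wide enough that every mode's own window fits
# inside it (ring-ring modes may span the centroid cutoff plus two ring
# radii); detection itself is governed by the per-mode windows
.candidate_cutoff <- function(crit) {
  max(crit$site_cutoff, crit$hbond_dist, crit$salt_bridge_dist,
      crit$chpi_dist, crit$xhpi_dist, crit$catpi_dist,
      crit$pipi_dist, crit$pipi_tshape_dist) + 3.0
}

.empty_contacts <- function() {
  tibble(
    mode = character(), chain = character(), resno = integer(),
    resid = character(), res_atoms = character(), lig_atoms = character(),
    distance = numeric(), centroid_dist = numeric(), angle = numeric(),
    height = numeric(), offset = numeric(), subtype = character()
  )
}

.contact_row <- function(mode, chain, resno, resid, res_atoms, lig_atoms,
                         distance, centroid_dist = NA_real_,
                         angle = NA_real_, height = NA_real_,
                         offset = NA_real_, subtype = NA_character_) {
  tibble(
    mode = mode, chain = chain, resno = as.integer(resno), resid = resid,
    res_atoms = res_atoms, lig_atoms = lig_atoms, distance = distance,
    centroid_dist = centroid_dist, angle = angle, height = height,
    offset = offset, subtype = subtype
  )
}

.xyz <- function(df, rows = NULL) {
  m <- as.matrix(df[, c("x", "y", "z")])
  if (is.null(rows)) m else m[rows, , drop = FALSE]
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

# height above the ring plane and lateral offset of a point
.point_ring_geom <- function(p, centroid, normal) {
  v <- p - centroid
  d <- sqrt(sum(v^2))
  h <- abs(sum(v * normal))
  list(dist = d, height = h, offset = sqrt(max(0, d^2 - h^2)))
}

.site_atoms <- function(cx, site) {
  dplyr::semi_join(cx$protein, site, by = c("chain", "resno", "resid"))
}

# ---- hydrogen inference on the ligand graph (heavy-atom PDB input) --------

.lig_heavy_degree <- function(cx) {
  n <- nrow(cx$ligand)
  heavy <- cx$ligand$element != "H"
  deg <- integer(n)
  for (b in seq_len(nrow(cx$lig_bonds))) {
    a1 <- cx$lig_bonds$a1[b]; a2 <- cx$lig_bonds$a2[b]
    if (heavy[a1] && heavy[a2]) {
      deg[a1] <- deg[a1] + 1L
      deg[a2] <- deg[a2] + 1L
    }
  }
  deg
}

.lig_explicit_h <- function(cx) {
  n <- nrow(cx$ligand)
  nh <- integer(n)
  is_h <- cx$ligand$element == "H"
  for (b in seq_len(nrow(cx$lig_bonds))) {
    a1 <- cx$lig_bonds$a1[b]; a2 <- cx$lig_bonds$a2[b]
    if (is_h[a1] && !is_h[a2]) nh[a2] <- nh[a2] + 1L
    if (is_h[a2] && !is_h[a1]) nh[a1] <- nh[a1] + 1L
  }
  nh
}

.lig_in_planar_ring <- function(cx, rings) {
  flag <- logical(nrow(cx$ligand))
  for (r in rings$ligand$atoms) flag[r] <- TRUE
  flag
}

# Does ligand heavy atom i plausibly carry a hydrogen? Explicit hydrogens
# win; otherwise a valence/geometry heuristic: terminal or low-degree atoms
# carry H, carbonyl-length C=O oxygens and planar-ring junctions do not.
.lig_has_h <- function(cx, rings) {
  lig <- cx$ligand
  n <- nrow(lig)
  deg <- .lig_heavy_degree(cx)
  expl <- .lig_explicit_h(cx)
  any_h <- any(lig$element == "H")
  planar <- .lig_in_planar_ring(cx, rings)
  xyz <- .xyz(lig)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (lig$element[i] == "H") next
    if (expl[i] > 0) { out[i] <- TRUE; next }
    if (any_h) next  # hydrogens are explicit in this file; none on this atom
    el <- lig$element[i]
    if (el == "C") {
      out[i] <- deg[i] <= 2 || (deg[i] == 3 && !planar[i])
    } else if (el == "N") {
      out[i] <- deg[i] <= 2 && !planar[i]
    } else if (el == "O") {
      if (deg[i] == 1) {
        j <- .lig_neighbours(cx, i)[1]
        # C=O bonds are ~1.23 A, C-OH ~1.36-1.43 A
        out[i] <- !is.na(j) && .dist3(xyz[i, ], xyz[j, ]) >= 1.32
      }
    } else if (el == "S") {
      out[i] <- deg[i] <= 1
    }
  }
  out
}

.lig_neighbours <- function(cx, i) {
  b <- cx$lig_bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# ligand cationic N: formally charged in the file is unknowable, so use a
# structural proxy: non-planar (sp3-type) nitrogen, i.e. an aliphatic amine
.lig_cationic_n <- function(cx, rings) {
  lig <- cx$ligand
  planar <- .lig_in_planar_ring(cx, rings)
  deg <- .lig_heavy_degree(cx)
  which(lig$element == "N" & !planar & deg <= 3 & !.lig_amide_n(cx))
}

.lig_amide_n <- function(cx) {
  lig <- cx$ligand
  xyz <- .xyz(lig)
  vapply(seq_len(nrow(lig)), function(i) {
    if (lig$element[i] != "N") return(FALSE)
    any(vapply(.lig_neighbours(cx, i), function(j) {
      if (lig$element[j] != "C") return(FALSE)
      any(vapply(.lig_neighbours(cx, j), function(k) {
        lig$element[k] == "O" && .dist3(xyz[j, ], xyz[k, ]) < 1.32
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
}

# ligand anionic O: oxygen of a carboxylate-like group (C bearing two
# terminal oxygens)
.lig_anionic_o <- function(cx) {
  lig <- cx$ligand
  deg <- .lig_heavy_degree(cx)
  which(vapply(seq_len(nrow(lig)), function(i) {
    if (lig$element[i] != "O" || deg[i] != 1) return(FALSE)
    j <- .lig_neighbours(cx, i)[1]
    if (is.na(j) || !(lig$element[j] %in% c("C", "S", "P"))) return(FALSE)
    o_nb <- sum(lig$element[.lig_neighbours(cx, j)] == "O")
    o_nb >= 2
  }, logical(1)))
}

# protein-side classification by residue/atom-name templates
.prot_cationic_n <- function(atoms, his_cation = FALSE) {
  sel <- (atoms$resid == "LYS" & atoms$elety == "NZ") |
    (atoms$resid == "ARG" & atoms$elety %in% c("NE", "NH1", "NH2"))
  if (his_cation) {
    sel <- sel | (atoms$resid == "HIS" & atoms$elety %in% c("ND1", "NE2"))
  }
  sel
}

.prot_anionic_o <- function(atoms) {
  (atoms$resid == "ASP" & atoms$elety %in% c("OD1", "OD2")) |
    (atoms$resid == "GLU" & atoms$elety %in% c("OE1", "OE2")) |
    (atoms$elety == "OXT")
}

# protein carbons without hydrogens: backbone carbonyl C and sp2 side-chain
# carbons bonded to heteroatoms/three ring atoms
.prot_c_no_h <- list(
  ALL = "C",
  ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD", ARG = "CZ",
  PHE = "CG", TYR = c("CG", "CZ"), TRP = c("CG", "CD2", "CE2"),
  HIS = "CG"
)

.prot_has_ch <- function(atoms) {
  vapply(seq_len(nrow(atoms)), function(i) {
    if (atoms$element[i] != "C") return(FALSE)
    if (atoms$elety[i] %in% .prot_c_no_h$ALL) return(FALSE)
    res_excl <- .prot_c_no_h[[atoms$resid[i]]]
    !(atoms$elety[i] %in% (res_excl %||% character()))
  }, logical(1))
}

# polar protein atoms that carry hydrogens (for XH-pi and H-bond donors);
# cationic nitrogens excluded - they belong to the cation-pi detector
.prot_xh_donor <- function(atoms) {
  backbone_n <- atoms$elety == "N" & atoms$resid != "PRO"
  side <- (atoms$resid == "SER" & atoms$elety == "OG") |
    (atoms$resid == "THR" & atoms$elety == "OG1") |
    (atoms$resid == "TYR" & atoms$elety == "OH") |
    (atoms$resid == "CYS" & atoms$elety == "SG") |
    (atoms$resid == "TRP" & atoms$elety == "NE1") |
    (atoms$resid == "ASN" & atoms$elety == "ND2") |
    (atoms$resid == "GLN" & atoms$elety == "NE2") |
    (atoms$resid == "HIS" & atoms$elety %in% c("ND1", "NE2"))
  backbone_n | side
}

# ---- detectors -------------------------------------------------------------

#' Detect hydrogen bonds
#'
#' Heavy-atom criterion: ligand N/O/S versus protein N/O/S pairs at or
#' below `hbond_dist` (default 3.5 A). When hydrogen coordinates are
#' present on the donor, the D-H...A angle must also reach `hbond_angle`.
#' Pairs that satisfy the salt-bridge criterion are reported by
#' [detect_salt_bridges()], not here.
#'
#' @param cx A `complex_structure`.
#' @param crit A [geometry_criteria()].
#' @param site Candidate residues, by default [binding_site_residues()]
#'   at a radius wide enough for every mode window.
#' @return A contacts tibble (see [interaction_map()]).
#' @export
detect_hbonds <- function(cx, crit = geometry_criteria(),
                          site = binding_site_residues(cx, .candidate_cutoff(crit))) {
  rings <- perceive_rings(cx, crit)
  lig <- cx$ligand
  lig_rows <- which(lig$element %in% c("N", "O", "S"))
  prot <- .site_atoms(cx, site)
  prot_rows <- which(prot$element %in% c("N", "O", "S"))
  if (!length(lig_rows) || !length(prot_rows)) return(.empty_contacts())

  lig_cat <- .lig_cationic_n(cx, rings)
  lig_ani <- .lig_anionic_o(cx)
  prot_cat <- .prot_cationic_n(prot, crit$his_cation)
  prot_ani <- .prot_anionic_o(prot)
  lig_h <- .lig_has_h(cx, rings)
  h_lig <- which(lig$element == "H")
  h_prot <- which(prot$element == "H")

  lxyz <- .xyz(lig); pxyz <- .xyz(prot)
  out <- list()
  for (i in lig_rows) {
    for (j in prot_rows) {
      d <- .dist3(lxyz[i, ], pxyz[j, ])
      if (d > crit$hbond_dist) next
      # salt-bridge pairs are not duplicated as hydrogen bonds
      if ((i %in% lig_cat && prot_ani[j]) || (i %in% lig_ani && prot_cat[j])) next
      # at least one side must be able to donate
      donor_lig <- lig_h[i]
      donor_prot <- .prot_xh_donor(prot[j, , drop = FALSE]) || prot_cat[j] ||
        prot$elety[j] %in% c("OG", "OG1", "OH")
      if (!donor_lig && !donor_prot) next
      ang <- .best_dha_angle(
        lxyz, pxyz, i, j, h_lig, h_prot, donor_lig, donor_prot
      )
      if (!is.na(ang) && ang < crit$hbond_angle) next
      out[[length(out) + 1]] <- .contact_row(
        "HBOND", prot$chain[j], prot$resno[j], prot$resid[j],
        prot$elety[j], lig$elety[i], d, angle = ang
      )
    }
  }
  if (!length(out)) return(.empty_contacts())
  bind_rows(out)
}

# best D-H...A angle over candidate hydrogens on whichever side can donate;
# NA when no hydrogen coordinates are available
.best_dha_angle <- function(lxyz, pxyz, i, j, h_lig, h_prot,
                            donor_lig, donor_prot) {
  best <- NA_real_
  angle_at <- function(h, d, a) {
    v1 <- d - h; v2 <- a - h
    acos(pmin(1, pmax(-1, sum(v1 * v2) /
      (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
  }
  if (donor_lig && length(h_lig)) {
    for (h in h_lig) {
      if (.dist3(lxyz[h, ], lxyz[i, ]) < 1.25) {
        a <- angle_at(lxyz[h, ], lxyz[i, ], pxyz[j, ])
        if (is.na(best) || a > best) best <- a
      }
    }
  }
  if (donor_prot && length(h_prot)) {
    for (h in h_prot) {
      if (.dist3(pxyz[h, ], pxyz[j, ]) < 1.25) {
        a <- angle_at(pxyz[h, ], pxyz[j, ], lxyz[i, ])
        if (is.na(best) || a > best) best <- a
      }
    }
  }
  best
}

#' Detect salt bridges
#'
#' Ligand charged-group atoms (structurally inferred aliphatic amine N or
#' carboxylate-like O) paired with Asp/Glu carboxylate oxygens or
#' Lys/Arg (optionally His) cationic nitrogens at or below
#' `salt_bridge_dist` (default 4.0 A, inclusive).
#'
#' @inheritParams detect_hbonds
#' @return A contacts tibble.
#' @export
detect_salt_bridges <- function(cx, crit = geometry_criteria(),
                                site = binding_site_residues(cx, .candidate_cutoff(crit))) {
  rings <- perceive_rings(cx, crit)
  lig <- cx$ligand
  prot <- .site_atoms(cx, site)
  lig_cat <- .lig_cationic_n(cx, rings)
  lig_ani <- .lig_anionic_o(cx)
  prot_cat <- which(.prot_cationic_n(prot, crit$his_cation))
  prot_ani <- which(.prot_anionic_o(prot))
  lxyz <- .xyz(lig); pxyz <- .xyz(prot)
  out <- list()
  pairs <- rbind(
    expand.grid(i = lig_cat, j = prot_ani),
    expand.grid(i = lig_ani, j = prot_cat)
  )
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    d <- .dist3(lxyz[i, ], pxyz[j, ])
    if (d <= crit$salt_bridge_dist) {
      out[[length(out) + 1]] <- .contact_row(
        "SALT_BRIDGE", prot$chain[j], prot$resno[j], prot$resid[j],
        prot$elety[j], lig$elety[i], d
      )
    }
  }
  if (!length(out)) return(.empty_contacts())
  bind_rows(out)
}

#' Detect pi-pi stacking
#'
#' Ring pairs are parallel-stacked when the centroid distance is at most
#' `pipi_dist`, the interplanar angle at most `pipi_parallel_angle` and
#' the lateral offset at most `pipi_offset`; T-shaped when the angle
#' falls in `pipi_tshape_angle` and the centroid distance is at most
#' `pipi_tshape_dist`. The subtype is recorded.
#'
#' @inheritParams detect_hbonds
#' @param rings Optional precomputed [perceive_rings()] output.
#' @return A contacts tibble.
#' @export
detect_pi_pi <- function(cx, crit = geometry_criteria(),
                         site = binding_site_residues(cx, .candidate_cutoff(crit)),
                         rings = perceive_rings(cx, crit, site)) {
  lr <- rings$ligand; pr <- rings$protein
  if (!nrow(lr) || !nrow(pr)) return(.empty_contacts())
  out <- list()
  for (a in seq_len(nrow(lr))) {
    for (b in seq_len(nrow(pr))) {
      c1 <- lr$centroid[[a]]; c2 <- pr$centroid[[b]]
      d <- .dist3(c1, c2)
      if (d > max(crit$pipi_dist, crit$pipi_tshape_dist)) next
      ang <- acos(pmin(1, abs(sum(lr$normal[[a]] * pr$normal[[b]])))) * 180 / pi
      off <- min(
        .point_ring_geom(c2, c1, lr$normal[[a]])$offset,
        .point_ring_geom(c1, c2, pr$normal[[b]])$offset
      )
      subtype <- NA_character_
      if (d <= crit$pipi_dist && ang <= crit$pipi_parallel_angle &&
          off <= crit$pipi_offset) {
        subtype <- "parallel"
      } else if (d <= crit$pipi_tshape_dist &&
                 ang >= crit$pipi_tshape_angle[1] &&
                 ang <= crit$pipi_tshape_angle[2]) {
        subtype <- "t_shaped"
      }
      if (is.na(subtype)) next
      dmin <- min(.cross_dist(.xyz(cx$ligand, lr$atoms[[a]]),
                              .xyz(cx$protein, pr$atoms[[b]])))
      out[[length(out) + 1]] <- .contact_row(
        "PI_PI", pr$chain[b], pr$resno[b], pr$resid[b],
        pr$atom_names[b], lr$atom_names[a], dmin,
        centroid_dist = d, angle = ang, offset = off, subtype = subtype
      )
    }
  }
  if (!length(out)) return(.empty_contacts())
  bind_rows(out)
}

.cross_dist <- function(m1, m2) {
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * m1 %*% t(m2)
  matrix(sqrt(pmax(0, d2)), nrow = nrow(m1))
}

# shared point-above-ring detector core for CH/cation/XH-pi
.point_to_ring_contacts <- function(points_df, point_rows, rings_df,
                                    rings_src_df, mode, max_dist, crit,
                                    flip = FALSE) {
  out <- list()
  pxyz <- .xyz(points_df)
  for (i in point_rows) {
    for (b in seq_len(nrow(rings_df))) {
      g <- .point_ring_geom(pxyz[i, ], rings_df$centroid[[b]],
                            rings_df$normal[[b]])
      if (g$dist > max_dist) next
      if (g$height < crit$pi_min_height) next
      if (g$offset > rings_df$radius[b] + crit$pi_offset_pad) next
      if (!flip) {
        # protein point onto ligand ring
        row <- .contact_row(
          mode, points_df$chain[i], points_df$resno[i], points_df$resid[i],
          points_df$elety[i], rings_df$atom_names[b], g$dist,
          centroid_dist = g$dist, height = g$height, offset = g$offset
        )
      } else {
        # ligand point onto protein ring
        row <- .contact_row(
          mode, rings_df$chain[b], rings_df$resno[b], rings_df$resid[b],
          rings_df$atom_names[b], points_df$elety[i], g$dist,
          centroid_dist = g$dist, height = g$height, offset = g$offset
        )
      }
      out[[length(out) + 1]] <- row
    }
  }
  out
}

#' Detect CH-pi contacts
#'
#' Hydrogen-bearing carbons within `chpi_dist` of an aromatic ring
#' centroid, at least `pi_min_height` above the ring plane and laterally
#' within ring radius + `pi_offset_pad`. Bidirectional: protein C-H onto
#' ligand rings and ligand C-H onto protein rings. Carbons belonging to a
#' ring pair already reported as pi-pi stacked can be suppressed via
#' `exclude` (done by [interaction_map()]).
#'
#' @inheritParams detect_pi_pi
#' @param exclude Optional pi-pi contacts tibble; ring-ring pairs listed
#'   there are not re-reported atom-by-atom as CH-pi.
#' @return A contacts tibble.
#' @export
detect_ch_pi <- function(cx, crit = geometry_criteria(),
                         site = binding_site_residues(cx, .candidate_cutoff(crit)),
                         rings = perceive_rings(cx, crit, site),
                         exclude = NULL) {
  prot <- .site_atoms(cx, site)
  lig <- cx$ligand
  lig_h <- .lig_has_h(cx, rings)

  # pi-pi stacked ring pairs: suppression is pairwise - a carbon of a
  # stacked ring is only excluded against its own stacking partner
  stacked_pairs <- character()
  if (!is.null(exclude) && nrow(exclude)) {
    stacked_pairs <- paste(exclude$chain, exclude$resno, exclude$res_atoms,
                           exclude$lig_atoms)
  }
  prot_ring_key <- function(b) {
    paste(rings$protein$chain[b], rings$protein$resno[b],
          rings$protein$atom_names[b])
  }
  # protein atom row -> key of the protein ring it belongs to (if any)
  prot_ring_of_atom <- rep(NA_character_, nrow(prot))
  if (nrow(rings$protein)) {
    for (b in seq_len(nrow(rings$protein))) {
      ring_names <- cx$protein$elety[rings$protein$atoms[[b]]]
      rows <- which(prot$resno == rings$protein$resno[b] &
                    prot$chain == rings$protein$chain[b] &
                    prot$elety %in% ring_names)
      prot_ring_of_atom[rows] <- prot_ring_key(b)
    }
  }
  lig_ring_of_atom <- rep(NA_character_, nrow(lig))
  if (nrow(rings$ligand)) {
    for (a in seq_len(nrow(rings$ligand))) {
      lig_ring_of_atom[rings$ligand$atoms[[a]]] <- rings$ligand$atom_names[a]
    }
  }

  out <- list()
  pxyz <- .xyz(prot); lxyz <- .xyz(lig)
  # protein C-H onto ligand rings
  for (i in which(.prot_has_ch(prot))) {
    for (a in seq_len(nrow(rings$ligand))) {
      if (!is.na(prot_ring_of_atom[i]) &&
          paste(prot_ring_of_atom[i], rings$ligand$atom_names[a]) %in%
            stacked_pairs) next
      g <- .point_ring_geom(pxyz[i, ], rings$ligand$centroid[[a]],
                            rings$ligand$normal[[a]])
      if (g$dist > crit$chpi_dist || g$height < crit$pi_min_height ||
          g$offset > rings$ligand$radius[a] + crit$pi_offset_pad) next
      out[[length(out) + 1]] <- .contact_row(
        "CH_PI", prot$chain[i], prot$resno[i], prot$resid[i],
        prot$elety[i], rings$ligand$atom_names[a], g$dist,
        centroid_dist = g$dist, height = g$height, offset = g$offset
      )
    }
  }
  # ligand C-H onto protein rings
  for (i in which(lig$element == "C" & lig_h)) {
    for (b in seq_len(nrow(rings$protein))) {
      if (!is.na(lig_ring_of_atom[i]) &&
          paste(prot_ring_key(b), lig_ring_of_atom[i]) %in% stacked_pairs) next
      g <- .point_ring_geom(lxyz[i, ], rings$protein$centroid[[b]],
                            rings$protein$normal[[b]])
      if (g$dist > crit$chpi_dist || g$height < crit$pi_min_height ||
          g$offset > rings$protein$radius[b] + crit$pi_offset_pad) next
      out[[length(out) + 1]] <- .contact_row(
        "CH_PI", rings$protein$chain[b], rings$protein$resno[b],
        rings$protein$resid[b], rings$protein$atom_names[b],
        lig$elety[i], g$dist,
        centroid_dist = g$dist, height = g$height, offset = g$offset
      )
    }
  }
  if (!length(out)) return(.empty_contacts())
  bind_rows(out)
}

#' Detect cation-pi contacts
#'
#' Cationic nitrogens (Lys NZ, Arg guanidinium N, optionally His ring N;
#' structurally inferred aliphatic amine N on the ligand side) within
#' `catpi_dist` of an aromatic ring centroid, with the same height/offset
#' window as CH-pi.
#'
#' @inheritParams detect_pi_pi
#' @return A contacts tibble.
#' @export
detect_cation_pi <- function(cx, crit = geometry_criteria(),
                             site = binding_site_residues(cx, .candidate_cutoff(crit)),
                             rings = perceive_rings(cx, crit, site)) {
  prot <- .site_atoms(cx, site)
  cat_rows <- which(.prot_cationic_n(prot, crit$his_cation))
  out <- .point_to_ring_contacts(prot, cat_rows, rings$ligand, cx$ligand,
                                 "CATION_PI", crit$catpi_dist, crit)
  lig_cat <- .lig_cationic_n(cx, rings)
  lig2 <- mutate(cx$ligand, chain = NA_character_, resno = NA_integer_,
                 resid = cx$ligand_code)
  out <- c(out, .point_to_ring_contacts(lig2, lig_cat, rings$protein, prot,
                                        "CATION_PI", crit$catpi_dist, crit,
                                        flip = TRUE))
  if (!length(out)) return(.empty_contacts())
  bind_rows(out)
}

#' Detect XH-pi contacts (X = N, O, S)
#'
#' Polar hydrogen-bearing atoms (backbone amide N, side-chain OH/NH/SH;
#' ligand N/O/S inferred to carry H) within `xhpi_dist` of an aromatic
#' ring centroid, same height/offset window as CH-pi. The mode label
#' (NH_PI, OH_PI, SH_PI) follows the donor element. Cationic nitrogens
#' are reported by [detect_cation_pi()], not here.
#'
#' @inheritParams detect_pi_pi
#' @return A contacts tibble.
#' @export
detect_xh_pi <- function(cx, crit = geometry_criteria(),
                         site = binding_site_residues(cx, .candidate_cutoff(crit)),
                         rings = perceive_rings(cx, crit, site)) {
  prot <- .site_atoms(cx, site)
  don_rows <- which(.prot_xh_donor(prot))
  out <- list()
  for (mode_el in list(c("NH_PI", "N"), c("OH_PI", "O"), c("SH_PI", "S"))) {
    rows <- don_rows[prot$element[don_rows] == mode_el[2]]
    out <- c(out, .point_to_ring_contacts(prot, rows, rings$ligand,
                                          cx$ligand, mode_el[1],
                                          crit$xhpi_dist, crit))
  }
  lig <- cx$ligand
  lig_h <- .lig_has_h(cx, rings)
  lig_cat <- .lig_cationic_n(cx, rings)
  lig2 <- mutate(lig, chain = NA_character_, resno = NA_integer_,
                 resid = cx$ligand_code)
  for (mode_el in list(c("NH_PI", "N"), c("OH_PI", "O"), c("SH_PI", "S"))) {
    rows <- setdiff(which(lig$element == mode_el[2] & lig_h), lig_cat)
    out <- c(out, .point_to_ring_contacts(lig2, rows, rings$protein, prot,
                                          mode_el[1], crit$xhpi_dist, crit,
                                          flip = TRUE))
  }
  if (!length(out)) return(.empty_contacts())
  bind_rows(out)
}

#' Full non-bonded interaction map of a complex
#'
#' Runs every detector over the binding site and returns the union of
#' contacts, sorted by residue number. A residue may carry several modes.
#' CH-pi contacts that merely re-describe an already-reported pi-pi ring
#' pair atom-by-atom are suppressed. The output is checked against each
#' mode's own geometric window before being returned.
#'
#' @param cx A `complex_structure`.
#' @param crit A [geometry_criteria()].
#' @return A tibble of class `interaction_map`: `mode`, `chain`, `resno`,
#'   `resid`, `res_atoms`, `lig_atoms`, `distance` (A), plus the
#'   mode-specific `centroid_dist`, `angle`, `height`, `offset`,
#'   `subtype` metrics.
#' @export
interaction_map <- function(cx, crit = geometry_criteria()) {
  site <- binding_site_residues(cx, .candidate_cutoff(crit))
  rings <- perceive_rings(cx, crit, site = NULL)
  pipi <- detect_pi_pi(cx, crit, site, rings)
  res <- bind_rows(
    detect_hbonds(cx, crit, site),
    detect_salt_bridges(cx, crit, site),
    pipi,
    detect_ch_pi(cx, crit, site, rings, exclude = pipi),
    detect_cation_pi(cx, crit, site, rings),
    detect_xh_pi(cx, crit, site, rings)
  )
  res <- arrange(res, .data$resno, .data$mode, .data$distance)
  .assert_contacts_within_windows(res, crit)
  class(res) <- c("interaction_map", class(res))
  res
}

# self-consistency: every reported contact satisfies its mode's window
.assert_contacts_within_windows <- function(res, crit) {
  lim <- c(
    HBOND = crit$hbond_dist, SALT_BRIDGE = crit$salt_bridge_dist,
    PI_PI = max(crit$pipi_dist, crit$pipi_tshape_dist),
    CH_PI = crit$chpi_dist, CATION_PI = crit$catpi_dist,
    NH_PI = crit$xhpi_dist, OH_PI = crit$xhpi_dist, SH_PI = crit$xhpi_dist
  )
  key <- ifelse(is.na(res$centroid_dist), res$distance, res$centroid_dist)
  # pi-pi reports the minimum interatomic distance, bounded by the
  # centroid criterion; use centroid_dist for the check
  bad <- key > lim[res$mode] + 1e-9
  if (any(bad)) {
    abort(paste0("internal error: ", sum(bad),
                 " contact(s) violate their own geometric window"))
  }
  invisible(res)
}

#' Plot an interaction map
#'
#' Residue-by-mode tile plot annotated with the closest contact distance.
#'
#' @param object An `interaction_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_map
#' @export
autoplot.interaction_map <- function(object, ...) {
  dat <- object |>
    group_by(.data$resid, .data$resno, .data$mode) |>
    summarise(distance = min(.data$distance), .groups = "drop") |>
    mutate(residue = stats::reorder(paste0(.data$resid, .data$resno),
                                    .data$resno))
  ggplot2::ggplot(dat, ggplot2::aes(.data$mode, .data$residue,
                                    fill = .data$distance)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$distance)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "closest\ndistance (Å)") +
    ggplot2::theme_minimal()
}
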