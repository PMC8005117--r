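# run code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Table-3-like ring-class composition of a kinase-inhibitor cohort
.default_class_weights <- c(
  "0" = 1, "1" = 117, "2" = 507, "3" = 819, "4" = 570, "5+" = 125
) / 2139

#' Generate a synthetic ligand cohort with a planted WHBC trend
#'
#' Emulates the statistical structure of a kinase-inhibitor cohort: each
#' ligand draws an aromatic ring-count class (default composition mirrors
#' the published cohort), and its WHBC target is normal around a line in
#' the ring-class abscissa, `intercept + slope * min(nAR, 5)`, truncated
#' at zero. The "5 and more" class is realised with a decaying tail over
#' 5-8 rings but shares the abscissa-5 mean, mirroring how the tabulated
#' trend treats its open-ended top class. Targets are realised as integer
#' `(nHDon, nHAcc, nSK)` triples, so the recorded WHBC is exactly
#' `(nHDon + nHAcc) / nSK`. With `smiles = TRUE` each tuple is also
#' realised as a molecule from a small fragment grammar (benzene /
#' pyridine / pyrimidine rings, alkyl linkers, hydroxyl / amine / methoxy
#' decorations) whose descriptor counts reproduce the tuple exactly.
#'
#' @param n Cohort size (default 2139).
#' @param class_weights Named probabilities over classes
#'   `c("0","1","2","3","4","5+")`; must sum to 1.
#' @param slope,intercept Planted line, WHBC units per ring / WHBC units
#'   (defaults -0.025 and 0.41, the magnitude of the published trend).
#' @param noise_sd WHBC noise around the line (default 0.05).
#' @param seed Integer seed; the cohort is fully deterministic given it.
#' @param smiles Also assemble a SMILES string per ligand (default FALSE).
#' @param max_resample Attempts to realise a feasible integer/grammar
#'   tuple before erroring (default 100).
#' @return A tibble `id`, `nAR`, `nHDon`, `nHAcc`, `nSK`, `WHBC`
#'   (+ `smiles`), with the seed stored in attribute `"seed"`.
#' @export
gen_ligand_cohort <- function(n = 2139,
                              class_weights = .default_class_weights,
                              slope = -0.025, intercept = 0.41,
                              noise_sd = 0.05, seed = 1,
                              smiles = FALSE, max_resample = 100) {
  stopifnot(n >= 1, noise_sd >= 0, max_resample >= 1)
  if (abs(sum(class_weights) - 1) > 1e-6) abort("class weights must sum to 1")
  lev <- c("0", "1", "2", "3", "4", "5+")
  if (!all(names(class_weights) %in% lev)) {
    abort("class weights must be named with 0,1,2,3,4,5+")
  }
  .with_seed(seed, {
    cls <- sample(names(class_weights), n, replace = TRUE,
                  prob = unname(class_weights))
    nar <- ifelse(cls == "5+",
                  sample(5:8, n, replace = TRUE,
                         prob = c(0.72, 0.16, 0.08, 0.04)),
                  suppressWarnings(as.integer(cls)))
    target <- pmax(0, stats::rnorm(n, intercept + slope * pmin(nar, 5), noise_sd))
    if (!smiles) {
      out <- .realise_tuples(nar, target, max_resample)
    } else {
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        rows[[i]] <- .realise_ligand(nar[i], target[i], TRUE, max_resample)
      }
      out <- bind_rows(rows)
    }
    out <- mutate(out, id = sprintf("syn_%04d", seq_len(n)),
                  WHBC = (.data$nHDon + .data$nHAcc) / .data$nSK) |>
      select("id", "nAR", "nHDon", "nHAcc", "nSK", "WHBC",
             any_of("smiles"))
    attr(out, "seed") <- seed
    out
  })
}

# vectorised tuple realisation: integer (nHDon, nHAcc, nSK) per ligand
.realise_tuples <- function(nar, target, max_resample) {
  n <- length(nar)
  extra <- ifelse(nar >= 1, stats::rpois(n, 6) + 2L,
                  sample(7:30, n, replace = TRUE))
  nsk <- 6L * nar + extra
  hb <- pmax(0L, as.integer(round(target * nsk)))
  for (k in seq_len(max_resample)) {
    bad <- which(hb > nsk)
    if (!length(bad)) break
    extra_b <- ifelse(nar[bad] >= 1, stats::rpois(length(bad), 6) + 2L,
                      sample(7:30, length(bad), replace = TRUE))
    nsk[bad] <- 6L * nar[bad] + extra_b
    hb[bad] <- pmax(0L, as.integer(round(target[bad] * nsk[bad])))
  }
  if (any(hb > nsk)) {
    abort("could not realise feasible integer tuples for the cohort")
  }
  d <- stats::rbinom(n, hb, 0.3)
  tibble(nAR = nar, nHDon = d, nHAcc = hb - d, nSK = nsk)
}

# realise one (nAR, target WHBC) pair as an integer tuple (+ SMILES)
.realise_ligand <- function(nar, target, smiles, max_resample) {
  for (try in seq_len(max_resample)) {
    extra <- if (nar >= 1) stats::rpois(1, 6) + 2L else sample(7:30, 1)
    nsk <- 6L * nar + extra
    hb <- max(0L, as.integer(round(target * nsk)))
    if (hb > nsk) next
    d <- stats::rbinom(1, hb, 0.3)
    a <- hb - d
    if (!smiles) {
      return(tibble(nAR = nar, nHDon = d, nHAcc = a, nSK = nsk))
    }
    smi <- .assemble_smiles(nar, d, a, nsk)
    if (!is.null(smi)) {
      return(tibble(nAR = nar, nHDon = d, nHAcc = a, nSK = nsk, smiles = smi))
    }
  }
  abort(sprintf(
    "could not realise a ligand with %d aromatic rings and target WHBC %.3f after %d attempts",
    nar, target, max_resample
  ))
}

# fragment grammar: ring templates as atom sequences; substituents may be
# attached at any written position except the first (which carries the
# incoming link); aromatic N atoms accept no substituent
.ring_templates <- list(
  benzene = c("c", "c", "c", "c", "c", "c"),
  pyridine = c("c", "n", "c", "c", "c", "c"),
  pyrimidine = c("c", "n", "c", "n", "c", "c")
)

# Build a SMILES string realising (nAR, nHDon, nHAcc, nSK) exactly under
# the package's own descriptor rules. Donor groups are OH/NH2 (each also
# an acceptor); excess acceptors become aromatic N (free) then methoxy
# (2 heavy atoms); remaining heavy atoms become an alkyl chain. Returns
# NULL when the tuple is infeasible under the grammar.
.assemble_smiles <- function(nar, d, a, nsk) {
  if (a < d) return(NULL)
  ring_n_needed <- a - d
  if (nar == 0) {
    # alkane with decorations
    n_ome <- ring_n_needed
    alkyl <- nsk - d - 2L * n_ome
    if (alkyl < 1 || d + n_ome > 2L * alkyl) return(NULL)
    decos <- c(rep(c("O", "N"), length.out = d), rep("OC", n_ome))
    return(.chain_smiles(alkyl, decos))
  }
  ring_n <- min(ring_n_needed, 2L * nar)
  n_ome <- ring_n_needed - ring_n
  alkyl <- nsk - 6L * nar - d - 2L * n_ome
  if (alkyl < 0) return(NULL)
  # choose ring types realising ring_n aromatic nitrogens
  n2 <- ring_n %/% 2L
  n1 <- ring_n %% 2L
  types <- c(rep("pyrimidine", n2), rep("pyridine", n1),
             rep("benzene", nar - n2 - n1))
  # decorations: donors alternate OH/NH2, then methoxys
  decos <- c(rep(c("O", "N"), length.out = d), rep("OC", n_ome))
  # substituent capacity: carbons per ring minus incoming/outgoing links
  cap <- vapply(seq_len(nar), function(i) {
    carbons <- sum(.ring_templates[[types[i]]] == "c") - 1L  # incoming link
    if (i < nar) carbons <- carbons - 1L                     # link to next ring
    carbons
  }, integer(1))
  if (alkyl > 0) cap[1] <- cap[1] - 1L  # chain occupies a slot on ring 1
  chain_cap <- if (alkyl > 0) 2L * alkyl - (alkyl > 0) else 0L
  if (length(decos) > sum(cap) + chain_cap) return(NULL)
  if (any(cap < 0)) return(NULL)
  # distribute decorations: fill ring slots first, then the chain
  ring_decos <- vector("list", nar)
  k <- 1L
  for (i in seq_len(nar)) {
    take <- min(cap[i], length(decos) - k + 1L)
    if (take > 0) {
      ring_decos[[i]] <- decos[k:(k + take - 1L)]
      k <- k + take
    }
  }
  chain_decos <- if (k <= length(decos)) decos[k:length(decos)] else character()
  if (alkyl == 0 && length(chain_decos)) return(NULL)

  chain <- if (alkyl > 0) .chain_smiles(alkyl, chain_decos) else NULL
  .rings_smiles(types, ring_decos, chain)
}

.chain_smiles <- function(n_c, decos) {
  if (n_c < 1) return(NULL)
  per <- split(decos, rep(seq_len(n_c), each = 2, length.out = length(decos)))
  paste(vapply(seq_len(n_c), function(i) {
    br <- per[[as.character(i)]] %||% character()
    paste0("C", paste0("(", br, ")", collapse = ""))
  }, character(1)), collapse = "")
}

.rings_smiles <- function(types, ring_decos, chain) {
  nar <- length(types)
  build <- function(i) {
    tmpl <- .ring_templates[[types[i]]]
    digit <- as.character(i)
    subs <- ring_decos[[i]] %||% character()
    branches <- character()
    if (i == 1 && !is.null(chain)) branches <- c(branches, chain)
    if (i < nar) branches <- c(branches, build(i + 1))
    branches <- c(branches, subs)
    # attach branches at successive carbon positions 2..6
    out <- tmpl[1]
    out <- paste0(out, digit)
    bi <- 1L
    for (p in 2:length(tmpl)) {
      out <- paste0(out, tmpl[p])
      if (tmpl[p] == "c" && bi <= length(branches)) {
        out <- paste0(out, "(", branches[bi], ")")
        bi <- bi + 1L
      }
    }
    if (bi <= length(branches)) return(NULL)
    paste0(out, digit)
  }
  build(1)
}

# ---- complex fixtures ------------------------------------------------------

# fixture ligand: planar aza-para-terphenyl; the ring A nitrogen (angle
# 180, pointing -x) is the hydrogen-bond acceptor anchor, the exocyclic
# aliphatic-typed amine on ring C (+x) the salt-bridge anchor
.fixture_ligand <- function() {
  hex <- function(cx) {
    ang <- seq(0, 300, by = 60) * pi / 180
    cbind(cx + 1.39 * cos(ang), 1.39 * sin(ang), 0)
  }
  a <- hex(0); b <- hex(4.26); c3 <- hex(8.52)
  xyz <- rbind(a, b, c3,
               c(11.32, 0, 0))    # N19 amine on ring C (C at angle 0)
  name <- c(paste0("C", 1:3), "N4", paste0("C", 5:18), "N19")
  el <- c(rep("C", 3), "N", rep("C", 14), "N")
  ring_bonds <- function(off) cbind(off + 1:6, off + c(2:6, 1))
  bonds <- rbind(
    ring_bonds(0), ring_bonds(6), ring_bonds(12),
    c(1, 10),   # ring A angle-0 atom to ring B angle-180 atom
    c(7, 16),   # ring B angle-0 atom to ring C angle-180 atom
    c(13, 19)   # ring C angle-0 carbon - N
  )
  list(xyz = xyz, name = name, element = el, bonds = bonds)
}

# per-mode probe definitions: site anchor, atoms (head first), inside
# sampling window for the head distance, cutoff for outside placement
.fixture_probes <- function() {
  list(
    PI_PI = list(site = "faceA+", resid = "PHE",
                 inside = c(3.4, 4.0), outside_at = 5.8),
    CH_PI = list(site = "faceA-", resid = "ALA",
                 inside = c(3.4, 4.1), outside_at = 4.8),
    CATION_PI = list(site = "faceB+", resid = "LYS",
                     inside = c(3.5, 5.0), outside_at = 6.3),
    NH_PI = list(site = "faceB-", resid = "GLY",
                 inside = c(3.5, 4.1), outside_at = 4.8),
    OH_PI = list(site = "faceC+", resid = "SER",
                 inside = c(3.5, 4.1), outside_at = 4.8),
    SH_PI = list(site = "faceC-", resid = "CYS",
                 inside = c(3.4, 4.2), outside_at = 4.8),
    HBOND = list(site = "planeO", resid = "SER",
                 inside = c(2.7, 3.2), outside_at = 3.8),
    SALT_BRIDGE = list(site = "planeN", resid = "ASP",
                       inside = c(2.9, 3.5), outside_at = 4.3)
  )
}

# atom positions of a probe residue given its head position and axis
.probe_atoms <- function(mode, head, axis) {
  u <- axis / sqrt(sum(axis^2))
  switch(mode,
    PI_PI = {
      ang <- seq(0, 300, by = 60) * pi / 180
      ring <- t(vapply(ang, function(a) {
        head + c(1.39 * cos(a), 1.39 * sin(a), 0)
      }, numeric(3)))
      list(name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CB"),
           el = rep("C", 7),
           xyz = rbind(ring, head + u * 1.45))
    },
    CH_PI = list(name = c("CB", "CA"), el = c("C", "C"),
                 xyz = rbind(head, head + u * 1.53)),
    CATION_PI = list(name = c("NZ", "CE", "CD"), el = c("N", "C", "C"),
                     xyz = rbind(head, head + u * 1.47, head + u * 2.97)),
    NH_PI = list(name = c("N", "CA"), el = c("N", "C"),
                 xyz = rbind(head, head + u * 1.46)),
    OH_PI = list(name = c("OG", "CB", "CA"), el = c("O", "C", "C"),
                 xyz = rbind(head, head + u * 1.42, head + u * 2.95)),
    SH_PI = list(name = c("SG", "CB", "CA"), el = c("S", "C", "C"),
                 xyz = rbind(head, head + u * 1.81, head + u * 3.33)),
    HBOND = list(name = c("OG", "CB", "CA"), el = c("O", "C", "C"),
                 xyz = rbind(head, head + u * 1.42,
                             head + u * 2.35 + c(0, 1.1, 0))),
    SALT_BRIDGE = list(name = c("OD1", "CG", "OD2", "CB"),
                       el = c("O", "C", "O", "C"),
                       xyz = rbind(head, head + u * 1.25,
                                   head + u * 1.85 + c(0, 1.05, 0),
                                   head + u * 2.55 + c(0, -0.85, 0)))
  )
}

#' Generate a PDB-format complex fixture with planted interactions
#'
#' Builds a planar three-ring ligand (with hydroxyl and amine anchors) at
#' the origin and places one probe residue per requested mode at a
#' prescribed geometry: inside its detection window, or `margin` beyond
#' the mode's cutoff. Fixtures are geometric ground truth for the
#' interaction detectors, not chemically realistic poses.
#'
#' @param modes Character vector of modes to plant (default all 8).
#' @param placement `"inside"` or `"outside"`, either a scalar or a named
#'   vector per mode.
#' @param margin Distance beyond the cutoff for outside placements
#'   (default 0.3).
#' @param seed Optional seed; when given, inside head distances are drawn
#'   uniformly within each mode's placement window, otherwise the window
#'   midpoint is used.
#' @param distances Optional named numeric overrides of the head distance
#'   per mode.
#' @return PDB-format text (ATOM/HETATM/CONECT records) as a single
#'   string, with the seed recorded in a REMARK line.
#' @export
gen_complex_fixture <- function(modes = .contact_modes,
                                placement = "inside", margin = 0.3,
                                seed = NULL, distances = NULL) {
  probes <- .fixture_probes()
  bad <- setdiff(modes, names(probes))
  if (length(bad)) abort(paste0("unknown mode(s): ", paste(bad, collapse = ", ")))
  if (length(placement) == 1 && is.null(names(placement))) {
    placement <- stats::setNames(rep(placement, length(modes)), modes)
  }
  if (!all(modes %in% names(placement))) {
    abort("placement must cover every requested mode")
  }
  .with_seed(seed, {
    site_pos <- list(
      "faceA+" = list(origin = c(-0.5, 0, 0), axis = c(0, 0, 1)),
      "faceA-" = list(origin = c(-0.5, 0, 0), axis = c(0, 0, -1)),
      "faceB+" = list(origin = c(4.26 - 0.5, 0, 0), axis = c(0, 0, 1)),
      "faceB-" = list(origin = c(4.26 - 0.5, 0, 0), axis = c(0, 0, -1)),
      "faceC+" = list(origin = c(8.52 - 0.5, 0, 0), axis = c(0, 0, 1)),
      "faceC-" = list(origin = c(8.52 - 0.5, 0, 0), axis = c(0, 0, -1)),
      "planeO" = list(origin = c(-1.39, 0, 0), axis = c(-1, 0, 0)),
      "planeN" = list(origin = c(11.32, 0, 0), axis = c(1, 0, 0))
    )
    res_atoms <- list()
    resno <- 10L
    for (mode in modes) {
      pr <- probes[[mode]]
      d <- if (!is.null(distances) && mode %in% names(distances)) {
        distances[[mode]]
      } else if (placement[[mode]] == "inside") {
        if (is.null(seed)) mean(pr$inside) else stats::runif(1, pr$inside[1], pr$inside[2])
      } else {
        pr$outside_at + (margin - 0.3)  # outside_at already includes 0.3
      }
      sp <- site_pos[[pr$site]]
      head <- sp$origin + sp$axis * d
      atoms <- .probe_atoms(mode, head, sp$axis)
      res_atoms[[length(res_atoms) + 1]] <- tibble(
        resid = pr$resid, resno = resno, name = atoms$name,
        el = atoms$el,
        x = atoms$xyz[, 1], y = atoms$xyz[, 2], z = atoms$xyz[, 3]
      )
      resno <- resno + 10L
    }
    prot <- if (length(res_atoms)) bind_rows(res_atoms) else
      tibble(resid = character(), resno = integer(), name = character(),
             el = character(), x = numeric(), y = numeric(), z = numeric())
    lig <- .fixture_ligand()

    # clash check across residues and against the ligand
    all_xyz <- rbind(as.matrix(prot[, c("x", "y", "z")]), lig$xyz)
    grp <- c(prot$resno, rep(0L, nrow(lig$xyz)))
    dmat <- .cross_dist(all_xyz, all_xyz)
    diag(dmat) <- Inf
    clash <- which(dmat < 1.5 & outer(grp, grp, "!="), arr.ind = TRUE)
    if (nrow(clash)) {
      abort(sprintf("fixture placement produces %d clash(es) < 1.5 A",
                    nrow(clash) / 2))
    }

    lines <- c(
      "HEADER    SYNTHETIC COMPLEX FIXTURE",
      sprintf("REMARK 300 GENERATED BY pkiprofiler::gen_complex_fixture SEED %s",
              if (is.null(seed)) "NONE" else seed)
    )
    serial <- 1L
    fmt <- function(type, serial, name, resid, chain, resno, x, y, z, el) {
      nm <- if (nchar(name) < 4) paste0(" ", name) else name
      sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              type, serial, nm, " ", resid, chain, resno, " ",
              x, y, z, 1, 0, el)
    }
    for (i in seq_len(nrow(prot))) {
      lines <- c(lines, fmt("ATOM", serial, prot$name[i], prot$resid[i], "A",
                            prot$resno[i], prot$x[i], prot$y[i], prot$z[i],
                            prot$el[i]))
      serial <- serial + 1L
    }
    lig_serial_start <- serial
    for (i in seq_along(lig$name)) {
      lines <- c(lines, fmt("HETATM", serial, lig$name[i], "LIG", "L", 900L,
                            lig$xyz[i, 1], lig$xyz[i, 2], lig$xyz[i, 3],
                            lig$element[i]))
      serial <- serial + 1L
    }
    for (b in seq_len(nrow(lig$bonds))) {
      lines <- c(lines, sprintf("CONECT%5d%5d",
                                lig_serial_start + lig$bonds[b, 1] - 1L,
                                lig_serial_start + lig$bonds[b, 2] - 1L))
    }
    paste(c(lines, "END", ""), collapse = "\n")
  })
}

#' Generate a synthetic per-residue energy ledger
#'
#' Random one-decimal gas-phase and dehydration energies with an exactly
#' consistent aqueous column and mode tags drawn over the 8 interaction
#' modes. Always at least one hydrogen-bonded residue.
#'
#' @param n_residues Number of rows (default 11).
#' @param seed Optional integer seed.
#' @param file Optional path; when given the ledger is also written as CSV.
#' @return A ledger tibble (columns of [read_energy_ledger()]), seed in
#'   attribute `"seed"`.
#' @export
gen_energy_ledger <- function(n_residues = 11, seed = NULL, file = NULL) {
  stopifnot(n_residues >= 1)
  .with_seed(seed, {
    res_names <- c("Met", "Lys", "Tyr", "Phe", "Val", "Ala", "Ile", "Leu",
                   "Gly", "Ser", "Cys", "Thr", "Asp", "Glu")
    tag_pool <- c("H-bond", "salt-bridge", "pi-pi", "CH-pi", "cation-pi",
                  "NH-pi", "OH-pi", "SH-pi")
    residue <- paste0(sample(res_names, n_residues, replace = TRUE),
                      sample(400:999, n_residues))
    modes <- vapply(seq_len(n_residues), function(i) {
      polar <- if (i == 1) TRUE else stats::runif(1) < 0.3
      tags <- character()
      if (polar) tags <- sample(c("H-bond", "salt-bridge"), 1, prob = c(0.85, 0.15))
      n_pi <- sample(0:2, 1, prob = c(if (polar) 0.3 else 0, 0.5, 0.2) /
                       sum(c(if (polar) 0.3 else 0, 0.5, 0.2)))
      tags <- c(tags, sample(setdiff(tag_pool, c("H-bond", "salt-bridge")), n_pi))
      paste(tags, collapse = ", ")
    }, character(1))
    de_gas <- round(stats::runif(n_residues, -13, -1), 1)
    de_deh <- round(stats::runif(n_residues, -0.5, 5.5), 1)
    led <- tibble(
      residue = residue, modes = modes,
      dE_gas = de_gas, dE_deh = de_deh,
      dE_aq = round(de_gas + de_deh, 1)
    )
    attr(led, "seed") <- seed
    if (!is.null(file)) readr::write_csv(led, file)
    led
  })
}
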