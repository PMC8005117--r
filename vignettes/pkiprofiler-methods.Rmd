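---
title: "Methods: descriptors, the exchange rule, and pi-interaction detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, the exchange rule, and pi-interaction detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkiprofiler)
```

## The scientific problem

Protein kinase inhibitors (PKIs) that bind the ATP pocket are strikingly
"flat": they carry unusually many aromatic rings (three on average,
up to eight) and few sp3 carbons. At the same time their hinge-region
hydrogen bonds are famously conserved. This package implements the
analysis chain built around the trade-off between those two features:

1. **Descriptor profiling** of ligand cohorts, including two derived
   descriptors: the *fraction of sp3 carbons*, Fsp3 = Nsp3/nC, and the
   *weighted hydrogen bond count*,
   WHBC = (nHDon + nHAcc)/nSK — the combined donor/acceptor count
   normalised by heavy-atom count, i.e. a size-independent measure of
   hydrogen-bonding capacity.
2. **Drug-likeness screening** against the Lipinski rule of five
   (MW < 500 Da, cLogP < 5, nHDon ≤ 5, nHAcc ≤ 10) and the Veber rule
   (RBN ≤ 10, nHDon + nHAcc < 12, TPSA < 140 Å²).
3. **The exchange rule**: binning a cohort by aromatic ring count and
   fitting mean WHBC against the ring-class abscissa by ordinary least
   squares. A negative slope means hydrogen-bonding capacity is traded
   for aromatic (π-originated) interaction capacity as rings are added.
4. **Geometric detection** of the non-bonded interaction modes those
   rings support in protein–ligand complexes: hydrogen bonds, salt
   bridges, π–π stacking, CH–π, cation–π and XH–π (X = N, O, S).
5. **Energy bookkeeping** over externally computed per-residue
   interaction energies via the thermodynamic cycle
   ΔEint(aq) = ΔEint(g) + ΔEDeh, where ΔEint(g) = E(AB) − E(A) − E(B)
   is the gas-phase supermolecular interaction energy and
   ΔEDeh = ΔGsol(AB) − ΔGsol(A) − ΔGsol(B) the dehydration penalty.
   Quantum-chemical and continuum-solvation engines are out of scope;
   their outputs are consumed as tabulated numbers.

## Descriptor rules and their configurability

The tools that popularised these descriptors do not publish their exact
perception rules, so the package states its own and exposes the genuinely
ambiguous choices via `descriptor_config()`:

- **Donors** (default): N or O bearing at least one hydrogen; S–H
  optionally included.
- **Acceptors** (default `"exclusions"`): every N and O except
  pyrrole-type aromatic N (its lone pair is part of the ring π system),
  amide N, nitro-group O and furan-type aromatic O. An `"all_no"` mode
  counts every N and O; caffeine, for instance, has 6 acceptors under
  the latter and 3 under the former.
- **Aromatic ratio** (default): aromatic heavy atoms / heavy atoms; a
  bond-ratio alternative is available.
- **Rotatable bonds**: single non-ring bonds between two non-terminal
  heavy atoms, excluding amide C–N.
- **cLogP** uses Wildman–Crippen atomic contributions and **TPSA**
  Ertl fragment contributions (both via OpenBabel) — reproducible
  published schemes closest to the cited tools.
- **Aromaticity** is perceived on the kekulised heavy-atom graph by a
  Hückel-style rule over the smallest set of smallest rings (SSSR):
  a 5–7-membered ring is aromatic when every member is sp2-capable and
  the π-electron count satisfies 4n + 2, with lone-pair contributions
  from substituent-free N/O/S and a one-electron contribution for
  kekulé double bonds into a fused partner ring. Fused systems count
  each constituent ring (naphthalene has two aromatic rings).

Fsp3 is by construction in [0, 1]; a published cohort table reports a
maximum of 1.36, which is impossible under the stated definition
(Nsp3 ≤ nC). The package enforces the mathematical range and treats the
printed value as a transcription artefact rather than emulating it.

The `"±"` spread in cohort summaries is reported as the standard error
of the mean: on the published cohort (n = 2139), printed spreads of
~0.03 on means of ~2.2 match SEM, not SD, magnitudes. SD is available
via `summarize_cohort(spread = "sd")`.

## The exchange-line fit

`class_distribution()` bins ligands into ring classes 0–4 and "5+",
mirroring the tabulated cohort structure; `fit_exchange_line()` then
regresses class-mean WHBC on the class abscissa. Three choices were
genuinely open and are resolved as follows (all configurable):

- the "5 and more" class sits at abscissa 5;
- the zero-ring class is excluded from the default fit — in a realistic
  cohort it is a near-singleton and would enter an unweighted fit with
  the same weight as classes holding hundreds of ligands;
- the fit is unweighted OLS; inverse-variance weighting by class SEM is
  available (`weighted = TRUE`).

On the published class means (0.381, 0.369, 0.326, 0.296, 0.293 at
x = 1…5) this yields slope −0.0249 WHBC per ring with r² = 0.94, the
inverse-linear relationship the exchange rule names. `fit_gaussian()`
summarises the per-class WHBC histograms by mu = sample mean and
sigma = sample SD (n − 1 denominator), flagging constant input as
degenerate rather than failing.

## Geometric interaction criteria

The binding-mode taxonomy names the modes but no thresholds, so the
detectors use literature-standard windows, all exposed via
`geometry_criteria()` (distances in Å, angles in degrees):

| mode | primary window | additional terms |
|---|---|---|
| hydrogen bond | D···A ≤ 3.5 (N/O/S) | D–H···A ≥ 120° when H present |
| salt bridge | charged N/O pair ≤ 4.0 | residue/atom-name templates |
| π–π parallel | centroid ≤ 5.5 | interplanar ≤ 30°, offset ≤ 2.5 |
| π–π T-shaped | centroid ≤ 6.0 | interplanar 60–90° |
| CH–π | C ≤ 4.5 to centroid | height ≥ 1.5, offset ≤ ring radius + 1.0 |
| cation–π | N⁺ ≤ 6.0 to centroid | same height/offset window |
| XH–π | X ≤ 4.5 to centroid | same height/offset window |

Criteria are heavy-atom-based by default so that hydrogen-free
depositions work; hydrogen-dependent angle terms activate only when
hydrogens are present. Ligand rings are perceived geometrically —
5–7-membered C/N/O/S cycles of the CONECT- or distance-derived bond
graph whose fitted plane (SVD) has RMS deviation ≤ 0.1 Å — because PDB
ligands carry no bond orders. Protein rings come from fixed atom-name
templates (Phe/Tyr six-rings, both Trp rings, His). Ligand protonation
is unknowable from coordinates, so charged groups are inferred
structurally (aliphatic amine N as cation, carboxylate-like O as anion)
and C–O bond length (≥ 1.32 Å) separates hydroxyls from carbonyls.

Three exclusivity rules keep the mode assignment unambiguous: pairs
satisfying the salt-bridge criterion are not re-reported as hydrogen
bonds; cationic nitrogens belong to cation–π, not NH–π; and the atoms
of a ring pair already reported as π–π stacked are not re-reported
atom-by-atom as CH–π against that same partner ring (pairwise
suppression, mirroring the hierarchy of standard interaction
profilers). Candidate residues are collected with a radius wide enough
for the largest mode window, so no contact is lost to the site
pre-filter; `binding_site_residues()` keeps its conventional 4.5 Å
default for site listings. Symmetry mates are ignored; alternate
locations resolve to the highest-occupancy conformer (ties to 'A').

## Energy-ledger semantics

`validate_ledger()` checks per-row additivity of the cycle sum with a
default tolerance of 0.15 kcal/mol — the worst-case accumulation when
both addends are independently rounded to one decimal. One row of the
shipped ibrutinib–BTK ledger (Lys430: −12.8 + 5.4 printed as −7.3)
carries exactly such a 0.1 kcal/mol rounding residual: it is flagged at
a 0.05 tolerance and passes at the default. `group_by_mode()` assigns
any residue whose tags include a hydrogen bond or salt bridge to the
polar group and all remaining π-tagged residues to the non-bonded-π
group; on the shipped ledger this reproduces the published combined
energies (−0.6 and −22.5 kcal/mol) exactly. A per-interaction energy
partition would need information the ledger does not carry.

## What the synthetic generators emulate — and what they do not

`gen_ligand_cohort()` plants the statistical structure the exchange-rule
analysis assumes: ring classes drawn with the published cohort's
composition (0.05%, 5.5%, 23.7%, 38.3%, 26.7%, 5.8%), WHBC targets
normal around `intercept + slope·min(nAR, 5)` (defaults −0.025/ring and
0.41, the magnitude of the published trend) with noise SD 0.05,
truncated at zero and realised as exact integer triples. The mean is
planted on the ring-class abscissa used by the trend fit — the top class
is realised with a decaying 5–8-ring tail but shares the abscissa-5
mean, since the tabulated relationship being emulated assigns that
open-ended class a single mean at x = 5. Planting on raw ring count
instead would make the generator's truth and the fit's estimand
systematically different quantities. With `smiles = TRUE`, tuples are
realised as parseable molecules from a fragment grammar (benzene /
pyridine / pyrimidine rings, alkyl linkers, hydroxyl / amine / methoxy
decorations) whose descriptor counts reproduce the tuple exactly under
both acceptor modes.

`gen_complex_fixture()` places probe residues at prescribed geometries
around a planar three-ring ligand: one probe per mode, inside its
window or a set margin (default 0.3 Å) beyond its cutoff, with clash
rejection below 1.5 Å. The fixtures are geometric, not chemical, ground
truth: probe residues are truncated to the atoms the detectors read,
rings are ideal hexagons, and no forcefield realism is claimed.
Passing detector tests on these fixtures demonstrates that the
geometric windows are implemented correctly and bounded as documented —
not that the windows themselves are optimal for real binding sites.
Likewise, cohort-level tests demonstrate estimator correctness under
the planted model, not that real PKI cohorts follow that model.
Checks against deposited structures (ibrutinib–BTK 5P9I, with its
2.99/2.82 Å hinge hydrogen bonds, and lenvatinib–VEGFR2 3WZD) require
downloading two coordinate files and are shipped as opt-in tests that
activate when the files are placed under `tests/testthat/structures/`.

All generators route randomness through a single seeded RNG per call,
restore the caller's RNG state, and record the seed in their output
(PDB REMARK line or attribute), so every synthetic input is exactly
reproducible across platforms.

## Numerical choices and problem sizes

Percentages and group sums are exact count arithmetic; OLS goes through
`stats::lm`; ring planes through SVD. Test problem sizes are chosen to
give stable statistics at interactive runtimes: slope-recovery checks
use 50 cohorts of n = 2000 (the published cohort's order of magnitude),
detector oracles use 20 randomised fixtures plus per-mode
inside/outside pairs, and the donor/acceptor brute-force comparison
uses 100 grammar-generated molecules.

## Known limitations

- Aromaticity perception targets drug-like chemistry; exotic systems
  (charged carbocycles, fused heteroaromatics with unusual tautomers)
  may be mis-perceived — as they are, differently, by any fixed rule set.
- Heavy-atom interaction criteria cannot see protonation or tautomeric
  state; His is treated as neutral by default (`his_cation = TRUE` to
  override).
- Ligand bond perception falls back to covalent-radius distances when
  CONECT records are absent; severely distorted ligands may gain or
  lose bonds.
- The curation blocklist is a documented stand-in for an unrecorded
  inhibitor/bystander separation step; it is deterministic but not a
  reconstruction of the original procedure.
- mmCIF input, halogen bonds, water-mediated bridges and metal
  coordination are out of scope.
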