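## Interface interaction detection and per-frame counting.
##
## All geometric thresholds are inclusive (<=, and closed angle windows); they
## live in `interaction_criteria()` so every run can override them from config.
## Distances are direct Euclidean: frames must be pre-imaged (see ensemble docs).

#' Geometric criteria for interaction detection
#'
#' Defaults: interface residues from heavy-atom pairs within 4.5 A; hydrogen
#' bonds from heavy-atom donor-acceptor distance <= 3.5 A with donor-H-acceptor
#' angle in [120, 180] degrees; salt bridges from side-chain N/O pairs of
#' oppositely charged residues <= 4.5 A (ion contacts reuse this cutoff);
#' cation-pi from ring-centroid to cation distance <= 6 A with the
#' centroid-cation vector at [0, 60] or [120, 180] degrees to the ring normal;
#' pi-stacking from ring-centroid distance <= 6 A (distance only); hydrophobic
#' contacts from hydrophobic atom pairs <= 4.5 A, counted per residue pair.
#'
#' @param interface_heavy_cutoff,hbond_da_cutoff,salt_cutoff,cation_pi_cutoff,pi_stack_cutoff,hydrophobic_cutoff distances in Angstrom.
#' @param hbond_angle_range,cation_pi_angle_windows angle limits in degrees.
#' @param include_his_cation treat protonated-His ring nitrogens as cations for
#'   cation-pi (off by default).
#' @return named list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(interface_heavy_cutoff = 4.5,
                                 hbond_da_cutoff = 3.5,
                                 hbond_angle_range = c(120, 180),
                                 salt_cutoff = 4.5,
                                 cation_pi_cutoff = 6.0,
                                 cation_pi_angle_windows = list(c(0, 60), c(120, 180)),
                                 pi_stack_cutoff = 6.0,
                                 hydrophobic_cutoff = 4.5,
                                 include_his_cation = FALSE) {
  cr <- list(interface_heavy_cutoff = interface_heavy_cutoff,
             hbond_da_cutoff = hbond_da_cutoff,
             hbond_angle_range = hbond_angle_range,
             salt_cutoff = salt_cutoff,
             cation_pi_cutoff = cation_pi_cutoff,
             cation_pi_angle_windows = cation_pi_angle_windows,
             pi_stack_cutoff = pi_stack_cutoff,
             hydrophobic_cutoff = hydrophobic_cutoff,
             include_his_cation = include_his_cation)
  stopifnot(all(unlist(cr[c(1, 2, 4, 5, 7, 8)]) > 0))
  class(cr) <- "interaction_criteria"
  cr
}

INTERACTION_KINDS <- c("hbond_direct", "hbond_bridge", "hbond_solvent",
                       "salt_bridge", "cation_pi", "pi_stack",
                       "hydrophobic_residue", "ion_contact")

## ---------------------------------------------------------------------------
## Atom typing tables (residue-template based; paper-silent conventions)

# side-chain N/O atoms of charged residues at pH 7.4
.SALT_POS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                  HIP = c("ND1", "NE2"))
.SALT_NEG <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.CATION_ATOMS <- list(LYS = "NZ", ARG = "CZ")
.CATION_ATOMS_HIS <- list(HIP = c("ND1", "NE2"))

.RING_TEMPLATES <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HID = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HIE = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

# carbon/sulfur atoms whose template neighbours include no N or O
.HYDROPHOBIC_ATOMS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  PRO = c("CB", "CG"), THR = "CG2", LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"), GLN = c("CB", "CG"), GLU = c("CB", "CG"),
  ASN = "CB", ASP = "CB", HIS = "CB", HID = "CB", HIE = "CB", HIP = "CB",
  CYS = c("CB", "SG")
)

.res_key <- function(atoms, idx = seq_len(nrow(atoms))) {
  paste(atoms$chain[idx], atoms$resid[idx], sep = ":")
}

## ---------------------------------------------------------------------------
## Interface definition

#' Identify interface residues between two selections
#'
#' A residue belongs to the interface iff one of its non-hydrogen atoms lies
#' within `interface_heavy_cutoff` of a non-hydrogen atom of the other
#' selection.
#'
#' @param model `structure_model`.
#' @param coords N x 3 frame coordinates.
#' @param fv_idx,ag_idx disjoint atom index sets.
#' @param criteria [interaction_criteria()].
#' @return list(fv_residues, ag_residues) of "chain:resid" keys.
#' @export
define_interface <- function(model, coords, fv_idx, ag_idx,
                             criteria = interaction_criteria()) {
  if (!length(fv_idx) || !length(ag_idx)) stop("empty selection")
  if (length(intersect(fv_idx, ag_idx))) stop("selections must be disjoint")
  at <- model$atoms
  f <- fv_idx[!at$is_hydrogen[fv_idx]]
  a <- ag_idx[!at$is_hydrogen[ag_idx]]
  d <- cross_dist(coords[f, , drop = FALSE], coords[a, , drop = FALSE])
  hit <- which(d <= criteria$interface_heavy_cutoff, arr.ind = TRUE)
  list(fv_residues = sort(unique(.res_key(at, f[hit[, 1]]))),
       ag_residues = sort(unique(.res_key(at, a[hit[, 2]]))))
}

## ---------------------------------------------------------------------------
## Hydrogen bonds

# hydrogen -> parent heavy atom (nearest N/O/S within 1.25 A, same residue)
.donor_h_pairs <- function(model, coords, idx) {
  at <- model$atoms
  h_idx <- idx[at$is_hydrogen[idx]]
  parent_ok <- idx[!at$is_hydrogen[idx] & at$element[idx] %in% c("N", "O", "S")]
  if (!length(h_idx) || !length(parent_ok)) {
    return(data.frame(donor = integer(), hydrogen = integer()))
  }
  d <- cross_dist(coords[h_idx, , drop = FALSE], coords[parent_ok, , drop = FALSE])
  same_res <- outer(.res_key(at, h_idx), .res_key(at, parent_ok), "==")
  d[!same_res] <- Inf
  j <- apply(d, 1, which.min)
  ok <- d[cbind(seq_along(h_idx), j)] <= 1.25
  data.frame(donor = parent_ok[j[ok]], hydrogen = h_idx[ok])
}

#' Detect hydrogen bonds from one selection (donors) to another (acceptors)
#'
#' Donors are N/O/S atoms carrying at least one covalently associated hydrogen
#' (nearest N/O/S within 1.25 A in the same residue); acceptors are N/O atoms.
#' A bond requires heavy-atom donor-acceptor distance <= `hbond_da_cutoff` and
#' donor-H-acceptor angle within `hbond_angle_range`. Run twice with swapped
#' selections for both directions.
#'
#' @param model `structure_model`.
#' @param coords N x 3 coordinates.
#' @param donor_set atom indices of the donating molecule (must include its
#'   hydrogens).
#' @param acceptor_set atom indices of the accepting molecule.
#' @param criteria [interaction_criteria()].
#' @param exclude_same_residue drop donor/acceptor pairs within one residue
#'   (always sensible; intramolecular counting relies on it).
#' @return data.frame(donor, hydrogen, acceptor, distance, angle).
#' @export
detect_hydrogen_bonds <- function(model, coords, donor_set, acceptor_set,
                                  criteria = interaction_criteria(),
                                  exclude_same_residue = TRUE) {
  at <- model$atoms
  if (!any(at$is_hydrogen[donor_set])) {
    stop("hydrogen-bond analysis requires explicit hydrogens in the donor selection")
  }
  dh <- .donor_h_pairs(model, coords, donor_set)
  acc <- acceptor_set[!at$is_hydrogen[acceptor_set] &
                        at$element[acceptor_set] %in% c("N", "O")]
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  if (!nrow(dh) || !length(acc)) return(empty)
  d_da <- cross_dist(coords[dh$donor, , drop = FALSE], coords[acc, , drop = FALSE])
  hit <- which(d_da <= criteria$hbond_da_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- vector("list", nrow(hit))
  n_out <- 0L
  for (r in seq_len(nrow(hit))) {
    i <- hit[r, 1]; j <- hit[r, 2]
    don <- dh$donor[i]; hyd <- dh$hydrogen[i]; a <- acc[j]
    if (a == don) next
    if (exclude_same_residue &&
        .res_key(at, don) == .res_key(at, a)) next
    ang <- vertex_angle(coords[don, ], coords[hyd, ], coords[a, ])
    # 1e-9 degree slack keeps the closed angle window inclusive under fp error
    if (ang >= criteria$hbond_angle_range[1] - 1e-9 &&
        ang <= criteria$hbond_angle_range[2] + 1e-9) {
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(donor = don, hydrogen = hyd, acceptor = a,
                                 distance = d_da[i, j], angle = ang)
    }
  }
  if (!n_out) return(empty)
  do.call(rbind, out[seq_len(n_out)])
}

## ---------------------------------------------------------------------------
## Salt bridges, ion contacts

`%||%` <- function(a, b) if (is.null(a)) b else a

.charged_atoms <- function(model, idx, sign) {
  at <- model$atoms
  tab <- if (sign > 0) .SALT_POS else .SALT_NEG
  if (!length(idx)) return(integer())
  sel <- idx[mapply(function(rn, nm) nm %in% (tab[[rn]] %||% ""),
                    at$resname[idx], at$name[idx])]
  if (sign < 0) sel <- sort(unique(c(sel, idx[at$name[idx] == "OXT"])))
  sel
}

#' Detect salt bridges between two selections
#'
#' Side-chain oxygen/nitrogen atoms of oppositely charged residues (Arg NE/NH*,
#' Lys NZ, protonated His ND1/NE2 positive; Asp OD*, Glu OE* and C-terminal
#' OXT negative) within `salt_cutoff`. One record per qualifying atom pair.
#'
#' @inheritParams detect_hydrogen_bonds
#' @param set1,set2 atom index sets of the two molecules (use the same set
#'   twice for intramolecular counting, same-residue pairs are excluded).
#' @return data.frame(pos_atom, neg_atom, distance).
#' @export
detect_salt_bridges <- function(model, coords, set1, set2,
                                criteria = interaction_criteria()) {
  at <- model$atoms
  empty <- data.frame(pos_atom = integer(), neg_atom = integer(),
                      distance = numeric())
  recs <- list(); n <- 0L
  for (dir in 1:2) {
    pos <- .charged_atoms(model, if (dir == 1) set1 else set2, +1)
    neg <- .charged_atoms(model, if (dir == 1) set2 else set1, -1)
    if (!length(pos) || !length(neg)) next
    d <- cross_dist(coords[pos, , drop = FALSE], coords[neg, , drop = FALSE])
    hit <- which(d <= criteria$salt_cutoff, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      p <- pos[hit[r, 1]]; q <- neg[hit[r, 2]]
      if (.res_key(at, p) == .res_key(at, q)) next
      n <- n + 1L
      recs[[n]] <- data.frame(pos_atom = p, neg_atom = q,
                              distance = d[hit[r, 1], hit[r, 2]])
    }
  }
  if (!n) return(empty)
  out <- unique(do.call(rbind, recs))
  out[order(out$pos_atom, out$neg_atom), , drop = FALSE]
}

#' Detect ion contacts with a molecule
#'
#' Salt-bridge thresholds applied to ion / N-or-O atom pairs.
#'
#' @inheritParams detect_salt_bridges
#' @param mol_idx atom indices of the molecule (typically the Fv).
#' @param ion_idx atom indices with role ion.
#' @return data.frame(ion, atom, distance).
#' @export
detect_ion_contacts <- function(model, coords, mol_idx, ion_idx,
                                criteria = interaction_criteria()) {
  at <- model$atoms
  empty <- data.frame(ion = integer(), atom = integer(), distance = numeric())
  part <- mol_idx[at$element[mol_idx] %in% c("N", "O")]
  if (!length(ion_idx) || !length(part)) return(empty)
  d <- cross_dist(coords[ion_idx, , drop = FALSE], coords[part, , drop = FALSE])
  hit <- which(d <= criteria$salt_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(ion = ion_idx[hit[, 1]], atom = part[hit[, 2]],
                    distance = d[hit])
  out[order(out$ion, out$atom), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Aromatic rings: cation-pi and pi-stacking

#' Enumerate aromatic rings in a selection
#'
#' Rings are taken from residue templates (Phe/Tyr six-ring, Trp five- and
#' six-ring separately, neutral His five-ring). A residue presenting only part
#' of a ring template is a structure error.
#'
#' @inheritParams detect_salt_bridges
#' @param idx atom index set to search.
#' @return list of lists with elements `atoms` (indices), `centroid`, `normal`.
#' @export
find_rings <- function(model, coords, idx) {
  at <- model$atoms
  rings <- list()
  keys <- unique(.res_key(at, idx))
  for (k in keys) {
    ridx <- idx[.res_key(at, idx) == k]
    rn <- at$resname[ridx[1]]
    tmpl <- .RING_TEMPLATES[[rn]]
    if (is.null(tmpl)) next
    for (ring_names in tmpl) {
      have <- ridx[at$name[ridx] %in% ring_names]
      if (!length(have)) next
      if (length(have) < length(ring_names)) {
        stop("incomplete aromatic ring in residue ", k, " (", rn, "): ",
             length(have), " of ", length(ring_names), " atoms present")
      }
      xyz <- coords[have, , drop = FALSE]
      cen <- colMeans(xyz)
      sv <- svd(sweep(xyz, 2, cen))
      rings[[length(rings) + 1]] <- list(atoms = have, residue = k,
                                         centroid = cen, normal = sv$v[, 3])
    }
  }
  rings
}

.cation_atoms <- function(model, idx, include_his) {
  if (!length(idx)) return(integer())
  at <- model$atoms
  tab <- .CATION_ATOMS
  if (include_his) tab <- c(tab, .CATION_ATOMS_HIS)
  idx[mapply(function(rn, nm) nm %in% (tab[[rn]] %||% ""),
             at$resname[idx], at$name[idx])]
}

#' Detect cation-pi interactions between two selections
#'
#' Cations (Lys NZ, Arg CZ; optionally protonated-His ring N) against aromatic
#' rings; requires centroid-cation distance <= `cation_pi_cutoff` and the angle
#' between the centroid->cation vector and the ring normal inside one of the
#' `cation_pi_angle_windows`.
#'
#' @inheritParams detect_salt_bridges
#' @return data.frame(cation, ring_residue, distance, angle).
#' @export
detect_cation_pi <- function(model, coords, set1, set2,
                             criteria = interaction_criteria()) {
  empty <- data.frame(cation = integer(), ring_residue = character(),
                      distance = numeric(), angle = numeric())
  recs <- list(); n <- 0L
  for (dir in 1:2) {
    cat_idx <- .cation_atoms(model, if (dir == 1) set1 else set2,
                             criteria$include_his_cation)
    rings <- find_rings(model, coords, if (dir == 1) set2 else set1)
    for (ci in cat_idx) {
      for (rg in rings) {
        v <- coords[ci, ] - rg$centroid
        dist <- sqrt(sum(v^2))
        if (dist > criteria$cation_pi_cutoff) next
        ang <- acos(pmin(1, pmax(-1, sum(v * rg$normal) / dist))) * 180 / pi
        in_win <- any(vapply(criteria$cation_pi_angle_windows,
                             function(w) ang >= w[1] - 1e-9 && ang <= w[2] + 1e-9,
                             logical(1)))
        if (in_win) {
          n <- n + 1L
          recs[[n]] <- data.frame(cation = ci, ring_residue = rg$residue,
                                  distance = dist, angle = ang)
        }
      }
    }
  }
  if (!n) return(empty)
  do.call(rbind, recs)
}

#' Detect pi-stacking between two selections
#'
#' Ring-centroid to ring-centroid distance <= `pi_stack_cutoff`; no angle
#' criterion is applied (distance-only rule).
#'
#' @inheritParams detect_salt_bridges
#' @return data.frame(ring1_residue, ring2_residue, distance).
#' @export
detect_pi_stacking <- function(model, coords, set1, set2,
                               criteria = interaction_criteria()) {
  r1 <- find_rings(model, coords, set1)
  r2 <- find_rings(model, coords, set2)
  empty <- data.frame(ring1_residue = character(), ring2_residue = character(),
                      distance = numeric())
  recs <- list(); n <- 0L
  for (a in r1) for (b in r2) {
    if (a$residue == b$residue) next
    dist <- sqrt(sum((a$centroid - b$centroid)^2))
    if (dist <= criteria$pi_stack_cutoff) {
      n <- n + 1L
      recs[[n]] <- data.frame(ring1_residue = a$residue,
                              ring2_residue = b$residue, distance = dist)
    }
  }
  if (!n) return(empty)
  do.call(rbind, recs)
}

## ---------------------------------------------------------------------------
## Hydrophobic residue contacts

.hydrophobic_atoms <- function(model, idx) {
  if (!length(idx)) return(integer())
  at <- model$atoms
  idx[mapply(function(rn, nm) nm %in% (.HYDROPHOBIC_ATOMS[[rn]] %||% ""),
             at$resname[idx], at$name[idx])]
}

#' Detect hydrophobic contacts, counted by residue pair
#'
#' Hydrophobic atoms are template carbons/sulfurs with no N/O neighbour.
#' Any number of qualifying atom pairs <= `hydrophobic_cutoff` between two
#' residues collapses to a single residue-pair record.
#'
#' @inheritParams detect_salt_bridges
#' @return data.frame(res1, res2, min_distance, n_atom_pairs).
#' @export
detect_hydrophobic <- function(model, coords, set1, set2,
                               criteria = interaction_criteria()) {
  at <- model$atoms
  h1 <- .hydrophobic_atoms(model, set1)
  h2 <- .hydrophobic_atoms(model, set2)
  empty <- data.frame(res1 = character(), res2 = character(),
                      min_distance = numeric(), n_atom_pairs = integer())
  if (!length(h1) || !length(h2)) return(empty)
  d <- cross_dist(coords[h1, , drop = FALSE], coords[h2, , drop = FALSE])
  hit <- which(d <= criteria$hydrophobic_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  k1 <- .res_key(at, h1[hit[, 1]])
  k2 <- .res_key(at, h2[hit[, 2]])
  same <- k1 == k2
  hit <- hit[!same, , drop = FALSE]; k1 <- k1[!same]; k2 <- k2[!same]
  if (!nrow(hit)) return(empty)
  # unordered residue pair key so intra-molecular double counting collapses
  lo <- pmin(k1, k2); hi <- pmax(k1, k2)
  key <- paste(lo, hi, sep = "|")
  agg <- tapply(d[hit], key, min)
  cnt <- tapply(d[hit], key, length)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  out <- data.frame(res1 = vapply(parts, `[`, "", 1),
                    res2 = vapply(parts, `[`, "", 2),
                    min_distance = as.numeric(agg),
                    n_atom_pairs = as.integer(cnt))
  out[order(out$res1, out$res2), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Bridging waters

#' Classify waters as bridging and report antibody-side hydrogen bonds
#'
#' A water is bridging iff, in the same frame, it forms at least one hydrogen
#' bond (either donor/acceptor direction) to the Fv selection AND one to the
#' antigen selection. Only first-order bridges count (one water between the two
#' molecules; water-water chains are excluded). Returns one `hbond_bridge`
#' record per antibody-side hydrogen bond through a bridging water, plus
#' `hbond_solvent` records for antibody-side bonds to non-bridging waters.
#'
#' @inheritParams detect_salt_bridges
#' @param fv_idx antibody atom indices (with hydrogens).
#' @param ag_idx antigen atom indices (with hydrogens); may be empty (apo), in
#'   which case every water bond is a solvent bond.
#' @param water_idx atom indices with role water.
#' @return list(bridge = records, solvent = records, bridging_waters =
#'   residue keys); records as in [detect_hydrogen_bonds()] plus `water`.
#' @export
detect_bridging_waters <- function(model, coords, fv_idx, ag_idx, water_idx,
                                   criteria = interaction_criteria()) {
  at <- model$atoms
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric(), water = character())
  if (!length(water_idx)) {
    return(list(bridge = empty, solvent = empty, bridging_waters = character()))
  }
  bond_both_ways <- function(mol, wat) {
    # an acceptor-only molecule side (no hydrogens) can still receive from water
    a <- if (any(at$is_hydrogen[mol])) {
      detect_hydrogen_bonds(model, coords, mol, wat, criteria)
    } else {
      data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
                 distance = numeric(), angle = numeric())
    }
    b <- detect_hydrogen_bonds(model, coords, wat, mol, criteria)
    ab <- rbind(a, b)
    if (nrow(ab)) {
      ab$water <- ifelse(at$role[ab$donor] %in% "water",
                         .res_key(at, ab$donor), .res_key(at, ab$acceptor))
    } else ab$water <- character(0)
    ab
  }
  fv_w <- bond_both_ways(fv_idx, water_idx)
  ag_w <- if (length(ag_idx)) bond_both_ways(ag_idx, water_idx) else empty
  bridging <- intersect(unique(fv_w$water), unique(ag_w$water))
  list(bridge = fv_w[fv_w$water %in% bridging, , drop = FALSE],
       solvent = fv_w[!fv_w$water %in% bridging, , drop = FALSE],
       bridging_waters = sort(bridging))
}

## ---------------------------------------------------------------------------
## Intramolecular counts

#' Count intramolecular interactions within one molecule
#'
#' Every interaction kind is evaluated within the selection; pairs within one
#' residue are excluded, sequence-adjacent pairs (i+1, i+2, i+3) are included.
#'
#' @inheritParams detect_salt_bridges
#' @param sel atom indices of the molecule (with hydrogens).
#' @return named integer vector: hbond, salt_bridge, cation_pi, pi_stack,
#'   hydrophobic_residue.
#' @export
count_intramolecular <- function(model, coords, sel,
                                 criteria = interaction_criteria()) {
  hb <- detect_hydrogen_bonds(model, coords, sel, sel, criteria,
                              exclude_same_residue = TRUE)
  sb <- detect_salt_bridges(model, coords, sel, sel, criteria)
  cp <- detect_cation_pi(model, coords, sel, sel, criteria)
  # within one molecule both directions see the same cation/ring pairs twice
  if (nrow(cp)) cp <- unique(cp)
  ps <- detect_pi_stacking(model, coords, sel, sel, criteria)
  if (nrow(ps)) {
    key <- paste(pmin(ps$ring1_residue, ps$ring2_residue),
                 pmax(ps$ring1_residue, ps$ring2_residue))
    ps <- ps[!duplicated(paste(key, round(ps$distance, 6))), , drop = FALSE]
  }
  hp <- detect_hydrophobic(model, coords, sel, sel, criteria)
  c(hbond = nrow(hb), salt_bridge = nrow(unique(sb)), cation_pi = nrow(cp),
    pi_stack = nrow(ps), hydrophobic_residue = nrow(hp))
}

## ---------------------------------------------------------------------------
## Trajectory summary

.restrict_to_residues <- function(model, idx, res_keys) {
  idx[.res_key(model$atoms, idx) %in% res_keys]
}

.frame_counts <- function(model, coords, fv_idx, ag_idx, water_idx, ion_idx,
                          solvent_fv_idx, criteria) {
  counts <- stats::setNames(numeric(length(INTERACTION_KINDS)), INTERACTION_KINDS)
  if (length(ag_idx)) {
    counts["hbond_direct"] <-
      nrow(detect_hydrogen_bonds(model, coords, fv_idx, ag_idx, criteria)) +
      nrow(detect_hydrogen_bonds(model, coords, ag_idx, fv_idx, criteria))
    counts["salt_bridge"] <- nrow(detect_salt_bridges(model, coords, fv_idx,
                                                      ag_idx, criteria))
    counts["cation_pi"] <- nrow(detect_cation_pi(model, coords, fv_idx, ag_idx,
                                                 criteria))
    counts["pi_stack"] <- nrow(detect_pi_stacking(model, coords, fv_idx, ag_idx,
                                                  criteria))
    counts["hydrophobic_residue"] <- nrow(detect_hydrophobic(model, coords,
                                                             fv_idx, ag_idx,
                                                             criteria))
  }
  bw <- detect_bridging_waters(model, coords, solvent_fv_idx, ag_idx,
                               water_idx, criteria)
  counts["hbond_bridge"] <- nrow(bw$bridge)
  counts["hbond_solvent"] <- nrow(bw$solvent)
  counts["ion_contact"] <- nrow(detect_ion_contacts(model, coords, fv_idx,
                                                    ion_idx, criteria))
  counts
}

#' Summarise intermolecular interactions over a trajectory
#'
#' In `fluctuating_interface` mode (default) the full antibody/antigen
#' cross-molecule atom sets are scanned every frame, capturing all interactions
#' as the system fluctuates. In `fixed_interface` mode detectors are restricted
#' to a reference interface residue selection (e.g. from a crystal structure),
#' supplied as `reference_interface` (the result of [define_interface()]).
#' Solvent hydrogen bonds use the antibody interface atoms including their
#' hydrogens; in fluctuating mode the whole Fv is eligible.
#'
#' @param ens an [ensemble()] with roles assigned.
#' @param mode "fluctuating_interface" or "fixed_interface".
#' @param reference_interface required for fixed mode; list(fv_residues,
#'   ag_residues) of "chain:resid" keys.
#' @param criteria [interaction_criteria()].
#' @param stride analyse every `stride`-th frame (default 1).
#' @return object of class `interaction_summary`: list(per_frame = T x kinds
#'   matrix, mean, sd, mode).
#' @export
summarize_trajectory <- function(ens, mode = c("fluctuating_interface",
                                               "fixed_interface"),
                                 reference_interface = NULL,
                                 criteria = interaction_criteria(),
                                 stride = 1L) {
  mode <- match.arg(mode)
  if (mode == "fixed_interface" && is.null(reference_interface)) {
    stop("fixed_interface mode requires reference_interface")
  }
  model <- ens$topology
  at <- model$atoms
  fv_all <- which(!is.na(at$role) & at$role %in% c("heavy", "light"))
  ag_all <- which(!is.na(at$role) & at$role == "antigen")
  water_idx <- which(!is.na(at$role) & at$role == "water")
  ion_idx <- which(!is.na(at$role) & at$role == "ion")
  if (!length(fv_all)) stop("no atoms with role heavy/light")
  if (!any(at$is_hydrogen[fv_all])) {
    stop("structure has no hydrogens on the Fv; hydrogen-bond analysis needs ",
         "explicit protonation")
  }
  fv_idx <- fv_all; ag_idx <- ag_all; solvent_fv <- fv_all
  if (mode == "fixed_interface") {
    fv_idx <- .restrict_to_residues(model, fv_all, reference_interface$fv_residues)
    ag_idx <- .restrict_to_residues(model, ag_all, reference_interface$ag_residues)
    solvent_fv <- fv_idx
  }
  frames <- seq(1, dim(ens$frames)[1], by = stride)
  per <- t(vapply(frames, function(i) {
    .frame_counts(model, get_frame(ens, i), fv_idx, ag_idx, water_idx,
                  ion_idx, solvent_fv, criteria)
  }, stats::setNames(numeric(length(INTERACTION_KINDS)), INTERACTION_KINDS)))
  sds <- if (nrow(per) > 1) apply(per, 2, stats::sd) else
    stats::setNames(numeric(ncol(per)), colnames(per))
  structure(list(per_frame = per,
                 mean = colMeans(per),
                 sd = sds,
                 mode = mode, frames = frames),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat("interaction summary (", x$mode, ", ", nrow(x$per_frame), " frames)\n", sep = "")
  print(data.frame(kind = names(x$mean), mean = round(x$mean, 3),
                   sd = round(x$sd, 3), row.names = NULL))
  invisible(x)
}

#' Percentage of intermolecular interactions not formed with bulk solvent
#'
#' Bridging waters count as intermolecular contacts; bulk-solvent hydrogen
#' bonds are the excluded class. Also returns the stricter non-solvent,
#' non-hydrophobic percentage. Computed from per-kind trajectory means.
#'
#' @param summary an `interaction_summary` from a holo system.
#' @return named numeric: nonsolvent_pct, nonsolvent_nonhydrophobic_pct,
#'   hydrophobic_pct, total_mean.
#' @export
nonsolvent_fraction <- function(summary) {
  m <- summary$mean
  total <- sum(m)
  if (total <= 0) stop("zero total interactions; nonsolvent fraction undefined")
  ns <- 100 * (total - m[["hbond_solvent"]]) / total
  nsnh <- 100 * (total - m[["hbond_solvent"]] - m[["hydrophobic_residue"]]) / total
  c(nonsolvent_pct = ns, nonsolvent_nonhydrophobic_pct = nsnh,
    hydrophobic_pct = 100 * m[["hydrophobic_residue"]] / total,
    total_mean = total)
}
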