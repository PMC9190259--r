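# Geometric detectors: inclusive thresholds, typing rules, water classes,
# oracle equivalence on random fixtures, trajectory summaries.

simple_pair_model <- function(d_fv_ag, with_h = TRUE, h_toward = TRUE) {
  # Fv backbone N(-H) donor vs antigen carbonyl O acceptor at distance d
  rows <- data.frame(
    serial = 1:4,
    name = c("N", "H", "O", "C"),
    element = c("N", "H", "O", "C"),
    resname = c("GLY", "GLY", "GLY", "GLY"),
    resid = c(1, 1, 1, 1),
    chain = c("H", "H", "A", "A"),
    x = 0, y = c(0, 1, d_fv_ag, d_fv_ag + 1.23), z = 0)
  if (!h_toward) rows$y[2] <- -1
  if (!with_h) rows <- rows[-2, ]
  fixture_model(rows, roles = c(H = "heavy", A = "antigen"))
}

test_that("interface residues follow the inclusive 4.5 A heavy-atom rule", {
  for (case in list(list(d = 4.4, n = 1), list(d = 4.5, n = 1),
                    list(d = 4.6, n = 0))) {
    fx <- simple_pair_model(case$d)
    iface <- define_interface(fx$model, fx$coords, 1:2, 3:4)
    expect_length(iface$fv_residues, case$n)
    expect_length(iface$ag_residues, case$n)
  }
  # hydrogens never define the interface: H at 3.0 A but heavy atoms far
  at <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                   element = c("N", "H", "O"), resname = "GLY",
                   resid = c(1, 1, 2), chain = c("H", "H", "A"),
                   x = 0, y = c(0, 3.2, 6.2), z = 0)
  fx <- fixture_model(at)
  iface <- define_interface(fx$model, fx$coords, 1:2, 3)
  expect_length(iface$fv_residues, 0)
  expect_error(define_interface(fx$model, fx$coords, integer(), 3), "empty")
})

test_that("hydrogen bonds respect both the 3.5 A and the 120-180 degree rule", {
  hb_at <- function(d, angle_ok = TRUE) {
    fx <- simple_pair_model(d)
    if (!angle_ok) NULL
    nrow(detect_hydrogen_bonds(fx$model, fx$coords, 1:2, 3:4))
  }
  expect_equal(hb_at(3.4), 1L)   # collinear: angle 180
  expect_equal(hb_at(3.5), 1L)   # inclusive boundary
  expect_equal(hb_at(3.6), 0L)
  # angle boundary: place acceptor so D-H-A is exactly 119 / 120 degrees
  angle_case <- function(theta_deg) {
    r <- 2.0  # H-A distance; D at origin-H along +y
    th <- theta_deg * pi / 180
    a_pos <- c(r * sin(th), 1 - r * cos(th), 0)  # H at (0,1,0), D at (0,0,0)
    at <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                     element = c("N", "H", "O"), resname = "GLY",
                     resid = c(1, 1, 2), chain = c("H", "H", "A"),
                     x = c(0, 0, a_pos[1]), y = c(0, 1, a_pos[2]),
                     z = c(0, 0, a_pos[3]))
    fx <- fixture_model(at)
    nrow(detect_hydrogen_bonds(fx$model, fx$coords, 1:2, 3))
  }
  expect_equal(angle_case(180), 1L)
  expect_equal(angle_case(120), 1L)
  expect_equal(angle_case(119), 0L)
  # no hydrogens in the donor set is an explicit error, not a silent zero
  fx <- simple_pair_model(3.0, with_h = FALSE)
  expect_error(detect_hydrogen_bonds(fx$model, fx$coords, 1, 2:3),
               "explicit hydrogens")
})

test_that("salt bridges take side-chain N/O pairs only, inclusive at 4.5 A", {
  salt_case <- function(d, neg_name = "OD1", neg_res = "ASP") {
    at <- data.frame(serial = 1:2, name = c("NZ", neg_name),
                     element = c("N", "O"), resname = c("LYS", neg_res),
                     resid = 1:2, chain = c("H", "A"),
                     x = 0, y = c(0, d), z = 0)
    fx <- fixture_model(at)
    nrow(detect_salt_bridges(fx$model, fx$coords, 1, 2))
  }
  expect_equal(salt_case(4.5), 1L)
  expect_equal(salt_case(4.6), 0L)
  # backbone carbonyl O is not a salt-bridge partner even at 3.0 A
  expect_equal(salt_case(3.0, neg_name = "O", neg_res = "GLY"), 0L)
})

test_that("cation-pi uses centroid distance and the two angle windows", {
  cation_ring <- function(dist, angle_deg) {
    th <- seq(0, 2 * pi, length.out = 7)[1:6]
    ring <- data.frame(serial = 1:6,
                       name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                       element = "C", resname = "PHE", resid = 1, chain = "A",
                       x = 1.39 * cos(th), y = 1.39 * sin(th), z = 0)
    phi <- angle_deg * pi / 180   # angle from ring normal (z axis)
    nz <- data.frame(serial = 7, name = "NZ", element = "N", resname = "LYS",
                     resid = 2, chain = "H",
                     x = dist * sin(phi), y = 0, z = dist * cos(phi))
    fx <- fixture_model(rbind(ring, nz))
    nrow(detect_cation_pi(fx$model, fx$coords, 7, 1:6))
  }
  expect_equal(cation_ring(5.9, 20), 1L)
  expect_equal(cation_ring(6.0, 0), 1L)     # inclusive distance
  expect_equal(cation_ring(6.1, 10), 0L)
  expect_equal(cation_ring(5.0, 90), 0L)    # in-plane: outside both windows
  expect_equal(cation_ring(5.0, 150), 1L)   # lower window via opposite normal
  expect_equal(cation_ring(5.0, 60), 1L)    # inclusive angle edge
})

test_that("pi-stacking is a distance-only centroid rule", {
  two_rings <- function(d, perpendicular = FALSE) {
    th <- seq(0, 2 * pi, length.out = 7)[1:6]
    r1 <- data.frame(serial = 1:6,
                     name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                     element = "C", resname = "PHE", resid = 1, chain = "H",
                     x = 1.39 * cos(th), y = 1.39 * sin(th), z = 0)
    r2 <- r1
    r2$serial <- 7:12; r2$chain <- "A"
    if (perpendicular) {
      r2$x <- 1.39 * cos(th); r2$z <- 1.39 * sin(th); r2$y <- 0
    }
    r2$z <- r2$z + d
    fx <- fixture_model(rbind(r1, r2))
    nrow(detect_pi_stacking(fx$model, fx$coords, 1:6, 7:12))
  }
  expect_equal(two_rings(5.9), 1L)
  expect_equal(two_rings(6.1), 0L)
  expect_equal(two_rings(5.0, perpendicular = TRUE), 1L)
  # an incomplete ring is a structure error
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  broken <- data.frame(serial = 1:5,
                       name = c("CG", "CD1", "CE1", "CZ", "CE2"),
                       element = "C", resname = "PHE", resid = 1, chain = "H",
                       x = 1.39 * cos(th)[1:5], y = 1.39 * sin(th)[1:5], z = 0)
  fx <- fixture_model(broken)
  expect_error(find_rings(fx$model, fx$coords, 1:5), "incomplete aromatic ring")
})

test_that("hydrophobic contacts collapse atom multiplicities to residue pairs", {
  at <- data.frame(serial = 1:5,
                   name = c("CD1", "CD2", "CG", "CD1", "CD2"),
                   element = "C", resname = "LEU",
                   resid = c(1, 1, 1, 2, 2), chain = c("H", "H", "H", "A", "A"),
                   x = c(0, 1.0, 0.5, 0, 1.0), y = c(0, 0, 0.8, 3.8, 4.2),
                   z = 0)
  fx <- fixture_model(at)
  rec <- detect_hydrophobic(fx$model, fx$coords, 1:3, 4:5)
  expect_equal(nrow(rec), 1L)          # many qualifying pairs, one residue pair
  expect_gte(rec$n_atom_pairs, 3L)
  # single-pair boundary: inclusive at 4.5, absent at 4.6
  pair_at <- function(d) {
    at2 <- data.frame(serial = 1:2, name = "CD1", element = "C",
                      resname = "LEU", resid = 1:2, chain = c("H", "A"),
                      x = 0, y = c(0, d), z = 0)
    fx2 <- fixture_model(at2)
    nrow(detect_hydrophobic(fx2$model, fx2$coords, 1, 2))
  }
  expect_equal(pair_at(4.5), 1L)
  expect_equal(pair_at(4.6), 0L)
})

test_that("bridging waters need simultaneous bonds to both molecules", {
  ens <- build_toy_complex(complex_spec(bridge = 1, solvent = 1))
  m <- ens$topology; co <- get_frame(ens, 1)
  fv <- select_atoms(m, role = c("heavy", "light"))
  ag <- select_atoms(m, role = "antigen")
  wat <- select_atoms(m, role = "water")
  bw <- detect_bridging_waters(m, co, fv, ag, wat)
  expect_equal(nrow(bw$bridge), 1L)
  expect_equal(nrow(bw$solvent), 1L)
  expect_length(bw$bridging_waters, 1L)
  # the two classes never share a record (partition invariant)
  expect_length(intersect(bw$bridge$water, bw$solvent$water), 0)
  # water -> water -> antigen chains do not bridge: pull the antigen-side
  # acceptor away and hang a second water off the first
  ens2 <- build_toy_complex(complex_spec(solvent = 1))
  m2 <- ens2$topology; co2 <- get_frame(ens2, 1)
  w2 <- data.frame(serial = max(m2$atoms$serial) + (1:3),
                   name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
                   resname = "HOH", resid = 99, chain = "W")
  at2 <- rbind(m2$atoms[, c("serial", "name", "element", "resname", "resid", "chain")], w2)
  ag2 <- data.frame(serial = max(at2$serial) + 1, name = "O", element = "O",
                    resname = "GLY", resid = 50, chain = "A")
  at2 <- rbind(at2, ag2)
  m3 <- structure_model(at2, roles = c(H = "heavy", L = "light", A = "antigen"))
  w1_o <- co2[select_atoms(m2, role = "water", name = "OW"), ]
  co3 <- rbind(co2,
               w1_o + c(0, 2.8, 0),          # second water O (chain via first)
               w1_o + c(0.93, 2.55, 0),      # its H1, sideways
               w1_o + c(0, 3.76, 0),         # its H2, donating upward
               w1_o + c(0, 5.6, 0))          # antigen O bonded to water 2 only
  bw2 <- detect_bridging_waters(m3, co3,
                                select_atoms(m3, role = c("heavy", "light")),
                                select_atoms(m3, role = "antigen"),
                                select_atoms(m3, role = "water"))
  expect_length(bw2$bridging_waters, 0)      # order-1 bridges only
  expect_gte(nrow(bw2$solvent), 1L)
})

test_that("ion contacts use salt-bridge thresholds against N/O partners only", {
  ion_case <- function(d, partner_name = "OD1", partner_el = "O") {
    at <- data.frame(serial = 1:2, name = c("NA", partner_name),
                     element = c("NA", partner_el),
                     resname = c("NA", "ASP"), resid = 1:2,
                     chain = c("I", "H"), x = 0, y = c(0, d), z = 0)
    fx <- fixture_model(at, roles = c(I = "ion", H = "heavy"))
    nrow(detect_ion_contacts(fx$model, fx$coords, 2, 1))
  }
  expect_equal(ion_case(4.4), 1L)
  expect_equal(ion_case(4.6), 0L)
  expect_equal(ion_case(3.0, partner_name = "CB", partner_el = "C"), 0L)
})

test_that("every detector matches its brute-force oracle on random fixtures", {
  set.seed(101)
  for (rep_i in 1:40) {
    fx <- random_hbond_fixture(n_heavy = 24)
    got <- detect_hydrogen_bonds(fx$model, fx$coords, fx$set1, fx$set2)
    got_keys <- sort(paste(got$donor, got$hydrogen, got$acceptor, sep = "-"))
    expect_identical(got_keys,
                     oracle_hbonds(fx$model, fx$coords, fx$set1, fx$set2))
  }
  for (rep_i in 1:40) {
    fx <- random_hydrophobic_fixture()
    got <- detect_hydrophobic(fx$model, fx$coords, fx$set1, fx$set2)
    got_keys <- sort(unique(paste(got$res1, got$res2, sep = "|")))
    expect_identical(got_keys,
                     oracle_hydrophobic_pairs(fx$model, fx$coords,
                                              fx$set1, fx$set2))
  }
  for (rep_i in 1:40) {
    fx <- random_salt_fixture()
    got <- detect_salt_bridges(fx$model, fx$coords, fx$set1, fx$set2)
    got_keys <- sort(paste(got$pos_atom, got$neg_atom, sep = "-"))
    expect_identical(got_keys,
                     oracle_salt_pairs(fx$model, fx$coords, fx$set1, fx$set2))
  }
})

test_that("intramolecular counts include i+1..i+3 neighbours, exclude self", {
  # two LEU residues, sequence neighbours, one qualifying atom pair
  at <- data.frame(serial = 1:4,
                   name = c("CD1", "H", "CD1", "H"),
                   element = c("C", "H", "C", "H"),
                   resname = "LEU", resid = c(1, 1, 2, 2), chain = "H",
                   x = c(0, 0.5, 4.0, 4.5), y = 0, z = 0)
  fx <- fixture_model(at)
  counts <- count_intramolecular(fx$model, fx$coords, 1:4)
  expect_equal(counts[["hydrophobic_residue"]], 1L)
  # backbone ladder: every amide donates to the previous residue's carbonyl
  # (sequence-adjacent i,i-1 pairs are included by the i+1..i+3 rule)
  n_res <- 8
  rows <- list()
  for (i in seq_len(n_res)) {
    rows[[i]] <- data.frame(
      serial = (i - 1) * 3 + 1:3,
      name = c("N", "H", "O"), element = c("N", "H", "O"),
      resname = "GLY", resid = i, chain = "H",
      x = 0,
      y = c(5 * i, 5 * i - 1, 5 * i + 2.5),  # N_i reaches O_(i-1) at 2.5 A
      z = 0)
  }
  fx2 <- fixture_model(do.call(rbind, rows))
  counts2 <- count_intramolecular(fx2$model, fx2$coords,
                                  seq_len(nrow(fx2$model$atoms)))
  expect_equal(counts2[["hbond"]], n_res - 1L)
})

test_that("trajectory summary: static ensembles give sd 0 and planted means", {
  ens <- build_toy_complex(complex_spec(hbond = 2, salt_bridge = 1,
                                        bridge = 1, solvent = 2), n_frames = 5)
  s <- summarize_trajectory(ens)
  expect_true(all(s$sd == 0))
  expect_equal(unname(s$mean[c("hbond_direct", "salt_bridge", "hbond_bridge",
                               "hbond_solvent")]), c(2, 1, 1, 2))
  # fixed vs fluctuating agree on a static frame when the reference interface
  # is the frame's own interface
  m <- ens$topology; co <- get_frame(ens, 1)
  iface <- define_interface(m, co, select_atoms(m, role = c("heavy", "light")),
                            select_atoms(m, role = "antigen"))
  s_fix <- summarize_trajectory(ens, mode = "fixed_interface",
                                reference_interface = iface)
  expect_equal(s_fix$mean[["hbond_direct"]], s$mean[["hbond_direct"]])
  expect_error(summarize_trajectory(ens, mode = "fixed_interface"),
               "reference_interface")
  # permuting frames permutes per-frame counts, means invariant
  perm <- c(3, 1, 5, 2, 4)
  ens_p <- ensemble(ens$topology, ens$frames[perm, , , drop = FALSE])
  s_p <- summarize_trajectory(ens_p)
  expect_equal(s_p$mean, s$mean)
  expect_equal(s_p$sd, s$sd)
  expect_equal(unname(s_p$per_frame), unname(s$per_frame[perm, ]))
})

test_that("a contact broken in half the frames halves its mean", {
  ens <- build_toy_complex(complex_spec(hbond = 2), n_frames = 4)
  # displace the acceptor of site 1 far away in frames 3 and 4
  ag_o <- select_atoms(ens$topology, chain = "A", resid = 1, name = "O")
  ens$frames[3:4, ag_o, 2] <- ens$frames[3:4, ag_o, 2] + 50
  s <- summarize_trajectory(ens)
  expect_equal(s$mean[["hbond_direct"]], 1.5)
  expect_true(s$mean[["hbond_direct"]] >= min(s$per_frame[, "hbond_direct"]))
  expect_true(s$mean[["hbond_direct"]] <= max(s$per_frame[, "hbond_direct"]))
})

test_that("nonsolvent percentages follow the stated arithmetic", {
  s <- structure(list(mean = c(hbond_direct = 5, hbond_bridge = 4,
                               hbond_solvent = 4, salt_bridge = 1,
                               cation_pi = 0, pi_stack = 0,
                               hydrophobic_residue = 6, ion_contact = 0)),
                 class = "interaction_summary")
  ns <- nonsolvent_fraction(s)
  expect_equal(ns[["nonsolvent_pct"]], 80)
  expect_equal(ns[["nonsolvent_nonhydrophobic_pct"]], 50)
  s$mean["hbond_solvent"] <- 0
  expect_equal(nonsolvent_fraction(s)[["nonsolvent_pct"]], 100)
  s$mean[] <- 0; s$mean["hbond_solvent"] <- 7
  expect_equal(nonsolvent_fraction(s)[["nonsolvent_pct"]], 0)
  s$mean[] <- 0
  expect_error(nonsolvent_fraction(s), "zero total")
})
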