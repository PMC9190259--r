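## Synthetic ensembles with planted, exactly-known ground truth.
##
## The toy Fv/antigen complexes realise each planted interaction strictly
## inside its geometric threshold while keeping everything else far apart
## (interaction sites are spaced 14 A along x; all cutoffs are <= 6 A). Every
## construction is audited: the package's detectors are run on the built frame
## and the build fails if any planted count is not recovered exactly.

.SITE_SPACING <- 14

# row-block helper: atoms as data.frame(name, element, x, y, z)
.atoms_df <- function(name, element, xyz) {
  data.frame(name = name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# generic 5-atom backbone; `base` is the N position. The amide hydrogen points
# along `h_offset`; CA/C/O extend along `tail` (kept away from the partner
# molecule even when the hydrogen points toward it).
.bb_block <- function(base, h_offset = c(0, -1, 0), tail = h_offset) {
  .atoms_df(c("N", "H", "CA", "C", "O"), c("N", "H", "C", "C", "O"),
            rbind(base,
                  base + h_offset,
                  base + c(1.2, 0, 0) + 1.0 * tail,
                  base + c(1.7, 0, 0) + 2.3 * tail,
                  base + c(0.9, 0, 0) + 3.2 * tail))
}

# water with ideal 104.5 degree geometry; H2 points along +y (toward an
# acceptor when one is planted), H1 sideways
.water_block <- function(o_pos) {
  h2 <- o_pos + c(0, 0.9572, 0)
  h1 <- o_pos + 0.9572 * c(sin(104.52 * pi / 180), cos(104.52 * pi / 180), 0)
  .atoms_df(c("OW", "HW1", "HW2"), c("O", "H", "H"), rbind(o_pos, h1, h2))
}

.ring_block <- function(centroid, plane = c("xz", "xy")) {
  plane <- match.arg(plane)
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  xyz <- if (plane == "xz") {
    cbind(1.39 * cos(th), 0, 1.39 * sin(th))
  } else {
    cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  }
  .atoms_df(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), rep("C", 6),
            sweep(xyz, 2, centroid, "+"))
}

# Each site builder returns list(fv=, ag=, wat=, ion=) of atom blocks tagged
# with residue names; coordinates already absolute for site abscissa x0.
.site_builders <- list(
  hbond = function(x0) {
    fv <- .bb_block(c(x0, -1.45, 0), h_offset = c(0, 1, 0), tail = c(0, -1, 0))
    ag <- .atoms_df(c("O", "C", "CA", "N", "H"), c("O", "C", "C", "N", "H"),
                    rbind(c(x0, 1.45, 0), c(x0, 2.68, 0), c(x0 + 1.2, 3.45, 0),
                          c(x0 + 1.4, 4.85, 0), c(x0 + 1.4, 5.85, 0)))
    list(fv = list(resname = "GLY", atoms = fv),
         ag = list(resname = "GLY", atoms = ag))
  },
  salt_bridge = function(x0) {
    fv <- rbind(.atoms_df(c("NZ", "HZ1"), c("N", "H"),
                          rbind(c(x0, -0.2, 0), c(x0, -1.2, 0))),
                .bb_block(c(x0, -3.4, 0)))
    ag <- rbind(.atoms_df(c("OD1", "OD2", "CG"), c("O", "O", "C"),
                          rbind(c(x0, 4.2, 0), c(x0 + 1.0, 5.4, 0),
                                c(x0 + 0.3, 5.3, 0.8))),
                .bb_block(c(x0, 8.0, 0), h_offset = c(0, 1, 0)))
    list(fv = list(resname = "LYS", atoms = fv),
         ag = list(resname = "ASP", atoms = ag))
  },
  cation_pi = function(x0) {
    fv <- rbind(.atoms_df(c("NZ", "HZ1"), c("N", "H"),
                          rbind(c(x0, 0, 0), c(x0, -1, 0))),
                .bb_block(c(x0, -3.4, 0)))
    ag <- rbind(.ring_block(c(x0, 5.0, 0), plane = "xz"),
                .bb_block(c(x0, 8.5, 0), h_offset = c(0, 1, 0)))
    list(fv = list(resname = "LYS", atoms = fv),
         ag = list(resname = "PHE", atoms = ag))
  },
  pi_stack = function(x0) {
    fv <- rbind(.ring_block(c(x0, 0, 0), plane = "xz"),
                .bb_block(c(x0, -3.5, 0)))
    ag <- rbind(.ring_block(c(x0, 5.0, 0), plane = "xz"),
                .bb_block(c(x0, 8.5, 0), h_offset = c(0, 1, 0)))
    list(fv = list(resname = "PHE", atoms = fv),
         ag = list(resname = "PHE", atoms = ag))
  },
  hydrophobic = function(x0) {
    fv <- rbind(.atoms_df(c("CD1", "CD2"), c("C", "C"),
                          rbind(c(x0, 0, 0), c(x0 - 1.55, -0.6, 0))),
                .bb_block(c(x0, -3.5, 0)))
    ag <- rbind(.atoms_df(c("CD1", "CD2"), c("C", "C"),
                          rbind(c(x0, 4.0, 0), c(x0 + 1.55, 4.6, 0))),
                .bb_block(c(x0, 7.5, 0), h_offset = c(0, 1, 0)))
    list(fv = list(resname = "LEU", atoms = fv),
         ag = list(resname = "LEU", atoms = ag))
  },
  bridge = function(x0) {
    fv <- .bb_block(c(x0, -1.45, 0), h_offset = c(0, 1, 0), tail = c(0, -1, 0))
    wat <- .water_block(c(x0, 1.45, 0))
    ag <- .atoms_df(c("O", "C", "CA", "N", "H"), c("O", "C", "C", "N", "H"),
                    rbind(c(x0, 4.25, 0), c(x0, 5.48, 0), c(x0 + 1.2, 6.25, 0),
                          c(x0 + 1.4, 7.65, 0), c(x0 + 1.4, 8.65, 0)))
    list(fv = list(resname = "GLY", atoms = fv),
         ag = list(resname = "GLY", atoms = ag),
         wat = list(resname = "HOH", atoms = wat))
  },
  solvent = function(x0) {
    fv <- .bb_block(c(x0, -1.45, 0), h_offset = c(0, 1, 0), tail = c(0, -1, 0))
    wat <- .water_block(c(x0, 1.45, 0))
    list(fv = list(resname = "GLY", atoms = fv),
         wat = list(resname = "HOH", atoms = wat))
  },
  ion = function(x0) {
    fv <- rbind(.atoms_df(c("OD1", "OD2"), c("O", "O"),
                          rbind(c(x0, -4.4, 0), c(x0 - 1.5, -5.2, 0))),
                .bb_block(c(x0, -7.9, 0)))
    ion <- .atoms_df("NA", "NA", rbind(c(x0, 0, 0)))
    list(fv = list(resname = "ASP", atoms = fv),
         ion = list(resname = "NA", atoms = ion))
  }
)

#' Specification of a toy Fv/antigen complex
#'
#' @param hbond,salt_bridge,cation_pi,pi_stack,hydrophobic,bridge,solvent,ion
#'   planted interaction counts (>= 0): direct hydrogen bonds, salt bridges,
#'   cation-pi, pi-stacking, hydrophobic residue contacts, bridging waters,
#'   bulk-water hydrogen bonds, ion contacts.
#' @param n_fv_residues,n_antigen_residues pad the chains with inert filler
#'   residues up to these counts (0 = no padding beyond interaction sites).
#' @param seed reserved for jittered variants; the default build is
#'   deterministic.
#' @return list of class `complex_spec`.
#' @export
complex_spec <- function(hbond = 0, salt_bridge = 0, cation_pi = 0,
                         pi_stack = 0, hydrophobic = 0, bridge = 0,
                         solvent = 0, ion = 0, n_fv_residues = 0,
                         n_antigen_residues = 0, seed = 1) {
  counts <- c(hbond = hbond, salt_bridge = salt_bridge, cation_pi = cation_pi,
              pi_stack = pi_stack, hydrophobic = hydrophobic, bridge = bridge,
              solvent = solvent, ion = ion)
  if (any(counts < 0)) stop("planted counts must be >= 0")
  structure(list(counts = counts, n_fv_residues = n_fv_residues,
                 n_antigen_residues = n_antigen_residues, seed = seed),
            class = "complex_spec")
}

#' Build a toy Fv(-antigen) complex realising planted interaction counts
#'
#' Every planted interaction is constructed strictly inside its geometric
#' threshold; all other atom pairs are kept clear of every cutoff. The built
#' frame is audited by running the package's interaction detectors and the
#' function fails if any planted count is not recovered exactly.
#'
#' @param spec a [complex_spec()].
#' @param n_frames replicate the frame this many times (static ensemble).
#' @param criteria criteria used for the audit.
#' @return an [ensemble()] with roles heavy/light/antigen/water/ion assigned.
#' @export
build_toy_complex <- function(spec, n_frames = 1,
                              criteria = interaction_criteria()) {
  stopifnot(inherits(spec, "complex_spec"))
  rows <- list()
  fv_res <- 0L; ag_res <- 0L; wat_res <- 0L; ion_res <- 0L
  site_i <- 0L
  add <- function(block, chain, resid) {
    at <- block$atoms
    at$resname <- block$resname
    at$chain <- chain
    at$resid <- resid
    rows[[length(rows) + 1]] <<- at
  }
  for (kind in names(spec$counts)) {
    k <- spec$counts[[kind]]
    if (k == 0) next
    for (rep_i in seq_len(k)) {
      site_i <- site_i + 1L
      parts <- .site_builders[[kind]]((site_i - 1L) * .SITE_SPACING)
      fv_res <- fv_res + 1L
      add(parts$fv, "H", fv_res)
      if (!is.null(parts$ag)) { ag_res <- ag_res + 1L; add(parts$ag, "A", ag_res) }
      if (!is.null(parts$wat)) { wat_res <- wat_res + 1L; add(parts$wat, "W", wat_res) }
      if (!is.null(parts$ion)) { ion_res <- ion_res + 1L; add(parts$ion, "I", ion_res) }
    }
  }
  # inert filler residues, far from all interaction sites
  while (fv_res < spec$n_fv_residues) {
    fv_res <- fv_res + 1L
    add(list(resname = "GLY", atoms = .bb_block(c(fv_res * .SITE_SPACING, -40, 0))),
        "H", fv_res)
  }
  while (ag_res < spec$n_antigen_residues) {
    ag_res <- ag_res + 1L
    add(list(resname = "GLY",
             atoms = .bb_block(c(ag_res * .SITE_SPACING, 40, 0),
                               h_offset = c(0, 1, 0))),
        "A", ag_res)
  }
  # a token light chain so the Fv has both variable domains
  add(list(resname = "GLY", atoms = .bb_block(c(0, -60, 0))), "L", 1L)
  add(list(resname = "GLY", atoms = .bb_block(c(.SITE_SPACING, -60, 0))), "L", 2L)
  df <- do.call(rbind, rows)
  atoms <- data.frame(serial = seq_len(nrow(df)), name = df$name,
                      element = df$element, resname = df$resname,
                      resid = df$resid, chain = df$chain,
                      stringsAsFactors = FALSE)
  roles <- c(H = "heavy", L = "light")
  if (ag_res > 0) roles <- c(roles, A = "antigen")
  if (wat_res > 0) roles <- c(roles, W = "water")
  if (ion_res > 0) roles <- c(roles, I = "ion")
  model <- structure_model(atoms, roles = roles)
  co <- as.matrix(df[, c("x", "y", "z")])
  frames <- array(rep(co, each = n_frames), dim = c(n_frames, nrow(co), 3))
  ens <- ensemble(model, frames)
  .audit_complex(ens, spec$counts, criteria)
  ens
}

# fail construction unless detectors recover every planted count exactly
.audit_complex <- function(ens, planted, criteria) {
  s <- summarize_trajectory(ens, mode = "fluctuating_interface",
                            criteria = criteria, stride = dim(ens$frames)[1])
  got <- s$per_frame[1, ]
  want <- c(hbond_direct = planted[["hbond"]],
            hbond_bridge = planted[["bridge"]],
            hbond_solvent = planted[["solvent"]],
            salt_bridge = planted[["salt_bridge"]],
            cation_pi = planted[["cation_pi"]],
            pi_stack = planted[["pi_stack"]],
            hydrophobic_residue = planted[["hydrophobic"]],
            ion_contact = planted[["ion"]])
  bad <- names(want)[got[names(want)] != want]
  if (length(bad)) {
    stop("generation error: planted counts not recovered for ",
         paste(sprintf("%s (planted %d, detected %d)", bad, want[bad],
                       as.integer(got[bad])), collapse = "; "))
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Dihedral ensembles

#' Generate a torsion time series from planted wrapped-Gaussian states
#'
#' Frame state labels are drawn i.i.d. from `populations`; each angle is the
#' state's mean plus wrapped-Gaussian noise of sd `spread`, wrapped to
#' (-180, 180]. State means must be separated by more than 3 x `spread`
#' (on at least one dihedral per state pair) or generation fails.
#'
#' @param n_dihedrals number of dihedrals D.
#' @param populations simplex weights over K states.
#' @param state_means optional K x D matrix of mean angles (degrees); default
#'   places states evenly around the circle.
#' @param spread wrapped-Gaussian sd in degrees.
#' @param n_frames number of frames T.
#' @param seed RNG seed.
#' @param cdr_id loop label.
#' @return list(series = `torsion_series`, labels = planted per-frame state
#'   ids, means = K x D planted means, populations).
#' @export
generate_dihedral_ensemble <- function(n_dihedrals, populations,
                                       state_means = NULL, spread = 8,
                                       n_frames = 1000, seed = 1,
                                       cdr_id = "CDR") {
  k <- length(populations)
  if (abs(sum(populations) - 1) > 1e-9 || any(populations <= 0)) {
    stop("populations must be positive and sum to 1")
  }
  if (is.null(state_means)) {
    state_means <- outer(seq_len(k), seq_len(n_dihedrals), function(s, d) {
      wrap_angle(-150 + (s - 1) * 360 / k + 10 * (d - 1))
    })
  }
  state_means <- matrix(state_means, nrow = k, ncol = n_dihedrals)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sep <- max(circ_diff(state_means[i, ], state_means[j, ]))
      if (sep <= 3 * spread) {
        stop("generation error: states ", i, " and ", j,
             " separated by ", round(sep, 1), " deg <= 3 x spread")
      }
    }
  }
  with_seed(seed, {
    labels <- sample.int(k, n_frames, replace = TRUE, prob = populations)
    noise <- matrix(stats::rnorm(n_frames * n_dihedrals, 0, spread),
                    n_frames, n_dihedrals)
    vals <- wrap_angle(state_means[labels, , drop = FALSE] + noise)
    list(series = torsion_series(vals, cdr_id = cdr_id), labels = labels,
         means = state_means, populations = populations)
  })
}

## ---------------------------------------------------------------------------
## Cartesian ensembles

#' Generate a Cartesian ensemble with planted cluster structure
#'
#' CDR atoms of the base structure are displaced along three fixed orthonormal
#' modes (rigid x/y/z translations of the CDR block, normalised in 3N space)
#' by per-cluster amplitudes plus Gaussian noise; all other atoms stay fixed,
#' so superposition on the non-CDR frame is exact.
#'
#' @param base an [ensemble()] supplying topology and the reference frame.
#' @param cdr_idx atom indices displaced by the modes.
#' @param centers list of length-3 numeric vectors: per-cluster mode
#'   amplitudes (mass-weighted-A PC-space offsets scale with sqrt(total CDR
#'   mass)).
#' @param spread Gaussian sd of the amplitudes.
#' @param n_frames total frames, split as evenly as possible across centers.
#' @param seed RNG seed.
#' @return list(ensemble, labels = planted cluster id per frame, modes).
#' @export
generate_cartesian_ensemble <- function(base, cdr_idx, centers, spread = 0.5,
                                        n_frames = 200, seed = 1) {
  if (!length(centers)) stop("need at least one center")
  centers <- lapply(centers, function(c3) { stopifnot(length(c3) == 3); c3 })
  n_cdr <- length(cdr_idx)
  base_co <- get_frame(base, 1)
  k <- length(centers)
  with_seed(seed, {
    labels <- rep(seq_len(k), length.out = n_frames)
    frames <- array(NA_real_, dim = c(n_frames, nrow(base_co), 3))
    amp_noise <- matrix(stats::rnorm(n_frames * 3, 0, spread), n_frames, 3)
    for (f in seq_len(n_frames)) {
      amp <- unlist(centers[[labels[f]]]) + amp_noise[f, ]
      co <- base_co
      # rigid translation modes: unit vectors in 3N space along x, y, z
      co[cdr_idx, 1] <- co[cdr_idx, 1] + amp[1] / sqrt(n_cdr)
      co[cdr_idx, 2] <- co[cdr_idx, 2] + amp[2] / sqrt(n_cdr)
      co[cdr_idx, 3] <- co[cdr_idx, 3] + amp[3] / sqrt(n_cdr)
      frames[f, , ] <- co
    }
    list(ensemble = ensemble(base$topology, frames), labels = labels)
  })
}

## ---------------------------------------------------------------------------
## Antibody panels

#' Specification of a synthetic antibody panel
#'
#' @param n_antibodies panel size (>= 3).
#' @param slope,intercept planted linear relation
#'   ln(K_d / nM) = slope * nonsolvent_pct + intercept + noise.
#' @param noise_sd Gaussian noise sd on ln(K_d).
#' @param fraction_range range of planted non-solvent percentages.
#' @param n_interactions total planted intermolecular interactions per
#'   antibody (sets the 1/n granularity with which the measured percentage can
#'   match the planted one).
#' @param outlier index of an antibody given an `outlier_shift` on ln(K_d)
#'   (0 = none), mirroring an anomalous panel member.
#' @param outlier_shift ln-units added to the outlier's ln(K_d).
#' @param seed RNG seed.
#' @export
panel_spec <- function(n_antibodies = 8, slope = -0.35, intercept = 25,
                       noise_sd = 0.5, fraction_range = c(60, 95),
                       n_interactions = 50, outlier = 0, outlier_shift = 6,
                       seed = 1) {
  if (n_antibodies < 3) stop("panel needs >= 3 antibodies")
  structure(list(n_antibodies = n_antibodies, slope = slope,
                 intercept = intercept, noise_sd = noise_sd,
                 fraction_range = fraction_range,
                 n_interactions = n_interactions, outlier = outlier,
                 outlier_shift = outlier_shift, seed = seed),
            class = "panel_spec")
}

# split a non-solvent interaction budget across kinds
.split_nonsolvent <- function(n_nonsolv) {
  hydroph <- round(0.30 * n_nonsolv)
  bridge <- round(0.20 * n_nonsolv)
  salt <- min(2L, max(0L, n_nonsolv - hydroph - bridge))
  hb <- n_nonsolv - hydroph - bridge - salt
  c(hbond = hb, salt_bridge = salt, hydrophobic = hydroph, bridge = bridge)
}

#' Generate a synthetic antibody panel with a planted affinity relationship
#'
#' Planted non-solvent percentages f_i are spread evenly over
#' `fraction_range`; ln(K_d)_i = slope * f_i + intercept + noise. Each
#' antibody's holo complex is built with interaction counts whose measured
#' non-solvent percentage equals f_i up to the 100/n_interactions rounding
#' granularity.
#'
#' @param spec a [panel_spec()].
#' @param build_complexes build the toy complexes (TRUE) or only return the
#'   planted counts (faster when only the arithmetic is needed).
#' @return data.frame-like list of class `antibody_panel` with one entry per
#'   antibody: antibody_id, ln_kd, kd_nM, koff, planted_fraction,
#'   planted_counts, holo (ensemble or NULL).
#' @export
generate_panel <- function(spec, build_complexes = TRUE) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_antibodies
  f <- seq(spec$fraction_range[1], spec$fraction_range[2], length.out = n)
  entries <- with_seed(spec$seed, {
    eps <- stats::rnorm(n, 0, spec$noise_sd)
    lapply(seq_len(n), function(i) {
      ln_kd <- spec$slope * f[i] + spec$intercept + eps[i]
      if (spec$outlier == i) ln_kd <- ln_kd + spec$outlier_shift
      n_tot <- spec$n_interactions
      n_solv <- round((1 - f[i] / 100) * n_tot)
      parts <- .split_nonsolvent(n_tot - n_solv)
      counts <- c(parts, solvent = n_solv)
      holo <- NULL
      if (build_complexes) {
        holo <- build_toy_complex(do.call(complex_spec, as.list(counts)))
      }
      list(antibody_id = sprintf("ab%02d", i), ln_kd = ln_kd,
           kd_nM = exp(ln_kd), koff = exp(0.8 * ln_kd - 5),
           planted_fraction = f[i], planted_counts = counts, holo = holo)
    })
  })
  structure(entries, class = "antibody_panel")
}
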