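# Independent brute-force oracles and random-fixture builders used across the
# suite. Everything here is deliberately scalar / double-loop so it shares no
# code path with the vectorised implementations it checks.

odist <- function(p, q) sqrt(sum((p - q)^2))

oangle <- function(a, h, b) {
  v1 <- a - h; v2 <- b - h
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

# build a structure_model + coords from a plain atom table with x/y/z columns
fixture_model <- function(at, roles = character()) {
  m <- structure_model(at[, c("serial", "name", "element", "resname",
                              "resid", "chain")], roles = roles)
  list(model = m, coords = as.matrix(at[, c("x", "y", "z")]))
}

# random donor/acceptor cloud: heavy N/O/C atoms, each its own residue, some
# with an attached hydrogen at 1.0 A
random_hbond_fixture <- function(n_heavy = 30, box = 7, chains = c("H", "A")) {
  el <- sample(c("N", "O", "C"), n_heavy, replace = TRUE)
  # each half always carries at least one protonated donor so the detector's
  # no-hydrogen guard never fires on these fixtures
  el[c(1, floor(n_heavy / 2) + 1)] <- "N"
  pos <- matrix(runif(n_heavy * 3, 0, box), ncol = 3)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_heavy)) {
    chain <- chains[1 + (i > n_heavy / 2)]
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial, name = el[i], element = el[i], resname = "UNK",
      resid = i, chain = chain, x = pos[i, 1], y = pos[i, 2], z = pos[i, 3])
    if (el[i] %in% c("N", "O") &&
        (runif(1) < 0.7 || i %in% c(1, floor(n_heavy / 2) + 1))) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = "H", element = "H", resname = "UNK",
        resid = i, chain = chain,
        x = pos[i, 1] + u[1], y = pos[i, 2] + u[2], z = pos[i, 3] + u[3])
    }
  }
  at <- do.call(rbind, rows)
  fx <- fixture_model(at)
  fx$set1 <- which(at$chain == chains[1])
  fx$set2 <- which(at$chain == chains[2])
  fx
}

# scalar reimplementation of the hydrogen-bond rule (donor side = set1)
oracle_hbonds <- function(model, coords, set1, set2, cutoff = 3.5,
                          amin = 120, amax = 180) {
  at <- model$atoms
  res <- character()
  for (d in set1) {
    if (at$is_hydrogen[d] || !(at$element[d] %in% c("N", "O", "S"))) next
    # hydrogens whose nearest same-residue N/O/S parent is d
    hs <- integer()
    for (h in set1) {
      if (!at$is_hydrogen[h] || at$resid[h] != at$resid[d] ||
          at$chain[h] != at$chain[d]) next
      best <- NA_integer_; bestd <- Inf
      for (p in set1) {
        if (at$is_hydrogen[p] || !(at$element[p] %in% c("N", "O", "S")) ||
            at$resid[p] != at$resid[h] || at$chain[p] != at$chain[h]) next
        dd <- odist(coords[h, ], coords[p, ])
        if (dd < bestd) { bestd <- dd; best <- p }
      }
      if (!is.na(best) && best == d && bestd <= 1.25) hs <- c(hs, h)
    }
    for (h in hs) {
      for (a in set2) {
        if (at$is_hydrogen[a] || !(at$element[a] %in% c("N", "O"))) next
        if (a == d) next
        if (at$resid[a] == at$resid[d] && at$chain[a] == at$chain[d]) next
        if (odist(coords[d, ], coords[a, ]) > cutoff) next
        ang <- oangle(coords[d, ], coords[h, ], coords[a, ])
        if (ang >= amin && ang <= amax) {
          res <- c(res, paste(d, h, a, sep = "-"))
        }
      }
    }
  }
  sort(res)
}

# random hydrophobic cloud: LEU CD1 (hydrophobic) and ASN ND2 (not), one atom
# per residue, split over two chains
random_hydrophobic_fixture <- function(n = 30, box = 8) {
  hydro <- runif(n) < 0.7
  at <- data.frame(serial = seq_len(n),
                   name = ifelse(hydro, "CD1", "ND2"),
                   element = ifelse(hydro, "C", "N"),
                   resname = ifelse(hydro, "LEU", "ASN"),
                   resid = seq_len(n),
                   chain = rep(c("H", "A"), length.out = n),
                   x = runif(n, 0, box), y = runif(n, 0, box),
                   z = runif(n, 0, box))
  fx <- fixture_model(at)
  fx$set1 <- which(at$chain == "H"); fx$set2 <- which(at$chain == "A")
  fx
}

oracle_hydrophobic_pairs <- function(model, coords, set1, set2, cutoff = 4.5) {
  at <- model$atoms
  is_hp <- function(i) (at$resname[i] == "LEU" && at$name[i] == "CD1")
  pairs <- character()
  for (i in set1) for (j in set2) {
    if (!is_hp(i) || !is_hp(j)) next
    ki <- paste(at$chain[i], at$resid[i], sep = ":")
    kj <- paste(at$chain[j], at$resid[j], sep = ":")
    if (ki == kj) next
    if (odist(coords[i, ], coords[j, ]) <= cutoff) {
      pairs <- c(pairs, paste(min(ki, kj), max(ki, kj), sep = "|"))
    }
  }
  sort(unique(pairs))
}

# random salt-bridge cloud: LYS NZ / ASP OD1 / backbone O decoys
random_salt_fixture <- function(n = 24, box = 8) {
  kind <- sample(c("NZ", "OD1", "O"), n, replace = TRUE)
  at <- data.frame(serial = seq_len(n), name = kind,
                   element = ifelse(kind == "NZ", "N", "O"),
                   resname = ifelse(kind == "NZ", "LYS",
                                    ifelse(kind == "OD1", "ASP", "GLY")),
                   resid = seq_len(n), chain = rep(c("H", "A"), length.out = n),
                   x = runif(n, 0, box), y = runif(n, 0, box),
                   z = runif(n, 0, box))
  fx <- fixture_model(at)
  fx$set1 <- which(at$chain == "H"); fx$set2 <- which(at$chain == "A")
  fx
}

oracle_salt_pairs <- function(model, coords, set1, set2, cutoff = 4.5) {
  at <- model$atoms
  res <- character()
  for (i in c(set1, set2)) for (j in c(set1, set2)) {
    pos_i <- at$resname[i] == "LYS" && at$name[i] == "NZ"
    neg_j <- at$resname[j] == "ASP" && at$name[j] == "OD1"
    if (!pos_i || !neg_j) next
    both1 <- (i %in% set1) && (j %in% set1)
    both2 <- (i %in% set2) && (j %in% set2)
    if (both1 || both2) next       # cross-molecule oracle
    if (odist(coords[i, ], coords[j, ]) <= cutoff) {
      res <- c(res, paste(i, j, sep = "-"))
    }
  }
  sort(unique(res))
}

# naive O(T^3) average-linkage agglomeration with a distance threshold
oracle_average_linkage <- function(pts, threshold) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < bestd) { bestd <- dd; best <- c(a, b) }
    }
    if (bestd > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# canonical form of a partition: relabel by first occurrence
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# 3-D grid quadrature of the Jensen-Shannon divergence between the Gaussian
# KDEs of two point clouds (shared per-dimension Silverman bandwidths)
oracle_jsd_quadrature <- function(p, q, step = 0.35, pad = 4) {
  pooled <- rbind(p, q)
  n <- nrow(pooled); d <- ncol(pooled)
  h <- apply(pooled, 2, sd) * (4 / ((d + 2) * n))^(1 / (d + 4))
  grids <- lapply(seq_len(d), function(j)
    seq(min(pooled[, j]) - pad, max(pooled[, j]) + pad, by = step))
  gx <- as.matrix(expand.grid(grids))
  dens <- function(data) {
    out <- numeric(nrow(gx))
    norm <- prod(h) * (2 * pi)^(d / 2) * nrow(data)
    for (i in seq_len(nrow(data))) {
      z2 <- rowSums(sweep(sweep(gx, 2, data[i, ]), 2, h, "/")^2)
      out <- out + exp(-z2 / 2)
    }
    out / norm
  }
  fp <- dens(p); fq <- dens(q); fm <- (fp + fq) / 2
  cell <- step^d
  term <- function(f) {
    ok <- f > 1e-300
    sum(f[ok] * log(f[ok] / fm[ok])) * cell
  }
  0.5 * term(fp) + 0.5 * term(fq)
}

# small toy base + CDR selection shared by the PCA tests
toy_base <- function() {
  base <- build_toy_complex(complex_spec(hbond = 1))
  list(base = base,
       cdr = select_atoms(base, chain = "H", resid = 1, backbone = TRUE))
}

ring_normal <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

random_cation_pi_fixture <- function(n_rings = 2, n_cations = 4) {
  rings <- list(); rows <- list(); serial <- 0L
  for (r in seq_len(n_rings)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(u * v) * u; v <- v / sqrt(sum(v^2))
    cen <- runif(3, 0, 10)
    th <- seq(0, 2 * pi, length.out = 7)[1:6]
    xyz <- t(vapply(th, function(t) cen + 1.39 * (cos(t) * u + sin(t) * v),
                    numeric(3)))
    rows[[r]] <- data.frame(serial = serial + 1:6,
                            name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                            element = "C", resname = "PHE", resid = r,
                            chain = "A", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3])
    serial <- serial + 6L
    rings[[r]] <- list(centroid = cen, normal = ring_normal(u, v), resid = r)
  }
  cat_rows <- data.frame(serial = serial + seq_len(n_cations), name = "NZ",
                         element = "N", resname = "LYS",
                         resid = n_rings + seq_len(n_cations), chain = "H",
                         x = runif(n_cations, 0, 10),
                         y = runif(n_cations, 0, 10),
                         z = runif(n_cations, 0, 10))
  at <- rbind(do.call(rbind, rows), cat_rows)
  fx <- fixture_model(at)
  fx$rings <- rings
  fx$cation_idx <- serial + seq_len(n_cations)
  fx$ring_idx <- seq_len(serial)
  fx
}

oracle_cation_pi <- function(fx, cutoff = 6, windows = list(c(0, 60), c(120, 180))) {
  out <- character()
  for (ci in fx$cation_idx) {
    p <- fx$coords[ci, ]
    for (rg in fx$rings) {
      v <- p - rg$centroid
      d <- sqrt(sum(v^2))
      if (d > cutoff) next
      cs <- sum(v * rg$normal) / (d * sqrt(sum(rg$normal^2)))
      ang <- acos(max(-1, min(1, cs))) * 180 / pi
      if (any(vapply(windows, function(w) ang >= w[1] - 1e-9 &&
                       ang <= w[2] + 1e-9, logical(1)))) {
        out <- c(out, paste(ci, rg$resid, sep = "-"))
      }
    }
  }
  sort(out)
}

oracle_pi_stack <- function(fx, cutoff = 6) {
  out <- character()
  for (a in fx$rings) for (b in fx$rings) {
    if (a$resid >= b$resid) next
    if (sqrt(sum((a$centroid - b$centroid)^2)) <= cutoff) {
      out <- c(out, paste(a$resid, b$resid, sep = "-"))
    }
  }
  sort(out)
}

# random scene of Fv donors/acceptors, antigen acceptors and waters for the
# bridging-water classification
random_water_fixture <- function(n_fv = 4, n_ag = 3, n_wat = 6, box = 9) {
  rows <- list(); serial <- 0L
  add_gly <- function(chain, resid) {
    base <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    df <- data.frame(serial = serial + 1:3, name = c("N", "H", "O"),
                     element = c("N", "H", "O"), resname = "GLY",
                     resid = resid, chain = chain,
                     x = c(base[1], base[1] + u[1], base[1] + 2),
                     y = c(base[2], base[2] + u[2], base[2]),
                     z = c(base[3], base[3] + u[3], base[3]))
    serial <<- serial + 3L
    df
  }
  for (i in seq_len(n_fv)) rows[[length(rows) + 1]] <- add_gly("H", i)
  for (i in seq_len(n_ag)) rows[[length(rows) + 1]] <- add_gly("A", i)
  for (i in seq_len(n_wat)) {
    o <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(u * v) * u; v <- v / sqrt(sum(v^2))
    h1 <- o + 0.96 * u
    h2 <- o + 0.96 * (cos(104.5 * pi / 180) * u + sin(104.5 * pi / 180) * v)
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial + 1:3, name = c("OW", "HW1", "HW2"),
      element = c("O", "H", "H"), resname = "HOH", resid = 100 + i,
      chain = "W", x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
      z = c(o[3], h1[3], h2[3]))
    serial <- serial + 3L
  }
  at <- do.call(rbind, rows)
  fx <- fixture_model(at, roles = c(H = "heavy", A = "antigen", W = "water"))
  fx$fv <- which(at$chain == "H"); fx$ag <- which(at$chain == "A")
  fx$wat <- which(at$chain == "W")
  fx
}

# classify waters with the scalar hydrogen-bond oracle
oracle_water_classes <- function(fx) {
  at <- fx$model$atoms
  water_of <- function(keys) {
    # bond key "d-h-a": water residue id from whichever atom is in the water set
    vapply(strsplit(keys, "-"), function(p) {
      ids <- as.integer(p)
      w <- ids[ids %in% fx$wat][1]
      at$resid[w]
    }, 0)
  }
  fv_bonds <- c(oracle_hbonds(fx$model, fx$coords, fx$fv, fx$wat),
                oracle_hbonds(fx$model, fx$coords, fx$wat, fx$fv))
  ag_bonds <- c(oracle_hbonds(fx$model, fx$coords, fx$ag, fx$wat),
                oracle_hbonds(fx$model, fx$coords, fx$wat, fx$ag))
  fv_w <- if (length(fv_bonds)) water_of(fv_bonds) else numeric()
  ag_w <- if (length(ag_bonds)) water_of(ag_bonds) else numeric()
  bridging <- intersect(unique(fv_w), unique(ag_w))
  list(n_bridge = sum(fv_w %in% bridging),
       n_solvent = sum(!fv_w %in% bridging),
       bridging = sort(bridging))
}

random_ion_fixture <- function(n_ion = 3, n_part = 10, box = 8) {
  el <- sample(c("N", "O", "C"), n_part, replace = TRUE)
  at <- rbind(
    data.frame(serial = seq_len(n_part), name = el, element = el,
               resname = "UNK", resid = seq_len(n_part), chain = "H",
               x = runif(n_part, 0, box), y = runif(n_part, 0, box),
               z = runif(n_part, 0, box)),
    data.frame(serial = n_part + seq_len(n_ion), name = "NA", element = "NA",
               resname = "NA", resid = n_part + seq_len(n_ion), chain = "I",
               x = runif(n_ion, 0, box), y = runif(n_ion, 0, box),
               z = runif(n_ion, 0, box)))
  fx <- fixture_model(at, roles = c(H = "heavy", I = "ion"))
  fx$mol <- seq_len(n_part); fx$ion <- n_part + seq_len(n_ion)
  fx
}

oracle_ion_contacts <- function(fx, cutoff = 4.5) {
  out <- character()
  at <- fx$model$atoms
  for (i in fx$ion) for (j in fx$mol) {
    if (!(at$element[j] %in% c("N", "O"))) next
    if (odist(fx$coords[i, ], fx$coords[j, ]) <= cutoff) {
      out <- c(out, paste(i, j, sep = "-"))
    }
  }
  sort(out)
}
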