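## CDR dihedral sampling: torsion extraction, histogram-peak state building,
## circular similarity and apo/holo state matching.

#' Compute backbone phi/psi time series for a residue stretch
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1); IUPAC
#' sign convention, degrees in (-180, 180]. Terminal torsions use flanking
#' residues when present in the topology, otherwise they are dropped.
#'
#' @param ens an [ensemble()].
#' @param chain chain id of the loop.
#' @param resid residue ids of the loop (consecutive).
#' @param cdr_id label stored with the series.
#' @return object of class `torsion_series`: list(cdr_id, labels, values
#'   (T x D matrix, degrees)).
#' @export
compute_backbone_torsions <- function(ens, chain, resid, cdr_id = "CDR") {
  at <- ens$topology$atoms
  bb_idx <- function(rid, nm) {
    i <- which(at$chain == chain & at$resid == rid & at$name == nm)
    if (length(i) != 1) NA_integer_ else i
  }
  tt <- dim(ens$frames)[1]
  quads <- list(); labels <- character()
  for (rid in resid) {
    n_i <- bb_idx(rid, "N"); ca_i <- bb_idx(rid, "CA"); c_i <- bb_idx(rid, "C")
    if (anyNA(c(n_i, ca_i, c_i))) {
      stop("missing backbone atom in residue ", chain, ":", rid)
    }
    c_prev <- bb_idx(rid - 1, "C")
    if (!is.na(c_prev)) {
      quads[[length(quads) + 1]] <- c(c_prev, n_i, ca_i, c_i)
      labels <- c(labels, paste0("phi_", rid))
    }
    n_next <- bb_idx(rid + 1, "N")
    if (!is.na(n_next)) {
      quads[[length(quads) + 1]] <- c(n_i, ca_i, c_i, n_next)
      labels <- c(labels, paste0("psi_", rid))
    }
  }
  if (!length(quads)) stop("no defined torsions for the given residues")
  vals <- matrix(NA_real_, nrow = tt, ncol = length(quads),
                 dimnames = list(NULL, labels))
  for (f in seq_len(tt)) {
    co <- get_frame(ens, f)
    for (q in seq_along(quads)) {
      ijkl <- quads[[q]]
      vals[f, q] <- dihedral_angle(co[ijkl[1], ], co[ijkl[2], ],
                                   co[ijkl[3], ], co[ijkl[4], ])
    }
  }
  torsion_series(vals, cdr_id = cdr_id)
}

#' Construct a torsion series from a matrix of angles
#'
#' @param values T x D matrix of angles in degrees, wrapped to (-180, 180].
#' @param cdr_id loop label.
#' @export
torsion_series <- function(values, cdr_id = "CDR") {
  values <- as.matrix(values)
  if (any(values <= -180 | values > 180)) values <- wrap_angle(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("d", seq_len(ncol(values)))
  }
  structure(list(cdr_id = cdr_id, labels = colnames(values), values = values),
            class = "torsion_series")
}

## ---------------------------------------------------------------------------
## State construction

# circular histogram bin index for angles in (-180, 180]
.bin_index <- function(x, bin_width) {
  i <- ceiling((x + 180) / bin_width)
  i[i < 1] <- 1
  i
}

# per-dihedral frame labels: peak id of the frame's bin, 0 for sub-threshold
.peak_labels <- function(angles, bin_width, min_count) {
  nb <- as.integer(360 / bin_width)
  idx <- .bin_index(angles, bin_width)
  counts <- tabulate(idx, nbins = nb)
  super <- counts >= min_count
  if (!any(super)) return(list(labels = rep(0L, length(angles)), n_peaks = 0L))
  # maximal circularly-contiguous runs of super-threshold bins
  peak_of_bin <- integer(nb)
  if (all(super)) {
    peak_of_bin[] <- 1L
  } else {
    # rotate so position 1 is sub-threshold, then label linear runs
    start <- which(!super)[1]
    ord <- ((seq_len(nb) - 1 + start - 1) %% nb) + 1
    runs <- rle(super[ord])
    lab <- integer(0); p <- 0L
    for (r in seq_along(runs$lengths)) {
      if (runs$values[r]) {
        p <- p + 1L
        lab <- c(lab, rep(p, runs$lengths[r]))
      } else {
        lab <- c(lab, rep(0L, runs$lengths[r]))
      }
    }
    peak_of_bin[ord] <- lab
  }
  list(labels = peak_of_bin[idx], n_peaks = max(peak_of_bin))
}

#' Build conformational states from a torsion series
#'
#' Each dihedral's circular histogram (bin width `bin_width` degrees) is
#' scanned for peaks: maximal circularly contiguous runs of bins each holding
#' at least `peak_bin_fraction` of the frames. A frame's state is the joint
#' vector of its per-dihedral peak labels; frames falling in any sub-threshold
#' bin are off-peak noise. States with population below `rare_state_fraction`,
#' together with noise frames, accumulate into the rare fraction and are
#' discarded. Kept-state mean angles are per-dihedral circular means over the
#' member frames.
#'
#' @param series a `torsion_series` (T >= 100 for the thresholds to be
#'   meaningful).
#' @param peak_bin_fraction minimum per-bin frame fraction for a peak bin
#'   (default 0.015).
#' @param rare_state_fraction minimum population of a kept state (default 0.01).
#' @param bin_width histogram bin width in degrees; must divide 360.
#' @return object of class `state_set`: list(states, rare_fraction, cdr_id,
#'   labels, thresholds); each state has `means`, `population`,
#'   `member_frames`.
#' @export
build_states <- function(series, peak_bin_fraction = 0.015,
                         rare_state_fraction = 0.01, bin_width = 10) {
  stopifnot(inherits(series, "torsion_series"))
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  vals <- series$values
  tt <- nrow(vals)
  if (tt < 100) stop("need at least 100 frames to build states (got ", tt, ")")
  min_count <- peak_bin_fraction * tt
  lab_mat <- vapply(seq_len(ncol(vals)), function(d) {
    .peak_labels(vals[, d], bin_width, min_count)$labels
  }, integer(tt))
  lab_mat <- matrix(lab_mat, nrow = tt)
  on_peak <- rowSums(lab_mat == 0L) == 0L
  key <- apply(lab_mat, 1, paste, collapse = ",")
  key[!on_peak] <- NA
  tab <- sort(table(key), decreasing = TRUE)
  states <- list()
  for (k in names(tab)) {
    pop <- tab[[k]] / tt
    if (pop < rare_state_fraction) next
    members <- which(!is.na(key) & key == k)
    means <- apply(vals[members, , drop = FALSE], 2, circ_mean)
    states[[length(states) + 1]] <- list(means = means, population = pop,
                                         member_frames = members)
  }
  kept <- if (length(states)) sum(vapply(states, `[[`, 0, "population")) else 0
  structure(list(states = states, rare_fraction = 1 - kept,
                 cdr_id = series$cdr_id, labels = series$labels,
                 thresholds = c(peak_bin_fraction = peak_bin_fraction,
                                rare_state_fraction = rare_state_fraction,
                                bin_width = bin_width)),
            class = "state_set")
}

#' Number of kept states
#' @param x a `state_set`.
#' @export
n_states <- function(x) length(x$states)

#' @export
print.state_set <- function(x, ...) {
  cat("state set for", x$cdr_id, "-", length(x$states), "state(s), rare fraction",
      round(x$rare_fraction, 4), "\n")
  for (i in seq_along(x$states)) {
    cat(sprintf("  state %d: pop %.3f, means (%s)\n", i,
                x$states[[i]]$population,
                paste(round(x$states[[i]]$means, 1), collapse = ", ")))
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## Circular similarity and matching

#' Circular similarity between two states
#'
#' Per dihedral, the absolute circular difference of the two mean torsions is
#' normalised to [0, 180] and rescaled to a score s = 1 - delta/180, so 1 means
#' identical and 0 means opposed by 180 degrees. Scores are aggregated across
#' dihedrals by the arithmetic mean (or the minimum via `aggregate = "min"`).
#'
#' @param a,b states (list with `means`) or bare named numeric mean vectors
#'   over the same dihedral labels.
#' @param aggregate "mean" (default) or "min".
#' @return score in [0, 1].
#' @export
circular_similarity <- function(a, b, aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  ma <- if (is.list(a)) a$means else a
  mb <- if (is.list(b)) b$means else b
  if (length(ma) != length(mb)) stop("states have different dihedral counts")
  if (!is.null(names(ma)) && !is.null(names(mb)) && !identical(names(ma), names(mb))) {
    stop("dihedral labels differ between states")
  }
  s <- 1 - circ_diff(ma, mb) / 180
  if (aggregate == "mean") mean(s) else min(s)
}

#' Match apo and holo state sets by circular similarity
#'
#' Greedy one-to-one matching in descending similarity order; pairs with
#' similarity >= `threshold` are considered the same conformation.
#'
#' @param apo,holo `state_set` objects over the same dihedral labels.
#' @param threshold minimum similarity for a match (default 0.8).
#' @param aggregate passed to [circular_similarity()].
#' @return object of class `match_report`: similarity matrix, matched pairs
#'   (data.frame apo, holo, similarity), apo_unique / holo_unique counts, and
#'   matched population fractions.
#' @export
match_states <- function(apo, holo, threshold = 0.8, aggregate = "mean") {
  if (!identical(apo$labels, holo$labels)) {
    stop("state sets built over different dihedral labels")
  }
  na <- length(apo$states); nh <- length(holo$states)
  sim <- matrix(NA_real_, na, nh)
  for (i in seq_len(na)) for (j in seq_len(nh)) {
    sim[i, j] <- circular_similarity(apo$states[[i]], holo$states[[j]],
                                     aggregate = aggregate)
  }
  pairs <- data.frame(apo = integer(), holo = integer(), similarity = numeric())
  if (na && nh) {
    cand <- which(sim >= threshold, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(sim[cand], decreasing = TRUE)
      used_a <- logical(na); used_h <- logical(nh)
      for (r in ord) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_a[i] || used_h[j]) next
        used_a[i] <- TRUE; used_h[j] <- TRUE
        pairs <- rbind(pairs, data.frame(apo = i, holo = j,
                                         similarity = sim[i, j]))
      }
    }
  }
  matched_pop_apo <- sum(vapply(pairs$apo, function(i)
    apo$states[[i]]$population, 0))
  matched_pop_holo <- sum(vapply(pairs$holo, function(j)
    holo$states[[j]]$population, 0))
  structure(list(similarity = sim, pairs = pairs,
                 apo_unique = na - nrow(pairs), holo_unique = nh - nrow(pairs),
                 matched_population = c(apo = matched_pop_apo,
                                        holo = matched_pop_holo),
                 threshold = threshold),
            class = "match_report")
}

#' Classify apo vs holo sampling by kept-state counts
#'
#' @param apo,holo `state_set` objects (or integers: kept-state counts).
#' @param tolerance count difference treated as equal (default 0, strict).
#' @return one of "more_apo", "equal", "more_holo".
#' @export
compare_sampling <- function(apo, holo, tolerance = 0L) {
  ka <- if (inherits(apo, "state_set")) n_states(apo) else as.integer(apo)
  kh <- if (inherits(holo, "state_set")) n_states(holo) else as.integer(holo)
  if (abs(ka - kh) <= tolerance) "equal" else if (ka > kh) "more_apo" else "more_holo"
}
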