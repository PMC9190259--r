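## Cartesian sampling analysis: rigid-body superposition, mass-weighted PCA of
## CDR backbone coordinates, average-linkage clustering of 3-PC projections,
## and the Jensen-Shannon ensemble-overlap score (DRES).

# Kabsch optimal rotation: rotate `mob` (n x 3, centered) onto `ref` (centered);
# proper rotation enforced (reflections rejected via sign correction).
.kabsch_rotation <- function(ref, mob) {
  h <- crossprod(mob, ref)          # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  # row-vector convention: apply as mob %*% R; smallest singular pair flipped
  # when the unconstrained optimum is a reflection
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superpose an ensemble onto a reference frame
#'
#' Each frame is rigid-body least-squares fitted (optimal proper rotation plus
#' translation) onto the reference coordinates over the alignment selection;
#' the transform is applied to all atoms.
#'
#' @param ens an [ensemble()].
#' @param ref_coords N x 3 reference coordinates (same topology), e.g.
#'   `get_frame(ref_ens, 1)`.
#' @param align_idx atom indices used for the fit (>= 3 non-collinear atoms;
#'   typically the V_H/V_L interface backbone).
#' @return the aligned ensemble.
#' @export
superpose <- function(ens, ref_coords, align_idx) {
  if (length(align_idx) < 3) stop("alignment selection needs >= 3 atoms")
  ref_sel <- ref_coords[align_idx, , drop = FALSE]
  ref_cen <- colMeans(ref_sel)
  ref_c <- sweep(ref_sel, 2, ref_cen)
  if (svd(ref_c)$d[2] < 1e-8) stop("alignment selection is (near-)collinear")
  out <- ens$frames
  for (f in seq_len(dim(ens$frames)[1])) {
    co <- matrix(ens$frames[f, , ], ncol = 3)
    mob_sel <- co[align_idx, , drop = FALSE]
    mob_cen <- colMeans(mob_sel)
    rot <- .kabsch_rotation(ref_c, sweep(mob_sel, 2, mob_cen))
    fitted <- sweep(sweep(co, 2, mob_cen) %*% rot, 2, ref_cen, "+")
    out[f, , ] <- fitted
  }
  ensemble(ens$topology, out, frame_stride_ps = ens$frame_stride_ps)
}

#' Select the V_H/V_L interface backbone by proximity
#'
#' Residues of either Fv chain whose heavy atoms lie within `cutoff` of the
#' other chain in the reference frame; returns their backbone atom indices.
#'
#' @param ens an [ensemble()] with heavy/light roles.
#' @param cutoff heavy-atom distance cutoff (default 4.5 A).
#' @param frame reference frame index.
#' @return integer atom indices.
#' @export
vh_vl_interface_backbone <- function(ens, cutoff = 4.5, frame = 1) {
  model <- ens$topology
  co <- get_frame(ens, frame)
  h_idx <- select_atoms(model, role = "heavy", heavy = TRUE)
  l_idx <- select_atoms(model, role = "light", heavy = TRUE)
  iface <- define_interface(model, co, h_idx, l_idx,
                            interaction_criteria(interface_heavy_cutoff = cutoff))
  keys <- c(iface$fv_residues, iface$ag_residues)
  bb <- select_atoms(model, backbone = TRUE)
  bb[.res_key(model$atoms, bb) %in% keys]
}

## ---------------------------------------------------------------------------
## PCA

# T x 3n matrix of sqrt(mass)-weighted selected coordinates
.weighted_coords <- function(ens, sel, sqrt_m) {
  tt <- dim(ens$frames)[1]
  x <- matrix(NA_real_, tt, 3 * length(sel))
  for (f in seq_len(tt)) {
    co <- matrix(ens$frames[f, sel, ], ncol = 3)
    x[f, ] <- as.vector(t(co * sqrt_m))
  }
  x
}

#' Fit a mass-weighted PCA on combined apo + holo frames
#'
#' Frames of both ensembles are concatenated (apo first), CDR-backbone
#' coordinates are weighted by sqrt(atomic mass), and the covariance matrix is
#' diagonalised. The shared basis lets apo and holo projections be compared.
#'
#' @param apo,holo aligned [ensemble()] objects sharing a topology.
#' @param sel atom indices of the CDR backbone used for the covariance.
#' @return object of class `pca_model`: mean vector, eigenvectors (columns,
#'   orthonormal), eigenvalues (descending, A^2 Da), variance_explained, sel,
#'   sqrt_mass.
#' @export
fit_pca <- function(apo, holo, sel) {
  stopifnot(nrow(apo$topology$atoms) == nrow(holo$topology$atoms))
  sqrt_m <- sqrt(apo$topology$atoms$mass[sel])
  x <- rbind(.weighted_coords(apo, sel, sqrt_m),
             .weighted_coords(holo, sel, sqrt_m))
  if (nrow(x) < 4) stop("need at least 4 combined frames for PCA")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (nrow(x) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  structure(list(mean = mu, vectors = eg$vectors, values = vals,
                 variance_explained = vals / sum(vals), sel = sel,
                 sqrt_mass = sqrt_m),
            class = "pca_model")
}

#' Project an ensemble onto the first k principal components
#'
#' @param model a `pca_model`.
#' @param ens an aligned [ensemble()] with the same topology.
#' @param first_k number of components (default 3).
#' @param ref_coords optional N x 3 reference structure; per-frame RMSD of the
#'   CDR selection to it is reported (unweighted, A).
#' @param source label ("apo"/"holo").
#' @return object of class `pca_projection`: coordinates (T x k, mass-weighted
#'   A), rmsd_to_reference, source.
#' @export
project_ensemble <- function(model, ens, first_k = 3, ref_coords = NULL,
                             source = "ensemble") {
  if (first_k > ncol(model$vectors)) stop("first_k exceeds available components")
  x <- .weighted_coords(ens, model$sel, model$sqrt_mass)
  proj <- sweep(x, 2, model$mean) %*% model$vectors[, seq_len(first_k), drop = FALSE]
  rmsd <- rep(NA_real_, nrow(proj))
  if (!is.null(ref_coords)) {
    refsel <- ref_coords[model$sel, , drop = FALSE]
    for (f in seq_len(dim(ens$frames)[1])) {
      co <- matrix(ens$frames[f, model$sel, ], ncol = 3)
      rmsd[f] <- sqrt(mean(rowSums((co - refsel)^2)))
    }
  }
  structure(list(coordinates = proj, rmsd_to_reference = rmsd, source = source),
            class = "pca_projection")
}

#' Cluster projected frames by average-linkage hierarchical clustering
#'
#' Agglomerative average linkage on Euclidean distances in PC space; the tree
#' is cut where the merge distance exceeds `threshold` (the default 11 is in
#' mass-weighted-Angstrom PC units, matching the mass-weighted covariance).
#'
#' @param proj a `pca_projection` or a T x k coordinate matrix.
#' @param threshold linkage-distance cut (default 11).
#' @return object of class `cluster_result`: labels (1..n_clusters, dense),
#'   n_clusters, threshold.
#' @export
cluster_projections <- function(proj, threshold = 11) {
  pts <- if (inherits(proj, "pca_projection")) proj$coordinates else as.matrix(proj)
  if (nrow(pts) < 2) {
    return(structure(list(labels = rep(1L, nrow(pts)), n_clusters = nrow(pts),
                          threshold = threshold), class = "cluster_result"))
  }
  hc <- stats::hclust(stats::dist(pts), method = "average")
  labels <- stats::cutree(hc, h = threshold)
  structure(list(labels = as.integer(labels),
                 n_clusters = max(labels), threshold = threshold),
            class = "cluster_result")
}

## ---------------------------------------------------------------------------
## DRES: Jensen-Shannon divergence between projected ensembles

# product-Gaussian KDE log-density of points (m x d) given data (n x d) and
# per-dimension bandwidths h (length d)
.kde_logdens <- function(points, data, h) {
  n <- nrow(data); d <- ncol(data)
  const <- -sum(log(h)) - d / 2 * log(2 * pi) - log(n)
  lk <- matrix(0, nrow(points), n)
  for (j in seq_len(d)) {
    z <- outer(points[, j], data[, j], "-") / h[j]
    lk <- lk - 0.5 * z^2
  }
  row_logsumexp(lk) + const
}

# Silverman's rule per dimension on pooled data (shared by both densities)
.silverman_bw <- function(pooled) {
  n <- nrow(pooled); d <- ncol(pooled)
  sds <- apply(pooled, 2, stats::sd)
  sds[sds < 1e-12] <- 1e-12
  sds * (4 / ((d + 2) * n))^(1 / (d + 4))
}

#' Dimensionality-reduction ensemble similarity (Jensen-Shannon divergence)
#'
#' Each projected ensemble is turned into a Gaussian kernel density estimate
#' (shared Silverman bandwidths from the pooled frames) and the Jensen-Shannon
#' divergence (natural log) between the two densities is estimated by Monte
#' Carlo: half the samples are drawn from each KDE and
#' JSD = (E_P[ln p/m] + E_Q[ln q/m]) / 2 with m = (p+q)/2. The score lies in
#' [0, ln 2]: 0 for identical ensembles, ln 2 for no overlap.
#'
#' @param apo_proj,holo_proj `pca_projection` objects (or T x k matrices) in
#'   the same PC basis, each with >= 10 frames.
#' @param n_samples Monte-Carlo sample count (default 10000).
#' @param seed RNG seed for the Monte-Carlo estimate.
#' @return object of class `dres_score`: value (nats), settings.
#' @export
dres <- function(apo_proj, holo_proj, n_samples = 10000, seed = 1) {
  p <- if (inherits(apo_proj, "pca_projection")) apo_proj$coordinates else as.matrix(apo_proj)
  q <- if (inherits(holo_proj, "pca_projection")) holo_proj$coordinates else as.matrix(holo_proj)
  if (nrow(p) < 10 || nrow(q) < 10) stop("each ensemble needs >= 10 frames for DRES")
  stopifnot(ncol(p) == ncol(q))
  d <- ncol(p)
  h <- .silverman_bw(rbind(p, q))
  sample_kde <- function(data, ns) {
    pick <- sample.int(nrow(data), ns, replace = TRUE)
    data[pick, , drop = FALSE] +
      matrix(stats::rnorm(ns * d), ns, d) %*% diag(h, d, d)
  }
  value <- with_seed(seed, {
    ns_p <- ceiling(n_samples / 2); ns_q <- n_samples - ns_p
    xp <- sample_kde(p, ns_p)
    xq <- sample_kde(q, ns_q)
    lp_p <- .kde_logdens(xp, p, h); lq_p <- .kde_logdens(xp, q, h)
    lp_q <- .kde_logdens(xq, p, h); lq_q <- .kde_logdens(xq, q, h)
    lm_p <- pmax(lp_p, lq_p) + log1p(exp(-abs(lp_p - lq_p))) - log(2)
    lm_q <- pmax(lp_q, lq_q) + log1p(exp(-abs(lp_q - lq_q))) - log(2)
    0.5 * mean(lp_p - lm_p) + 0.5 * mean(lq_q - lm_q)
  })
  value <- min(max(value, 0), log(2))
  structure(list(value = value,
                 settings = list(bandwidth = h, n_samples = n_samples,
                                 seed = seed, bandwidth_rule = "silverman")),
            class = "dres_score")
}

#' @export
print.dres_score <- function(x, ...) {
  cat(sprintf("DRES = %.4f nats (0 = identical, ln 2 = %.4f = disjoint)\n",
              x$value, log(2)))
  invisible(x)
}
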