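# Superposition, mass-weighted PCA, linkage clustering, DRES.

rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

test_that("superposition undoes rigid-body motion and is idempotent", {
  set.seed(31)
  tb <- toy_base()
  ref <- get_frame(tb$base, 1)
  align <- select_atoms(tb$base, chain = c("H", "A"), backbone = TRUE)
  # frames are rotated + translated copies of the reference
  tt <- 5
  frames <- array(NA_real_, dim = c(tt, nrow(ref), 3))
  for (f in seq_len(tt)) {
    frames[f, , ] <- ref %*% rand_rotation() +
      matrix(rnorm(3, 0, 10), nrow(ref), 3, byrow = TRUE)
  }
  ens <- ensemble(tb$base$topology, frames)
  fit <- superpose(ens, ref, align)
  for (f in seq_len(tt)) {
    rmsd <- sqrt(mean(rowSums((get_frame(fit, f)[align, ] - ref[align, ])^2)))
    expect_lt(rmsd, 1e-6)
  }
  # idempotent: aligning the aligned ensemble is a no-op
  fit2 <- superpose(fit, ref, align)
  expect_lt(max(abs(fit2$frames - fit$frames)), 1e-9)
  # pre-translating the input changes nothing after fitting
  ens_t <- ensemble(tb$base$topology, sweep(frames, 3, c(5, -3, 2), "+"))
  fit_t <- superpose(ens_t, ref, align)
  expect_equal(fit_t$frames, fit$frames, tolerance = 1e-9)
  # degenerate alignment selections are rejected
  expect_error(superpose(ens, ref, align[1:2]), ">= 3 atoms")
  colinear <- ref
  colinear[align[1:4], ] <- cbind(1:4, 0, 0)
  expect_error(superpose(ens, colinear, align[1:4]), "collinear")
})

test_that("superposition matches bio3d least-squares fitting", {
  set.seed(32)
  tb <- toy_base()
  ref <- get_frame(tb$base, 1)
  align <- select_atoms(tb$base, chain = "H", backbone = TRUE)
  co <- ref + matrix(rnorm(length(ref), 0, 0.4), nrow(ref), 3)
  ens <- ensemble(tb$base$topology, array(co, c(1, dim(co))))
  fit <- superpose(ens, ref, align)
  ours <- sqrt(mean(rowSums((get_frame(fit, 1)[align, ] - ref[align, ])^2)))
  theirs_xyz <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(co)),
                               fixed.inds = bio3d::atom2xyz(align),
                               mobile.inds = bio3d::atom2xyz(align))
  theirs <- bio3d::rmsd(as.vector(t(ref)), theirs_xyz,
                        a.inds = bio3d::atom2xyz(align),
                        b.inds = bio3d::atom2xyz(align))
  # agreement with bio3d, and never worse than it (our fit is the optimum)
  expect_equal(ours, as.numeric(theirs), tolerance = 2e-3)
  expect_lte(ours, as.numeric(theirs) + 1e-6)
})

test_that("PCA identities: rank, mass scaling, eigenvalue recovery, projection", {
  tb <- toy_base()
  # single planted mode: rank-1 covariance
  g1 <- generate_cartesian_ensemble(tb$base, tb$cdr, list(c(0, 0, 0)),
                                    spread = 0, n_frames = 30, seed = 1)
  amp <- rnorm(30, 0, 2)
  for (f in 1:30) {
    g1$ensemble$frames[f, tb$cdr, 1] <-
      g1$ensemble$frames[f, tb$cdr, 1] + amp[f] / sqrt(length(tb$cdr))
  }
  p1 <- fit_pca(g1$ensemble, g1$ensemble, tb$cdr)
  expect_gte(p1$variance_explained[1], 0.999)
  expect_equal(sum(p1$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(p1$values) <= 1e-9))
  expect_true(all(p1$values >= 0))
  # eigenvector orthonormality
  v <- p1$vectors[, 1:5]
  expect_equal(crossprod(v), diag(5), tolerance = 1e-8)
  # doubling masses doubles eigenvalues, leaves directions unchanged
  heavier <- g1$ensemble
  heavier$topology$atoms$mass <- heavier$topology$atoms$mass * 2
  p2 <- fit_pca(heavier, heavier, tb$cdr)
  expect_equal(p2$values[1], 2 * p1$values[1], tolerance = 1e-9)
  expect_equal(abs(sum(p2$vectors[, 1] * p1$vectors[, 1])), 1, tolerance = 1e-9)
  # three orthogonal planted modes with variance ratios 9:3:1
  g3 <- generate_cartesian_ensemble(tb$base, tb$cdr, list(c(0, 0, 0)),
                                    spread = 0, n_frames = 5000, seed = 5)
  set.seed(6)
  a3 <- cbind(rnorm(5000, 0, 3), rnorm(5000, 0, sqrt(3)), rnorm(5000, 0, 1))
  for (k in 1:3) {
    g3$ensemble$frames[, tb$cdr, k] <-
      g3$ensemble$frames[, tb$cdr, k] + a3[, k] / sqrt(length(tb$cdr))
  }
  p3 <- fit_pca(g3$ensemble, g3$ensemble, tb$cdr)
  expect_equal(p3$values[1] / p3$values[3], 9, tolerance = 0.05 * 9)
  expect_equal(p3$values[2] / p3$values[3], 3, tolerance = 0.05 * 3)
  # projection identities hold exactly on the ensemble the model was fit on
  # (apo followed by holo; here the same frames twice)
  cat_ens <- ensemble(g3$ensemble$topology,
                      g3$ensemble$frames[c(1:5000, 1:5000), , , drop = FALSE])
  pr <- project_ensemble(p3, cat_ens, first_k = 3)
  expect_equal(apply(pr$coordinates, 2, var), p3$values[1:3], tolerance = 1e-6,
               ignore_attr = TRUE)
  # the mean structure projects to the origin
  mean_coords <- matrix(0, 1, ncol(pr$coordinates))
  mu_frame <- g3$ensemble
  mu_x <- colMeans(abflex:::.weighted_coords(g3$ensemble, tb$cdr, p3$sqrt_mass))
  expect_equal(as.numeric((mu_x - p3$mean) %*% p3$vectors[, 1:3]),
               as.numeric(mean_coords), tolerance = 1e-9)
  # residual variance after 3 PCs equals the trailing eigenvalue sum
  x <- abflex:::.weighted_coords(g3$ensemble, tb$cdr, p3$sqrt_mass)
  x <- rbind(x, x)  # model was fitted on apo+holo concatenation
  xc <- sweep(x, 2, p3$mean)
  total_var <- sum(apply(xc, 2, var))
  expect_equal(total_var - sum(p3$values[1:3]), sum(p3$values[-(1:3)]),
               tolerance = 1e-6)
  expect_error(project_ensemble(p3, g3$ensemble, first_k = 1000), "exceeds")
  expect_error(fit_pca(ensemble(tb$base$topology,
                                tb$base$frames[1, , , drop = FALSE]),
                       ensemble(tb$base$topology,
                                tb$base$frames[1, , , drop = FALSE]),
                       tb$cdr),
               "at least 4")
})

test_that("average-linkage clustering matches a naive O(T^3) oracle", {
  set.seed(41)
  for (rep_i in 1:8) {
    k <- sample(1:4, 1)
    n <- sample(40:80, 1)
    centers <- matrix(rnorm(k * 3, 0, 30), k, 3)
    pts <- centers[sample(k, n, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(n * 3), n, 3)
    got <- cluster_projections(pts, threshold = 11)
    want <- oracle_average_linkage(pts, 11)
    expect_identical(canonical_partition(got$labels), canonical_partition(want))
  }
  # monotonicity: cluster count non-increasing in the threshold
  pts <- matrix(rnorm(150 * 3, 0, 8), 150, 3)
  counts <- vapply(c(2, 5, 11, 20, 50),
                   function(h) cluster_projections(pts, h)$n_clusters, 0L)
  expect_true(all(diff(counts) <= 0))
  # two tight, distant blobs at the paper threshold
  blobs <- rbind(matrix(rnorm(60, 0, 1), 20, 3),
                 matrix(rnorm(60, 40, 1), 20, 3))
  expect_equal(cluster_projections(blobs, 11)$n_clusters, 2L)
  expect_equal(cluster_projections(matrix(rnorm(60, 0, 1), 20, 3),
                                   11)$n_clusters, 1L)
})

test_that("DRES obeys its analytic anchors and matches quadrature", {
  set.seed(51)
  p <- matrix(rnorm(300), 100, 3)
  # identical ensembles score exactly zero
  expect_equal(dres(p, p, seed = 1)$value, 0)
  # far-separated ensembles approach ln 2
  q_far <- p + 50
  expect_equal(dres(p, q_far, seed = 1)$value, log(2), tolerance = 0.01)
  # symmetry up to Monte-Carlo error, and the ln 2 bound
  q <- matrix(rnorm(300, 1, 1), 100, 3)
  d1 <- dres(p, q, n_samples = 20000, seed = 2)$value
  d2 <- dres(q, p, n_samples = 20000, seed = 3)$value
  expect_lt(abs(d1 - d2), 0.02)
  expect_lte(d1, log(2) + 1e-9)
  expect_gte(d1, 0)
  # quadrature oracle on planted 1-D-offset Gaussian clouds
  for (offset in c(0.5, 1.5, 3)) {
    pp <- matrix(rnorm(300), 100, 3)
    qq <- cbind(rnorm(100, offset), rnorm(100), rnorm(100))
    mc <- dres(pp, qq, n_samples = 20000, seed = 4)$value
    exact <- oracle_jsd_quadrature(pp, qq)
    expect_lt(abs(mc - exact), 0.02)
  }
  expect_error(dres(p[1:5, ], q, seed = 1), ">= 10 frames")
})
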