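## Small shared helpers: atomic masses, circular statistics, seeded evaluation.

# Standard atomic weights (Da) for elements that occur in protein/solvent systems.
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098, MG = 24.305,
  CA = 40.078, MN = 54.938, ZN = 65.38, FE = 55.845
)

#' Look up standard atomic masses
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Da.
#' @keywords internal
element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  m <- .ATOMIC_MASS[key]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Wrap angles into (-180, 180]
#' @param x angles in degrees.
#' @keywords internal
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  # map -180 to +180 so the range is half-open
  w[w == -180] <- 180
  w
}

#' Absolute circular difference in [0, 180]
#' @keywords internal
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Circular mean of angles in degrees, result in (-180, 180]
#' @keywords internal
circ_mean <- function(x) {
  r <- x * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Dihedral angle of four points
#'
#' Standard IUPAC-sign torsion: looking down the b-c axis, the angle from
#' plane (a,b,c) to plane (b,c,d), in degrees in (-180, 180].
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    stop("dihedral undefined: collinear atoms")
  }
  m1 <- c(b2[2] * n1[3] - b2[3] * n1[2],
          b2[3] * n1[1] - b2[1] * n1[3],
          b2[1] * n1[2] - b2[2] * n1[1])
  nb2 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Pairwise Euclidean distances between two coordinate sets
#' @param a,b matrices (n x 3, m x 3).
#' @return n x m distance matrix.
#' @keywords internal
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Angle at vertex h between vectors h->a and h->b, degrees in [0, 180]
#' @keywords internal
vertex_angle <- function(a, h, b) {
  v1 <- a - h; v2 <- b - h
  cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' log-sum-exp along rows
#' @keywords internal
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
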