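# Shared builders and independent oracles for the test suite.

# Smooth, clash-free random chain: a seeded helical/wavy backbone with
# unit-ish bonds, suitable for finite-difference and invariance checks
# (random walks self-intersect and put pair energies on the r^-12 wall).
wavy_chain <- function(n, seed) {
  # all bending angles are kept clearly bent (sin(theta) > 0.25): the
  # angular forces are exact gradients away from the collinear limit,
  # where the torsional torque is deliberately tapered
  for (attempt in 0:20) {
    set.seed(seed + 1000 * attempt)
    a <- runif(1, 0.2, 0.5)
    b <- runif(1, 0.4, 0.9)
    t <- seq_len(n)
    pos <- cbind(cos(b * t), sin(b * t), a * t)
    # rescale to unit mean bond length, add a little noise
    bl <- mean(sqrt(rowSums(diff(pos)^2)))
    pos <- pos / bl + matrix(rnorm(3 * n, sd = 0.03), n, 3)
    conf <- chain_configuration(pos)
    if (min(sin(chain_angles(conf)$theta)) > 0.25) return(conf)
  }
  stop("could not generate a well-bent chain")
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Maximum relative finite-difference force error over all coordinates.
fd_force_error <- function(efun, pos, h = 1e-6) {
  ev <- efun(pos)
  err <- 0
  for (i in seq_len(nrow(pos))) {
    for (c in 1:3) {
      pp <- pos
      pp[i, c] <- pp[i, c] + h
      pm <- pos
      pm[i, c] <- pm[i, c] - h
      fd <- -(efun(pp)$energy - efun(pm)$energy) / (2 * h)
      err <- max(err, abs(fd - ev$forces[i, c]) / max(1, abs(fd)))
    }
  }
  err
}

# A gently curved 10-bead native structure whose bending angles sit well
# inside (0, pi), used for thermostat and equipartition checks.
curved_native_10 <- function() {
  build_chain_from_internal(rep(1, 9),
                            seq(2.0, 2.6, length.out = 8),
                            seq(1.2, -1.2, length.out = 7))
}

# Independent hard segment/triangle oracle: solves the 3 x 3 linear system
# p0 + t (p1 - p0) = v1 + u (v2 - v1) + v (v3 - v1) for (t, u, v) and
# tests 0 < t < 1, u > 0, v > 0, u + v < 1 (Moeller-Trumbore style),
# entirely different from the plane-crossing + edge-margin implementation.
raycast_crossing <- function(p0, p1, tri) {
  A <- cbind(p1 - p0, -(tri[2, ] - tri[1, ]), -(tri[3, ] - tri[1, ]))
  sol <- tryCatch(solve(A, tri[1, ] - p0), error = function(e) NULL)
  if (is.null(sol)) return(0L)
  t <- sol[1]
  u <- sol[2]
  v <- sol[3]
  if (t <= 0 || t >= 1 || u <= 0 || v <= 0 || u + v >= 1) return(0L)
  nrm <- pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
  if (sum(nrm * (p1 - p0)) > 0) 1L else -1L
}

# Distance of the segment/plane intersection point from the nearest
# triangle edge or from the plane-straddle margin, used to exclude
# marginal cases (within the switch width) from hard-sign comparisons.
raycast_margin <- function(p0, p1, tri) {
  nrm <- pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
  a2 <- sqrt(sum(nrm^2))
  if (a2 < 1e-12) return(0)
  nhat <- nrm / a2
  s0 <- sum(nhat * (p0 - tri[1, ]))
  s1 <- sum(nhat * (p1 - tri[1, ]))
  if (abs(s0 - s1) < 1e-12) return(min(abs(s0), abs(s1)))
  t <- s0 / (s0 - s1)
  q <- p0 + max(0, min(1, t)) * (p1 - p0)
  q <- q - sum(nhat * (q - tri[1, ])) * nhat
  edge_d <- function(a, b) {
    m <- pracma::cross(nhat, b - a)
    m <- m / sqrt(sum(m^2))
    sum(m * (q - a))
  }
  min(abs(s0), abs(s1),
      abs(edge_d(tri[1, ], tri[2, ])),
      abs(edge_d(tri[2, ], tri[3, ])),
      abs(edge_d(tri[3, ], tri[1, ])))
}

# Numerical-quadrature oracle for the Gauss integral of one straight
# segment pair: tensor Gauss-Legendre quadrature of the integrand over
# the unit square, with a two-resolution convergence check (errors if
# the quadrature has not converged, so the caller can skip the case).
gauss_pair_quadrature <- function(p1, p2, p3, p4, tol = 1e-8) {
  a <- p2 - p1
  b <- p4 - p3
  axb <- pracma::cross(a, b)
  eval_n <- function(n) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    S <- outer(gl$x, rep(1, n))
    T <- outer(rep(1, n), gl$x)
    rx <- (p1[1] + S * a[1]) - (p3[1] + T * b[1])
    ry <- (p1[2] + S * a[2]) - (p3[2] + T * b[2])
    rz <- (p1[3] + S * a[3]) - (p3[3] + T * b[3])
    val <- (rx * axb[1] + ry * axb[2] + rz * axb[3]) /
      (rx^2 + ry^2 + rz^2)^(3 / 2)
    drop(gl$w %*% val %*% gl$w) / (4 * pi)
  }
  q1 <- eval_n(64)
  q2 <- eval_n(128)
  if (abs(q2 - q1) > tol) stop("quadrature not converged")
  q2
}

# Bundle used across tests: the standard L2 mini-lasso system plus its
# homogeneous force field and bridge parameters.
standard_mini_lasso <- function(seed = 1) {
  ml <- make_mini_lasso(12, 10, "L2", seed = seed)
  params <- model_parameters()
  ml$params <- params
  ml$ff <- efm_forcefield(n_beads(ml$conf))
  ml$bridges <- bridge_parameters(ml$ref, temperature = params$temperature)
  ml
}

# Tiny hand-written PDB fragment: 3 CA atoms of chain A at 3.8 A spacing
# plus one chain B residue (tests splice in altloc duplicates as needed).
pdb_snippet <- function() {
  c("HEADER    TEST",
    "ATOM      1  N   ALA A   1      -1.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  LEU B   1       0.000   5.000   0.000  1.00  0.00           C",
    "END")
}
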