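# Elastic folder model: parameters, force fields, potentials, total forces.

#' Model parameters in reduced units
#'
#' Reduced units: length in sigma (= 3.8 Angstrom, the Calpha-Calpha
#' spacing), energy in E, mass m = 1, time in tau_MD = sigma * sqrt(m / E),
#' temperature in E / k_B.
#'
#' @param sigma length unit (1.0).
#' @param epsilon energy unit (1.0), also the WCA well scale.
#' @param mass bead mass (1.0).
#' @param k_fene FENE bond strength (30).
#' @param R0 maximal FENE bond length (1.5 sigma).
#' @param dt integration time step (5e-4 tau_MD).
#' @param tau_frict Langevin friction time (1.0); the friction coefficient
#'   is gamma = mass / tau_frict.
#' @param temperature simulation temperature (0.1 E / k_B).
#' @param wca_exclude_bonded exclude directly bonded pairs from the WCA
#'   steric sum. Default `FALSE`: the steric sum runs over all pairs, the
#'   standard FENE + WCA combination whose bonded pair term has its
#'   minimum at 0.961 sigma (excluding bonded pairs leaves the FENE bond
#'   without a repulsive core and the chain collapses).
#' @return list of class `model_parameters`.
#' @export
model_parameters <- function(sigma = 1.0, epsilon = 1.0, mass = 1.0,
                             k_fene = 30.0, R0 = 1.5, dt = 5e-4,
                             tau_frict = 1.0, temperature = 0.1,
                             wca_exclude_bonded = FALSE) {
  if (R0 <= sigma) stop("R0 must exceed sigma")
  if (dt <= 0 || tau_frict <= 0) stop("dt and tau_frict must be positive")
  structure(list(sigma = sigma, epsilon = epsilon, mass = mass,
                 k_fene = k_fene, R0 = R0, dt = dt, tau_frict = tau_frict,
                 temperature = temperature,
                 wca_exclude_bonded = wca_exclude_bonded),
            class = "model_parameters")
}

#' Angular force field of the elastic folder model
#'
#' Holds the per-angle bending stiffnesses (N - 2 values) and torsion
#' first-harmonic stiffnesses (N - 3 values); the third harmonic is always
#' k3 = k1 / 3 and is derived, never stored. Neighboring coefficients can be
#' constrained pairwise equal, which halves the dimensionality of the
#' stochastic search; the constraint groups are stored as index sets over
#' the combined coefficient vector (bending block first, then torsion).
#'
#' @param n_beads chain length N.
#' @param k_bend scalar or N - 2 vector of bending stiffnesses.
#' @param k1_tor scalar or N - 3 vector of torsion stiffnesses.
#' @param paired constrain neighboring coefficient pairs to be equal.
#' @return object of class `efm_forcefield`.
#' @export
efm_forcefield <- function(n_beads, k_bend = 36.5, k1_tor = 38.5,
                           paired = TRUE) {
  nb <- n_beads - 2
  nt <- n_beads - 3
  k_bend <- rep_len(k_bend, nb)
  k1_tor <- rep_len(k1_tor, nt)
  if (any(c(k_bend, k1_tor) <= 0)) stop("stiffnesses must be positive")
  pairing <- coefficient_pairing(n_beads, paired)
  ff <- structure(list(k_bend = k_bend, k1_tor = k1_tor, pairing = pairing,
                       n_beads = n_beads),
                  class = "efm_forcefield")
  enforce_pairing(ff)
}

# Constraint groups over the combined coefficient vector
# (k_bend[1..N-2], k1_tor[1..N-3]): neighboring pairs within each block,
# with a trailing singleton when the block length is odd.
coefficient_pairing <- function(n_beads, paired = TRUE) {
  nb <- n_beads - 2
  nt <- n_beads - 3
  if (!paired) {
    return(as.list(seq_len(nb + nt)))
  }
  block <- function(n, offset) {
    if (n == 0) return(list())
    starts <- seq(1, n, by = 2)
    lapply(starts, function(s) offset + s:min(s + 1, n))
  }
  c(block(nb, 0), block(nt, nb))
}

ff_to_vector <- function(ff) c(ff$k_bend, ff$k1_tor)

ff_from_vector <- function(ff, k) {
  nb <- length(ff$k_bend)
  ff$k_bend <- k[seq_len(nb)]
  ff$k1_tor <- k[nb + seq_len(length(ff$k1_tor))]
  ff
}

# Make paired coefficients exactly equal (first member of each group wins).
enforce_pairing <- function(ff) {
  k <- ff_to_vector(ff)
  for (g in ff$pairing) k[g] <- k[g[1]]
  ff_from_vector(ff, k)
}

pairing_satisfied <- function(ff) {
  k <- ff_to_vector(ff)
  all(vapply(ff$pairing, function(g) all(k[g] == k[g[1]]), logical(1)))
}

#' @export
print.efm_forcefield <- function(x, ...) {
  cat("<efm_forcefield>", x$n_beads, "beads;",
      length(x$pairing), "constraint groups; mean k_bend",
      round(mean(x$k_bend), 2), ", mean k1_tor", round(mean(x$k1_tor), 2),
      "\n")
  invisible(x)
}

#' Disulfide-bridge potential parameters
#'
#' One truncated, force-shifted Lennard-Jones well per cysteine pair. The
#' LJ length sigma_b of each pair is fixed so the well minimum sits at the
#' native pair distance (sigma_b = d_native / 2^(1/6)); the well depth
#' defaults to 10 k_B T of the run so thermal fluctuations rarely break a
#' formed bridge. Disabling the term models a reducing environment.
#'
#' @param ref [extract_reference_geometry()] output carrying bridge pairs.
#' @param temperature run temperature, used for the default depth.
#' @param epsilon_b well depth per pair (scalar or vector); default 10 T.
#' @param r_cut_factor cutoff as a multiple of sigma_b (default 2.5).
#' @param enabled `TRUE` for oxidizing, `FALSE` for reducing conditions.
#' @return object of class `bridge_parameters`.
#' @export
bridge_parameters <- function(ref, temperature = 0.1, epsilon_b = NULL,
                              r_cut_factor = 2.5, enabled = TRUE) {
  nb <- nrow(ref$bridge_idx)
  sigma_b <- ref$bridge_ref_dist / 2^(1 / 6)
  epsilon_b <- rep_len(epsilon_b %||% (10 * temperature), nb)
  r_cut <- r_cut_factor * sigma_b
  if (nb > 0 && any(r_cut <= 2^(1 / 6) * sigma_b)) {
    stop("r_cut must exceed the bridge well minimum")
  }
  structure(list(pairs0 = matrix(as.integer(ref$bridge_idx - 1L), nb, 2),
                 pairs = ref$bridge_pairs, sigma_b = sigma_b,
                 epsilon_b = epsilon_b, r_cut = r_cut, enabled = enabled),
            class = "bridge_parameters")
}

bridges_disabled <- function() {
  structure(list(pairs0 = matrix(integer(0), 0, 2), pairs = list(),
                 sigma_b = numeric(0), epsilon_b = numeric(0),
                 r_cut = numeric(0), enabled = FALSE),
            class = "bridge_parameters")
}

#' Pair potentials of the model
#'
#' `wca_energy()` is the Weeks-Chandler-Andersen purely repulsive core:
#' the Lennard-Jones potential shifted up by epsilon and cut at its minimum
#' `2^(1/6) sigma`, continuous at the cutoff. `fene_energy()` is the
#' finitely extensible nonlinear elastic bond, diverging as r approaches
#' R0. `bridge_pair_energy()` is the truncated, force-shifted Lennard-Jones
#' well used for disulfide bridges: both the energy and its derivative
#' vanish at the cutoff.
#'
#' @param r pair distance(s), sigma units.
#' @param epsilon,sigma LJ energy and length scales.
#' @param k_fene,R0 FENE strength and maximal extension.
#' @param epsilon_b,sigma_b,r_cut bridge well depth, length, cutoff.
#' @return energies in reduced units.
#' @name pair_potentials
NULL

#' @rdname pair_potentials
#' @export
wca_energy <- function(r, epsilon = 1.0, sigma = 1.0) {
  if (any(r <= 0)) stop("r must be positive")
  sr6 <- (sigma / r)^6
  ifelse(r < 2^(1 / 6) * sigma, 4 * epsilon * (sr6^2 - sr6) + epsilon, 0)
}

#' @rdname pair_potentials
#' @export
fene_energy <- function(r, k_fene = 30.0, R0 = 1.5) {
  if (any(r < 0)) stop("r must be non-negative")
  if (any(r >= R0)) stop("bond overstretched: r >= R0")
  -(k_fene / 2) * R0^2 * log(1 - (r / R0)^2)
}

#' @rdname pair_potentials
#' @export
bridge_pair_energy <- function(r, epsilon_b, sigma_b, r_cut) {
  if (any(r <= 0)) stop("r must be positive")
  ulj <- function(x) 4 * epsilon_b * ((sigma_b / x)^12 - (sigma_b / x)^6)
  dulj <- function(x) {
    -24 * epsilon_b * (2 * (sigma_b / x)^12 - (sigma_b / x)^6) / x
  }
  ifelse(r < r_cut, ulj(r) - ulj(r_cut) - (r - r_cut) * dulj(r_cut), 0)
}

#' Angular potentials
#'
#' `bending_energy()` is the harmonic bending term `k (theta - theta0)^2`
#' (no 1/2 factor). `torsion_energy()` is the two-harmonic torsion term
#' `k1 [1 - cos(phi - phi0)] + k3 [1 - cos(3 (phi - phi0))]`, written so
#' the reference angle phi0 is the global minimum with zero energy; the
#' third harmonic defaults to the model constraint k3 = k1 / 3.
#'
#' @param theta,theta0 bending angle and its reference, radians in
#'   `[0, pi]`.
#' @param phi,phi0 torsion angle and its reference, radians.
#' @param k,k1,k3 stiffness coefficients.
#' @return energies in reduced units.
#' @name angular_potentials
NULL

#' @rdname angular_potentials
#' @export
bending_energy <- function(theta, theta0, k) {
  k * (theta - theta0)^2
}

#' @rdname angular_potentials
#' @export
torsion_energy <- function(phi, phi0, k1, k3 = k1 / 3) {
  dphi <- phi - phi0
  k1 * (1 - cos(dphi)) + k3 * (1 - cos(3 * dphi))
}

#' Total energy and forces of the elastic folder model
#'
#' Sums the steric (WCA), bond (FENE), angular (bending + torsion) and,
#' under oxidizing conditions, disulfide-bridge terms, and returns the
#' exact negative gradient as per-bead forces.
#'
#' @param conf a [chain_configuration()].
#' @param ref matching [extract_reference_geometry()] output.
#' @param ff an [efm_forcefield()].
#' @param params [model_parameters()].
#' @param bridges [bridge_parameters()] or `NULL` (reducing conditions).
#' @return list with `energy`, `forces` (N x 3) and per-term `components`.
#' @export
efm_total_energy_forces <- function(conf, ref, ff, params = model_parameters(),
                                    bridges = NULL) {
  pos <- conf$positions
  if (length(ref$theta0) != nrow(pos) - 2) {
    stop("configuration and reference dimensions differ")
  }
  efm_energy_forces_cpp(pos, unclass(ref), unclass(ff), unclass(params),
                        unclass(bridges %||% bridges_disabled()))
}
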