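# Clementi-type Calpha Go model: 12-10 native contacts + angular terms.

#' Build a Go-model force field from a native structure
#'
#' Native contacts are taken from a SMOG-style contact file (two
#' whitespace-separated 1-based residue-id columns) when supplied, or built
#' from the native structure with a Calpha distance cutoff otherwise. Each
#' contact interacts through a 12-10 Lennard-Jones well with its minimum at
#' the native pair distance. Backbone stiffness uses the same bending and
#' torsion potentials as the elastic folder model, with homogeneous
#' coefficients and an independent third torsion harmonic. Under oxidizing
#' conditions the contact amplitude of the bridge-forming cysteine pairs is
#' raised to `10 k_B T`; those pairs are always present as contacts, so in
#' reducing conditions they keep the default (weaker) amplitude.
#'
#' @param conf native [chain_configuration()].
#' @param contact_file path to a SMOG-style contact list, or `NULL`.
#' @param cutoff Calpha contact cutoff in sigma units (default 7.5 Angstrom
#'   / 3.8) when no contact file is given.
#' @param min_sep minimal sequence separation `|i - j|` for contacts.
#' @param cys_pairs list of length-2 residue-id vectors naming the
#'   bridge-forming cysteine pairs.
#' @param oxidizing logical; rescale cysteine contacts to `10 k_B T`.
#' @param kBT thermal energy of the intended run.
#' @param E_default default contact amplitude (energy units).
#' @param k_bend_homog,k1_tor_homog,k3_tor_homog homogeneous angular
#'   stiffnesses (defaults 40.0, 1.0, 0.5).
#' @param k_bond harmonic bond stiffness; bonds are harmonic around the
#'   native bond lengths (default 100).
#' @param ev_sigma excluded-volume diameter for non-contact pairs (default
#'   4.0 Angstrom / 3.8).
#' @return object of class `go_forcefield`.
#' @export
build_go_forcefield <- function(conf, contact_file = NULL,
                                cutoff = 7.5 / 3.8, min_sep = 3,
                                cys_pairs = list(), oxidizing = FALSE,
                                kBT = 0.7, E_default = 1.0,
                                k_bend_homog = 40.0, k1_tor_homog = 1.0,
                                k3_tor_homog = 0.5, k_bond = 100.0,
                                ev_sigma = 4.0 / 3.8) {
  pos <- conf$positions
  n <- nrow(pos)
  if (!is.null(contact_file)) {
    pairs <- parse_contact_file(contact_file)
  } else {
    pairs <- contacts_by_cutoff(pos, cutoff, min_sep)
    pairs <- cbind(conf$residue_ids[pairs[, 1]], conf$residue_ids[pairs[, 2]])
  }
  # ensure bridge-forming cysteines are contacts in both environments
  for (cp in cys_pairs) {
    cp <- sort(as.integer(cp))
    hit <- pairs[, 1] == cp[1] & pairs[, 2] == cp[2]
    if (!any(hit)) pairs <- rbind(pairs, cp)
  }
  i <- residue_index(conf, pairs[, 1], "contact")
  j <- residue_index(conf, pairs[, 2], "contact")
  if (any(abs(i - j) < min_sep)) {
    stop(sprintf("contact with |i - j| < %d", min_sep))
  }
  r_nat <- sqrt(rowSums((pos[i, , drop = FALSE] - pos[j, , drop = FALSE])^2))
  E <- rep(E_default, length(i))
  cys <- rep(FALSE, length(i))
  for (cp in cys_pairs) {
    cp <- sort(as.integer(cp))
    cys <- cys | (pairs[, 1] == cp[1] & pairs[, 2] == cp[2])
  }
  if (oxidizing) E[cys] <- 10 * kBT
  ang <- chain_angles(conf)
  bond_r0 <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                             pos[-n, , drop = FALSE])^2))
  structure(list(contacts = data.frame(i = pairs[, 1], j = pairs[, 2],
                                       r_native = r_nat, E_ij = E,
                                       cysteine = cys),
                 contacts0 = cbind(as.integer(i - 1L), as.integer(j - 1L)),
                 E_ij = E, r_native = r_nat,
                 bond_r0 = bond_r0, k_bond = k_bond,
                 theta0 = ang$theta, phi0 = ang$phi,
                 k_bend_homog = k_bend_homog, k1_tor_homog = k1_tor_homog,
                 k3_tor_homog = k3_tor_homog,
                 ev_epsilon = 1.0, ev_sigma = ev_sigma,
                 ev_r_cut = 2.0 * ev_sigma, ev_min_sep = as.integer(min_sep),
                 oxidizing = oxidizing, n_beads = n),
            class = "go_forcefield")
}

# SMOG-style contact list: two whitespace-separated 1-based residue ids per
# line; '#' comments and blank lines allowed.
parse_contact_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- matrix(NA_integer_, sum(keep), 2)
  row <- 0
  for (ln in which(keep)) {
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    vals <- suppressWarnings(as.integer(fields))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      stop(sprintf("malformed contact file at line %d: '%s'", ln, lines[ln]))
    }
    row <- row + 1
    out[row, ] <- sort(vals[1:2])
  }
  out
}

contacts_by_cutoff <- function(pos, cutoff, min_sep) {
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  sel <- which(upper.tri(d) & d < cutoff &
                 abs(row(d) - col(d)) >= min_sep, arr.ind = TRUE)
  sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
}

#' @export
print.go_forcefield <- function(x, ...) {
  cat("<go_forcefield>", x$n_beads, "beads,", nrow(x$contacts),
      "native contacts", if (x$oxidizing) "(oxidizing)" else "(reducing)",
      "\n")
  invisible(x)
}

#' Total energy and forces of the Go model
#'
#' 12-10 native-contact attractions (each minimal at its native distance),
#' FENE bonds, homogeneous bending/torsion terms referenced to the native
#' angles, and a force-shifted 12-power excluded volume for non-contact
#' pairs. Forces are the exact negative gradient.
#'
#' @param conf a [chain_configuration()].
#' @param goff a [build_go_forcefield()] object.
#' @param params [model_parameters()].
#' @return list with `energy`, `forces` and per-term `components`.
#' @export
go_total_energy_forces <- function(conf, goff, params = model_parameters()) {
  if (n_beads(conf) != goff$n_beads) {
    stop("configuration and force field dimensions differ")
  }
  go_energy_forces_cpp(conf$positions, unclass(goff), unclass(params))
}
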