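# Chain configurations: construction, PDB parsing, stretched initial states.

#' Create a chain configuration
#'
#' A chain configuration is an ordered set of Calpha bead positions in
#' reduced length units (sigma = 3.8 Angstrom), together with the original
#' residue numbers so that residue-based selections (bridge cysteines, loop
#' and tail reductions) address the right beads even when the resolved
#' sequence has gaps.
#'
#' @param positions numeric N x 3 matrix of bead coordinates (sigma units).
#' @param residue_ids integer vector of length N; defaults to `1:N`.
#' @param chain_label single character identifier.
#' @return an object of class `chain_configuration`.
#' @export
chain_configuration <- function(positions, residue_ids = NULL,
                                chain_label = "A") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (any(!is.finite(positions))) stop("positions contain non-finite values")
  n <- nrow(positions)
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  if (length(residue_ids) != n) stop("residue_ids length must match positions")
  if (n >= 2) {
    b <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                         positions[-n, , drop = FALSE])^2))
    if (any(b <= 0)) stop("consecutive beads coincide")
  }
  structure(list(positions = positions,
                 residue_ids = as.integer(residue_ids),
                 chain_label = chain_label),
            class = "chain_configuration")
}

#' @export
print.chain_configuration <- function(x, ...) {
  cat("<chain_configuration> chain", x$chain_label, "with",
      nrow(x$positions), "beads, residues", min(x$residue_ids), "-",
      max(x$residue_ids), "\n")
  invisible(x)
}

#' Number of beads in a configuration
#' @param conf a [chain_configuration()].
#' @return integer bead count.
#' @export
n_beads <- function(conf) nrow(conf$positions)

# Map residue ids to bead row indices; errors on missing ids.
residue_index <- function(conf, residue_ids, what = "residue") {
  idx <- match(as.integer(residue_ids), conf$residue_ids)
  if (anyNA(idx)) {
    stop(sprintf("unknown %s residue: %s", what,
                 paste(residue_ids[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Parse the Calpha trace of one chain from PDB text
#'
#' Reads the CA `ATOM` records of one chain from PDB-format text and returns
#' one bead per resolved residue, ordered by residue number, with
#' coordinates converted from Angstrom to reduced units (divided by 3.8).
#' When a residue carries alternate locations, the first CA record is kept
#' with a warning. The narrow fixed-column CA extraction is implemented
#' directly so the function can consume raw text streams and enforce these
#' contracts; full-featured PDB handling is out of scope.
#'
#' @param pdb_text character vector of PDB lines, a single string with
#'   embedded newlines, or a path to a PDB file.
#' @param chain_label chain identifier (column 22 of ATOM records).
#' @return a [chain_configuration()] in sigma units.
#' @export
parse_calpha_chain <- function(pdb_text, chain_label = "A") {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    pdb_text <- readLines(pdb_text, warn = FALSE)
  } else if (length(pdb_text) == 1) {
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  }
  rec <- substr(pdb_text, 1, 6)
  atom <- pdb_text[rec == "ATOM  " | rec == "ATOM"]
  name <- trimws(substr(atom, 13, 16))
  ca <- atom[name == "CA"]
  if (length(ca) == 0) stop("empty chain: no CA ATOM records found")
  ch <- substr(ca, 22, 22)
  sel <- ca[ch == chain_label]
  if (length(sel) == 0) {
    stop(sprintf("chain not found: no CA atoms for chain '%s'", chain_label))
  }
  resseq <- as.integer(substr(sel, 23, 26))
  dup <- duplicated(resseq)
  if (any(dup)) {
    warning(sprintf("duplicate CA records for residue(s) %s; keeping first altloc",
                    paste(unique(resseq[dup]), collapse = ", ")))
    sel <- sel[!dup]
    resseq <- resseq[!dup]
  }
  xyz <- cbind(as.numeric(substr(sel, 31, 38)),
               as.numeric(substr(sel, 39, 46)),
               as.numeric(substr(sel, 47, 54)))
  ord <- order(resseq)
  chain_configuration(xyz[ord, , drop = FALSE] / 3.8, resseq[ord], chain_label)
}

#' Generate a random stretched initial configuration
#'
#' Beads are placed along a uniformly random direction at unit (sigma)
#' spacing, perturbed transversally with Gaussian noise, then relaxed by a
#' few steepest-descent steps on the bonded FENE + WCA pair terms so the
#' chain starts strain-free. The end-to-end distance stays close to
#' `(N - 1) * sigma`, i.e. essentially fully stretched. The same seed gives
#' a bitwise-identical configuration.
#'
#' @param n number of beads (>= 4).
#' @param seed integer seed.
#' @param spacing initial bond length in sigma units.
#' @param noise_sd transverse Gaussian perturbation (sigma units).
#' @param relax_steps steepest-descent iterations on the bonded terms.
#' @param params [model_parameters()] supplying the FENE constants.
#' @return a [chain_configuration()].
#' @export
generate_stretched_configuration <- function(n, seed, spacing = 1.0,
                                             noise_sd = 0.05,
                                             relax_steps = 300,
                                             params = model_parameters()) {
  if (n < 4) stop("n must be >= 4")
  pos <- with_seed(seed, {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    base <- outer((seq_len(n) - 1) * spacing, u)
    noise <- matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    # keep the perturbation transverse to the stretching axis
    noise <- noise - outer(drop(noise %*% u), u)
    base + noise
  })
  pos <- relax_bonded(pos, params, relax_steps)
  chain_configuration(pos)
}

# Steepest descent on the bonded pair terms only (FENE attraction plus WCA
# repulsion between consecutive beads), enough to remove the strain left by
# the random placement without collapsing the stretched geometry.
relax_bonded <- function(pos, params, steps, step_size = 4e-4) {
  n <- nrow(pos)
  k <- params$k_fene
  R0 <- params$R0
  eps <- params$epsilon
  sig <- params$sigma
  for (s in seq_len(steps)) {
    d <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
    r2 <- rowSums(d^2)
    fene_fac <- -k / (1 - r2 / R0^2)              # dU/dr / r with sign
    sr2 <- sig^2 / r2
    sr6 <- sr2^3
    wca_fac <- ifelse(r2 < 2^(1 / 3) * sig^2,
                      24 * eps * (2 * sr6^2 - sr6) / r2, 0)
    fac <- fene_fac + wca_fac                     # force on bead i+1 along +d
    fb <- d * fac
    f <- matrix(0, n, 3)
    f[-1, ] <- f[-1, ] + fb
    f[-n, ] <- f[-n, ] - fb
    pos <- pos + step_size * f
  }
  pos
}

#' Rebuild Cartesian coordinates from internal coordinates
#'
#' Inverse of [extract_reference_geometry()]: given bond lengths, bending
#' angles and torsion angles (in the conventions of this package: interior
#' bending angle in `[0, pi]`, signed dihedral in `(-pi, pi]`), constructs a
#' chain by sequential placement. The result reproduces the original chain
#' up to a rigid-body motion.
#'
#' @param bond_lengths numeric vector, length N - 1.
#' @param theta0 bending angles, length N - 2.
#' @param phi0 torsion angles, length N - 3.
#' @return a [chain_configuration()].
#' @export
build_chain_from_internal <- function(bond_lengths, theta0, phi0) {
  n <- length(bond_lengths) + 1
  if (length(theta0) != n - 2 || length(phi0) != n - 3) {
    stop("inconsistent internal coordinate lengths")
  }
  pos <- matrix(0, n, 3)
  pos[2, ] <- c(bond_lengths[1], 0, 0)
  ang <- pi - theta0[1]
  pos[3, ] <- pos[2, ] + bond_lengths[2] * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n - 3)) {
    a <- pos[i, ]
    b <- pos[i + 1, ]
    c_ <- pos[i + 2, ]
    bc <- c_ - b
    bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nrm <- pracma_cross(ab, bc)
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- pracma_cross(nrm, bc)
    th <- theta0[i + 1]
    ph <- phi0[i]
    l <- bond_lengths[i + 2]
    d_local <- l * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
    pos[i + 3, ] <- c_ + cbind(bc, m, nrm) %*% d_local
  }
  chain_configuration(pos)
}

# small cross product helper (avoid importing pracma for this)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' End-to-end distance of a configuration
#' @param conf a [chain_configuration()].
#' @return numeric distance in sigma units.
#' @export
end_to_end_distance <- function(conf) {
  p <- conf$positions
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}
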