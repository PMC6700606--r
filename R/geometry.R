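# Reference geometry extraction and rigid-body superposition.

#' Bending and torsion angles of a chain
#'
#' Bending angle i is the interior angle at bead i + 1 between the two bond
#' vectors meeting there (collinear beads give theta = pi). Torsion angle i
#' is the right-handed signed dihedral of beads i..i+3 in `(-pi, pi]`.
#' Degenerate dihedrals (collinear quadruplets) are `NA`.
#'
#' @param conf a [chain_configuration()] or N x 3 matrix.
#' @return list with components `theta` (length N - 2) and `phi` (N - 3).
#' @export
chain_angles <- function(conf) {
  pos <- if (inherits(conf, "chain_configuration")) conf$positions else conf
  chain_angles_cpp(pos)
}

#' Extract the reference geometry of a native structure
#'
#' Computes the native bending and torsion angles, bond lengths and
#' disulfide-bridge pair distances that parameterize the structure-based
#' potentials. Bridge pairs are addressed by PDB residue number, not by
#' array position, so selections survive unresolved residues.
#'
#' @param conf native [chain_configuration()].
#' @param bridge_pairs list of length-2 integer vectors (residue ids), or a
#'   2-column matrix, or `NULL` for no bridges.
#' @return an object of class `reference_geometry` with fields `theta0`,
#'   `phi0`, `bond_lengths`, `bridge_pairs`, `bridge_idx`,
#'   `bridge_ref_dist`.
#' @export
extract_reference_geometry <- function(conf, bridge_pairs = NULL) {
  if (n_beads(conf) < 4) stop("need at least 4 beads")
  ang <- chain_angles(conf)
  if (anyNA(ang$phi)) {
    stop(sprintf("degenerate dihedral at quadruplet(s) %s (collinear beads)",
                 paste(which(is.na(ang$phi)), collapse = ", ")))
  }
  p <- conf$positions
  n <- nrow(p)
  bl <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  if (!is.null(bridge_pairs)) {
    if (is.matrix(bridge_pairs)) {
      bridge_pairs <- lapply(seq_len(nrow(bridge_pairs)),
                             function(i) bridge_pairs[i, ])
    }
    idx <- t(vapply(bridge_pairs, function(pr) {
      if (length(pr) != 2 || pr[1] == pr[2]) {
        stop("each bridge pair must name two distinct residues")
      }
      residue_index(conf, pr, what = "bridge")
    }, integer(2)))
    bdist <- sqrt(rowSums((p[idx[, 1], , drop = FALSE] -
                             p[idx[, 2], , drop = FALSE])^2))
  } else {
    idx <- matrix(integer(0), 0, 2)
    bdist <- numeric(0)
  }
  structure(list(theta0 = ang$theta, phi0 = ang$phi, bond_lengths = bl,
                 bridge_pairs = bridge_pairs %||% list(),
                 bridge_idx = idx, bridge_ref_dist = bdist),
            class = "reference_geometry")
}

#' @export
print.reference_geometry <- function(x, ...) {
  cat("<reference_geometry>", length(x$bond_lengths) + 1, "beads,",
      nrow(x$bridge_idx), "bridge pair(s); mean bond length",
      round(mean(x$bond_lengths), 3), "sigma\n")
  invisible(x)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Rotates and translates `P` onto `Q` minimizing the RMSD, with the proper
#' rotation enforced (no reflection).
#'
#' @param P,Q N x 3 coordinate matrices.
#' @return the transformed copy of `P`.
#' @export
superpose_onto <- function(P, Q) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P0 %*% t(R), 2, cq, "+")
}
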