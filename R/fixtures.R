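# Deterministic synthetic test systems: mini-lasso structures, linked
# curve pairs, and piecewise observable traces.

# Densify a piecewise-linear path at a fine arc-length step.
densify_polyline <- function(waypoints, step = 0.02) {
  out <- waypoints[1, , drop = FALSE]
  for (k in 2:nrow(waypoints)) {
    seg <- waypoints[k, ] - waypoints[k - 1, ]
    len <- sqrt(sum(seg^2))
    m <- max(1, ceiling(len / step))
    frac <- seq_len(m) / m
    out <- rbind(out, matrix(waypoints[k - 1, ], m, 3, byrow = TRUE) +
                   outer(frac, seg))
  }
  out
}

# Superimpose a gentle helical displacement (perpendicular to the local
# tangent, amplitude ramped in from zero at the start) on a dense path:
# its curvature is nonzero everywhere, which keeps the bending angles of
# the resampled chain away from the collinear limit.
wiggle_path <- function(fine, amp = 0.18, omega = 1.4, ramp = 1.5) {
  n <- nrow(fine)
  s <- c(0, cumsum(sqrt(rowSums(diff(fine)^2))))
  tang <- rbind(fine[2, ] - fine[1, ],
                (fine[-(1:2), , drop = FALSE] -
                   fine[-((n - 1):n), , drop = FALSE]) / 2,
                fine[n, ] - fine[n - 1, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  out <- fine
  for (i in seq_len(n)) {
    t_i <- tang[i, ]
    n1 <- c(0, 1, 0) - sum(c(0, 1, 0) * t_i) * t_i
    if (sqrt(sum(n1^2)) < 0.3) n1 <- c(1, 0, 0) - sum(c(1, 0, 0) * t_i) * t_i
    n1 <- n1 / sqrt(sum(n1^2))
    n2 <- pracma_cross(t_i, n1)
    a <- amp * min(1, s[i] / ramp)
    out[i, ] <- fine[i, ] + a * (cos(omega * s[i]) * n1 +
                                   sin(omega * s[i]) * n2)
  }
  out
}

# Greedy Euclidean resampling: walk along a dense path placing a bead as
# soon as the distance from the previous bead reaches `spacing`, so bond
# lengths are uniform regardless of path corners.
resample_euclidean <- function(fine, spacing, n) {
  beads <- matrix(NA_real_, n, 3)
  last <- fine[1, ]
  got <- 0
  for (i in 2:nrow(fine)) {
    if (sqrt(sum((fine[i, ] - last)^2)) >= spacing) {
      got <- got + 1
      beads[got, ] <- fine[i, ]
      last <- fine[i, ]
      if (got == n) return(beads)
    }
  }
  stop("infeasible geometry: path too short for requested bead count")
}

#' Generate a synthetic mini-lasso reference structure
#'
#' Builds a desk-scale stand-in for a complex-lasso protein: a planar
#' near-circular covalent loop whose two ends (the "cysteine" bridge pair)
#' sit 1.2 sigma apart, continued by a tail that threads the loop once
#' (class L1) or twice in opposite directions through a hairpin (class
#' L2). Bead spacing is 1 sigma; a small seeded jitter breaks exact
#' collinearity so all dihedrals are defined, and the generated chain is
#' verified clash-free (non-bonded pairs > 0.9 sigma). The returned
#' topology spec selects 5 loop and 3 (L1) or 5 (L2) tail residues and
#' carries the native piercing signature computed from the generated
#' geometry. Deterministic under `(params, seed)`.
#'
#' @param n_loop loop bead count (>= 8).
#' @param n_tail tail bead count (>= 4; >= 8 for L2).
#' @param lasso_class "L1" or "L2".
#' @param spacing bead spacing in sigma units.
#' @param seed integer seed for the jitter.
#' @param jitter_sd Gaussian jitter amplitude (sigma units).
#' @return list with `conf` (chain, loop beads first, then tail), `ref`
#'   (reference geometry with the bridge pair), `spec` (topology spec),
#'   `bridge_pair` (residue ids).
#' @export
make_mini_lasso <- function(n_loop = 12, n_tail = 10, lasso_class = c("L2", "L1"),
                            spacing = 1.0, seed = 1, jitter_sd = 0.02) {
  lasso_class <- match.arg(lasso_class)
  if (n_loop < 8) stop("n_loop must be >= 8")
  if (n_tail < 4) stop("n_tail must be >= 4")
  if (lasso_class == "L2" && n_tail < 8) stop("L2 needs n_tail >= 8")
  gap <- 1.2 * spacing
  # circle radius such that n_loop - 1 unit chords plus one gap chord
  # close the circle
  radius <- stats::uniroot(function(R) {
    (n_loop - 1) * 2 * asin(spacing / (2 * R)) + 2 * asin(gap / (2 * R)) -
      2 * pi
  }, c(n_loop * spacing / (2 * pi) * 0.8, n_loop * spacing))$root
  dth <- 2 * asin(spacing / (2 * radius))
  thg <- 2 * asin(gap / (2 * radius))
  ang <- thg / 2 + (seq_len(n_loop) - 1) * dth
  loop <- cbind(radius * cos(ang), radius * sin(ang), 0)
  attach_pt <- loop[n_loop, ]                 # tail continues from here
  if (lasso_class == "L1") {
    waypoints <- rbind(attach_pt,
                       c(0.6 * attach_pt[1], 0.6 * attach_pt[2], -1.2),
                       c(0, 0, -1.2),
                       c(0, 0, n_tail + 3))
  } else {
    waypoints <- rbind(attach_pt,
                       c(0.6 * attach_pt[1], 0.6 * attach_pt[2], -1.2),
                       c(0.55, 0, -1.2),
                       c(0.55, 0, 1.8),
                       c(0, 0, 2.45),
                       c(-0.55, 0, 1.8),
                       c(-0.55, 0, -(n_tail + 3)))
  }
  fine <- wiggle_path(densify_polyline(waypoints))
  tail <- resample_euclidean(fine, spacing, n_tail)
  pos <- rbind(loop, tail)
  pos <- pos + with_seed(seed, {
    matrix(stats::rnorm(length(pos), sd = jitter_sd), nrow(pos), 3)
  })
  # clash and bond-range checks
  d <- as.matrix(stats::dist(pos))
  nb <- upper.tri(d) & (col(d) - row(d)) > 1
  if (min(d[nb]) <= 0.9 * spacing) {
    stop("infeasible geometry: steric clash in generated structure")
  }
  bl <- sqrt(rowSums(diff(pos)^2))
  if (any(bl < 0.8 * spacing | bl > 1.3 * spacing)) {
    stop("infeasible geometry: bond length outside the FENE working range")
  }
  conf <- chain_configuration(pos)
  bridge_pair <- c(1L, n_loop)
  ref <- extract_reference_geometry(conf, list(bridge_pair))

  loop_sel <- unique(round(seq(1, n_loop, length.out = 5)))
  tail_ids <- n_loop + seq_len(n_tail)
  z <- pos[tail_ids, 3]
  if (lasso_class == "L1") {
    pick <- function(ztarget) tail_ids[which.min(abs(z - ztarget))]
    tail_sel <- unique(c(pick(-1), pick(0.6), pick(1.8)))
    split <- NULL
  } else {
    apex <- which.max(z)
    up <- seq_len(apex)                        # ascending strand
    down <- seq(apex, n_tail)
    pick_in <- function(idx, ztarget) {
      tail_ids[idx[which.min(abs(z[idx] - ztarget))]]
    }
    tail_sel <- c(pick_in(up, -0.8), pick_in(up, 1.0), tail_ids[apex],
                  pick_in(down, 1.0), pick_in(down, -0.8))
    tail_sel <- tail_sel[!duplicated(tail_sel)]
    split <- which(tail_sel == tail_ids[apex])
  }
  # switch width scaled to this structure's geometric margins (~0.5-1
  # sigma at desk scale, versus ~1-2 sigma for a full-size protein loop),
  # keeping the same margin-to-width ratio as the 0.2-sigma default
  spec <- topology_spec(conf$residue_ids[loop_sel], tail_sel,
                        tail_split_index = split, switch_width = 0.1)
  spec$native_signature <- native_piercing_signature(conf, spec)
  if (length(spec$native_signature) == 0) {
    stop("infeasible geometry: generated structure has no piercing")
  }
  list(conf = conf, ref = ref, spec = spec, bridge_pair = bridge_pair,
       lasso_class = lasso_class)
}

#' Generate a Hopf-link test pair
#'
#' Two planar circles discretized as closed polylines: interlocked (a Hopf
#' link, |G| = 1) when the center separation is below the radius sum and
#' the planes are perpendicular, unlinked when pulled far apart.
#'
#' @param radius circle radius.
#' @param separation distance between the circle centers along x.
#' @param n_vertices vertices per circle (>= 8).
#' @return list of two (n_vertices + 1) x 3 closed polylines.
#' @export
make_hopf_pair <- function(radius = 1, separation = 1, n_vertices = 64) {
  if (n_vertices < 8) stop("n_vertices must be >= 8")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)
  c1 <- cbind(radius * cos(th), radius * sin(th), 0)
  c2 <- cbind(separation + radius * cos(th), 0, radius * sin(th))
  list(c1, c2)
}

#' Construct synthetic observable traces
#'
#' Builds a trace-only trajectory record from piecewise descriptions of
#' the observables, for analyzer unit tests. Each observable is given as
#' a data.frame with columns `t0`, `t1`, `v0` and optionally `v1`
#' (linear ramp; constant when absent). Segments must tile `[0,
#' tau_run]` without overlap.
#'
#' @param pieces named list of piecewise data.frames (e.g. `d_b1`, `L`,
#'   `F`).
#' @param tau_run total trace length (tau_MD).
#' @param dt_sample sampling interval.
#' @return a `trajectory_record` carrying only `sample_times` and
#'   `traces`.
#' @export
make_trace <- function(pieces, tau_run, dt_sample = 1) {
  if (length(pieces) == 0) stop("empty trace specification")
  times <- seq(0, tau_run, by = dt_sample)
  traces <- data.frame(time = times)
  for (nm in names(pieces)) {
    df <- pieces[[nm]]
    ord <- order(df$t0)
    df <- df[ord, , drop = FALSE]
    if (df$t0[1] > 0 || df$t1[nrow(df)] < tau_run) {
      stop(sprintf("trace '%s' does not cover [0, tau_run]", nm))
    }
    if (nrow(df) > 1 && any(df$t0[-1] < df$t1[-nrow(df)] - 1e-9)) {
      stop(sprintf("overlapping segments in trace '%s'", nm))
    }
    vals <- vapply(times, function(t) {
      k <- max(which(df$t0 <= t + 1e-9))
      v1 <- if (!is.null(df$v1)) df$v1[k] else df$v0[k]
      span <- df$t1[k] - df$t0[k]
      frac <- if (span > 0) min(1, max(0, (t - df$t0[k]) / span)) else 0
      df$v0[k] + frac * (v1 - df$v0[k])
    }, numeric(1))
    traces[[nm]] <- vals
  }
  structure(list(sample_times = times, frames = NULL, traces = traces,
                 seed = NA_integer_, run_length = tau_run,
                 diverged_step = NA_integer_),
            class = "trajectory_record")
}
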