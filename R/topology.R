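# Reduced-structure complex-lasso descriptors: lasso variable L and the
# open-curve Gauss linking number G.

#' Topology specification for a complex lasso
#'
#' Describes the reduced structure used by the topological descriptors: an
#' ordered selection of loop residues whose first and last entries are the
#' bridge-forming cysteines (the loop surface is fan-triangulated over
#' them), an ordered selection of threading-tail residues, an optional
#' split position assigning opposite integration orientations to the two
#' tail halves (needed for lassos whose tail pierces the loop twice in
#' opposite directions), and the native piercing signature: the list of
#' (tail part, crossing direction) events that define the native topology.
#'
#' @param loop_residues ordered residue ids, length >= 3; first and last
#'   must be the bridge cysteines.
#' @param tail_residues ordered residue ids, length >= 2, disjoint from the
#'   loop selection.
#' @param tail_split_index position in `tail_residues` separating the two
#'   oppositely-oriented tail parts (`NULL` for a single part).
#' @param native_signature list of `list(part =, dir =)` events; computed
#'   from a native structure with [native_piercing_signature()] if omitted
#'   at construction.
#' @param switch_width Fermi width of the geometric switches (sigma units).
#' @return object of class `topology_spec`.
#' @export
topology_spec <- function(loop_residues, tail_residues,
                          tail_split_index = NULL, native_signature = NULL,
                          switch_width = 0.2) {
  loop_residues <- as.integer(loop_residues)
  tail_residues <- as.integer(tail_residues)
  if (length(loop_residues) < 3) stop("need at least 3 loop residues")
  if (length(tail_residues) < 2) stop("need at least 2 tail residues")
  if (length(intersect(loop_residues, tail_residues)) > 0) {
    stop("loop and tail residue sets must be disjoint")
  }
  if (!is.null(tail_split_index)) {
    tail_split_index <- as.integer(tail_split_index)
    if (tail_split_index < 2 || tail_split_index > length(tail_residues) - 1) {
      stop("tail_split_index must be interior to the tail selection")
    }
  }
  structure(list(loop_residues = loop_residues,
                 tail_residues = tail_residues,
                 tail_split_index = tail_split_index,
                 native_signature = native_signature,
                 switch_width = switch_width),
            class = "topology_spec")
}

#' Reduce a configuration to its loop and tail polylines
#'
#' Selects the loop and tail residues of a [topology_spec()] from a
#' configuration and returns ordered 3-D polylines in sigma units, plus the
#' fan triangulation of the loop: `M_l - 2` triangles sharing the first
#' loop vertex, oriented by the loop traversal from the first bridge
#' cysteine to the second.
#'
#' @param conf a [chain_configuration()].
#' @param spec a [topology_spec()].
#' @return list with `loop` (M_l x 3), `tails` (list of polylines; two
#'   entries when the tail is split, sharing the split vertex) and
#'   `triangles` ((M_l - 2) x 3 vertex-index matrix into `loop`).
#' @export
reduce_structure <- function(conf, spec) {
  li <- residue_index(conf, spec$loop_residues, "loop")
  ti <- residue_index(conf, spec$tail_residues, "tail")
  loop <- conf$positions[li, , drop = FALSE]
  tail_all <- conf$positions[ti, , drop = FALSE]
  tails <- if (is.null(spec$tail_split_index)) {
    list(tail_all)
  } else {
    s <- spec$tail_split_index
    list(tail_all[1:s, , drop = FALSE],
         tail_all[s:nrow(tail_all), , drop = FALSE])
  }
  ml <- nrow(loop)
  triangles <- cbind(1L, 2:(ml - 1L), 3:ml)
  list(loop = loop, tails = tails, triangles = triangles)
}

#' Signed and soft crossing of a segment through a triangle
#'
#' Determines whether the open segment `p0 -> p1` pierces the triangle
#' interior, with sign +1 when the segment runs along the triangle normal
#' (fixed by the vertex order) and -1 against it. The accompanying soft
#' scores replace the sharp test by products of Fermi switches of width `w`
#' on the geometric margins: the signed distances of the two segment
#' endpoints from the triangle plane (how decisively the segment straddles
#' it) and the in-plane signed distances of the intersection point from
#' the three edges (how far inside the triangle it pierces). `soft_up` and
#' `soft_down` score the two crossing directions; `soft` is their maximum.
#' In the sharp limit `w -> 0` the soft scores reproduce the hard sign.
#'
#' @param p0,p1 segment endpoints (length-3 numerics).
#' @param triangle 3 x 3 matrix of vertex coordinates (rows).
#' @param w Fermi switch width in sigma units.
#' @return list with `sign` (-1, 0, +1), `soft`, `soft_up`, `soft_down`.
#' @export
segment_triangle_crossing <- function(p0, p1, triangle, w = 0.2) {
  cm <- crossing_margins(p0, p1, triangle)
  if (cm$degenerate) {
    warning("degenerate (zero-area) triangle")
    return(list(sign = 0L, soft = 0, soft_up = 0, soft_down = 0))
  }
  edges <- prod(fermi(cm$d, w))
  soft_up <- fermi(-cm$s0, w) * fermi(cm$s1, w) * edges
  soft_down <- fermi(cm$s0, w) * fermi(-cm$s1, w) * edges
  list(sign = cm$hard, soft = max(soft_up, soft_down),
       soft_up = soft_up, soft_down = soft_down)
}

# Shared crossing geometry: signed plane distances of the endpoints, the
# (clamped) intersection parameter, in-plane edge margins of the piercing
# point (positive inside the triangle) and the hard signed crossing.
crossing_margins <- function(p0, p1, triangle) {
  v1 <- triangle[1, ]
  v2 <- triangle[2, ]
  v3 <- triangle[3, ]
  nvec <- pracma_cross(v2 - v1, v3 - v1)
  a2 <- sqrt(sum(nvec^2))
  if (a2 < 1e-10) return(list(degenerate = TRUE))
  nhat <- nvec / a2
  s0 <- sum(nhat * (p0 - v1))
  s1 <- sum(nhat * (p1 - v1))
  t_un <- if (abs(s0 - s1) > 1e-12) s0 / (s0 - s1) else 0.5
  q <- p0 + max(0, min(1, t_un)) * (p1 - p0)
  q <- q - sum(nhat * (q - v1)) * nhat            # project into the plane
  edge_margin <- function(a, b) {
    e <- b - a
    m <- pracma_cross(nhat, e)
    m <- m / sqrt(sum(m^2))
    sum(m * (q - a))                              # positive inside
  }
  d <- c(edge_margin(v1, v2), edge_margin(v2, v3), edge_margin(v3, v1))
  hard <- if (s0 * s1 < 0 && t_un > 0 && t_un < 1 && all(d > 0)) {
    if (s1 > s0) 1L else -1L
  } else 0L
  list(degenerate = FALSE, s0 = s0, s1 = s1, t = t_un, d = d, hard = hard,
       nhat = nhat)
}

# All hard piercing events of the reduced tail parts through the loop
# surface: data.frame(part, segment, triangle, dir).
hard_piercings <- function(red, w = 0.2) {
  out <- list()
  tri_list <- lapply(seq_len(nrow(red$triangles)), function(k) {
    red$loop[red$triangles[k, ], , drop = FALSE]
  })
  for (p in seq_along(red$tails)) {
    tp <- red$tails[[p]]
    for (s in seq_len(nrow(tp) - 1)) {
      for (k in seq_along(tri_list)) {
        cr <- suppressWarnings(
          segment_triangle_crossing(tp[s, ], tp[s + 1, ], tri_list[[k]], w))
        if (cr$sign != 0) {
          out[[length(out) + 1]] <- data.frame(part = p, segment = s,
                                               triangle = k, dir = cr$sign)
        }
      }
    }
  }
  if (length(out) == 0) {
    data.frame(part = integer(0), segment = integer(0),
               triangle = integer(0), dir = integer(0))
  } else {
    do.call(rbind, out)
  }
}

#' Native piercing signature of a structure
#'
#' Runs the hard crossing detection on a (native) configuration and
#' returns the per-tail-part piercing events as a signature usable in a
#' [topology_spec()]. Multiple crossings of one part through different
#' fan triangles in the same direction count as a single event (the fan
#' triangles tile one surface).
#'
#' @param conf native [chain_configuration()].
#' @param spec a [topology_spec()] (its `native_signature` is ignored).
#' @return list of `list(part =, dir =)` events.
#' @export
native_piercing_signature <- function(conf, spec) {
  red <- reduce_structure(conf, spec)
  hp <- hard_piercings(red, spec$switch_width)
  if (nrow(hp) == 0) return(list())
  key <- unique(hp[, c("part", "dir")])
  lapply(seq_len(nrow(key)), function(i) {
    list(part = key$part[i], dir = key$dir[i])
  })
}

#' Continuous lasso variable L
#'
#' Scores how completely a configuration realizes the native complex-lasso
#' topology, from 0 (non-native) to 1 (native). For every event of the
#' native signature (a required piercing of the triangulated loop surface
#' by a tail part, in a required direction), the best realization over the
#' part's segments and the loop triangles is scored as a product of Fermi
#' switches of width `w`: the in-plane margins of the piercing point
#' inside the triangle, and the reach of the tail part beyond each side of
#' the triangle plane (the entry side before the piercing segment, the
#' exit side after it), which measures that the tail genuinely passes
#' through rather than merely touching. L is the product of the event
#' scores; surplus non-native crossings do not reduce it.
#'
#' @param conf a [chain_configuration()].
#' @param spec a [topology_spec()] with a non-empty `native_signature`.
#' @return L in `[0, 1]`.
#' @export
lasso_variable <- function(conf, spec) {
  sig <- spec$native_signature
  if (is.null(sig) || length(sig) == 0) {
    stop("topology spec has no native signature")
  }
  red <- reduce_structure(conf, spec)
  w <- spec$switch_width
  n_tri <- nrow(red$triangles)
  L <- 1
  for (ev in sig) {
    tp <- red$tails[[ev$part]]
    best <- 0
    for (k in seq_len(n_tri)) {
      tri <- red$loop[red$triangles[k, ], , drop = FALSE]
      nvec <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      a2 <- sqrt(sum(nvec^2))
      if (a2 < 1e-10) next
      nhat <- nvec / a2
      svals <- drop((tp - matrix(tri[1, ], nrow(tp), 3, byrow = TRUE)) %*%
                      nhat)
      # The fan triangles tile one loop surface, so only margins against
      # the loop rim matter for the switch: triangle k = (v1, v_{k+1},
      # v_{k+2}) contributes rim edge (v_{k+1}, v_{k+2}) always, plus
      # (v1, v_{k+1}) for the first and (v_{k+2}, v1) for the last
      # triangle. The interior (shared) edges gate which triangle owns
      # the crossing but are not switched on - a piercing near a shared
      # edge is not near the surface rim.
      rim <- c(k == 1, TRUE, k == n_tri)
      for (s in seq_len(nrow(tp) - 1)) {
        cm <- crossing_margins(tp[s, ], tp[s + 1, ], tri)
        if (cm$degenerate) next
        if (any(cm$d[!rim] < 0)) next        # crossing owned by a neighbor
        edges <- prod(fermi(cm$d[rim], w))
        reach_in <- max(-ev$dir * svals[1:s])
        reach_out <- max(ev$dir * svals[(s + 1):length(svals)])
        score <- edges * fermi(reach_in, w) * fermi(reach_out, w)
        if (score > best) best <- score
      }
    }
    L <- L * best
  }
  L
}

#' Gauss linking number of open polygonal curves
#'
#' Evaluates the Gauss double line integral between two polygonal curves
#' as the exact analytic sum over straight segment pairs. For closed
#' curves this is the integer linking number; for open curves it is a
#' real-valued entanglement descriptor. Several tail parts may be given;
#' each enters with its own orientation (+1 follows vertex order, -1
#' reverses it), so a double piercing in opposite spatial directions
#' contributes additively instead of cancelling.
#'
#' @param loop M x 3 vertex matrix (for lasso use, traversed from one
#'   bridge cysteine to the other).
#' @param tails a single K x 3 matrix or a list of such polylines.
#' @param orientations integer vector of +1 / -1 per tail part.
#' @return G (real).
#' @export
gauss_linking_number <- function(loop, tails, orientations = NULL) {
  if (is.matrix(tails)) tails <- list(tails)
  orientations <- orientations %||% rep(1, length(tails))
  if (length(orientations) != length(tails)) {
    stop("one orientation per tail part required")
  }
  G <- 0
  for (p in seq_along(tails)) {
    tp <- tails[[p]]
    if (orientations[p] < 0) tp <- tp[rev(seq_len(nrow(tp))), , drop = FALSE]
    G <- G + gauss_linking_cpp(loop, tp)
  }
  G
}

#' Gauss linking number of a configuration under a topology spec
#'
#' Reduces the configuration and integrates the loop polyline (ends at the
#' bridge cysteines, so G responds to the loop opening and closing)
#' against the tail part(s); when the tail is split, the second part is
#' integrated with reversed orientation.
#'
#' @param conf a [chain_configuration()].
#' @param spec a [topology_spec()].
#' @return G (real).
#' @export
lasso_gauss <- function(conf, spec) {
  red <- reduce_structure(conf, spec)
  ori <- if (length(red$tails) == 2) c(1, -1) else 1
  gauss_linking_number(red$loop, red$tails, ori)
}
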