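# Plain-text interchange: multi-frame XYZ, JSON reference geometry and
# force fields, CSV traces.

#' Write and read multi-frame XYZ
#'
#' Stores sampled configurations (or a single chain) in the standard XYZ
#' format, one frame per block, with the sample time in the comment line.
#' Coordinates are kept in sigma units.
#'
#' @param traj a `trajectory_record`, a [chain_configuration()], or an
#'   N x 3 matrix.
#' @param path output file.
#' @param element atom label to write (cosmetic).
#' @return `path`, invisibly (writer); list of frames plus times (reader).
#' @name xyz_io
NULL

#' @rdname xyz_io
#' @export
write_xyz <- function(traj, path, element = "CA") {
  frames <- if (inherits(traj, "trajectory_record")) {
    lapply(seq_len(dim(traj$frames)[3]), function(s) frame_positions(traj, s))
  } else if (inherits(traj, "chain_configuration")) {
    list(traj$positions)
  } else {
    list(as.matrix(traj))
  }
  times <- if (inherits(traj, "trajectory_record")) {
    traj$sample_times
  } else {
    0
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_along(frames)) {
    p <- frames[[s]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf("t= %.6g", times[s]), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", element,
                       p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' @rdname xyz_io
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  times <- numeric(0)
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    tm <- suppressWarnings(as.numeric(sub("^t=\\s*", "", lines[i + 1])))
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), n, 3)
    times <- c(times, if (is.na(tm)) length(frames) - 1 else tm)
    i <- i + 2 + n
  }
  list(frames = frames, times = times)
}

#' Write a Calpha-only PDB file
#'
#' Writes one CA ATOM record per bead (alanine placeholder residues),
#' converting coordinates from sigma units back to Angstrom. Useful for
#' exporting generated fixtures to structure viewers and parsers.
#'
#' @param conf a [chain_configuration()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(conf, path) {
  p <- conf$positions * 3.8
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(p)), substr(conf$chain_label, 1, 1), conf$residue_ids,
    p[, 1], p[, 2], p[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Reference geometry and force field JSON interchange
#'
#' @param ref a `reference_geometry`.
#' @param ff an [efm_forcefield()].
#' @param path file path.
#' @return the written path (writers) or the reconstructed object
#'   (readers).
#' @name json_io
NULL

#' @rdname json_io
#' @export
write_reference_json <- function(ref, path) {
  jsonlite::write_json(list(theta0 = ref$theta0, phi0 = ref$phi0,
                            bond_lengths = ref$bond_lengths,
                            bridges = ref$bridge_pairs,
                            bridge_ref_dist = ref$bridge_ref_dist),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname json_io
#' @export
read_reference_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bridges <- if (length(x$bridges)) {
    lapply(seq_len(nrow(as.matrix(x$bridges))), function(i) {
      as.integer(as.matrix(x$bridges)[i, ])
    })
  } else {
    list()
  }
  n <- length(x$bond_lengths) + 1
  structure(list(theta0 = x$theta0, phi0 = x$phi0,
                 bond_lengths = x$bond_lengths,
                 bridge_pairs = bridges,
                 bridge_idx = matrix(unlist(bridges), ncol = 2,
                                     byrow = TRUE),
                 bridge_ref_dist = x$bridge_ref_dist),
            class = "reference_geometry")
}

#' @rdname json_io
#' @export
write_forcefield_json <- function(ff, path) {
  jsonlite::write_json(list(n_beads = ff$n_beads, k_bend = ff$k_bend,
                            k1_tor = ff$k1_tor,
                            pairing = lapply(ff$pairing, as.integer)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname json_io
#' @export
read_forcefield_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ff <- efm_forcefield(x$n_beads, k_bend = x$k_bend, k1_tor = x$k1_tor)
  if (!is.null(x$pairing)) {
    ff$pairing <- lapply(x$pairing, as.integer)
    ff <- enforce_pairing(ff)
  }
  ff
}

#' Write trajectory traces as CSV
#'
#' @param traj a `trajectory_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traj, path) {
  utils::write.csv(traj$traces, path, row.names = FALSE)
  invisible(path)
}
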