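# Langevin dynamics driver and trajectory observables.

#' Model wrappers for the trajectory engine
#'
#' `efm_model()` bundles a reference geometry, an angular force field and
#' optional bridge parameters; `go_model()` wraps a Go force field. Both
#' can be handed to [run_trajectory()].
#'
#' @param ref [extract_reference_geometry()] output.
#' @param ff [efm_forcefield()].
#' @param bridges [bridge_parameters()] or `NULL` (reducing).
#' @param goff [build_go_forcefield()] object.
#' @return an energy/force provider for [run_trajectory()].
#' @name trajectory_models
NULL

#' @rdname trajectory_models
#' @export
efm_model <- function(ref, ff, bridges = NULL) {
  structure(list(type = "efm", ref = ref, ff = ff,
                 bridges = bridges %||% bridges_disabled()),
            class = "lf_model")
}

#' @rdname trajectory_models
#' @export
go_model <- function(goff) {
  structure(list(type = "go", goff = goff), class = "lf_model")
}

#' Energy and forces of a model at a configuration
#'
#' @param model an [efm_model()] or [go_model()].
#' @param conf a [chain_configuration()].
#' @param params [model_parameters()].
#' @return list with `energy`, `forces`, `components`.
#' @export
model_energy_forces <- function(model, conf, params = model_parameters()) {
  if (model$type == "efm") {
    efm_total_energy_forces(conf, model$ref, model$ff, params, model$bridges)
  } else {
    go_total_energy_forces(conf, model$goff, params)
  }
}

#' Minimize the energy of a configuration
#'
#' Adaptive-step steepest descent on the model energy, used to locate the
#' stationary structure nearest a reference (the native structure itself
#' is generally not an exact minimum: FENE + WCA bonds equilibrate at
#' 0.961 sigma while native bonds sit near 1.0 sigma).
#'
#' @param model an [efm_model()] or [go_model()].
#' @param conf starting [chain_configuration()].
#' @param params [model_parameters()].
#' @param max_steps iteration cap.
#' @param force_tol convergence threshold on the maximum force component.
#' @return the minimized [chain_configuration()].
#' @export
minimize_energy <- function(model, conf, params = model_parameters(),
                            max_steps = 2000, force_tol = 1e-8) {
  n <- n_beads(conf)
  shape <- function(x) matrix(x, n, 3)
  fn <- function(x) {
    tryCatch(model_energy_forces(
      model, chain_configuration(shape(x), conf$residue_ids), params)$energy,
      error = function(e) 1e10)  # overstretched bond: finite penalty
  }
  gr <- function(x) {
    tryCatch(-as.vector(model_energy_forces(
      model, chain_configuration(shape(x), conf$residue_ids),
      params)$forces),
      error = function(e) rep(0, length(x)))
  }
  opt <- stats::optim(as.vector(conf$positions), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_steps, factr = 10))
  pos <- shape(opt$par)
  # polish with plain descent until the forces are tiny
  ev <- model_energy_forces(model, chain_configuration(pos, conf$residue_ids),
                            params)
  step <- 1e-4
  for (it in seq_len(2000)) {
    if (max(abs(ev$forces)) < force_tol) break
    cand <- pos + step * ev$forces
    ev2 <- tryCatch(
      model_energy_forces(model,
                          chain_configuration(cand, conf$residue_ids),
                          params),
      error = function(e) NULL)
    if (!is.null(ev2) && ev2$energy <= ev$energy) {
      pos <- cand
      ev <- ev2
      step <- min(step * 1.5, 0.01)
    } else {
      step <- step / 2
      if (step < 1e-15) break
    }
  }
  chain_configuration(pos, conf$residue_ids, conf$chain_label)
}

#' Run a Langevin dynamics trajectory
#'
#' Propagates a model with the BAOAB splitting of underdamped Langevin
#' dynamics at temperature T, friction gamma = mass / tau_frict, and time
#' step dt. Initial velocities are Maxwell-Boltzmann draws from the
#' trajectory seed; the same seed yields a bit-identical trajectory.
#' Frames are sampled every `sample_every` steps (1 tau_MD at the
#' defaults), observables are evaluated on each sampled frame, and the
#' record carries the potential-energy trace. Setting `tau_frict = Inf`
#' in `params` disables the thermostat (microcanonical limit).
#'
#' @param model an [efm_model()] or [go_model()].
#' @param conf0 initial [chain_configuration()].
#' @param params [model_parameters()].
#' @param n_steps number of integration steps.
#' @param seed integer seed.
#' @param sample_every sampling stride in steps (default 2000 = 1 tau_MD).
#' @param observers named list of functions `f(positions)` evaluated on
#'   each sampled N x 3 frame; their values become trace columns.
#' @param temperature run temperature; defaults to `params$temperature`.
#' @param allow_partial if `TRUE`, a diverging trajectory returns its valid
#'   prefix with a warning instead of an error.
#' @return object of class `trajectory_record`: `sample_times`, `frames`
#'   (3 x N x S array), `traces` (data.frame), `seed`, `run_length`,
#'   `diverged_step`.
#' @export
run_trajectory <- function(model, conf0, params = model_parameters(),
                           n_steps, seed, sample_every = 2000,
                           observers = list(), temperature = NULL,
                           allow_partial = FALSE) {
  stopifnot(inherits(model, "lf_model"))
  temperature <- temperature %||% params$temperature
  gamma <- if (is.finite(params$tau_frict)) params$mass / params$tau_frict else 0
  pos0 <- conf0$positions
  res <- if (model$type == "efm") {
    run_langevin_efm_cpp(pos0, unclass(model$ref), unclass(model$ff),
                         unclass(params), unclass(model$bridges),
                         params$dt, n_steps, sample_every, temperature,
                         gamma, params$mass, as.integer(seed))
  } else {
    run_langevin_go_cpp(pos0, unclass(model$goff), unclass(params),
                        params$dt, n_steps, sample_every, temperature,
                        gamma, params$mass, as.integer(seed))
  }
  if (res$diverged_step >= 0) {
    msg <- sprintf("integration diverged at step %d", res$diverged_step)
    if (!allow_partial) stop(msg)
    warning(paste(msg, "- returning valid prefix"))
  }
  frames <- res$frames
  n_samp <- dim(frames)[3]
  traces <- data.frame(time = res$times, energy = res$energies,
                       kinetic = res$kinetic)
  for (nm in names(observers)) {
    f <- observers[[nm]]
    traces[[nm]] <- vapply(seq_len(n_samp),
                           function(s) f(t(frames[, , s])), numeric(1))
  }
  structure(list(sample_times = res$times, frames = frames, traces = traces,
                 residue_ids = conf0$residue_ids, seed = as.integer(seed),
                 run_length = n_steps * params$dt,
                 diverged_step = if (res$diverged_step >= 0)
                   res$diverged_step else NA_integer_,
                 velocities = res$velocities),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat("<trajectory_record>", length(x$sample_times), "samples over",
      x$run_length, "tau_MD; traces:",
      paste(setdiff(names(x$traces), "time"), collapse = ", "), "\n")
  invisible(x)
}

# Positions of sample s as an N x 3 matrix.
frame_positions <- function(traj, s) t(traj$frames[, , s])

#' Standard trajectory observers
#'
#' Factories returning functions of an N x 3 frame, for use as
#' [run_trajectory()] observers: the mean-square displacement from a
#' native structure (`obs_msd`), the lasso variable (`obs_lasso`), the
#' Gauss linking number of the reduced loop/tail curves (`obs_gauss`) and
#' a pair distance such as the bridge cysteine separation
#' (`obs_pair_distance`).
#'
#' @param native native [chain_configuration()].
#' @param superpose superpose optimally before the MSD (default `TRUE`).
#' @param conf template [chain_configuration()] fixing the residue-id to
#'   bead mapping.
#' @param spec a [topology_spec()].
#' @param pair length-2 residue-id vector.
#' @return a function `f(positions) -> numeric(1)`.
#' @name observers
NULL

#' @rdname observers
#' @export
obs_msd <- function(native, superpose = TRUE) {
  ref <- native$positions
  function(pos) msd_positions(pos, ref, superpose)
}

#' @rdname observers
#' @export
obs_lasso <- function(conf, spec) {
  force(spec)
  ids <- conf$residue_ids
  function(pos) {
    lasso_variable(chain_configuration(pos, ids), spec)
  }
}

#' @rdname observers
#' @export
obs_gauss <- function(conf, spec) {
  force(spec)
  ids <- conf$residue_ids
  function(pos) {
    lasso_gauss(chain_configuration(pos, ids), spec)
  }
}

#' @rdname observers
#' @export
obs_pair_distance <- function(conf, pair) {
  idx <- residue_index(conf, pair, "pair")
  function(pos) sqrt(sum((pos[idx[1], ] - pos[idx[2], ])^2))
}
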