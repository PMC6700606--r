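# Success criterion, MSD, landscapes, transition times and pathway
# classification of folding trajectory ensembles.

#' Run an ensemble of folding trajectories with standard observables
#'
#' Launches `n_traj` Langevin folding trajectories of the elastic folder
#' model from fresh random stretched configurations (seeds derived from
#' `seed`), recording the MSD from the native structure (`F`), the lasso
#' variable (`L`), the Gauss linking number (`G`) and the first bridge
#' distance (`d_b1`) along each. A trajectory that diverges contributes
#' its valid prefix.
#'
#' @param system a list with `conf` (native), `ref`, `spec` and
#'   `bridge_pair`, as returned by [make_mini_lasso()] (or assembled from
#'   a parsed structure).
#' @param ff an [efm_forcefield()].
#' @param n_traj ensemble size.
#' @param tau_run trajectory length (tau_MD).
#' @param seed master seed.
#' @param oxidizing include the disulfide-bridge potential.
#' @param params [model_parameters()].
#' @param sample_every sampling stride in steps.
#' @return list of `trajectory_record`s.
#' @export
run_folding_ensemble <- function(system, ff, n_traj, tau_run, seed,
                                 oxidizing = FALSE,
                                 params = model_parameters(),
                                 sample_every = 2000) {
  bridges <- if (oxidizing) {
    bridge_parameters(system$ref, temperature = params$temperature)
  } else {
    NULL
  }
  model <- efm_model(system$ref, ff, bridges)
  n <- n_beads(system$conf)
  n_steps <- round(tau_run / params$dt)
  obs <- list(F = obs_msd(system$conf),
              L = obs_lasso(system$conf, system$spec),
              G = obs_gauss(system$conf, system$spec),
              d_b1 = obs_pair_distance(system$conf, system$bridge_pair))
  lapply(seq_len(n_traj), function(i) {
    conf0 <- generate_stretched_configuration(n, derive_seed(seed, 21, i),
                                              params = params)
    run_trajectory(model, conf0, params, n_steps,
                   derive_seed(seed, 23, i), sample_every = sample_every,
                   observers = obs, allow_partial = TRUE)
  })
}

msd_positions <- function(pos, ref, superpose = TRUE) {
  if (superpose) pos <- superpose_onto(pos, ref)
  mean(rowSums((pos - ref)^2))
}

#' Mean-square displacement from the native configuration
#'
#' `F = (1 / (N sigma^2)) * sum_i |r_i - r_i^0|^2`, by default after
#' optimal rigid-body superposition (trajectories start in random
#' orientations, and `sqrt(F)` is then the RMSD from the native
#' structure).
#'
#' @param conf a [chain_configuration()] or N x 3 matrix.
#' @param native the native configuration (same N).
#' @param superpose superpose before the displacement sum (default
#'   `TRUE`).
#' @return F (dimensionless).
#' @export
msd_from_native <- function(conf, native, superpose = TRUE) {
  pos <- if (inherits(conf, "chain_configuration")) conf$positions else conf
  ref <- if (inherits(native, "chain_configuration")) native$positions else native
  if (nrow(pos) != nrow(ref)) stop("configurations differ in length")
  msd_positions(pos, ref, superpose)
}

#' Fraction of native contacts Q
#'
#' @param conf a [chain_configuration()].
#' @param contacts data.frame with residue-id columns `i`, `j` and
#'   `r_native` (as produced by [build_go_forcefield()]).
#' @param factor a native pair counts as formed when its distance is below
#'   `factor * r_native` (default 1.2).
#' @return Q in `[0, 1]`.
#' @export
native_contact_fraction <- function(conf, contacts, factor = 1.2) {
  if (nrow(contacts) == 0) stop("empty contact list")
  i <- residue_index(conf, contacts$i, "contact")
  j <- residue_index(conf, contacts$j, "contact")
  p <- conf$positions
  r <- sqrt(rowSums((p[i, , drop = FALSE] - p[j, , drop = FALSE])^2))
  mean(r < factor * contacts$r_native)
}

#' Folded-state criterion
#'
#' A configuration counts as fully folded only when both the RMSD from the
#' native structure is below 0.9 (`sqrt(F) < 0.9`) and the lasso variable
#' exceeds 0.9, so that near-native geometry without the native topology
#' (or vice versa) is rejected.
#'
#' @param F mean-square displacement (not its square root).
#' @param L lasso variable.
#' @param f_threshold RMSD threshold (default 0.9).
#' @param l_threshold lasso threshold (default 0.9).
#' @return logical.
#' @export
is_folded <- function(F, L, f_threshold = 0.9, l_threshold = 0.9) {
  sqrt(F) < f_threshold & L > l_threshold
}

# First time from which `cond` holds continuously for `persistence` time
# units (and the window fits inside the sampled range); NA when never.
first_sustained <- function(times, cond, persistence) {
  cond[is.na(cond)] <- FALSE
  n <- length(times)
  if (n == 0) return(NA_real_)
  # suffix run length of TRUE starting at each index
  run <- integer(n)
  run[n] <- as.integer(cond[n])
  if (n > 1) {
    for (i in (n - 1):1) run[i] <- if (cond[i]) run[i + 1] + 1L else 0L
  }
  t_end <- times[n]
  for (i in seq_len(n)) {
    if (!cond[i]) next
    t_stop <- times[i] + persistence
    if (t_stop > t_end + 1e-9) return(NA_real_)
    j <- i + run[i] - 1L
    if (times[j] + 1e-9 >= t_stop) return(times[i])
  }
  NA_real_
}

#' Transition times of a folding trajectory
#'
#' Extracts the bridge formation time `t_b` (first sustained approach of
#' the bridge cysteines below `bridge_threshold`), the topology formation
#' time `t_k` (first sustained `L > 0.9`) and the folding time `t_f`
#' (first sustained visit of the native basin, [is_folded()]). Each
#' condition must hold continuously for `persistence` time units (default
#' 10 tau_MD) for the transition to count; a time is `NA` when its
#' condition is never sustained within the run.
#'
#' @param traj a `trajectory_record` whose traces include `d_b1`, `L` and
#'   `F`.
#' @param bridge_threshold closure threshold for `d_b1` (for a bridge of
#'   LJ length sigma_b1 the natural choice is `1.5 * sigma_b1`).
#' @param persistence persistence window (tau_MD).
#' @param f_threshold,l_threshold folded-basin thresholds.
#' @return list with elements `t_b`, `t_k`, `t_f` (`NA` when absent).
#' @export
transition_times <- function(traj, bridge_threshold, persistence = 10,
                             f_threshold = 0.9, l_threshold = 0.9) {
  tr <- traj$traces
  for (nm in c("d_b1", "L", "F")) {
    if (is.null(tr[[nm]])) stop(sprintf("missing trace '%s'", nm))
  }
  times <- tr$time
  if (length(times) > 1) {
    dt_samp <- stats::median(diff(times))
    if (dt_samp > persistence / 5 + 1e-9) {
      warning("sampling interval exceeds persistence/5; times may be coarse")
    }
  }
  list(t_b = first_sustained(times, tr$d_b1 < bridge_threshold, persistence),
       t_k = first_sustained(times, tr$L > l_threshold, persistence),
       t_f = first_sustained(times,
                             is_folded(tr$F, tr$L, f_threshold, l_threshold),
                             persistence))
}

#' Classify the folding pathway of a successful trajectory
#'
#' Distinguishes the three folding mechanisms of complex-lasso proteins by
#' the order of loop closure and topology formation: "open-loop" when the
#' lasso forms before the bridge contact (`t_k < t_b`, or no sustained
#' closure by `t_k`); otherwise "threading" when the bridge distance stays
#' below the reopening threshold throughout `[t_b, t_k]` (the tail pierces
#' the already-closed loop), and "reopening" when it exceeds the threshold
#' in that window (a wide fluctuation of the bridge lets the tail in).
#' The comparison uses `t_k` versus `t_b` only; `t_f` may precede `t_b`
#' inside the native basin without affecting the label.
#'
#' @param traj a `trajectory_record` with a `d_b1` trace.
#' @param times [transition_times()] of the trajectory (`t_f` required).
#' @param reopen_threshold bridge distance above which the loop counts as
#'   reopened (should exceed the closure threshold; default
#'   `2.0 * sigma_b1` passed by the caller).
#' @return one of "threading", "reopening", "open-loop", "unresolved".
#' @export
classify_pathway <- function(traj, times, reopen_threshold) {
  if (is.na(times$t_f)) stop("not a successful trajectory (t_f absent)")
  if (is.na(times$t_k)) return("unresolved")
  if (is.na(times$t_b) || times$t_k < times$t_b) return("open-loop")
  tr <- traj$traces
  win <- tr$time >= times$t_b - 1e-9 & tr$time <= times$t_k + 1e-9
  if (!any(win)) return("unresolved")
  if (any(tr$d_b1[win] > reopen_threshold)) "reopening" else "threading"
}

#' Analyze an ensemble of trajectories
#'
#' Computes the transition times, success flag and pathway label of every
#' trajectory in an ensemble.
#'
#' @param trajs list of `trajectory_record`s with `d_b1`, `L`, `F` traces.
#' @param bridge_threshold closure threshold (see [transition_times()]).
#' @param reopen_threshold reopening threshold (see [classify_pathway()]).
#' @param persistence persistence window (tau_MD).
#' @return data.frame with one row per trajectory: `t_b`, `t_k`, `t_f`,
#'   `success`, `label`.
#' @export
analyze_ensemble <- function(trajs, bridge_threshold, reopen_threshold,
                             persistence = 10) {
  rows <- lapply(trajs, function(tr) {
    tt <- transition_times(tr, bridge_threshold, persistence)
    success <- !is.na(tt$t_f)
    label <- if (success) {
      classify_pathway(tr, tt, reopen_threshold)
    } else {
      NA_character_
    }
    data.frame(t_b = tt$t_b, t_k = tt$t_k, t_f = tt$t_f,
               success = success, label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Folding probability and pathway distribution
#'
#' `P_f = n_f / n_tot` over the ensemble, and the per-mechanism
#' probabilities (class counts over the total), which sum exactly to
#' `P_f`.
#'
#' @param results data.frame from [analyze_ensemble()] (or a list of
#'   trajectories together with the threshold arguments of that
#'   function).
#' @param ... forwarded to [analyze_ensemble()] when `results` is a list.
#' @return list with `P_f`, `P_threading`, `P_reopening`, `P_open_loop`,
#'   `P_unresolved`, `n_total`.
#' @export
pathway_statistics <- function(results, ...) {
  if (!is.data.frame(results)) results <- analyze_ensemble(results, ...)
  n <- nrow(results)
  if (n == 0) stop("empty ensemble")
  frac <- function(lbl) sum(results$label == lbl, na.rm = TRUE) / n
  list(P_f = sum(results$success) / n,
       P_threading = frac("threading"),
       P_reopening = frac("reopening"),
       P_open_loop = frac("open-loop"),
       P_unresolved = frac("unresolved"),
       n_total = n)
}

#' Folding landscape F = -log f
#'
#' Pools the sampled values of two reaction variables over an ensemble of
#' trajectories, bins them in 2-D, normalizes the histogram to a
#' probability per bin and returns `F = -log f` with empty bins left
#' undefined (`NA`), without pseudo-counts. Restricting to the successful
#' trajectories (via `select`) gives the successful folding landscape
#' `F_s`.
#'
#' @param trajs list of `trajectory_record`s.
#' @param var_x,var_y trace column names.
#' @param bins number of bins per axis, or a list of two break vectors.
#' @param select optional logical vector choosing trajectories (e.g. the
#'   `success` column of [analyze_ensemble()]).
#' @return object of class `lf_landscape`: `x_breaks`, `y_breaks`,
#'   `counts`, `surface`, `n_samples`, axis names.
#' @export
folding_landscape <- function(trajs, var_x, var_y, bins = 40, select = NULL) {
  if (!is.null(select)) trajs <- trajs[select]
  if (length(trajs) == 0) stop("empty trajectory selection")
  xs <- unlist(lapply(trajs, function(tr) tr$traces[[var_x]]))
  ys <- unlist(lapply(trajs, function(tr) tr$traces[[var_y]]))
  if (is.null(xs) || is.null(ys)) stop("requested traces not found")
  if (is.list(bins)) {
    xb <- bins[[1]]
    yb <- bins[[2]]
  } else {
    xb <- seq(min(xs), max(xs), length.out = bins + 1)
    yb <- seq(min(ys), max(ys), length.out = bins + 1)
  }
  ix <- findInterval(xs, xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(ys, yb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(xb) - 1, length(yb) - 1)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  f <- counts / length(xs)
  surface <- ifelse(counts > 0, -log(f), NA_real_)
  structure(list(x_breaks = xb, y_breaks = yb, counts = counts,
                 surface = surface, n_samples = length(xs),
                 var_x = var_x, var_y = var_y),
            class = "lf_landscape")
}

#' @export
print.lf_landscape <- function(x, ...) {
  cat("<lf_landscape>", x$var_x, "x", x$var_y, "with", x$n_samples,
      "samples in", nrow(x$counts), "x", ncol(x$counts), "bins\n")
  invisible(x)
}
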