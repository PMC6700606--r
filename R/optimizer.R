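# Stochastic single-force-field optimization (SFFO) and its evolutionary
# population extension (MFFO): Metropolis tuning of the angular
# stiffnesses toward reproducible folding.

#' Optimizer configuration
#'
#' Parameters of the stochastic force-field search. The defaults are the
#' production-scale settings (16 test trajectories per mutation of length
#' 3.5e3 tau_MD, mutation SD 2.5, MSD threshold F0 = 0.9, Fermi width
#' w = 0.2, EMA smoothing alpha = 0.03 giving a 33-step decay time,
#' ranking every m = 50 steps, population 16 with 6 winners and 4 random
#' low-fit parents drawn uniformly in [30, 60]); pass smaller values for
#' desk-scale experiments.
#'
#' @param n_test folding test trajectories per mutation.
#' @param tau_run test trajectory length (tau_MD).
#' @param delta_k_sd mutation SD for the stiffness perturbation.
#' @param F0 MSD threshold of the folding-probability proxy.
#' @param w Fermi switching width of the proxy.
#' @param alpha EMA smoothing factor in (0, 1).
#' @param m_cycle SFFO steps per ranking cycle.
#' @param N_K population size.
#' @param N_win winners kept verbatim each cycle.
#' @param N_low randomly generated low-fit parents for the crossover.
#' @param k_rand_range uniform range for random parent coefficients.
#' @param k_floor positive lower bound for any stiffness.
#' @param sample_every trajectory sampling stride (steps).
#' @param temperature folding test temperature.
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(n_test = 16, tau_run = 3.5e3, delta_k_sd = 2.5,
                             F0 = 0.9, w = 0.2, alpha = 0.03, m_cycle = 50,
                             N_K = 16, N_win = 6, N_low = 4,
                             k_rand_range = c(30, 60), k_floor = 1.0,
                             sample_every = 2000, temperature = 0.1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (N_win > N_K) stop("N_win cannot exceed N_K")
  if (k_floor <= 0) stop("k_floor must be positive")
  structure(list(n_test = n_test, tau_run = tau_run, delta_k_sd = delta_k_sd,
                 F0 = F0, w = w, alpha = alpha, m_cycle = m_cycle,
                 N_K = N_K, N_win = N_win, N_low = N_low,
                 k_rand_range = k_rand_range, k_floor = k_floor,
                 sample_every = sample_every, temperature = temperature),
            class = "optimizer_config")
}

#' Folding reference system for the optimizer
#'
#' Bundles everything a folding test needs: the native configuration, its
#' reference geometry, the model parameters and (optionally) bridge
#' parameters for oxidizing-condition optimization.
#'
#' @param native native [chain_configuration()].
#' @param ref [extract_reference_geometry()] of the native structure.
#' @param params [model_parameters()].
#' @param bridges [bridge_parameters()] or `NULL` (reducing).
#' @return list of class `folding_reference`.
#' @export
folding_reference <- function(native, ref, params = model_parameters(),
                              bridges = NULL) {
  structure(list(native = native, ref = ref, params = params,
                 bridges = bridges), class = "folding_reference")
}

#' Mutate one constrained coefficient group of a force field
#'
#' Picks one pairing group uniformly at random and adds a single
#' Gaussian-distributed increment (SD `delta_k_sd`) to all of its members,
#' so paired coefficients stay exactly equal; the result is clipped at the
#' positive floor. The same seed reproduces the same mutation.
#'
#' @param ff an [efm_forcefield()].
#' @param config an [optimizer_config()].
#' @param seed integer seed.
#' @return the mutated force field.
#' @export
mutate_forcefield <- function(ff, config, seed) {
  with_seed(seed, {
    g <- ff$pairing[[sample.int(length(ff$pairing), 1)]]
    dk <- stats::rnorm(1, sd = config$delta_k_sd)
    k <- ff_to_vector(ff)
    k[g] <- pmax(config$k_floor, k[g] + dk)
    ff_from_vector(ff, k)
  })
}

# Folding-probability proxy of a set of minimum-MSD values: the mean Fermi
# switch on the threshold margin F0 - F.
pi_f_from_msd <- function(F_min, F0 = 0.9, w = 0.2) {
  mean(fermi(F0 - F_min, w))
}

#' Evaluate the folding propensity of a force field
#'
#' Runs `n_test` Langevin folding trajectories from fresh random stretched
#' configurations (derived seeds), each of length `tau_run`, records the
#' MSD trace from the native structure, and takes per trajectory
#' `F(tau_min)`, the minimum MSD attained along the run. Returns the mean
#' of those minima (the Metropolis objective) and the folding-probability
#' proxy `pi_f` (mean Fermi switch of `F0 - F(tau_min)` with width `w`).
#' A diverging trajectory contributes the minimum over its valid prefix,
#' with a warning.
#'
#' @param ff an [efm_forcefield()].
#' @param reference a [folding_reference()].
#' @param config an [optimizer_config()].
#' @param seed integer seed.
#' @return list with `mean_F`, `pi_f` and the per-trajectory `F_min`.
#' @export
evaluate_forcefield <- function(ff, reference, config, seed) {
  n <- n_beads(reference$native)
  params <- reference$params
  n_steps <- round(config$tau_run / params$dt)
  model <- efm_model(reference$ref, ff, reference$bridges)
  F_min <- vapply(seq_len(config$n_test), function(i) {
    s_conf <- derive_seed(seed, 11, i)
    s_traj <- derive_seed(seed, 13, i)
    conf0 <- generate_stretched_configuration(n, s_conf, params = params)
    traj <- run_trajectory(model, conf0, params, n_steps, s_traj,
                           sample_every = config$sample_every,
                           observers = list(
                             F = obs_msd(reference$native)),
                           temperature = config$temperature,
                           allow_partial = TRUE)
    min(traj$traces$F)
  }, numeric(1))
  list(mean_F = mean(F_min),
       pi_f = pi_f_from_msd(F_min, config$F0, config$w),
       F_min = F_min)
}

#' Metropolis acceptance of a mutated force field
#'
#' Accepts the mutation with probability
#' `min(1, exp(mean_F_old - mean_F_new))`: any improvement of the average
#' minimum MSD is always accepted, a worsening with exponentially
#' suppressed probability.
#'
#' @param mean_F_old,mean_F_new mean minimum-MSD of incumbent and mutant.
#' @param seed integer seed for the acceptance draw.
#' @return logical.
#' @export
metropolis_accept <- function(mean_F_old, mean_F_new, seed) {
  p <- min(1, exp(mean_F_old - mean_F_new))
  if (p >= 1) return(TRUE)
  with_seed(seed, stats::runif(1) < p)
}

#' Exponential moving average update
#'
#' `Pi <- alpha * pi_new + (1 - alpha) * Pi_prev`; at alpha = 0.03 the
#' weight decays with an e-folding time of 33 steps.
#'
#' @param Pi_prev previous smoothed value.
#' @param pi_new new observation.
#' @param alpha smoothing factor in (0, 1].
#' @return updated value.
#' @export
ema_update <- function(Pi_prev, pi_new, alpha) {
  alpha * pi_new + (1 - alpha) * Pi_prev
}

# One population entry: the force field, its stored evaluation, and the
# EMA of the folding proxy.
new_entry <- function(ff) {
  list(ff = ff, mean_F = NA_real_, Pi_f = NA_real_)
}

#' One SFFO step on a population entry
#'
#' Mutates the entry's force field, evaluates the mutant with `n_test`
#' folding trajectories, and accepts or rejects by the Metropolis rule
#' against the stored objective of the incumbent (measured when it was
#' last tested; no re-test). The folding proxy measured for the tested
#' mutant feeds the entry's EMA whether or not the mutation is accepted,
#' since a local mutation perturbs the folding propensity only weakly. An
#' entry without a stored objective (a fresh hybrid) is evaluated first.
#'
#' @param entry list with `ff`, `mean_F`, `Pi_f`.
#' @param reference a [folding_reference()].
#' @param config an [optimizer_config()].
#' @param seed integer seed.
#' @return the updated entry (plus `accepted` flag).
#' @export
sffo_step <- function(entry, reference, config, seed) {
  if (is.na(entry$mean_F)) {
    ev0 <- evaluate_forcefield(entry$ff, reference, config,
                               derive_seed(seed, 1))
    entry$mean_F <- ev0$mean_F
    if (is.na(entry$Pi_f)) entry$Pi_f <- ev0$pi_f
  }
  ff_new <- mutate_forcefield(entry$ff, config, derive_seed(seed, 2))
  ev <- evaluate_forcefield(ff_new, reference, config, derive_seed(seed, 3))
  accepted <- metropolis_accept(entry$mean_F, ev$mean_F, derive_seed(seed, 4))
  if (accepted) {
    entry$ff <- ff_new
    entry$mean_F <- ev$mean_F
  }
  entry$Pi_f <- if (is.na(entry$Pi_f)) {
    ev$pi_f
  } else {
    ema_update(entry$Pi_f, ev$pi_f, config$alpha)
  }
  entry$accepted <- accepted
  entry
}

#' Rank a population and rebuild it by crossover
#'
#' Sorts the entries by decreasing folding proxy `Pi_f` (ties broken by
#' entry index), keeps the `N_win` best verbatim, and rebuilds the
#' remaining `N_K - N_win` entries as hybrids: every constrained
#' coefficient group is copied from a uniformly chosen parent among the
#' winners plus `N_low` randomly generated force fields (coefficients
#' uniform in `k_rand_range`), which maintains diversity. Hybrids carry no
#' EMA history; their proxy restarts at the first value they measure.
#'
#' @param entries list of population entries (each with `Pi_f`).
#' @param config an [optimizer_config()].
#' @param seed integer seed.
#' @return list of `N_K` entries, winners first.
#' @export
rank_and_crossover <- function(entries, config, seed) {
  ord <- order(-vapply(entries, function(e) e$Pi_f, numeric(1)),
               seq_along(entries))
  winners <- entries[ord[seq_len(config$N_win)]]
  n_hyb <- config$N_K - config$N_win
  if (n_hyb == 0) return(winners)
  template <- winners[[1]]$ff
  parents <- lapply(winners, function(e) ff_to_vector(e$ff))
  with_seed(seed, {
    for (r in seq_len(config$N_low)) {
      kr <- stats::runif(length(ff_to_vector(template)),
                         config$k_rand_range[1], config$k_rand_range[2])
      ffr <- enforce_pairing(ff_from_vector(template, kr))
      parents[[length(parents) + 1]] <- ff_to_vector(ffr)
    }
    hybrids <- lapply(seq_len(n_hyb), function(h) {
      k <- ff_to_vector(template)
      for (g in template$pairing) {
        p <- sample.int(length(parents), 1)
        k[g] <- parents[[p]][g]
      }
      new_entry(ff_from_vector(template, k))
    })
    c(winners, hybrids)
  })
}

#' Multiple force-field optimization (MFFO)
#'
#' Evolutionary optimization of the angular force field: a population of
#' `N_K` force fields each undergoes `m_cycle` independent SFFO steps per
#' cycle (their EMA folding proxies updating every step), then the
#' population is ranked by the proxy and rebuilt by winner-preserving
#' crossover. With `crossover = FALSE` (or `N_win = N_K`) the procedure
#' degenerates to `N_K` independent SFFO runs, the serial baseline.
#'
#' @param reference a [folding_reference()].
#' @param config an [optimizer_config()].
#' @param cycles number of ranking cycles.
#' @param master_seed integer master seed; every sub-computation derives
#'   its own stream from it.
#' @param crossover apply the ranking/crossover step between cycles.
#' @param init_k optional 2-column matrix of (k_bend, k1_tor) initial
#'   homogeneous values per entry; defaults to the grid of combinations
#'   of 20, 40, 60, 80 (recycled to `N_K`).
#' @return list with `best` (top-ranked force field), `population`, and
#'   `history` (per-cycle best/mean proxy and acceptance counts).
#' @export
mffo_run <- function(reference, config, cycles, master_seed,
                     crossover = TRUE, init_k = NULL) {
  if (cycles < 1) stop("cycles must be >= 1")
  n <- n_beads(reference$native)
  if (is.null(init_k)) {
    grid <- as.matrix(expand.grid(c(20, 40, 60, 80), c(20, 40, 60, 80)))
    init_k <- grid[rep_len(seq_len(nrow(grid)), config$N_K), , drop = FALSE]
  }
  entries <- lapply(seq_len(config$N_K), function(j) {
    new_entry(efm_forcefield(n, k_bend = init_k[j, 1], k1_tor = init_k[j, 2]))
  })
  history <- data.frame(cycle = integer(0), best_Pi_f = numeric(0),
                        mean_Pi_f = numeric(0), accepted = integer(0))
  for (cy in seq_len(cycles)) {
    n_acc <- 0
    entries <- lapply(seq_along(entries), function(j) {
      e <- entries[[j]]
      for (st in seq_len(config$m_cycle)) {
        e <- sffo_step(e, reference, config,
                       derive_seed(master_seed, cy, j, st))
        if (isTRUE(e$accepted)) n_acc <<- n_acc + 1
      }
      e
    })
    pf <- vapply(entries, function(e) e$Pi_f, numeric(1))
    history <- rbind(history,
                     data.frame(cycle = cy, best_Pi_f = max(pf),
                                mean_Pi_f = mean(pf), accepted = n_acc))
    # with N_win = N_K the selection is degenerate (everyone survives):
    # skip the reordering so the run is identical to independent SFFOs
    if (crossover && config$N_win < config$N_K && cy < cycles) {
      entries <- rank_and_crossover(entries, config,
                                    derive_seed(master_seed, cy, 999))
    }
  }
  pf <- vapply(entries, function(e) e$Pi_f, numeric(1))
  best <- entries[[order(-pf, seq_along(entries))[1]]]
  list(best = best$ff, best_Pi_f = best$Pi_f, population = entries,
       history = history)
}
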