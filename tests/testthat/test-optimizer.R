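# Desk-scale folding system shared by the optimizer tests: the smallest
# L1 mini-lasso, with short test runs sized to its ~2 tau_MD folding time.
opt_system <- function() {
  ml <- make_mini_lasso(8, 4, "L1", seed = 3)
  list(ml = ml,
       reference = folding_reference(ml$conf, ml$ref, model_parameters()),
       config = optimizer_config(n_test = 4, tau_run = 1.5, m_cycle = 4,
                                 N_K = 6, N_win = 2, N_low = 2, alpha = 0.3,
                                 sample_every = 250))
}

test_that("mutations change exactly one constrained group, identically", {
  sys <- opt_system()
  ff <- efm_forcefield(12)
  for (seed in 1:20) {
    mut <- mutate_forcefield(ff, sys$config, seed)
    k0 <- c(ff$k_bend, ff$k1_tor)
    k1 <- c(mut$k_bend, mut$k1_tor)
    changed <- which(k1 != k0)
    hit <- vapply(ff$pairing, function(g) all(g %in% changed) ||
                    !any(g %in% changed), logical(1))
    expect_true(all(hit))                       # whole groups only
    touched <- vapply(ff$pairing, function(g) any(g %in% changed),
                      logical(1))
    expect_equal(sum(touched), 1)               # exactly one group
    # both members receive the same increment
    g <- ff$pairing[[which(touched)]]
    expect_equal(length(unique(k1[g] - k0[g])), 1)
  }
  expect_identical(mutate_forcefield(ff, sys$config, 5),
                   mutate_forcefield(ff, sys$config, 5))
})

test_that("mutation increments have the prescribed spread and floor", {
  sys <- opt_system()
  ff <- efm_forcefield(12)
  dks <- vapply(1:10000, function(seed) {
    mut <- mutate_forcefield(ff, sys$config, seed)
    d <- c(mut$k_bend, mut$k1_tor) - c(ff$k_bend, ff$k1_tor)
    d[d != 0][1]
  }, numeric(1))
  dks <- dks[!is.na(dks)]
  expect_lt(abs(sd(dks) - 2.5) / 2.5, 0.03)
  # a coefficient driven below the floor is clipped there
  tiny <- efm_forcefield(12, k_bend = 1.05, k1_tor = 1.05)
  clipped <- FALSE
  for (seed in 1:50) {
    mut <- mutate_forcefield(tiny, sys$config, seed)
    expect_true(all(c(mut$k_bend, mut$k1_tor) >= sys$config$k_floor))
    if (any(c(mut$k_bend, mut$k1_tor) == sys$config$k_floor)) clipped <- TRUE
  }
  expect_true(clipped)
})

test_that("the folding proxy is the mean Fermi switch of the MSD margin", {
  # theta(0) = 1/2 when the minimum MSD sits exactly at the threshold
  expect_equal(lassofold:::pi_f_from_msd(rep(0.9, 8), F0 = 0.9, w = 0.2),
               0.5)
  Fs <- c(0.1, 0.5, 0.9, 1.3, 2.0)
  expect_equal(lassofold:::pi_f_from_msd(Fs, 0.9, 0.2),
               mean(1 / (1 + exp(-(0.9 - Fs) / 0.2))))
})

test_that("evaluation measures the minimum-MSD statistic reproducibly", {
  sys <- opt_system()
  ff <- efm_forcefield(12)
  ev1 <- suppressWarnings(
    evaluate_forcefield(ff, sys$reference, sys$config, seed = 42))
  ev2 <- suppressWarnings(
    evaluate_forcefield(ff, sys$reference, sys$config, seed = 42))
  expect_identical(ev1$F_min, ev2$F_min)
  expect_equal(ev1$mean_F, mean(ev1$F_min))
  expect_equal(ev1$pi_f, lassofold:::pi_f_from_msd(ev1$F_min, 0.9, 0.2))
  expect_equal(length(ev1$F_min), 4)
  expect_true(all(ev1$F_min >= 0))
})

test_that("Metropolis acceptance follows min(1, exp(dF))", {
  expect_true(metropolis_accept(1.0, 0.5, seed = 1))   # improvement
  expect_true(metropolis_accept(1.0, 1.0, seed = 1))   # equal
  acc <- vapply(1:1e5, function(s) metropolis_accept(1.0, 2.0, s),
                logical(1))
  expect_lt(abs(mean(acc) - exp(-1)), 0.005)
})

test_that("EMA updates converge and decay with a 33-step e-folding time", {
  expect_equal(ema_update(0.2, 0.8, alpha = 1), 0.8)
  x <- 0.1
  for (i in 1:500) x <- ema_update(x, 0.7, alpha = 0.1)
  expect_equal(x, 0.7, tolerance = 1e-6)
  alpha <- 0.03
  expect_equal(round(-1 / log(1 - alpha)), 33)
  # empirical: after 33 updates with zero observations a unit value decays
  # to ~ 1/e
  x <- 1
  for (i in 1:33) x <- ema_update(x, 0, alpha)
  expect_equal(x, exp(-1), tolerance = 0.02)
})

test_that("SFFO accept/reject paths update or preserve the force field", {
  sys <- opt_system()
  # an unbeatable stored objective forces the reject branch
  entry <- lassofold:::new_entry(efm_forcefield(12))
  entry$mean_F <- -8
  entry$Pi_f <- 0.5
  for (step in 1:4) {
    before <- entry$ff
    entry <- suppressWarnings(
      sffo_step(entry, sys$reference, sys$config, seed = 1000 + step))
    expect_false(entry$accepted)
    expect_identical(entry$ff, before)        # bitwise unchanged
    expect_equal(entry$mean_F, -8)            # incumbent score kept
  }
  # ... while a hopeless one forces acceptance, updating the entry
  entry2 <- lassofold:::new_entry(efm_forcefield(12))
  entry2$mean_F <- 1e6
  entry2$Pi_f <- 0.5
  before2 <- entry2$ff
  entry2 <- suppressWarnings(
    sffo_step(entry2, sys$reference, sys$config, seed = 77))
  expect_true(entry2$accepted)
  expect_false(identical(entry2$ff, before2))
  expect_lt(entry2$mean_F, 1e6)
  # the proxy EMA moves on both paths and pairing survives
  for (e in list(entry, entry2)) {
    expect_false(isTRUE(all.equal(e$Pi_f, 0.5)))
    k <- c(e$ff$k_bend, e$ff$k1_tor)
    expect_true(all(vapply(e$ff$pairing, function(g) all(k[g] == k[g[1]]),
                           logical(1))))
  }
})

test_that("ranking keeps winners and builds hybrids from parent groups", {
  sys <- opt_system()
  cfg <- sys$config
  entries <- lapply(1:6, function(j) {
    e <- lassofold:::new_entry(efm_forcefield(12, k_bend = 10 * j,
                                              k1_tor = 10 * j))
    e$Pi_f <- j / 10
    e$mean_F <- 1
    e
  })
  out <- rank_and_crossover(entries, cfg, seed = 9)
  expect_equal(length(out), 6)
  # the two highest-proxy entries survive verbatim, best first
  expect_identical(out[[1]]$ff, entries[[6]]$ff)
  expect_identical(out[[2]]$ff, entries[[5]]$ff)
  # every hybrid group comes verbatim from some parent (winner or random
  # parent in [30, 60])
  for (h in 3:6) {
    kh <- c(out[[h]]$ff$k_bend, out[[h]]$ff$k1_tor)
    for (g in out[[h]]$ff$pairing) {
      from_winner <- any(vapply(entries[5:6], function(e) {
        all(kh[g] == c(e$ff$k_bend, e$ff$k1_tor)[g])
      }, logical(1)))
      in_random_range <- all(kh[g] >= 30 & kh[g] <= 60) &&
        length(unique(kh[g])) == 1
      expect_true(from_winner || in_random_range)
    }
    expect_true(is.na(out[[h]]$Pi_f))           # no inherited history
  }
  # degenerate selection: N_win = N_K leaves the population unchanged
  cfg_all <- optimizer_config(N_K = 6, N_win = 6, N_low = 2)
  out2 <- rank_and_crossover(entries, cfg_all, seed = 9)
  expect_identical(lapply(out2, function(e) e$ff),
                   lapply(entries[6:1], function(e) e$ff))
})

test_that("pairing survives thousands of mutate and crossover operations", {
  sys <- opt_system()
  ff <- efm_forcefield(12)
  ok <- TRUE
  for (seed in 1:5000) {
    ff2 <- mutate_forcefield(ff, sys$config, seed)
    ok <- ok && all(vapply(ff2$pairing, function(g) {
      k <- c(ff2$k_bend, ff2$k1_tor)
      all(k[g] == k[g[1]])
    }, logical(1)))
  }
  expect_true(ok)
  entries <- lapply(1:6, function(j) {
    e <- lassofold:::new_entry(efm_forcefield(12, 20 + j, 30 + j))
    e$Pi_f <- j / 10
    e
  })
  for (seed in 1:200) {
    out <- rank_and_crossover(entries, sys$config, seed)
    for (e in out) {
      k <- c(e$ff$k_bend, e$ff$k1_tor)
      expect_true(all(vapply(e$ff$pairing, function(g) all(k[g] == k[g[1]]),
                             logical(1))))
    }
  }
})

test_that("MFFO bookkeeping is consistent and degenerates without crossover", {
  sys <- opt_system()
  cfg <- optimizer_config(n_test = 2, tau_run = 1.0, m_cycle = 2, N_K = 3,
                          N_win = 3, N_low = 1, alpha = 0.3,
                          sample_every = 250)
  res <- suppressWarnings(
    mffo_run(sys$reference, cfg, cycles = 3, master_seed = 5))
  expect_equal(nrow(res$history), 3)
  expect_true(all(res$history$accepted <= cfg$m_cycle * cfg$N_K))
  expect_true(all(res$history$best_Pi_f >= res$history$mean_Pi_f))
  # N_win = N_K: crossover on and off give identical runs
  res2 <- suppressWarnings(
    mffo_run(sys$reference, cfg, cycles = 3, master_seed = 5,
             crossover = FALSE))
  expect_equal(res$history, res2$history)
  expect_identical(res$best, res2$best)
})
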