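test_that("MSD from native follows its definition and the Kabsch oracle", {
  ml <- standard_mini_lasso()
  expect_equal(msd_from_native(ml$conf, ml$conf), 0)
  # a pure translation: zero after superposition, 75 without (3 * 5^2)
  shifted <- chain_configuration(ml$conf$positions +
                                   matrix(5, 22, 3))
  expect_equal(msd_from_native(shifted, ml$conf, superpose = TRUE), 0,
               tolerance = 1e-12)
  expect_equal(msd_from_native(shifted, ml$conf, superpose = FALSE), 75,
               tolerance = 1e-12)
  expect_error(msd_from_native(wavy_chain(10, 1), ml$conf), "length")
})

test_that("superposed MSD matches an independent bio3d fit", {
  skip_if_not_installed("bio3d")
  ref <- wavy_chain(18, 21)$positions
  mob <- wavy_chain(18, 22)$positions
  got <- msd_from_native(mob, ref, superpose = TRUE)
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(ref)),
                   mobile = matrix(as.vector(t(mob)), nrow = 1)))
  oracle <- mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - ref)^2))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("native contact fraction counts formed pairs", {
  ml <- standard_mini_lasso()
  goff <- build_go_forcefield(ml$conf, cys_pairs = list(ml$bridge_pair))
  expect_equal(native_contact_fraction(ml$conf, goff$contacts), 1.0)
  st <- generate_stretched_configuration(22, 8)
  expect_lt(native_contact_fraction(st, goff$contacts), 0.05)
  expect_equal(native_contact_fraction(st, goff$contacts, factor = 1e6), 1.0)
})

test_that("the folded criterion combines RMSD and topology", {
  expect_true(is_folded(0.64, 0.95))      # sqrt(F) = 0.8 < 0.9
  expect_false(is_folded(0.64, 0.5))
  expect_false(is_folded(1.0, 0.95))      # sqrt(F) = 1.0 >= 0.9
  # monotone: lowering F or raising L never unfolds
  set.seed(1)
  for (k in 1:50) {
    F <- runif(1, 0, 2)
    L <- runif(1)
    if (is_folded(F, L)) {
      expect_true(is_folded(F * runif(1), L))
      expect_true(is_folded(F, L + (1 - L) * runif(1)))
    }
  }
})

test_that("transition times require sustained conditions", {
  thr <- 1.5
  # d_b1 dips below threshold transiently at t in [20, 25], then stays
  # below from t = 100 on
  tr <- make_trace(list(
    d_b1 = data.frame(t0 = c(0, 20, 25, 100), t1 = c(20, 25, 100, 200),
                      v0 = c(3, 1.0, 3, 1.0)),
    L = data.frame(t0 = c(0, 150), t1 = c(150, 200), v0 = c(0, 1)),
    F = data.frame(t0 = c(0, 150), t1 = c(150, 200), v0 = c(2, 0.25))),
    tau_run = 200)
  tt <- transition_times(tr, bridge_threshold = thr, persistence = 10)
  expect_equal(tt$t_b, 100)
  expect_equal(tt$t_k, 150)
  expect_equal(tt$t_f, 150)
  # never-satisfied condition is absent
  tr2 <- make_trace(list(
    d_b1 = data.frame(t0 = 0, t1 = 200, v0 = 3),
    L = data.frame(t0 = 0, t1 = 200, v0 = 1),
    F = data.frame(t0 = 0, t1 = 200, v0 = 0.25)), tau_run = 200)
  tt2 <- transition_times(tr2, bridge_threshold = thr)
  expect_true(is.na(tt2$t_b))
  expect_equal(tt2$t_k, 0)
  expect_equal(tt2$t_f, 0)
  # a condition satisfied only in the last instants cannot be sustained
  tr3 <- make_trace(list(
    d_b1 = data.frame(t0 = c(0, 195), t1 = c(195, 200), v0 = c(3, 1)),
    L = data.frame(t0 = 0, t1 = 200, v0 = 0),
    F = data.frame(t0 = 0, t1 = 200, v0 = 2)), tau_run = 200)
  expect_true(is.na(transition_times(tr3, thr)$t_b))
  # missing trace errors by name
  tr4 <- tr
  tr4$traces$L <- NULL
  expect_error(transition_times(tr4, thr), "missing trace 'L'")
})

test_that("pathway classification reproduces hand-labeled traces", {
  thr <- 1.5
  reopen <- 2.5
  base_F <- function(tf) {
    data.frame(t0 = c(0, tf), t1 = c(tf, 200), v0 = c(2, 0.25))
  }
  # open-loop: topology at t = 50, sustained closure only from t = 80
  t_open <- make_trace(list(
    d_b1 = data.frame(t0 = c(0, 80), t1 = c(80, 200), v0 = c(3, 1)),
    L = data.frame(t0 = c(0, 50), t1 = c(50, 200), v0 = c(0, 1)),
    F = base_F(80)), tau_run = 200)
  tt <- transition_times(t_open, thr)
  expect_equal(classify_pathway(t_open, tt, reopen), "open-loop")
  # threading: closure at t = 30, loop stays closed until topology at 90
  t_thread <- make_trace(list(
    d_b1 = data.frame(t0 = c(0, 30), t1 = c(30, 200), v0 = c(3, 1)),
    L = data.frame(t0 = c(0, 90), t1 = c(90, 200), v0 = c(0, 1)),
    F = base_F(90)), tau_run = 200)
  tt <- transition_times(t_thread, thr)
  expect_equal(tt$t_b, 30)
  expect_equal(classify_pathway(t_thread, tt, reopen), "threading")
  # reopening: closure at t = 30, a wide fluctuation to d_b1 ~ 4 at t = 60
  t_reopen <- make_trace(list(
    d_b1 = data.frame(t0 = c(0, 30, 55, 65), t1 = c(30, 55, 65, 200),
                      v0 = c(3, 1, 4.0, 1)),
    L = data.frame(t0 = c(0, 90), t1 = c(90, 200), v0 = c(0, 1)),
    F = base_F(90)), tau_run = 200)
  tt <- transition_times(t_reopen, thr)
  expect_equal(classify_pathway(t_reopen, tt, reopen), "reopening")
  # an unsuccessful trajectory cannot be classified
  t_fail <- make_trace(list(
    d_b1 = data.frame(t0 = 0, t1 = 200, v0 = 3),
    L = data.frame(t0 = 0, t1 = 200, v0 = 0),
    F = data.frame(t0 = 0, t1 = 200, v0 = 2)), tau_run = 200)
  tt <- transition_times(t_fail, thr)
  expect_error(classify_pathway(t_fail, tt, reopen), "not a successful")
})

test_that("classification is invariant to finer resampling", {
  thr <- 1.5
  pieces <- list(
    d_b1 = data.frame(t0 = c(0, 30, 55, 65), t1 = c(30, 55, 65, 200),
                      v0 = c(3, 1, 4, 1)),
    L = data.frame(t0 = c(0, 90), t1 = c(90, 200), v0 = c(0, 1)),
    F = data.frame(t0 = c(0, 90), t1 = c(90, 200), v0 = c(2, 0.25)))
  for (dt in c(2, 1, 0.5)) {
    tr <- make_trace(pieces, tau_run = 200, dt_sample = dt)
    tt <- transition_times(tr, thr)
    expect_equal(classify_pathway(tr, tt, 2.5), "reopening")
  }
})

test_that("pathway statistics sum exactly to the folding probability", {
  thr <- 1.5
  mk <- function(tb, tk, tf, spike = FALSE) {
    db <- if (is.na(tb)) {
      data.frame(t0 = 0, t1 = 200, v0 = 3)
    } else if (spike) {
      data.frame(t0 = c(0, tb, 60, 70), t1 = c(tb, 60, 70, 200),
                 v0 = c(3, 1, 4, 1))
    } else {
      data.frame(t0 = c(0, tb), t1 = c(tb, 200), v0 = c(3, 1))
    }
    L <- if (is.na(tk)) {
      data.frame(t0 = 0, t1 = 200, v0 = 0)
    } else {
      data.frame(t0 = c(0, tk), t1 = c(tk, 200), v0 = c(0, 1))
    }
    F <- if (is.na(tf)) {
      data.frame(t0 = 0, t1 = 200, v0 = 2)
    } else {
      data.frame(t0 = c(0, tf), t1 = c(tf, 200), v0 = c(2, 0.25))
    }
    make_trace(list(d_b1 = db, L = L, F = F), tau_run = 200)
  }
  ens <- list(mk(80, 50, 80),            # open-loop
              mk(30, 90, 90),            # threading
              mk(30, 90, 90, spike = TRUE),  # reopening
              mk(NA, 50, 50),            # open-loop without closure
              mk(30, NA, NA),            # failed
              mk(NA, NA, NA))            # failed
  res <- analyze_ensemble(ens, bridge_threshold = thr,
                          reopen_threshold = 2.5)
  st <- pathway_statistics(res)
  expect_equal(st$P_f, 4 / 6)
  expect_equal(st$P_open_loop, 2 / 6)
  expect_equal(st$P_threading, 1 / 6)
  expect_equal(st$P_reopening, 1 / 6)
  expect_identical(st$P_threading + st$P_reopening + st$P_open_loop +
                     st$P_unresolved, st$P_f)
  # no successes: all zeros
  st0 <- pathway_statistics(analyze_ensemble(ens[5:6], thr, 2.5))
  expect_equal(st0$P_f, 0)
  expect_equal(st0$P_open_loop + st0$P_threading + st0$P_reopening, 0)
})

test_that("landscape histograms match a brute-force recount", {
  set.seed(5)
  trajs <- lapply(1:3, function(k) {
    make_trace(list(
      F = data.frame(t0 = 0, t1 = 100, v0 = k, v1 = 0.1 * k),
      d_b1 = data.frame(t0 = 0, t1 = 100, v0 = 4, v1 = 1)),
      tau_run = 100)
  })
  ls <- folding_landscape(trajs, "F", "d_b1", bins = 8)
  expect_equal(sum(ls$counts), ls$n_samples)
  xs <- unlist(lapply(trajs, function(tr) tr$traces$F))
  ys <- unlist(lapply(trajs, function(tr) tr$traces$d_b1))
  ix <- findInterval(xs, ls$x_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(ys, ls$y_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  recount <- table(factor(ix, 1:8), factor(iy, 1:8))
  expect_equal(unname(as.vector(recount)), as.vector(ls$counts))
  # empty bins are undefined, populated bins carry F = -log f
  expect_true(anyNA(ls$surface))
  filled <- which(ls$counts > 0)
  expect_equal(ls$surface[filled], -log(ls$counts[filled] / ls$n_samples))
  # two equally populated bins get equal F
  tr1 <- make_trace(list(F = data.frame(t0 = c(0, 50), t1 = c(50, 100),
                                        v0 = c(1, 2)),
                         d_b1 = data.frame(t0 = 0, t1 = 100, v0 = 1)),
                    tau_run = 99)
  ls2 <- folding_landscape(list(tr1), "F", "d_b1",
                           bins = list(c(0.5, 1.5, 2.5), c(0, 2)))
  expect_equal(ls2$surface[1, 1], ls2$surface[2, 1])
  expect_error(folding_landscape(list(), "F", "d_b1"), "empty")
})
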