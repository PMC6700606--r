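test_that("loop reduction fan-triangulates with M_l - 2 triangles", {
  ml <- standard_mini_lasso()
  red <- reduce_structure(ml$conf, ml$spec)
  expect_equal(nrow(red$triangles), length(ml$spec$loop_residues) - 2)
  expect_equal(nrow(red$triangles), 3)          # M_l = 5
  spec3 <- topology_spec(ml$spec$loop_residues[c(1, 3, 5)],
                         ml$spec$tail_residues,
                         native_signature = ml$spec$native_signature)
  expect_equal(nrow(reduce_structure(ml$conf, spec3)$triangles), 1)
  bad <- ml$spec
  bad$loop_residues[2] <- 999L
  expect_error(reduce_structure(ml$conf, bad), "unknown loop residue")
})

test_that("segment-triangle crossings behave on constructed geometries", {
  # triangle large relative to the switch width, pierced at the centroid
  tri <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  centroid <- colMeans(tri)
  up <- segment_triangle_crossing(centroid - c(0, 0, 3), centroid + c(0, 0, 3),
                                  tri)
  expect_equal(up$sign, 1L)
  expect_gt(up$soft, 0.99)
  down <- segment_triangle_crossing(centroid + c(0, 0, 3),
                                    centroid - c(0, 0, 3), tri)
  expect_equal(down$sign, -1L)
  # parallel, offset from the plane: no crossing
  par <- segment_triangle_crossing(c(-1, 0.5, 1), c(2, 0.5, 1), tri)
  expect_equal(par$sign, 0L)
  expect_lt(par$soft, 0.5)
  # degenerate triangle
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_warning(res <- segment_triangle_crossing(c(0, 0, -1), c(0, 0, 1),
                                                  flat),
                 "degenerate")
  expect_equal(res$sign, 0L)
})

test_that("hard crossing signs agree with an independent ray-cast oracle", {
  skip_if_not_installed("pracma")
  set.seed(42)
  tri <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.3, 1.4, 0.2))
  w <- 0.2
  n_checked <- 0
  for (k in seq_len(1e4)) {
    p0 <- runif(3, -1, 2)
    p1 <- p0 + rnorm(3)
    if (raycast_margin(p0, p1, tri) <= w) next   # skip marginal cases
    got <- segment_triangle_crossing(p0, p1, tri, w)$sign
    want <- raycast_crossing(p0, p1, tri)
    expect_identical(got, want)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 1000)
})

test_that("soft scores approach the hard indicator as w -> 0", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  inside <- segment_triangle_crossing(c(0.5, 0.5, -1), c(0.5, 0.5, 1), tri,
                                      w = 1e-4)
  outside <- segment_triangle_crossing(c(1.8, 1.8, -1), c(1.8, 1.8, 1), tri,
                                       w = 1e-4)
  expect_equal(inside$soft_up, 1, tolerance = 1e-6)
  expect_equal(outside$soft_up, 0, tolerance = 1e-6)
})

test_that("lasso variable is high on native structures and low otherwise", {
  ml <- standard_mini_lasso()
  expect_gt(lasso_variable(ml$conf, ml$spec), 0.9)
  l1 <- make_mini_lasso(12, 6, "L1", seed = 2)
  expect_gt(lasso_variable(l1$conf, l1$spec), 0.9)
  # a stretched chain has no piercing
  st <- generate_stretched_configuration(22, 4)
  expect_lt(lasso_variable(st, ml$spec), 0.1)
  # reflecting the tail through the loop plane flips the piercing
  # direction: the native signature is no longer realized
  refl <- ml$conf$positions
  refl[13:22, 3] <- -refl[13:22, 3]
  refl_conf <- chain_configuration(refl, ml$conf$residue_ids)
  expect_lt(lasso_variable(refl_conf, ml$spec), 0.1)
  # ... and the ray-cast oracle confirms the flip on the reduced geometry
  red_n <- reduce_structure(ml$conf, ml$spec)
  red_r <- reduce_structure(refl_conf, ml$spec)
  dirs <- function(red) {
    out <- c()
    for (p in seq_along(red$tails)) {
      tp <- red$tails[[p]]
      for (s in seq_len(nrow(tp) - 1)) {
        for (k in seq_len(nrow(red$triangles))) {
          tri <- red$loop[red$triangles[k, ], ]
          out <- c(out, raycast_crossing(tp[s, ], tp[s + 1, ], tri))
        }
      }
    }
    out[out != 0]
  }
  expect_equal(sort(dirs(red_r)), sort(-dirs(red_n)))
})

test_that("L1 structures carry exactly one hard piercing", {
  l1 <- make_mini_lasso(12, 6, "L1", seed = 7)
  red <- reduce_structure(l1$conf, l1$spec)
  hits <- 0
  for (p in seq_along(red$tails)) {
    tp <- red$tails[[p]]
    for (s in seq_len(nrow(tp) - 1)) {
      for (k in seq_len(nrow(red$triangles))) {
        tri <- red$loop[red$triangles[k, ], ]
        hits <- hits + abs(raycast_crossing(tp[s, ], tp[s + 1, ], tri))
      }
    }
  }
  expect_equal(hits, 1)
  expect_equal(length(l1$spec$native_signature), 1)
})

test_that("Gauss linking number is the Hopf invariant on closed curves", {
  hp <- make_hopf_pair(1, 1, 64)
  expect_lt(abs(abs(gauss_linking_number(hp[[1]], hp[[2]])) - 1), 1e-3)
  far <- make_hopf_pair(1, 10, 64)
  expect_lt(abs(gauss_linking_number(far[[1]], far[[2]])), 1e-3)
})

test_that("segment-pair Gauss integrals match adaptive quadrature", {
  skip_if_not_installed("pracma")
  set.seed(99)
  worst <- 0
  compared <- 0
  for (k in 1:100) {
    p1 <- runif(3, -1, 1)
    p2 <- p1 + rnorm(3)
    p3 <- runif(3, -1, 1) + c(0, 0, 1.5)   # keep the pair non-singular
    p4 <- p3 + rnorm(3)
    analytic <- lassofold:::segment_pair_gauss_cpp(p1, p2, p3, p4)
    quad <- tryCatch(gauss_pair_quadrature(p1, p2, p3, p4),
                     error = function(e) NA)   # rare quadrature failure
    if (is.na(quad)) next
    worst <- max(worst, abs(analytic - quad))
    compared <- compared + 1
  }
  expect_lt(worst, 1e-6)
  expect_gte(compared, 95)
})

test_that("G is antisymmetric, rigid-invariant and refinement-invariant", {
  ml <- standard_mini_lasso()
  red <- reduce_structure(ml$conf, ml$spec)
  loop <- red$loop
  tail1 <- red$tails[[1]]
  G <- gauss_linking_number(loop, tail1)
  expect_equal(gauss_linking_number(loop, tail1, orientations = -1), -G,
               tolerance = 1e-12)
  R <- random_rotation(4)
  shift <- matrix(c(2, -1, 3), 1, 3)
  move <- function(m) m %*% R + matrix(shift, nrow(m), 3, byrow = TRUE)
  expect_equal(gauss_linking_number(move(loop), move(tail1)), G,
               tolerance = 1e-9)
  refine <- function(m) {
    out <- m[1, , drop = FALSE]
    for (i in 2:nrow(m)) {
      out <- rbind(out, (m[i - 1, ] + m[i, ]) / 2, m[i, ])
    }
    out
  }
  expect_equal(gauss_linking_number(refine(loop), refine(tail1)), G,
               tolerance = 1e-9)
})

test_that("the native mini-lasso attains G >= 1 together with L > 0.9", {
  ml <- standard_mini_lasso()
  expect_gt(lasso_variable(ml$conf, ml$spec), 0.9)
  expect_gte(lasso_gauss(ml$conf, ml$spec), 1)
  # without the split-tail orientation the two L2 piercings cancel
  red <- reduce_structure(ml$conf, ml$spec)
  naive <- gauss_linking_number(red$loop, red$tails, orientations = c(1, 1))
  expect_lt(abs(naive), abs(lasso_gauss(ml$conf, ml$spec)))
})

test_that("coincident vertices across curves are regularized with a warning", {
  a <- cbind(c(0, 1), c(0, 0), c(0, 0))
  b <- cbind(c(0, 0.5), c(0, 1), c(0, 0.5))   # shares the first vertex
  expect_warning(g <- gauss_linking_number(a, b), "regularized")
  expect_true(is.finite(g))
})
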