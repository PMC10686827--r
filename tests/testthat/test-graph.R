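test_that("graph construction respects edge budgets and chain edges", {
  st <- make_synthetic_set(1, c(500, 500), seed = 2)[[1]]
  g <- build_graph(st, 12, 8, 2, seed = 5)
  expect_lte(nrow(g$edges), 500 * 20)
  for (i in c(1, 100, 499))
    expect_true(any(g$edges[, 1] == i & g$edges[, 2] == i + 1))
  g1 <- build_graph(st, 12, 8, 2, seed = 5)
  expect_identical(g$edges, g1$edges)
  g2 <- build_graph(st, 12, 8, 2, seed = 6)
  expect_false(identical(g$edges, g2$edges))
  expect_error(build_graph(st, 1, 8), "k_local")
  expect_warning(build_graph(make_ideal_helix(5), 10, 0), "clamping")
})

test_that("edge count grows linearly with residue count", {
  cnt <- vapply(c(500, 1000), function(N)
    nrow(build_graph(make_ideal_helix(N), 12, 8, 2, seed = N)$edges), 1)
  expect_gte(cnt[2] / cnt[1], 1.8)
  expect_lte(cnt[2] / cnt[1], 2.2)
})

test_that("edge features are invariant under rigid motions", {
  st <- make_synthetic_set(1, c(60, 60), seed = 9)[[1]]
  g <- build_graph(st, 10, 6, 2, seed = 3)
  f1 <- featurize_edges(st, g)$edge_features
  rm_ <- random_rigid_motion(seed = 4)
  f2 <- featurize_edges(transform_structure(st, rm_$R, rm_$b), g)$edge_features
  expect_lt(max(abs(f1$rel_pos - f2$rel_pos)), 1e-5)
  expect_lt(max(abs(f1$quat - f2$quat)), 1e-5)
  expect_lt(max(abs(f1$dist - f2$dist)), 1e-5)
})

test_that("chain-edge distances on an ideal helix are ~3.8 A", {
  h <- make_ideal_helix(40)
  g <- build_graph(h, 6, 0, 2, seed = 1)
  f <- featurize_edges(h, g)$edge_features
  chain_e <- abs(f$seq_offset) == 1
  expect_true(all(abs(f$dist[chain_e] - 3.8) < 0.1))
})

test_that("reversing an edge gives the inverse relative transform", {
  st <- make_synthetic_set(1, c(30, 30), seed = 12)[[1]]
  fr <- residue_frames(st)
  # brute-force frame algebra for a handful of pairs
  R_of <- function(i) matrix(fr$rot[i, ], 3, 3)
  for (pair in list(c(2, 17), c(5, 9), c(25, 3))) {
    i <- pair[1]; j <- pair[2]
    rij <- t(R_of(i)) %*% (fr$origin[j, ] - fr$origin[i, ])
    rji <- t(R_of(j)) %*% (fr$origin[i, ] - fr$origin[j, ])
    Rrel <- t(R_of(i)) %*% R_of(j)
    expect_equal(as.numeric(-t(Rrel) %*% rij), as.numeric(rji),
                 tolerance = 1e-10)
  }
})

test_that("residue frames are right-handed orthonormal and reject collinear atoms", {
  st <- make_synthetic_set(1, c(25, 25), seed = 5)[[1]]
  fr <- residue_frames(st)
  for (i in c(1, 10, 25)) {
    R <- matrix(fr$rot[i, ], 3, 3)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-6)
    expect_equal(det(R), 1, tolerance = 1e-6)
  }
  bad <- st
  bad$n[3, ] <- bad$ca[3, ] + 2 * (bad$c[3, ] - bad$ca[3, ])  # collinear
  expect_error(residue_frames(bad), "3")
})

test_that("consensus re-solves extracted geometries from random initialization", {
  st <- make_synthetic_set(1, c(100, 100), seed = 11)[[1]]
  g <- build_graph(st, 12, 8, 2, seed = 5)
  eg <- extract_edge_geometry(st, g)
  init <- with_seed_local(42, matrix(rnorm(300, sd = 10), 100, 3))
  out <- solve_consensus(eg, g, init, n_iters = 10)
  expect_lt(kabsch_rmsd(out, ca_coords(st)), 1e-2)
  # the true structure is an (almost exact) fixed point
  out2 <- solve_consensus(eg, g, ca_coords(st), n_iters = 3, init = "frames")
  expect_lt(max(abs(out2 - ca_coords(st))), 1e-6)
})

test_that("consensus handles the one-constraint case and degenerate inputs", {
  g2 <- structure(list(n_nodes = 2L, edges = matrix(c(1L, 2L), 1, 2),
                       chain = c("A", "A"), k_local = 2L, k_random = 0L,
                       exponent_p = 2), class = "geometry_graph")
  pred <- matrix(c(1, 2, 2), 1, 3)
  init <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  o <- solve_consensus(edge_geometry(pred, 1), g2, init, n_iters = 4,
                       init = "frames")
  fr <- backbonediff:::frames_from_ca(init, c("A", "A"))
  rel <- backbonediff:::frame_pullback(fr$rot[1, , drop = FALSE],
                                       matrix(o[2, ] - o[1, ], 1, 3))
  expect_equal(as.numeric(rel), c(1, 2, 2), tolerance = 1e-8)
  # doubling all confidences leaves the solution unchanged
  st <- make_synthetic_set(1, c(40, 40), seed = 3)[[1]]
  g <- build_graph(st, 8, 4, 2, seed = 2)
  eg <- extract_edge_geometry(st, g)
  o1 <- solve_consensus(eg, g, ca_coords(st), n_iters = 4)
  o2 <- solve_consensus(edge_geometry(eg$pred, eg$weights * 2), g,
                        ca_coords(st), n_iters = 4)
  expect_equal(o1, o2, tolerance = 1e-10)
  # disconnected graphs are rejected with component sizes
  gd <- structure(list(n_nodes = 3L, edges = matrix(c(1L, 2L), 1, 2),
                       chain = c("A", "A", "B"), k_local = 2L, k_random = 0L,
                       exponent_p = 2), class = "geometry_graph")
  expect_error(solve_consensus(edge_geometry(pred, 1), gd,
                               matrix(0, 3, 3) + rnorm(9), 3),
               "disconnected")
  expect_error(edge_geometry(pred, -1), "positive")
})
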