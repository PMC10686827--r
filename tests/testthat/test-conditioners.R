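test_that("symmetry groups have the right orders and verify closure", {
  expect_equal(symmetry_group("C4")$order, 4L)
  expect_equal(symmetry_group("D3")$order, 6L)
  expect_equal(symmetry_group("T")$order, 12L)
  expect_equal(symmetry_group("O")$order, 24L)
  expect_equal(symmetry_group("I")$order, 60L)
  g <- symmetry_group("I")
  key <- function(R) paste(round(R, 8), collapse = ",")
  keys <- vapply(g$rotations, key, "")
  for (a in g$rotations[c(2, 17, 41)]) for (b in g$rotations[c(3, 30)]) {
    expect_true(key(a %*% b) %in% keys)
    expect_lt(max(abs(crossprod(a) - diag(3))), 1e-8)
    expect_equal(det(a), 1, tolerance = 1e-8)
  }
  expect_error(symmetry_group("X9"), "unknown")
})

test_that("symmetry tessellation replicates the asymmetric unit exactly", {
  au <- make_ideal_helix(50)
  cond <- make_symmetry_conditioner("C4", n_au = 50)
  cx <- apply_conditioner(cond, au)
  expect_equal(n_residues(cx), 200L)
  expect_equal(length(unique(cx$chain)), 4L)
  # group invariance: each element permutes subunits to < 1e-6 A
  g <- symmetry_group("C4")
  ca <- ca_coords(cx)
  blocks <- lapply(1:4, function(c) ca[((c - 1) * 50 + 1):(c * 50), ])
  for (R in g$rotations) {
    for (c1 in 1:4) {
      rot <- blocks[[c1]] %*% t(R)
      dev <- min(vapply(blocks, function(b) max(abs(b - rot)), 1))
      expect_lt(dev, 1e-6)
    }
  }
  # idempotence: applying the hard transform twice equals once
  x1 <- cond$hard(ca_coords(au), 0.5)
  x2 <- cond$hard(x1, 0.5)
  expect_lt(max(abs(x1 - x2)), 1e-6)
  # complex-sized input is re-symmetrized, not re-expanded
  expect_equal(nrow(cond$hard(x1 + 0.01, 0.5)), 200L)
  expect_error(cond$hard(matrix(0, 77, 3), 0.5), "expected")
})

test_that("multi-chain asymmetric units are relabelled per copy", {
  au <- backbone_structure(rbind(ca_coords(make_ideal_helix(10)),
                                 sweep(ca_coords(make_ideal_helix(10)), 2,
                                       c(15, 0, 0), "+")),
                           chain = rep(c("A", "B"), each = 10))
  cx <- apply_conditioner(make_symmetry_conditioner("C3", n_au = 20), au)
  expect_equal(n_residues(cx), 60L)
  expect_equal(length(unique(cx$chain)), 6L)
})

test_that("the soft symmetry energy vanishes on symmetric complexes", {
  au <- make_ideal_helix(20)
  hard <- make_symmetry_conditioner("C3", n_au = 20)
  soft <- make_symmetry_conditioner("C3", n_au = 20, mode = "soft",
                                    force_constant = 2)
  cx <- hard$hard(ca_coords(au), 0)
  expect_lt(soft$energy(cx, 0), 1e-12)
  broken <- cx; broken[1, ] <- broken[1, ] + 1
  expect_gt(soft$energy(broken, 0), 0)
  g <- soft$grad(broken, 0)
  gfd <- matrix(0, nrow(broken), 3)
  for (i in c(1, 2, 21)) for (d in 1:3) {
    e <- 1e-6
    xp <- broken; xp[i, d] <- xp[i, d] + e
    xm <- broken; xm[i, d] <- xm[i, d] - e
    gfd[i, d] <- (soft$energy(xp, 0) - soft$energy(xm, 0)) / (2 * e)
  }
  expect_equal(g[c(1, 2, 21), ], gfd[c(1, 2, 21), ], tolerance = 1e-5)
})

test_that("replacement conditioning clamps residues exactly at t = 0", {
  ref <- make_ideal_helix(60)
  prior <- polymer_prior(60)
  sch <- diffusion_schedule(100)
  den <- prior_data_denoiser(sch)
  # full clamp reproduces the reference exactly
  cond <- make_substructure_conditioner(ref, rep(TRUE, 60), prior, sch, seed = 4)
  st <- reverse_sample(prior, sch, den, sampler_settings(1, 0, 100, seed = 7),
                       conditioners = cond)
  expect_identical(ca_coords(st), ca_coords(ref))
  expect_identical(st$o, ref$o)
  # empty mask leaves the unconditional trajectory untouched
  c0 <- make_substructure_conditioner(ref, integer(0), prior, sch)
  s1 <- reverse_sample(prior, sch, den, sampler_settings(1, 0, 100, seed = 8))
  s2 <- reverse_sample(prior, sch, den, sampler_settings(1, 0, 100, seed = 8),
                       conditioners = c0)
  expect_identical(ca_coords(s1), ca_coords(s2))
  # half clamp: clamped half exact, free half varies across seeds
  ch <- make_substructure_conditioner(ref, 1:30, prior, sch, seed = 4)
  h1 <- reverse_sample(prior, sch, den, sampler_settings(1, 0, 100, seed = 9),
                       conditioners = ch)
  h2 <- reverse_sample(prior, sch, den, sampler_settings(1, 0, 100, seed = 10),
                       conditioners = ch)
  expect_identical(ca_coords(h1)[1:30, ], ca_coords(ref)[1:30, ])
  expect_gt(max(abs(ca_coords(h1)[31:60, ] - ca_coords(h2)[31:60, ])), 0.5)
  # the hard transform is idempotent at fixed t
  x <- with_seed_local(3, matrix(rnorm(180), 60, 3))
  expect_identical(ch$hard(ch$hard(x, 0.37), 0.37), ch$hard(x, 0.37))
  expect_error(make_substructure_conditioner(ref, rep(TRUE, 61)), "longer")
  expect_error(make_substructure_conditioner(ref, c(0L)), "outside")
})

test_that("clamp masks parse from chain:range strings", {
  ref <- make_ideal_helix(10)
  expect_identical(parse_clamp_mask("A:2-4", ref), 2:4)
  expect_identical(parse_clamp_mask("A:1-2,A:9-10", ref), c(1:2, 9:10))
  expect_error(parse_clamp_mask("B:1-2", ref), "no residues")
  expect_error(parse_clamp_mask("A:x", ref), "bad clamp")
})

test_that("distance restraints have exact minima and correct gradients", {
  dc <- make_distance_conditioner(rbind(c(1, 5), c(2, 9)), c(6, 8), 2)
  x <- ca_coords(make_random_coil(10, seed = 2))
  # zero energy and gradient when distances hit their targets
  x0 <- matrix(0, 2, 3); x0[2, 1] <- 7
  d1 <- make_distance_conditioner(rbind(c(1, 2)), 7, 3)
  expect_equal(d1$energy(x0, 0), 0)
  expect_equal(d1$grad(x0, 0), matrix(0, 2, 3))
  g <- dc$grad(x, 0.1)
  gfd <- matrix(0, 10, 3)
  for (i in 1:10) for (d in 1:3) {
    e <- 1e-5
    xp <- x; xp[i, d] <- xp[i, d] + e
    xm <- x; xm[i, d] <- xm[i, d] - e
    gfd[i, d] <- (dc$energy(xp, 0.1) - dc$energy(xm, 0.1)) / (2 * e)
  }
  expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-5)
  expect_error(make_distance_conditioner(rbind(c(3, 3)), 5), "i == j")
  expect_error(make_distance_conditioner(rbind(c(1, 2)), -1), "positive")
})

test_that("distance guidance pulls the sampled pair toward its target", {
  sch <- diffusion_schedule(80)
  prior <- polymer_prior(12)
  den <- prior_data_denoiser(sch)
  mean_d <- vapply(c(0, 1, 10), function(k) {
    conds <- if (k > 0) make_distance_conditioner(rbind(c(1, 12)), 4, k)
    out <- sample_reverse_latent(prior, sch, den,
                                 sampler_settings(1, 0, 80, seed = 100 + k),
                                 conditioners = conds, n_samples = 150)
    mean(vapply(out, function(x) sqrt(sum((x[1, ] - x[12, ])^2)), 1))
  }, 1)
  # unconditional mean pair distance is far from 4 A; guidance closes in
  expect_true(all(diff(abs(mean_d - 4)) < 0))
})

test_that("entropic OT has the exact one-to-one and coincident limits", {
  expect_equal(entropic_ot(matrix(c(0, 0, 0), 1, 3),
                           matrix(c(3, 0, 0), 1, 3), 1)$cost, 9,
               tolerance = 1e-10)
  cl <- with_seed_local(2, matrix(rnorm(60), 20, 3) * 5)
  same <- entropic_ot(cl, cl, 0.5)
  apart <- suppressWarnings(entropic_ot(cl, sweep(cl, 2, c(40, 0, 0), "+"), 0.5))
  expect_lt(same$cost, 0.05 * apart$cost)            # entropic floor only
  expect_lt(max(abs(same$grad_x)), 1e-3 * max(abs(apart$grad_x)))
  expect_error(entropic_ot(cl, cl, 0), "epsilon")
})

test_that("the shape-energy gradient matches finite differences", {
  cl <- with_seed_local(4, matrix(rnorm(60), 20, 3) * 5)
  sc <- make_shape_conditioner(cl, epsilon = 4)
  x <- with_seed_local(5, matrix(rnorm(45), 15, 3) * 5)
  g <- sc$grad(x, 0.1)
  gfd <- matrix(0, 15, 3)
  for (i in 1:15) for (d in 1:3) {
    e <- 1e-5
    xp <- x; xp[i, d] <- xp[i, d] + e
    xm <- x; xm[i, d] <- xm[i, d] - e
    gfd[i, d] <- (sc$energy(xp, 0.1) - sc$energy(xm, 0.1)) / (2 * e)
  }
  expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-5)
})

test_that("shape guidance reduces the OT distance to an L-shaped cloud", {
  L_cloud <- rbind(cbind(0, 0, seq(0, 24, by = 3)),
                   cbind(seq(3, 15, by = 3), 0, 0))
  sch <- diffusion_schedule(60)
  prior <- polymer_prior(20)
  den <- prior_data_denoiser(sch)
  sc <- make_shape_conditioner(L_cloud, epsilon = 6, weight = 0.02)
  cost_of <- function(conds, seed) {
    # far-apart transients may hit the Sinkhorn iteration cap by design
    out <- suppressWarnings(sample_reverse_latent(
      prior, sch, den, sampler_settings(1, 0, 60, seed = seed),
      conditioners = conds, n_samples = 1))[[1]]
    entropic_ot(out, L_cloud, 6)$cost
  }
  seeds <- 1:25
  free <- vapply(seeds, function(s) cost_of(NULL, s), 1)
  guided <- vapply(seeds, function(s) cost_of(sc, s), 1)
  expect_lt(mean(guided), mean(free))
})

test_that("classifier guidance is off at scale zero and helix-seeking otherwise", {
  hc <- helix_content_classifier()
  expect_gt(hc$log_prob(ca_coords(make_ideal_helix(40)), 0),
            10 * hc$log_prob(ca_coords(make_ideal_strand(40)), 0))
  g <- hc$grad(ca_coords(make_random_coil(20, seed = 3)), 0)
  x <- ca_coords(make_random_coil(20, seed = 3))
  for (i in c(1, 8, 20)) for (d in 1:3) {
    e <- 1e-5
    xp <- x; xp[i, d] <- xp[i, d] + e
    xm <- x; xm[i, d] <- xm[i, d] - e
    expect_equal(g[i, d], (hc$log_prob(xp, 0) - hc$log_prob(xm, 0)) / (2 * e),
                 tolerance = 1e-6)
  }
  sch <- diffusion_schedule(60)
  prior <- polymer_prior(25)
  den <- prior_data_denoiser(sch)
  c0 <- make_classifier_conditioner(hc$log_prob, 0, grad_fn = hc$grad)
  s1 <- sample_reverse_latent(prior, sch, den, sampler_settings(1, 0, 60, seed = 5),
                              n_samples = 1)[[1]]
  s2 <- sample_reverse_latent(prior, sch, den, sampler_settings(1, 0, 60, seed = 5),
                              conditioners = c0, n_samples = 1)[[1]]
  expect_equal(s1, s2, tolerance = 1e-9)
  # mean helix score rises monotonically with the guidance scale
  score_at <- function(scale) {
    conds <- if (scale > 0)
      make_classifier_conditioner(hc$log_prob, scale, grad_fn = hc$grad)
    mean(vapply(1:40, function(s) {
      x <- sample_reverse_latent(prior, sch, den,
                                 sampler_settings(1, 0, 60, seed = 500 + s),
                                 conditioners = conds, n_samples = 1)[[1]]
      hc$log_prob(x, 0)
    }, 1))
  }
  scores <- vapply(c(0, 1, 5), score_at, 1)
  expect_true(all(diff(scores) > 0))
  bad <- make_classifier_conditioner(function(coords, t) NaN, 1)
  expect_error(bad$energy(matrix(0, 2, 3), 0.5), "non-finite")
})

test_that("conditioners compose in order and an empty composition is a no-op", {
  expect_null(backbonediff:::normalize_conditioners(list()))
  sch <- diffusion_schedule(50)
  prior <- polymer_prior(10)
  den <- prior_data_denoiser(sch)
  a <- reverse_sample(prior, sch, den, sampler_settings(1, 0, 50, seed = 2))
  b <- reverse_sample(prior, sch, den, sampler_settings(1, 0, 50, seed = 2),
                      conditioners = list())
  expect_identical(ca_coords(a), ca_coords(b))
  # symmetry composed with symmetry-consistent distance restraints stays exact
  sym <- make_symmetry_conditioner("C3", n_au = 10)
  dist <- make_distance_conditioner(rbind(c(1, 10), c(11, 20), c(21, 30)),
                                    rep(9, 3), 0.5)
  both <- compose_conditioners(list(sym, dist))
  prior30 <- polymer_prior(30)
  st <- reverse_sample(prior30, sch, den, sampler_settings(1, 0, 50, seed = 4),
                       conditioners = both)
  ca <- ca_coords(st)
  R <- symmetry_group("C3")$rotations[[2]]
  blocks <- lapply(1:3, function(c) ca[((c - 1) * 10 + 1):(c * 10), ])
  rot <- blocks[[1]] %*% t(R)
  expect_lt(min(vapply(blocks, function(b) max(abs(b - rot)), 1)), 1e-6)
  # composed energies are summed
  comp <- compose_conditioners(list(dist, dist))
  x <- matrix(rnorm(90), 30, 3)
  expect_equal(comp$energy(x, 0), 2 * dist$energy(x, 0))
})
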