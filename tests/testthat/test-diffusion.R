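test_that("the schedule is variance preserving with clamped endpoints", {
  sch <- diffusion_schedule(100)
  ts <- seq(0, 1, by = 0.05)
  expect_equal(sch$alpha(ts)^2 + sch$sigma(ts)^2, rep(1, length(ts)),
               tolerance = 1e-12)
  expect_identical(sch$alpha(0), 1)
  expect_identical(sch$sigma(0), 0)
  expect_lt(sch$alpha(1), 0.01)
  expect_gt(sch$sigma(1), 0.99)
  expect_true(all(diff(sch$alpha(ts)) < 0))
  expect_error(diffusion_schedule(1), "n_steps")
})

test_that("forward marginal interpolates between data and prior", {
  p <- polymer_prior(60)
  sch <- diffusion_schedule()
  x0 <- ca_coords(make_ideal_helix(60))
  expect_identical(forward_marginal(p, sch, x0, 0), x0)
  expect_error(forward_marginal(p, sch, x0, 1.2), "t")
  # at t = 1 the Rg^2 matches the prior closed form
  rg2 <- replicate(5000, rg2_of(forward_marginal(p, sch, x0, 1)))
  expect_lt(abs(mean(rg2) / prior_rg2(p) - 1), 0.03)
  # whitened residual variance equals sigma(t)^2
  t0 <- 0.55
  v <- replicate(2000, {
    xt <- forward_marginal(p, sch, x0, t0)
    mean(whiten(p, xt - sch$alpha(t0) * x0)^2)
  })
  expect_lt(abs(mean(v) / sch$sigma(t0)^2 - 1), 0.05)
  # rigid-residue noise: a structure input moves all atoms per residue alike
  st <- make_ideal_helix(60)
  xt <- forward_marginal(p, sch, st, 0.5, seed = 3)
  expect_equal(xt$n - st$n, ca_coords(xt) - ca_coords(st), tolerance = 1e-12)
})

test_that("score conversion reproduces closed forms", {
  p1 <- polymer_prior(1, centroid_sigma = 1)
  sch <- diffusion_schedule()
  den <- gaussian_toy_denoiser(p1, sch, c(0, 0, 0), diag(3))
  for (t in c(0.2, 0.5, 0.9)) {
    x <- matrix(rnorm(3), 1, 3)
    expect_lt(max(abs(score_from_denoiser(p1, sch, den, x, t) + x)), 1e-10)
  }
  expect_error(score_from_denoiser(p1, sch, den, matrix(0, 1, 3), 0), "t = 0")
  # denoiser x_t / alpha(t) gives identically zero score
  dz <- new_denoiser(function(x, t) x / sch$alpha(t))
  p <- polymer_prior(12)
  x <- sample_prior(p, 1, seed = 2)[[1]]
  expect_lt(max(abs(score_from_denoiser(p, sch, dz, x, 0.4))), 1e-9)
  # linear denoiser gives a score linear in x_t
  dl <- new_denoiser(function(x, t) 0.3 * x)
  s1 <- score_from_denoiser(p, sch, dl, x, 0.4)
  s2 <- score_from_denoiser(p, sch, dl, 2 * x, 0.4)
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
})

test_that("reverse sampling recovers the Gaussian data law at lambda = 1", {
  p1 <- polymer_prior(1, centroid_sigma = 1)
  sch <- diffusion_schedule()
  mu <- c(1, -2, 0.5)
  Sg <- matrix(c(1, 0.3, 0, 0.3, 0.8, 0.2, 0, 0.2, 0.5), 3, 3)
  den <- gaussian_toy_denoiser(p1, sch, mu, Sg)
  out <- sample_reverse_latent(p1, sch, den, sampler_settings(1, 0, 200, seed = 12),
                               n_samples = 8000)
  X <- do.call(rbind, out)
  expect_lt(max(abs(colMeans(X) - mu)), 0.05 * max(abs(mu)))
  expect_lt(max(abs(cov(X) - Sg)) / max(abs(Sg)), 0.05)
})

test_that("low-temperature sampling tempers the Gaussian toward N(mu, Sigma/lambda)", {
  p1 <- polymer_prior(1, centroid_sigma = 1)
  sch <- diffusion_schedule()
  den <- gaussian_toy_denoiser(p1, sch, c(0, 0, 0), diag(3))
  vars <- vapply(c(1, 2, 4, 8), function(lam) {
    X <- do.call(rbind, sample_reverse_latent(
      p1, sch, den, sampler_settings(lam, 0, 150, seed = lam), n_samples = 4000))
    mean(apply(X, 2, var))
  }, 1)
  expect_lt(abs(vars[1] - 1), 0.05)
  expect_lt(abs(vars[3] - 0.25) / 0.25, 0.10)
  # diversity decreases monotonically with inverse temperature
  expect_true(all(diff(vars) < 0))
})

test_that("the corrector keeps the tempered law and sampling is reproducible", {
  p1 <- polymer_prior(1, centroid_sigma = 1)
  sch <- diffusion_schedule()
  den <- gaussian_toy_denoiser(p1, sch, c(0.5, 0, -1), 0.6 * diag(3))
  X <- do.call(rbind, sample_reverse_latent(
    p1, sch, den, sampler_settings(4, 2, 150, seed = 7), n_samples = 6000))
  expect_lt(max(abs(cov(X) - 0.6 * diag(3) / 4)) / 0.15, 0.10)
  s <- sampler_settings(1, 0, 60, seed = 5)
  p <- polymer_prior(20)
  dz <- prior_data_denoiser(sch)
  a <- reverse_sample(p, sch, dz, s)
  b <- reverse_sample(p, sch, dz, s)
  expect_identical(ca_coords(a), ca_coords(b))
})

test_that("halving the step size leaves the Gaussian-toy covariance within MC error", {
  p1 <- polymer_prior(1, centroid_sigma = 1)
  sch <- diffusion_schedule()
  den <- gaussian_toy_denoiser(p1, sch, c(0, 0, 0), diag(3))
  v <- vapply(c(150, 300), function(ns) {
    X <- do.call(rbind, sample_reverse_latent(
      p1, sch, den, sampler_settings(1, 0, ns, seed = 31), n_samples = 5000))
    mean(apply(X, 2, var))
  }, 1)
  # MC standard error of a variance estimate over 5000 x 3 draws is ~1.6%
  expect_lt(abs(v[1] - v[2]), 2 * 1.3 * sqrt(2 / 15000))
})

test_that("sampler settings validate and a broken denoiser aborts with its step", {
  expect_error(sampler_settings(0.5), "inverse_temperature")
  expect_error(sampler_settings(1, -1), "langevin_factor")
  expect_error(sampler_settings(1, 0, 1), "n_steps")
  p <- polymer_prior(6)
  sch <- diffusion_schedule()
  bad <- new_denoiser(function(x, t) x * NA_real_)
  expect_error(
    reverse_sample(p, sch, bad, sampler_settings(1, 0, 20, seed = 1)),
    "reverse step 1")
})
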