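# Shared fixtures.  Everything is generated in code; the expensive desk-scale
# training run is memoized so several test files can share one fit.

.fixture_env <- new.env(parent = emptyenv())

# Helix-rich training corpus plus held-out jittered helices, as used for the
# denoising-gain checks.
training_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- c(
      lapply(1:80, function(k) make_ideal_helix(20 + (k %% 40), seed = k,
                                                jitter = 0.15)),
      make_synthetic_set(40, c(40, 70), seed = 21))
  }
  .fixture_env$corpus
}

heldout_helices <- function(n = 20L) {
  lapply(seq_len(n), function(k) make_ideal_helix(26 + 2 * k, seed = 1000 + k,
                                                  jitter = 0.15))
}

# Desk-scale trained denoiser (about a minute of CPU), shared across tests.
trained_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    fit <- train_denoiser(training_corpus(), n_epochs = 25, seed = 5,
                          hidden = 64, lr = 1e-3)
    fit <- train_denoiser(training_corpus(), n_epochs = 10, seed = 6,
                          hidden = 64, lr = 2e-4, init_params = fit$params)
    .fixture_env$fit <- fit
  }
  .fixture_env$fit
}

# Tiny untrained fit for shape/equivariance contracts that do not need a
# good model.
untrained_fit <- function(hidden = 32L) {
  train_denoiser(list(make_ideal_helix(8L)), n_epochs = 0L, seed = 1L,
                 hidden = hidden)
}

# Exact optimal denoiser when the data distribution *is* the prior: in the
# variance-preserving whitened process the posterior mean is alpha(t) x_t.
prior_data_denoiser <- function(schedule) {
  new_denoiser(function(x, t) schedule$alpha(t) * x, batched = TRUE,
               name = "prior-data")
}

random_rigid_motion <- function(seed = NULL) {
  with_seed_local(seed, {
    ax <- stats::rnorm(3)
    list(R = rotation_about_axis_local(ax, stats::runif(1, 0.3, 2.8)),
         b = stats::rnorm(3, sd = 8))
  })
}

with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

rotation_about_axis_local <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transform_structure <- function(st, R, b) {
  for (a in c("n", "ca", "c", "o")) st[[a]] <- sweep(st[[a]] %*% t(R), 2, b, "+")
  st
}

rg2_of <- function(ca) {
  cc <- sweep(ca, 2, colMeans(ca))
  mean(rowSums(cc^2))
}

# Independent brute-force contact order (double loop), the oracle for the
# vectorized implementation.
contact_order_bruteforce <- function(ca, cutoff = 8, min_separation = 3) {
  n <- nrow(ca)
  tot <- 0; nc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i < min_separation) next
    if (sqrt(sum((ca[i, ] - ca[j, ])^2)) <= cutoff) {
      nc <- nc + 1; tot <- tot + (j - i)
    }
  }
  if (nc == 0) return(0)
  tot / (n * nc)
}

# Grid-search rigid-superposition oracle (coarse Euler grid + local
# refinement), used to validate the Kabsch implementation on tiny inputs.
rmsd_grid_oracle <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  rmsd_of <- function(ang) {
    R <- rotation_about_axis_local(c(0, 0, 1), ang[3]) %*%
      rotation_about_axis_local(c(0, 1, 0), ang[2]) %*%
      rotation_about_axis_local(c(1, 0, 0), ang[1])
    sqrt(mean(rowSums((bc - ac %*% t(R))^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 25L)[-25L]
  best <- NULL; best_v <- Inf
  for (a1 in grid) for (a2 in seq(0, pi, length.out = 13L)) for (a3 in grid) {
    v <- rmsd_of(c(a1, a2, a3))
    if (v < best_v) { best_v <- v; best <- c(a1, a2, a3) }
  }
  o <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 2000))
  o$value
}
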