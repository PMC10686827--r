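#' Variance-preserving diffusion schedule
#'
#' Signal and noise amplitudes on t in [0, 1] with log-SNR linear in t
#' (natural-log units, `logsnr_max` at t = 0 down to `logsnr_min` at t = 1),
#' so `alpha(t)^2 + sigma(t)^2 = 1` everywhere (variance preserving in the
#' whitened space).  The endpoints t = 0 are clamped to `alpha = 1`,
#' `sigma = 0` exactly (a 5e-5 discontinuity at the default +10 bound), which
#' makes zero-noise operations such as replacement conditioning exact at
#' t = 0.
#'
#' @param n_steps Reverse-integration grid size (>= 2).
#' @param logsnr_max,logsnr_min Log-SNR at t = 0 and t = 1.
#' @return Object of class `diffusion_schedule` with functions `alpha`,
#'   `sigma`, `beta` (noise injection rate `-d log alpha^2 / dt`) and the
#'   grid size.
#' @export
diffusion_schedule <- function(n_steps = 200L, logsnr_max = 10, logsnr_min = -10) {
  stopifnot_scalar(n_steps, "n_steps", min = 2)
  if (logsnr_max <= logsnr_min) stop("logsnr_max must exceed logsnr_min")
  rate <- logsnr_max - logsnr_min
  logsnr <- function(t) logsnr_max - rate * t
  alpha <- function(t) ifelse(t <= 0, 1, sqrt(stats::plogis(logsnr(t))))
  sigma <- function(t) ifelse(t <= 0, 0, sqrt(stats::plogis(-logsnr(t))))
  beta <- function(t) rate * stats::plogis(-logsnr(t))
  structure(list(alpha = alpha, sigma = sigma, beta = beta,
                 n_steps = as.integer(n_steps),
                 logsnr_max = logsnr_max, logsnr_min = logsnr_min),
            class = "diffusion_schedule")
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat(sprintf("<diffusion_schedule: log-SNR %g -> %g, %d steps>\n",
              x$logsnr_max, x$logsnr_min, x$n_steps))
  invisible(x)
}

check_t <- function(t, allow_zero = TRUE) {
  stopifnot_scalar(t, "t", min = 0, max = 1)
  if (!allow_zero && t <= 0) stop("t = 0 is not allowed here (zero noise)")
  t
}

#' Forward (noising) marginal of the correlated diffusion
#'
#' Draws `x_t = alpha(t) x0 + sigma(t) unwhiten(z)` with `z` standard normal.
#' At t = 0 this returns `x0` exactly; at t = 1 the distribution equals the
#' polymer prior.  When `x0` is a `backbone_structure`, the CA noise field
#' displaces every atom of a residue rigidly (rigid-residue noise) and a
#' structure is returned.
#'
#' @param prior A `polymer_prior` matching the residue count of `x0`.
#' @param schedule A `diffusion_schedule`.
#' @param x0 N x 3 CA matrix or a `backbone_structure`.
#' @param t Diffusion time in \[0, 1\].
#' @param seed Optional seed.
#' @return Same type as `x0`.
#' @export
forward_marginal <- function(prior, schedule, x0, t, seed = NULL) {
  check_t(t)
  is_struct <- inherits(x0, "backbone_structure")
  ca0 <- if (is_struct) ca_coords(x0) else as_coord_matrix(x0, "x0")
  if (nrow(ca0) != prior$n_residues) stop("x0 does not match prior$n_residues")
  a <- schedule$alpha(t); s <- schedule$sigma(t)
  noise <- if (s > 0) {
    z <- with_seed(seed, matrix(stats::rnorm(prior$latent_dim * 3L),
                                prior$latent_dim, 3L))
    s * unwhiten(prior, z)
  } else 0
  ca_t <- a * ca0 + noise
  if (is_struct) set_ca_coords(x0, ca_t) else ca_t
}

#' Denoiser objects
#'
#' A denoiser is a callable mapping `(x_t, t)` to predicted clean CA
#' coordinates `x0`, wrapped with metadata: `n_residues` (or NULL for a
#' length-agnostic denoiser) and whether it accepts stacked batches.
#' Conforming implementations are expected to be SE(3)-equivariant; the test
#' suite checks this numerically rather than assuming it.
#'
#' @param fn Function `(x, t, ...)` returning predicted x0 (same shape as x).
#' @param n_residues Residue count the denoiser expects, or NULL.
#' @param batched TRUE when `fn` accepts an n x 3 x B array.
#' @param name Display name.
#' @return Object of class `denoiser`.
#' @export
new_denoiser <- function(fn, n_residues = NULL, batched = FALSE,
                         name = "denoiser") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, n_residues = n_residues, batched = batched,
                 name = name), class = "denoiser")
}

#' @export
print.denoiser <- function(x, ...) {
  cat(sprintf("<denoiser '%s'%s%s>\n", x$name,
              if (is.null(x$n_residues)) "" else sprintf(", N = %d", x$n_residues),
              if (x$batched) ", batched" else ""))
  invisible(x)
}

call_denoiser <- function(denoiser, x, t) {
  out <- denoiser$fn(x, t)
  if (!all(is.finite(out)))
    stop("denoiser returned non-finite values at t = ", signif(t, 4))
  out
}

#' Analytic optimal denoiser for Gaussian data
#'
#' For clean data distributed as `N(mu, Sigma)` over the CA rows (columns
#' treated via the full `3N`-dimensional mean/covariance in whitened space),
#' the posterior mean `E[x0 | x_t]` has the closed form
#' `mu + alpha Sigma_z (alpha^2 Sigma_z + sigma^2 I)^-1 (z_t - alpha mu)` in
#' whitened coordinates.  Used as the exactly-solvable reference model for
#' sampler validation ("Gaussian toy").
#'
#' @param prior A `polymer_prior` (typically `n_residues = 1`,
#'   `centroid_sigma = 1`, for which whitening is the identity).
#' @param schedule A `diffusion_schedule`.
#' @param mean 3-vector (or N x 3 matrix) data mean in coordinate space.
#' @param cov 3 x 3 covariance across the spatial dimensions (single-residue
#'   toy) in coordinate space.
#' @return A batched `denoiser`.
#' @export
gaussian_toy_denoiser <- function(prior, schedule, mean, cov) {
  if (prior$n_residues != 1L)
    stop("the analytic Gaussian toy is defined for single-point (N = 1) priors")
  mu <- as.numeric(mean)
  Sg <- as.matrix(cov)
  if (length(mu) != 3L || !all(dim(Sg) == c(3L, 3L)))
    stop("mean must be length 3 and cov 3 x 3")
  cs <- prior$centroid_sigma
  if (cs <= 0) stop("toy prior needs centroid_sigma > 0")
  fn <- function(x, t) {
    a <- schedule$alpha(t); s2 <- schedule$sigma(t)^2
    X <- if (length(dim(x)) == 3L) matrix(aperm(x, c(3L, 2L, 1L)), ncol = 3L)
    else matrix(x, ncol = 3L)
    # whitened variable is x / cs; covariances scale accordingly
    Sz <- Sg / cs^2
    muz <- mu / cs
    G <- a * Sz %*% solve(a^2 * Sz + s2 * diag(3))
    Z <- X / cs
    X0z <- sweep(sweep(Z, 2L, a * muz) %*% t(G), 2L, muz, "+")
    X0 <- X0z * cs
    if (length(dim(x)) == 3L) aperm(array(t(X0), dim = c(3L, 1L, nrow(X0))), c(2L, 1L, 3L))
    else matrix(X0, nrow = 1L)
  }
  new_denoiser(fn, n_residues = 1L, batched = TRUE, name = "gaussian-toy")
}

#' Identity denoiser (baseline)
#'
#' Returns `x_t` unchanged; the reference baseline that a trained denoiser
#' must beat on held-out denoising error.
#' @return A `denoiser`.
#' @export
identity_denoiser <- function() {
  new_denoiser(function(x, t) x, batched = TRUE, name = "identity")
}

#' Score of the time-t marginal from a denoiser
#'
#' Standard diffusion identity: with prior covariance `C`,
#' `score = C^+ (alpha(t) xhat0 - x_t) / sigma(t)^2` where `xhat0` is the
#' denoiser prediction.  For the analytic Gaussian denoiser this equals the
#' exact `grad log p_t`.
#'
#' @param prior A `polymer_prior`.
#' @param schedule A `diffusion_schedule`.
#' @param denoiser A `denoiser`.
#' @param x_t N x 3 coordinate matrix.
#' @param t Diffusion time in (0, 1].
#' @return N x 3 score array (coordinate space).
#' @export
score_from_denoiser <- function(prior, schedule, denoiser, x_t, t) {
  check_t(t, allow_zero = FALSE)
  x_t <- as_coord_matrix(x_t, "x_t")
  xhat <- call_denoiser(denoiser, x_t, t)
  a <- schedule$alpha(t); s2 <- schedule$sigma(t)^2
  resid <- a * xhat - x_t
  # C^+ r = Rinv^T Rinv r
  t(prior$factor_inv) %*% (prior$factor_inv %*% resid) / s2
}

#' Sampler settings for the reverse diffusion
#'
#' `inverse_temperature` (lambda >= 1) rescales the score and divides the
#' injected noise variance, biasing samples toward high-likelihood states at
#' the cost of diversity; `langevin_factor` (psi >= 0) adds that many
#' Langevin corrector sub-steps per grid step at the same temperature.
#' `lambda = 1, psi = 0` is the standard ancestral reverse process.
#'
#' @param inverse_temperature Lambda >= 1.
#' @param langevin_factor Psi >= 0 (integer number of corrector sub-steps).
#' @param n_steps Reverse grid size (>= 2).
#' @param seed Optional seed.
#' @return Object of class `sampler_settings`.
#' @export
sampler_settings <- function(inverse_temperature = 1, langevin_factor = 0,
                             n_steps = 200L, seed = NULL) {
  stopifnot_scalar(inverse_temperature, "inverse_temperature", min = 1)
  stopifnot_scalar(langevin_factor, "langevin_factor", min = 0)
  stopifnot_scalar(n_steps, "n_steps", min = 2)
  structure(list(inverse_temperature = inverse_temperature,
                 langevin_factor = as.integer(langevin_factor),
                 n_steps = as.integer(n_steps), seed = seed),
            class = "sampler_settings")
}

# One reverse predictor step + psi corrector sub-steps for a batch of latent
# states Z (m x 3 x B), shared across the acceptance-grade Gaussian runs and
# structure sampling (B = 1).  `score_fn(Z_list_of_x, t)` returns the latent
# score for each batch member; hard_fn applies hard conditioner transforms in
# coordinate space.
reverse_integrate <- function(prior, schedule, settings, score_latent_fn,
                              hard_latent_fn = NULL, n_batch = 1L) {
  lam <- settings$inverse_temperature
  psi <- settings$langevin_factor
  n_steps <- settings$n_steps
  m <- prior$latent_dim
  ts <- seq(1, 0, length.out = n_steps + 1L)
  Z <- array(stats::rnorm(m * 3L * n_batch, sd = sqrt(1 / lam)),
             dim = c(m, 3L, n_batch))
  if (!is.null(hard_latent_fn)) Z <- hard_latent_fn(Z, 1)
  for (k in seq_len(n_steps)) {
    t_cur <- ts[k]; t_next <- ts[k + 1L]
    dt <- t_cur - t_next
    b <- schedule$beta(t_cur)
    S <- tryCatch(score_latent_fn(Z, t_cur), error = function(e)
      stop(sprintf("reverse step %d (t = %.4f): %s", k, t_cur,
                   conditionMessage(e)), call. = FALSE))
    noise <- array(stats::rnorm(length(Z)), dim = dim(Z))
    # score scaled by lambda; injected noise variance scaled by 1/lambda
    Z <- Z + (b / 2 * Z + (b / lam) * (lam * S)) * dt +
      sqrt(b * dt / lam) * noise
    if (!is.null(hard_latent_fn)) Z <- hard_latent_fn(Z, t_next)
    if (psi > 0L && t_next > 0) {
      eps <- 0.1 * schedule$sigma(t_next)^2 / lam
      for (j in seq_len(psi)) {
        Sc <- score_latent_fn(Z, t_next)
        xi <- array(stats::rnorm(length(Z)), dim = dim(Z))
        Z <- Z + eps * lam * Sc + sqrt(2 * eps) * xi
        if (!is.null(hard_latent_fn)) Z <- hard_latent_fn(Z, t_next)
      }
    }
  }
  Z
}

#' Reverse-time diffusion sampling of CA coordinate fields
#'
#' Integrates the reverse SDE in whitened space (Euler-Maruyama on a uniform
#' grid) from t = 1 to t = 0, with the low-temperature modification of
#' [sampler_settings()] and optional conditioners.  This is the low-level
#' engine behind [reverse_sample()]; it returns raw CA matrices and supports
#' batched runs for distribution-level validation.
#'
#' @inheritParams score_from_denoiser
#' @param settings A `sampler_settings`.
#' @param conditioners A conditioner (or list of conditioners) or NULL.
#' @param n_samples Number of independent chains.
#' @return List of N x 3 CA matrices (length `n_samples`).
#' @export
sample_reverse_latent <- function(prior, schedule, denoiser, settings,
                                  conditioners = NULL, n_samples = 1L) {
  stopifnot_scalar(n_samples, "n_samples", min = 1)
  conds <- normalize_conditioners(conditioners)
  lam <- settings$inverse_temperature
  batched_ok <- isTRUE(denoiser$batched) && is.null(conds)
  a_fun <- schedule$alpha; s_fun <- schedule$sigma
  R <- prior$factor; Rinv <- prior$factor_inv
  unwh_batch <- function(Z) {
    X <- array(0, dim = c(prior$n_residues, 3L, dim(Z)[3L]))
    for (d in 1:3) X[, d, ] <- R %*% matrix(Z[, d, ], nrow = dim(Z)[1L])
    X
  }
  wh_batch <- function(X) {
    Z <- array(0, dim = c(prior$latent_dim, 3L, dim(X)[3L]))
    for (d in 1:3) Z[, d, ] <- Rinv %*% matrix(X[, d, ], nrow = dim(X)[1L])
    Z
  }
  score_latent <- function(Z, t) {
    a <- a_fun(t); s2 <- s_fun(t)^2
    X <- unwh_batch(Z)
    B <- dim(Z)[3L]
    Xhat <- if (batched_ok) {
      out <- denoiser$fn(X, t)
      if (!all(is.finite(out))) stop("denoiser returned non-finite values at t = ",
                                     signif(t, 4))
      out
    } else {
      out <- array(0, dim = dim(X))
      for (bi in seq_len(B))
        out[, , bi] <- call_denoiser(denoiser, X[, , bi, drop = TRUE] |>
                                       matrix(ncol = 3L), t)
      out
    }
    S <- (a * wh_batch(Xhat) - Z) / s2
    if (!is.null(conds)) {
      # soft-energy guidance: annealed by alpha(t)^2 (energies are defined
      # on clean-structure geometry, so guidance ramps in as the signal
      # does) and norm-clipped to keep the guided SDE non-stiff at high
      # noise levels
      anneal <- a^2
      for (bi in seq_len(dim(Z)[3L])) {
        g <- conditioner_grad(conds, matrix(X[, , bi], ncol = 3L), t)
        if (!is.null(g)) {
          gz <- anneal * (t(R) %*% g)
          gn <- sqrt(mean(gz^2))
          if (is.finite(gn) && gn > 3) gz <- gz * (3 / gn)
          S[, , bi] <- S[, , bi] - gz
        }
      }
    }
    S
  }
  hard_latent <- if (!is.null(conds) && has_hard(conds)) {
    function(Z, t) {
      for (bi in seq_len(dim(Z)[3L])) {
        x <- matrix(unwhiten(prior, matrix(Z[, , bi], ncol = 3L)), ncol = 3L)
        x2 <- conditioner_hard(conds, x, t)
        Z[, , bi] <- whiten(prior, x2)
      }
      Z
    }
  } else NULL
  Zfin <- with_seed(settings$seed,
                    reverse_integrate(prior, schedule, settings, score_latent,
                                      hard_latent, n_batch = as.integer(n_samples)))
  out <- lapply(seq_len(dim(Zfin)[3L]), function(bi) {
    x <- matrix(unwhiten(prior, matrix(Zfin[, , bi], ncol = 3L)), ncol = 3L)
    if (!is.null(conds)) x <- conditioner_hard(conds, x, 0)
    x
  })
  out
}

#' Sample a backbone structure by reverse diffusion
#'
#' Runs [sample_reverse_latent()] for a single chain of the reverse process
#' and assembles a `backbone_structure` (N, C, O rebuilt from the CA trace;
#' conditioner `finalize` hooks applied, e.g. exact substructure copy-in or
#' chain relabelling of symmetric complexes).
#'
#' @inheritParams sample_reverse_latent
#' @param n_residues Length of the sampled chain (ignored when `prior` is
#'   given explicitly sized).
#' @return A `backbone_structure`.
#' @export
reverse_sample <- function(prior, schedule, denoiser, settings,
                           n_residues = prior$n_residues,
                           conditioners = NULL) {
  if (!is.null(denoiser$n_residues) && denoiser$n_residues != prior$n_residues)
    stop("denoiser expects a different residue count than the prior")
  ca <- sample_reverse_latent(prior, schedule, denoiser, settings,
                              conditioners, n_samples = 1L)[[1L]]
  st <- backbone_structure(ca)
  conds <- normalize_conditioners(conditioners)
  if (!is.null(conds)) st <- conditioner_finalize(conds, st)
  st
}
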