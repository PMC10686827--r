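#' Chain- and Rg-constrained Gaussian prior over CA coordinates
#'
#' The prior over an N-residue CA field is a correlated Gaussian built from a
#' discrete random walk along the chain (cumulative sum of i.i.d. Gaussian
#' steps) with the centroid projected out, rescaled so that the ensemble-mean
#' squared radius of gyration obeys the globular scaling law
#' `E[Rg^2] = r0^2 * N^(2 nu)` exactly, plus an optional independent global
#' translation mode of variance `centroid_sigma^2` per coordinate.  Adjacent
#' residues are therefore more strongly correlated than distant ones (chain
#' constraint) while the overall size follows the stated Rg law.
#'
#' The same covariance applies independently to each of the three spatial
#' dimensions.  Its symmetric eigendecomposition provides the factor `R`
#' (`cov = R R^T`) used by [unwhiten()] and the (pseudo-)inverse map used by
#' [whiten()]; with `centroid_sigma = 0` the covariance has rank N-1 and the
#' whitening pair is mutually inverse on the centred subspace.
#'
#' @param n_residues Number of residues (>= 1).
#' @param r0 Rg prefactor in angstroms (> 0).
#' @param nu Rg scaling exponent, in (0, 1).
#' @param centroid_sigma Standard deviation (A) of the global translation
#'   mode; 0 pins the centroid at the origin.
#' @return An object of class `polymer_prior` with elements `n_residues`,
#'   `r0`, `nu`, `centroid_sigma`, `factor` (N x m), `factor_inv` (m x N),
#'   `cov` (N x N) and `latent_dim` m.
#' @export
polymer_prior <- function(n_residues, r0 = 2.0, nu = 0.4, centroid_sigma = 0) {
  stopifnot_scalar(n_residues, "n_residues", min = 1)
  stopifnot_scalar(r0, "r0")
  if (r0 <= 0) stop("r0 must be > 0")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu >= 1)
    stop("nu must lie strictly inside (0, 1)")
  stopifnot_scalar(centroid_sigma, "centroid_sigma", min = 0)
  n <- as.integer(n_residues)
  if (n == 1L) {
    C <- matrix(centroid_sigma^2, 1L, 1L)
  } else {
    idx <- seq_len(n)
    W <- outer(idx, idx, pmin)          # random-walk covariance, unit steps
    P <- diag(n) - matrix(1 / n, n, n)  # centroid projector
    Cw <- P %*% W %*% P
    # per-coordinate E[Rg^2] contribution is tr(Cw)/n; three dimensions
    scale <- r0^2 * n^(2 * nu) * n / (3 * sum(diag(Cw)))
    C <- scale * Cw + centroid_sigma^2 * matrix(1, n, n)
    C <- (C + t(C)) / 2
  }
  eig <- eigen(C, symmetric = TRUE)
  keep <- eig$values > max(eig$values, 0) * 1e-10
  if (!any(keep)) {
    R <- matrix(0, n, 0L); Rinv <- matrix(0, 0L, n)
  } else {
    lam <- eig$values[keep]
    U <- eig$vectors[, keep, drop = FALSE]
    R <- U %*% diag(sqrt(lam), length(lam))
    Rinv <- diag(1 / sqrt(lam), length(lam)) %*% t(U)
  }
  structure(list(n_residues = n, r0 = r0, nu = nu,
                 centroid_sigma = centroid_sigma,
                 factor = R, factor_inv = Rinv, cov = C,
                 latent_dim = ncol(R)),
            class = "polymer_prior")
}

#' @export
print.polymer_prior <- function(x, ...) {
  cat(sprintf(
    "<polymer_prior: N = %d, r0 = %g A, nu = %g, centroid_sigma = %g A, rank %d>\n",
    x$n_residues, x$r0, x$nu, x$centroid_sigma, x$latent_dim))
  cat(sprintf("  E[Rg^2] = %g A^2 (Rg law r0^2 N^(2 nu))\n",
              x$r0^2 * x$n_residues^(2 * x$nu)))
  invisible(x)
}

#' Expected squared radius of gyration under a polymer prior
#' @param prior A `polymer_prior`.
#' @return `r0^2 * N^(2 nu)` (0 for a single residue).
#' @export
prior_rg2 <- function(prior) {
  if (prior$n_residues == 1L) 0 else prior$r0^2 * prior$n_residues^(2 * prior$nu)
}

#' Map latent (whitened) variables to correlated CA coordinates
#'
#' `unwhiten` applies the covariance factor `R` to each spatial dimension,
#' so i.i.d. standard-normal latents become draws from the prior; [whiten()]
#' is its (pseudo-)inverse.
#'
#' @param prior A `polymer_prior`.
#' @param latent m x k matrix (k columns, usually 3 spatial dimensions) or a
#'   length-m vector.
#' @return N x k matrix (or length-N vector for vector input).
#' @export
unwhiten <- function(prior, latent) {
  vec <- is.null(dim(latent))
  if (vec) latent <- matrix(latent, ncol = 1L)
  if (nrow(latent) != prior$latent_dim)
    stop(sprintf("latent has %d rows; prior latent dimension is %d",
                 nrow(latent), prior$latent_dim))
  out <- prior$factor %*% latent
  if (vec) as.numeric(out) else out
}

#' Whitening transform of a polymer prior
#' @param prior A `polymer_prior`.
#' @param coords N x k coordinate matrix (or length-N vector).
#' @return m x k latent matrix (or length-m vector).
#' @export
whiten <- function(prior, coords) {
  vec <- is.null(dim(coords))
  if (vec) coords <- matrix(coords, ncol = 1L)
  if (nrow(coords) != prior$n_residues)
    stop(sprintf("coords has %d rows; prior is over %d residues",
                 nrow(coords), prior$n_residues))
  out <- prior$factor_inv %*% coords
  if (vec) as.numeric(out) else out
}

#' Draw CA fields from a polymer prior
#'
#' Each sample is `unwhiten(z)` with `z` i.i.d. standard normal; seeded draws
#' are reproducible.
#'
#' @param prior A `polymer_prior`.
#' @param n_samples Number of draws (>= 1).
#' @param seed Optional seed.
#' @return List of N x 3 CA coordinate matrices.
#' @export
sample_prior <- function(prior, n_samples, seed = NULL) {
  stopifnot_scalar(n_samples, "n_samples", min = 1)
  m <- prior$latent_dim
  with_seed(seed, lapply(seq_len(n_samples), function(i)
    unwhiten(prior, matrix(stats::rnorm(m * 3L), m, 3L))))
}
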