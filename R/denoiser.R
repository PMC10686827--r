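#' Random-graph message-passing denoiser
#'
#' The trainable denoiser predicts, for every edge of a freshly built random
#' geometry graph over the noisy structure, the clean-structure position of
#' residue j in residue i's backbone frame together with a confidence
#' weight, and then synthesizes global coordinates with [solve_consensus()].
#' All network inputs are rototranslation-invariant edge features and all
#' outputs live in local frames, so the full map is SE(3)-equivariant by
#' construction (and tested numerically).  Message passing is a small
#' multilayer perceptron over the per-edge feature vector; the architecture
#' is deliberately compact so that training on a few hundred synthetic
#' backbones takes minutes on one CPU.
#'
#' @name backbone_denoiser
NULL

feat_dim <- 14L

# Per-edge feature matrix: distance, direction and relative orientation of
# j in i's frame, sequence offset, chain flag, t.
edge_feature_matrix <- function(ef, t) {
  soff <- pmax(pmin(ef$seq_offset, 32L), -32L) / 32
  cbind(ef$dist / 10, ef$unit, ef$quat, soff, ef$same_chain, t, ef$rel_pos / 10)
}

# One message-passing round: an edge encoder, mean-aggregation of edge
# messages into node embeddings, and an edge decoder reading the raw edge
# features together with both endpoint embeddings.
init_mlp_params <- function(hidden, seed) {
  with_seed(seed, {
    glorot <- function(n_in, n_out)
      matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
    list(W1 = glorot(feat_dim, hidden), b1 = rep(0, hidden),
         Wn = glorot(hidden, hidden), bn = rep(0, hidden),
         W2 = glorot(feat_dim + 2L * hidden, hidden), b2 = rep(0, hidden),
         W3 = glorot(hidden, 4L) * 0.1, b3 = rep(0, 4L))
  })
}

mlp_forward <- function(params, F, edges, n_nodes) {
  i <- edges[, 1L]; j <- edges[, 2L]
  H1 <- tanh(sweep(F %*% params$W1, 2L, params$b1, "+"))
  agg <- rowsum(H1, i, reorder = FALSE)
  nodes <- as.integer(rownames(agg))
  deg <- as.numeric(rowsum(rep(1, nrow(F)), i, reorder = FALSE))
  M <- matrix(0, n_nodes, ncol(H1))
  M[nodes, ] <- agg / deg
  N1 <- tanh(sweep(M %*% params$Wn, 2L, params$bn, "+"))
  G <- cbind(F, N1[i, , drop = FALSE], N1[j, , drop = FALSE])
  H2 <- tanh(sweep(G %*% params$W2, 2L, params$b2, "+"))
  out <- sweep(H2 %*% params$W3, 2L, params$b3, "+")
  list(out = out, H1 = H1, H2 = H2, F = F, G = G, M = M, N1 = N1,
       deg = deg, nodes = nodes, edges = edges, n_nodes = n_nodes)
}

mlp_backward <- function(params, fwd, d_out) {
  i <- fwd$edges[, 1L]; j <- fwd$edges[, 2L]
  h <- ncol(fwd$H1); fd <- ncol(fwd$F)
  gW3 <- crossprod(fwd$H2, d_out); gb3 <- colSums(d_out)
  dH2 <- d_out %*% t(params$W3)
  dA2 <- dH2 * (1 - fwd$H2^2)
  gW2 <- crossprod(fwd$G, dA2); gb2 <- colSums(dA2)
  dG <- dA2 %*% t(params$W2)
  dN1 <- matrix(0, fwd$n_nodes, h)
  acc_i <- rowsum(dG[, fd + seq_len(h), drop = FALSE], i, reorder = FALSE)
  acc_j <- rowsum(dG[, fd + h + seq_len(h), drop = FALSE], j, reorder = FALSE)
  dN1[as.integer(rownames(acc_i)), ] <- dN1[as.integer(rownames(acc_i)), ] + acc_i
  dN1[as.integer(rownames(acc_j)), ] <- dN1[as.integer(rownames(acc_j)), ] + acc_j
  dAn <- dN1 * (1 - fwd$N1^2)
  gWn <- crossprod(fwd$M, dAn); gbn <- colSums(dAn)
  dM <- dAn %*% t(params$Wn)
  degv <- rep(0, fwd$n_nodes); degv[fwd$nodes] <- fwd$deg
  dH1 <- dM[i, , drop = FALSE] / degv[i]
  dA1 <- dH1 * (1 - fwd$H1^2)
  gW1 <- crossprod(fwd$F, dA1); gb1 <- colSums(dA1)
  list(W1 = gW1, b1 = gb1, Wn = gWn, bn = gbn, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3)
}

# Edge predictions from the network: local target position (current relative
# position plus a learned correction) and a positive confidence weight.
# Both heads are preconditioned on the noise level: the correction is scaled
# by ~10 sigma(t) (the coordinate-space noise scale) and the log-confidence
# is offset by its matching inverse variance, so the network only has to
# learn O(1) residuals across the whole time range.
edge_predictions_from_net <- function(params, Fmat, rel_pos, sigma_t,
                                      edges, n_nodes) {
  fwd <- mlp_forward(params, Fmat, edges, n_nodes)
  scale <- max(10 * sigma_t, 0.05)
  delta <- fwd$out[, 1:3, drop = FALSE] * scale
  logw <- pmin(pmax(fwd$out[, 4L] - 2 * log(scale), -9), 9)
  list(pred = rel_pos + delta, w = exp(logw), fwd = fwd, logw = logw,
       scale = scale)
}

#' Forward pass of the graph denoiser
#'
#' Builds a fresh random graph over the noisy coordinates, featurizes the
#' edges, runs the network to predict per-edge inter-residue geometries and
#' confidences, and solves for the consensus structure (warm-started at the
#' input, so the output stays in the input's pose).
#'
#' @param fit A `backbone_denoiser` (trained or freshly initialized).
#' @param x_t Noisy CA coordinates (n x 3 matrix) or a `backbone_structure`.
#' @param t Diffusion time.
#' @param graph_seed Optional seed for the random graph (when NULL the
#'   current RNG stream is used, so sampling remains reproducible under the
#'   sampler's master seed).
#' @return List: `x0` (denoised n x 3 CA matrix), `edge_predictions`
#'   (an `edge_geometry`), `graph`.
#' @export
denoiser_forward <- function(fit, x_t, t, graph_seed = NULL) {
  stopifnot(inherits(fit, "backbone_denoiser"))
  ca <- if (inherits(x_t, "backbone_structure")) ca_coords(x_t) else
    as_coord_matrix(x_t, "x_t")
  chain <- if (inherits(x_t, "backbone_structure")) x_t$chain else
    rep("A", nrow(ca))
  cfg <- fit$graph
  g <- build_graph(ca, cfg$k_local, cfg$k_random, cfg$exponent_p,
                   seed = graph_seed, chain = chain)
  ef <- edge_features_from_frames(frames_from_ca(ca, chain), g)
  Fmat <- edge_feature_matrix(ef, t)
  sig <- if (t <= 0) 0 else
    sqrt(stats::plogis(-(fit$logsnr[1L] - (fit$logsnr[1L] - fit$logsnr[2L]) * t)))
  np <- edge_predictions_from_net(fit$params, Fmat, ef$rel_pos, sig,
                                  g$edges, g$n_nodes)
  if (!all(is.finite(np$pred)))
    stop("non-finite activations in the denoiser output layer")
  eg <- edge_geometry(np$pred, np$w)
  x0 <- solve_consensus(eg, g, ca, n_iters = fit$consensus_iters,
                        tol = fit$consensus_tol, init = "frames")
  list(x0 = x0, edge_predictions = eg, graph = g)
}

#' Wrap a trained fit (or analytic model) as a sampler denoiser
#'
#' @param x A `backbone_denoiser` fit or a `denoiser`.
#' @param ... Passed on (unused).
#' @return A `denoiser` for [reverse_sample()].
#' @export
as_denoiser <- function(x, ...) UseMethod("as_denoiser")

#' @export
as_denoiser.denoiser <- function(x, ...) x

#' @export
as_denoiser.backbone_denoiser <- function(x, ...) {
  new_denoiser(function(xt, t) denoiser_forward(x, xt, t)$x0,
               n_residues = NULL, batched = FALSE, name = "graph-denoiser")
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the graph denoiser at desk scale
#'
#' Minimizes the expected edge-geometry denoising error over uniformly
#' sampled diffusion times: for each training structure and step, noisy
#' coordinates are drawn from the forward marginal, a random graph is built
#' on them, and the network regresses the clean inter-residue geometries
#' (position of j's CA in i's clean backbone frame) under a Gaussian
#' heteroscedastic loss `w |err|^2 - 3 log w` that also trains the
#' confidence weights.  The loss never passes through the consensus solver,
#' which keeps CPU training in the minutes range for a few hundred
#' structures of up to ~100 residues.
#'
#' @param synthetic_set List of `backbone_structure` training examples
#'   (e.g. from [make_synthetic_set()]).
#' @param schedule A `diffusion_schedule`.
#' @param n_epochs Training epochs.
#' @param seed Master seed (initialization, t and noise draws, graphs).
#' @param hidden Hidden width of the edge MLP.
#' @param k_local,k_random,exponent_p Graph construction settings.
#' @param r0,nu Polymer-prior parameters used for the forward noising.
#' @param lr Adam learning rate.
#' @param t_min Smallest diffusion time sampled during training.
#' @param consensus_iters,consensus_tol Consensus settings stored for
#'   inference.
#' @param init_params Optional parameter list to resume from.
#' @return An object of class `backbone_denoiser`.
#' @export
train_denoiser <- function(synthetic_set, schedule = diffusion_schedule(),
                           n_epochs = 20L, seed = 1L, hidden = 48L,
                           k_local = 12L, k_random = 6L, exponent_p = 2,
                           r0 = 2.0, nu = 0.4, lr = 1e-3, t_min = 0.02,
                           consensus_iters = 4L, consensus_tol = 1e-4,
                           init_params = NULL) {
  if (!length(synthetic_set)) stop("empty training set")
  stopifnot(all(vapply(synthetic_set, inherits, TRUE, "backbone_structure")))
  params <- init_params %||% init_mlp_params(hidden, derive_seed(seed, 1L))
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  priors <- list()
  get_prior <- function(n) {
    key <- as.character(n)
    if (is.null(priors[[key]])) priors[[key]] <<- polymer_prior(n, r0, nu)
    priors[[key]]
  }
  loss_history <- numeric(n_epochs)
  with_seed(derive_seed(seed, 2L), {
    for (ep in seq_len(n_epochs)) {
      ord <- sample(length(synthetic_set))
      ep_loss <- 0
      for (si in ord) {
        st <- synthetic_set[[si]]
        n <- n_residues(st)
        prior <- get_prior(n)
        t <- stats::runif(1, t_min, 1)
        a <- schedule$alpha(t); s <- schedule$sigma(t)
        z <- matrix(stats::rnorm(prior$latent_dim * 3L), prior$latent_dim, 3L)
        ca_t <- a * ca_coords(st) + s * unwhiten(prior, z)
        g <- build_graph(ca_t, k_local, k_random, exponent_p, chain = st$chain)
        fr_t <- frames_from_ca(ca_t, st$chain)
        ef_t <- edge_features_from_frames(fr_t, g)
        Fmat <- edge_feature_matrix(ef_t, t)
        ed <- g$edges
        # clean relative displacement expressed in the *noisy* frame of i:
        # the frame is known to the network, and the consensus solver's
        # Procrustes stage absorbs any common per-node rotation, so this
        # convention removes the unlearnable frame-mismatch noise from the
        # regression target
        ca0 <- ca_coords(st)
        target <- frame_pullback(fr_t$rot[ed[, 1L], , drop = FALSE],
                                 ca0[ed[, 2L], , drop = FALSE] -
                                   ca0[ed[, 1L], , drop = FALSE])
        np <- edge_predictions_from_net(params, Fmat, ef_t$rel_pos, s,
                                        ed, n)
        err <- np$pred - target
        err2 <- rowSums(err^2)
        loss <- mean(np$w * err2 - 3 * np$logw)
        if (!is.finite(loss)) stop("divergent (non-finite) loss at epoch ", ep)
        E <- nrow(ed)
        d_out <- cbind(2 * np$w * err * np$scale, (np$w * err2 - 3)) / E
        d_out[, 4L][np$logw <= -9 | np$logw >= 9] <- 0
        grads <- mlp_backward(params, np$fwd, d_out)
        upd <- adam_update(params, grads, state, lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss
      }
      loss_history[ep] <- ep_loss / length(synthetic_set)
    }
  })
  structure(list(params = params, hidden = as.integer(hidden),
                 graph = list(k_local = as.integer(k_local),
                              k_random = as.integer(k_random),
                              exponent_p = exponent_p),
                 prior_params = list(r0 = r0, nu = nu),
                 consensus_iters = as.integer(consensus_iters),
                 consensus_tol = consensus_tol,
                 logsnr = c(schedule$logsnr_max, schedule$logsnr_min),
                 loss_history = loss_history,
                 n_train = length(synthetic_set),
                 version = 1L),
            class = "backbone_denoiser")
}

#' @export
print.backbone_denoiser <- function(x, ...) {
  cat(sprintf("<backbone_denoiser: hidden %d, k_local %d + k_random %d, %d epochs on %d structures>\n",
              x$hidden, x$graph$k_local, x$graph$k_random,
              length(x$loss_history), x$n_train))
  if (length(x$loss_history))
    cat(sprintf("  loss %0.4f -> %0.4f\n", x$loss_history[1L],
                utils::tail(x$loss_history, 1L)))
  invisible(x)
}

#' @export
summary.backbone_denoiser <- function(object, ...) {
  np <- sum(vapply(object$params, length, 1L))
  cat("Graph message-passing backbone denoiser\n")
  cat(sprintf("  parameters      : %d\n", np))
  cat(sprintf("  hidden width    : %d\n", object$hidden))
  cat(sprintf("  graph           : k_local %d, k_random %d, p = %g\n",
              object$graph$k_local, object$graph$k_random, object$graph$exponent_p))
  cat(sprintf("  prior           : r0 = %g, nu = %g\n",
              object$prior_params$r0, object$prior_params$nu))
  cat(sprintf("  training        : %d epochs on %d structures; final loss %0.4f\n",
              length(object$loss_history), object$n_train,
              utils::tail(object$loss_history, 1L)))
  invisible(object)
}

#' @export
coef.backbone_denoiser <- function(object, ...) {
  unlist(object$params)
}

#' @export
plot.backbone_denoiser <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "mean edge loss",
                 main = "denoiser training loss", ...)
  invisible(x)
}

#' @export
predict.backbone_denoiser <- function(object, newdata, t = 0.2,
                                      graph_seed = NULL, ...) {
  ca0 <- denoiser_forward(object, newdata, t, graph_seed)$x0
  if (inherits(newdata, "backbone_structure")) set_ca_coords(newdata, ca0)
  else ca0
}

#' @export
simulate.backbone_denoiser <- function(object, nsim = 1, seed = NULL,
                                       n_residues = 64L,
                                       settings = NULL, schedule = NULL,
                                       conditioners = NULL, ...) {
  schedule <- schedule %||% diffusion_schedule()
  prior <- polymer_prior(n_residues, object$prior_params$r0, object$prior_params$nu)
  lapply(seq_len(nsim), function(k) {
    s <- settings %||% sampler_settings()
    s$seed <- derive_seed(seed %||% 1L, k)
    reverse_sample(prior, schedule, as_denoiser(object), s,
                   conditioners = conditioners)
  })
}

#' Held-out denoising residuals
#'
#' Per-structure RMSD (after optimal rigid superposition) between the
#' denoised prediction and the clean structure at diffusion time `t`,
#' together with the identity-baseline RMSD (`xhat = x_t`).
#'
#' @param object A `backbone_denoiser`.
#' @param structures List of clean `backbone_structure` objects.
#' @param t Diffusion time of the noise applied before denoising.
#' @param seed Seed for the noise draws.
#' @param ... Unused.
#' @return Data frame with columns `rmsd` (denoiser) and `rmsd_identity`.
#' @export
residuals.backbone_denoiser <- function(object, structures, t = 0.2,
                                        seed = 1L, ...) {
  schedule <- diffusion_schedule()
  out <- with_seed(seed, {
    do.call(rbind, lapply(structures, function(st) {
      n <- n_residues(st)
      prior <- polymer_prior(n, object$prior_params$r0, object$prior_params$nu)
      a <- schedule$alpha(t); s <- schedule$sigma(t)
      z <- matrix(stats::rnorm(prior$latent_dim * 3L), prior$latent_dim, 3L)
      ca_t <- a * ca_coords(st) + s * unwhiten(prior, z)
      x0 <- denoiser_forward(object, ca_t, t)$x0
      data.frame(rmsd = kabsch_rmsd(x0, ca_coords(st)),
                 rmsd_identity = kabsch_rmsd(ca_t, ca_coords(st)))
    }))
  })
  rownames(out) <- NULL
  out
}

#' Save / load denoiser checkpoints
#'
#' Checkpoints are R serialization files holding the full fit object,
#' including a `version` field checked on load.
#'
#' @param fit A `backbone_denoiser`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `backbone_denoiser` (load).
#' @export
save_denoiser <- function(fit, path) {
  stopifnot(inherits(fit, "backbone_denoiser"))
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version) || obj$version != 1L)
    stop("unsupported checkpoint version in ", path)
  structure(obj, class = "backbone_denoiser")
}
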