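#' Composable conditioners
#'
#' A conditioner contributes, inside every reverse-diffusion step, any of:
#' a hard coordinate transform (applied after each predictor/corrector
#' update; required to be idempotent), a soft energy with gradient (added to
#' the score before the update), a structure-level `apply` used outside the
#' sampler, and a `finalize` hook run on the assembled output structure.
#'
#' @param name Display name.
#' @param hard Function `(coords, t) -> coords` or NULL.
#' @param energy Function `(coords, t) -> scalar` or NULL.
#' @param grad Function `(coords, t) -> n x 3 gradient` or NULL.
#' @param apply_structure Function `(structure, t) -> structure` or NULL.
#' @param finalize Function `(structure) -> structure` or NULL.
#' @param params List of parameters (metadata).
#' @return Object of class `conditioner`.
#' @export
new_conditioner <- function(name, hard = NULL, energy = NULL, grad = NULL,
                            apply_structure = NULL, finalize = NULL,
                            params = list()) {
  structure(list(name = name, hard = hard, energy = energy, grad = grad,
                 apply_structure = apply_structure, finalize = finalize,
                 params = params),
            class = "conditioner")
}

#' @export
print.conditioner <- function(x, ...) {
  caps <- c(if (!is.null(x$hard)) "hard", if (!is.null(x$energy)) "energy")
  cat(sprintf("<conditioner '%s' [%s]>\n", x$name,
              paste(caps, collapse = "+")))
  invisible(x)
}

normalize_conditioners <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "conditioner")) return(x)
  if (is.list(x)) {
    if (!length(x)) return(NULL)
    return(compose_conditioners(x))
  }
  stop("conditioners must be a conditioner object or a list of them")
}

has_hard <- function(cond) !is.null(cond$hard)

conditioner_hard <- function(cond, coords, t) {
  if (is.null(cond) || is.null(cond$hard)) return(coords)
  cond$hard(coords, t)
}

conditioner_energy <- function(cond, coords, t) {
  if (is.null(cond) || is.null(cond$energy)) return(0)
  e <- cond$energy(coords, t)
  if (!is.finite(e)) stop("conditioner '", cond$name, "' produced a non-finite energy")
  e
}

conditioner_grad <- function(cond, coords, t) {
  if (is.null(cond) || is.null(cond$grad)) return(NULL)
  g <- cond$grad(coords, t)
  if (!all(is.finite(g))) stop("conditioner '", cond$name, "' produced a non-finite gradient")
  g
}

conditioner_finalize <- function(cond, st) {
  if (is.null(cond) || is.null(cond$finalize)) return(st)
  cond$finalize(st)
}

#' Apply a conditioner to a structure
#'
#' Applies the hard transform at time `t` (via the conditioner's
#' structure-level handler when it has one, e.g. symmetry tessellation, and
#' otherwise through the CA field with rigid-residue displacement) and then
#' the finalize hook.
#'
#' @param conditioner A `conditioner`.
#' @param structure A `backbone_structure`.
#' @param t Diffusion time (default 0 = clean coordinates).
#' @return A `backbone_structure`.
#' @export
apply_conditioner <- function(conditioner, structure, t = 0) {
  stopifnot(inherits(conditioner, "conditioner"))
  st <- if (!is.null(conditioner$apply_structure)) {
    conditioner$apply_structure(structure, t)
  } else if (!is.null(conditioner$hard)) {
    set_ca_coords(structure, conditioner$hard(ca_coords(structure), t))
  } else structure
  conditioner_finalize(conditioner, st)
}

#' Compose conditioners
#'
#' Hard transforms are applied in list order; energies and gradients are
#' summed; finalize hooks run in order.  An empty list is the identity
#' conditioner.
#'
#' @param conditioner_list List of `conditioner` objects (possibly empty).
#' @return A `conditioner`.
#' @export
compose_conditioners <- function(conditioner_list) {
  stopifnot(all(vapply(conditioner_list, inherits, TRUE, "conditioner")))
  cl <- conditioner_list
  any_hard <- any(vapply(cl, function(c) !is.null(c$hard), TRUE))
  any_energy <- any(vapply(cl, function(c) !is.null(c$energy), TRUE))
  any_grad <- any(vapply(cl, function(c) !is.null(c$grad), TRUE))
  any_app <- any(vapply(cl, function(c) !is.null(c$apply_structure), TRUE))
  new_conditioner(
    name = paste0("compose(", paste(vapply(cl, `[[`, "", "name"), collapse = ", "), ")"),
    hard = if (any_hard) function(coords, t) {
      for (c in cl) coords <- conditioner_hard(c, coords, t)
      coords
    },
    energy = if (any_energy) function(coords, t)
      sum(vapply(cl, conditioner_energy, 0, coords = coords, t = t)),
    grad = if (any_grad) function(coords, t) {
      g <- matrix(0, nrow(coords), 3L)
      for (c in cl) {
        gc <- conditioner_grad(c, coords, t)
        if (!is.null(gc)) g <- g + gc
      }
      g
    },
    apply_structure = if (any_app || any_hard) function(st, t) {
      for (c in cl) st <- apply_conditioner(c, st, t)
      st
    },
    finalize = function(st) {
      for (c in cl) st <- conditioner_finalize(c, st)
      st
    },
    params = list(members = vapply(cl, `[[`, "", "name")))
}

## ---------------------------------------------------------------- symmetry

close_group <- function(gens, max_order = 200L) {
  key <- function(R) paste(round(R, 8), collapse = ",")
  elems <- list(diag(3))
  names(elems) <- key(diag(3))
  repeat {
    added <- FALSE
    for (a in elems) for (g in gens) {
      p <- a %*% g
      k <- key(p)
      if (is.null(elems[[k]])) {
        elems[[k]] <- p
        added <- TRUE
        if (length(elems) > max_order) stop("group closure exceeded ", max_order, " elements")
      }
    }
    if (!added) break
  }
  unname(elems)
}

#' Point-symmetry rotation groups
#'
#' Rotation groups used for symmetric assembly generation: cyclic `Cn`,
#' dihedral `Dn`, tetrahedral `T` (12 rotations), octahedral `O` (24) and
#' icosahedral `I` (60).  The polyhedral groups are built by numerical
#' closure of a generator pair and verified (closure to 1e-8, identity
#' present, expected order) rather than entered by hand.
#'
#' @param name One of `"Cn"`/`"Dn"` with a number (e.g. `"C4"`, `"D3"`) or
#'   `"T"`, `"O"`, `"I"`.
#' @return Object of class `symmetry_group`: `name`, `order`, `rotations`.
#' @export
symmetry_group <- function(name) {
  name <- toupper(trimws(name))
  phi <- (1 + sqrt(5)) / 2
  rots <- if (grepl("^C[0-9]+$", name)) {
    n <- as.integer(sub("^C", "", name))
    if (n < 1L) stop("Cn needs n >= 1")
    lapply(seq_len(n) - 1L, function(k) rotation_about_axis(c(0, 0, 1), 2 * pi * k / n))
  } else if (grepl("^D[0-9]+$", name)) {
    n <- as.integer(sub("^D", "", name))
    if (n < 1L) stop("Dn needs n >= 1")
    cn <- lapply(seq_len(n) - 1L, function(k) rotation_about_axis(c(0, 0, 1), 2 * pi * k / n))
    flips <- lapply(seq_len(n) - 1L, function(k)
      rotation_about_axis(c(cos(pi * k / n), sin(pi * k / n), 0), pi))
    c(cn, flips)
  } else if (name == "T") {
    close_group(list(rotation_about_axis(c(1, 1, 1), 2 * pi / 3),
                     rotation_about_axis(c(0, 0, 1), pi)))
  } else if (name == "O") {
    close_group(list(rotation_about_axis(c(1, 1, 1), 2 * pi / 3),
                     rotation_about_axis(c(0, 0, 1), pi / 2)))
  } else if (name == "I") {
    close_group(list(rotation_about_axis(c(0, 1, phi), 2 * pi / 5),
                     rotation_about_axis(c(0, 0, 1), pi)))
  } else stop("unknown symmetry group: ", name)
  expected <- if (grepl("^C", name)) as.integer(sub("^C", "", name))
  else if (grepl("^D", name)) 2L * as.integer(sub("^D", "", name))
  else c(T = 12L, O = 24L, I = 60L)[[name]]
  validate_group(rots, expected, name)
  structure(list(name = name, order = length(rots), rotations = rots),
            class = "symmetry_group")
}

validate_group <- function(rots, expected, name) {
  if (length(rots) != expected)
    stop(sprintf("group %s has %d elements, expected %d", name, length(rots), expected))
  key <- function(R) paste(round(R, 8), collapse = ",")
  keys <- vapply(rots, key, "")
  if (anyDuplicated(keys)) stop("duplicate group elements in ", name)
  for (R in rots) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
      stop("non-orthonormal (or improper) rotation in group ", name)
  }
  # closure
  for (i in seq_along(rots)) {
    p <- rots[[i]] %*% rots[[(i %% length(rots)) + 1L]]
    if (!key(p) %in% keys) stop("group ", name, " is not closed under composition")
  }
  invisible(TRUE)
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat(sprintf("<symmetry_group %s: order %d>\n", x$name, x$order))
  invisible(x)
}

#' Symmetry (tessellation) conditioner
#'
#' Hard transform that replicates an asymmetric unit (AU) through every
#' element of a rotation group, and re-symmetrizes complex-sized input by
#' orbit averaging: each AU atom is pulled back through all group elements,
#' averaged, and pushed forward again.  The output is exactly G-invariant
#' and the transform is idempotent.  Because the transform is an (affine)
#' projection applied after every sampler update, the injected noise is
#' effectively drawn for the asymmetric unit and tessellated, so the whole
#' reverse process is G-invariant.  A soft variant exposes the symmetry
#' deviation as a harmonic energy instead.
#'
#' @param group A `symmetry_group` (or name accepted by [symmetry_group()]).
#' @param n_au Residue count of the asymmetric unit.  If NULL it is fixed by
#'   the first input the conditioner sees (treated as the AU).
#' @param mode `"hard"` (projection, default) or `"soft"` (energy).
#' @param force_constant Spring constant for `mode = "soft"`
#'   (kcal-like units per A^2; only relative scale matters).
#' @return A `conditioner`.
#' @export
make_symmetry_conditioner <- function(group, n_au = NULL, mode = c("hard", "soft"),
                                      force_constant = 10) {
  if (is.character(group)) group <- symmetry_group(group)
  stopifnot(inherits(group, "symmetry_group"))
  mode <- match.arg(mode)
  env <- new.env(parent = emptyenv())
  env$n_au <- if (is.null(n_au)) NULL else as.integer(n_au)
  ord <- group$order
  rots <- group$rotations
  resolve <- function(nr) {
    if (is.null(env$n_au)) env$n_au <- nr
    na <- env$n_au
    if (nr == na) "au" else if (nr == na * ord) "complex"
    else stop(sprintf("symmetry conditioner: input has %d residues; expected %d (AU) or %d (complex)",
                      nr, na, na * ord))
  }
  expand_m <- function(m) do.call(rbind, lapply(rots, function(R) m %*% t(R)))
  symmetrize_m <- function(m) {
    na <- env$n_au
    au <- matrix(0, na, 3L)
    for (c in seq_len(ord)) {
      rows <- ((c - 1L) * na + 1L):(c * na)
      au <- au + m[rows, , drop = FALSE] %*% rots[[c]]  # R^T pullback: x %*% R == t(R^T x^T)
    }
    au <- au / ord
    expand_m(au)
  }
  project <- function(m) switch(resolve(nrow(m)), au = expand_m(m), complex = symmetrize_m(m))
  hard_fn <- function(coords, t) project(coords)
  energy_fn <- function(coords, t) {
    p <- project(coords)
    if (nrow(p) != nrow(coords)) return(0)  # AU input: nothing to penalize yet
    force_constant / 2 * sum((coords - p)^2)
  }
  grad_fn <- function(coords, t) {
    p <- project(coords)
    if (nrow(p) != nrow(coords)) return(matrix(0, nrow(coords), 3L))
    force_constant * (coords - p)
  }
  apply_structure <- function(st, t) {
    kind <- resolve(n_residues(st))
    na <- env$n_au
    if (kind == "au") {
      chans <- lapply(c("n", "ca", "c", "o"), function(a) expand_m(st[[a]]))
      names(chans) <- c("n", "ca", "c", "o")
      chain <- symmetric_chain_labels(st$chain, ord)
      backbone_structure(ca = chans$ca, n = chans$n, c = chans$c, o = chans$o,
                         chain = chain)
    } else {
      chans <- lapply(c("n", "ca", "c", "o"), function(a) symmetrize_m(st[[a]]))
      names(chans) <- c("n", "ca", "c", "o")
      backbone_structure(ca = chans$ca, n = chans$n, c = chans$c, o = chans$o,
                         chain = st$chain, resno = st$resno)
    }
  }
  finalize <- function(st) {
    nr <- n_residues(st)
    if (!is.null(env$n_au) && nr == env$n_au * ord &&
        length(unique(st$chain)) < ord) {
      st$chain <- symmetric_chain_labels(st$chain[seq_len(env$n_au)], ord)
      st$resno <- rep(st$resno[seq_len(env$n_au)], ord)
    }
    st
  }
  if (mode == "hard") {
    new_conditioner(paste0("symmetry:", group$name), hard = hard_fn,
                    apply_structure = apply_structure, finalize = finalize,
                    params = list(group = group, n_au = n_au, mode = mode))
  } else {
    new_conditioner(paste0("symmetry-soft:", group$name), energy = energy_fn,
                    grad = grad_fn, finalize = finalize,
                    params = list(group = group, n_au = n_au, mode = mode,
                                  force_constant = force_constant))
  }
}

symmetric_chain_labels <- function(au_chain, ord) {
  pool <- c(LETTERS, letters, as.character(0:9))
  au_ids <- unique(au_chain)
  need <- length(au_ids) * ord
  if (need > length(pool))
    stop("cannot assign ", need, " distinct single-character chain labels")
  unlist(lapply(seq_len(ord), function(c) {
    map <- stats::setNames(pool[(c - 1L) * length(au_ids) + seq_along(au_ids)], au_ids)
    unname(map[au_chain])
  }))
}

## ------------------------------------------------------------ substructure

#' Substructure (replacement / infilling) conditioner
#'
#' Clamps a set of residues to a reference structure: at each reverse step
#' the clamped CA rows are replaced by the reference coordinates noised to
#' the current time via the forward marginal (replacement conditioning, the
#' standard diffusion inpainting scheme).  The per-step noise is a
#' deterministic function of `(seed, t)`, so the hard transform is
#' idempotent at fixed t while still refreshing along the trajectory.  At
#' t = 0 clamped residues equal the reference exactly, and the finalize hook
#' copies the full reference backbone atoms into the clamped rows.
#'
#' @param reference A `backbone_structure` of the generated length.
#' @param clamp_mask Logical vector (length = residues) or integer indices
#'   of residues to clamp.
#' @param prior,schedule Prior and schedule used for the forward noising;
#'   defaults match the sampler defaults.
#' @param seed Seed of the conditioner's private noise stream.
#' @return A `conditioner`.
#' @export
make_substructure_conditioner <- function(reference, clamp_mask,
                                          prior = NULL, schedule = NULL,
                                          seed = 0L) {
  stopifnot(inherits(reference, "backbone_structure"))
  nres <- n_residues(reference)
  if (is.logical(clamp_mask)) {
    if (length(clamp_mask) > nres) stop("clamp mask longer than the structure")
    mask <- which(clamp_mask)
  } else {
    mask <- as.integer(clamp_mask)
  }
  if (length(mask) && (min(mask) < 1L || max(mask) > nres))
    stop("clamp mask indexes outside the structure")
  if (is.null(prior)) prior <- polymer_prior(nres)
  if (is.null(schedule)) schedule <- diffusion_schedule()
  ref_ca <- ca_coords(reference)
  hard_fn <- function(coords, t) {
    if (!length(mask)) return(coords)
    if (nrow(coords) != nres) stop("substructure conditioner: wrong length")
    noised <- forward_marginal(prior, schedule, ref_ca, t,
                               seed = derive_seed(seed, round(t * 1e7)))
    coords[mask, ] <- noised[mask, , drop = FALSE]
    coords
  }
  finalize <- function(st) {
    if (!length(mask)) return(st)
    for (a in c("n", "ca", "c", "o"))
      st[[a]][mask, ] <- reference[[a]][mask, , drop = FALSE]
    st
  }
  # an empty mask contributes nothing: no hard transform at all, so the
  # sampler trajectory is bit-identical to the unconditional one
  new_conditioner("substructure", hard = if (length(mask)) hard_fn,
                  finalize = finalize,
                  params = list(mask = mask, n_residues = nres, seed = seed))
}

#' Parse a chain:range clamp-mask specification
#'
#' Accepts strings like `"A:1-25"` or `"A:3-10,B:1-5"` (1-based, inclusive)
#' against a reference structure and returns the integer residue indices.
#'
#' @param ranges Character range specification.
#' @param structure Reference `backbone_structure`.
#' @return Integer vector of residue indices.
#' @export
parse_clamp_mask <- function(ranges, structure) {
  out <- integer(0)
  for (part in strsplit(ranges, ",")[[1]]) {
    m <- regmatches(part, regexec("^\\s*([^:]+):(\\d+)-(\\d+)\\s*$", part))[[1]]
    if (length(m) != 4L) stop("bad clamp range: ", part)
    ch <- m[2]; from <- as.integer(m[3]); to <- as.integer(m[4])
    idx <- which(structure$chain == ch & structure$resno >= from &
                   structure$resno <= to)
    if (!length(idx)) stop("clamp range matches no residues: ", part)
    out <- c(out, idx)
  }
  sort(unique(out))
}

## ----------------------------------------------------------------- distance

#' Pairwise distance restraint conditioner
#'
#' Harmonic energy `sum k (d_ij - d_target)^2 / 2` over CA pairs, with its
#' analytic gradient added to the score during sampling.
#'
#' @param pairs m x 2 matrix of residue indices (i != j).
#' @param targets Target distances (A, > 0), length m (recycled if scalar).
#' @param force_constant Spring constant k (per A^2).
#' @return A `conditioner`.
#' @export
make_distance_conditioner <- function(pairs, targets, force_constant = 1) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1L] == pairs[, 2L])) stop("distance restraint with i == j")
  targets <- rep_len(as.numeric(targets), nrow(pairs))
  if (any(targets <= 0)) stop("target distances must be positive")
  stopifnot_scalar(force_constant, "force_constant", min = 0)
  k <- force_constant
  energy_fn <- function(coords, t) {
    d <- sqrt(rowSums((coords[pairs[, 1L], , drop = FALSE] -
                         coords[pairs[, 2L], , drop = FALSE])^2))
    sum(k * (d - targets)^2 / 2)
  }
  grad_fn <- function(coords, t) {
    g <- matrix(0, nrow(coords), 3L)
    dv <- coords[pairs[, 1L], , drop = FALSE] - coords[pairs[, 2L], , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    coef <- k * (d - targets) / pmax(d, 1e-12)
    gg <- dv * coef
    for (r in seq_len(nrow(pairs))) {
      g[pairs[r, 1L], ] <- g[pairs[r, 1L], ] + gg[r, ]
      g[pairs[r, 2L], ] <- g[pairs[r, 2L], ] - gg[r, ]
    }
    g
  }
  new_conditioner("distance", energy = energy_fn, grad = grad_fn,
                  params = list(pairs = pairs, targets = targets, k = k))
}

## -------------------------------------------------------------------- shape

#' Entropy-regularized optimal transport between point sets
#'
#' Log-domain Sinkhorn scaling with uniform marginals and squared-Euclidean
#' ground cost.  Returns the regularized objective
#' `<P, C> + epsilon KL(P || a x b)` whose gradient in the source points is
#' `2 (r_i x_i - (P y)_i)` (envelope theorem at the optimal plan).
#'
#' @param x Source points (n x 3).
#' @param y Target points (m x 3).
#' @param epsilon Entropic regularization (A^2, > 0).
#' @param max_iter Iteration cap; a warning is issued (and the last iterate
#'   used) if the marginals have not converged.
#' @param tol Marginal L1 tolerance.
#' @return List: `cost`, `transport` (`<P,C>` part), `plan`, `grad_x`,
#'   `converged`, `iterations`.
#' @export
entropic_ot <- function(x, y, epsilon = 1, max_iter = 1000L, tol = 1e-9) {
  x <- as_coord_matrix(x, "x"); y <- as_coord_matrix(y, "y")
  stopifnot_scalar(epsilon, "epsilon")
  if (epsilon <= 0) stop("epsilon must be > 0")
  n <- nrow(x); m <- nrow(y)
  a <- rep(1 / n, n); b <- rep(1 / m, m)
  C <- outer(rowSums(x^2), rep(1, m)) + outer(rep(1, n), rowSums(y^2)) -
    2 * x %*% t(y)
  C <- pmax(C, 0)
  f <- rep(0, n); g <- rep(0, m)
  la <- log(a); lb <- log(b)
  conv <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    M <- (outer(f, g, "+") - C) / epsilon
    f <- f - epsilon * (apply(M + rep(lb, each = n), 1L, logsumexp))
    M <- (outer(f, g, "+") - C) / epsilon
    g <- g - epsilon * (apply(M + rep(la, times = m), 2L, logsumexp))
    # marginal violation of the row sums
    M <- (outer(f, g, "+") - C) / epsilon
    P <- exp(M + outer(la, lb, "+"))
    err <- sum(abs(rowSums(P) - a))
    if (err < tol) { conv <- TRUE; break }
  }
  if (!conv) warning("Sinkhorn iterations did not fully converge; using last iterate")
  transport <- sum(P * C)
  kl <- sum(P * (M))  # P * log(P/(a b)) summed, since log P = M + la + lb
  cost <- transport + epsilon * kl
  r <- rowSums(P)
  grad_x <- 2 * (x * r - P %*% y)
  list(cost = cost, transport = transport, plan = P, grad_x = grad_x,
       converged = conv, iterations = it)
}

#' Shape conditioner via entropic optimal transport
#'
#' Soft energy equal to `weight` times the entropy-regularized OT cost
#' between the structure's CA point set and a user-provided target point
#' cloud; its gradient steers sampling toward the target shape (heuristic
#' classifier guidance on geometry).
#'
#' @param point_cloud m x 3 matrix (or path readable by
#'   [read_point_cloud()]).
#' @param epsilon Entropic regularization (A^2, > 0).
#' @param weight Energy scale.
#' @param max_iter,tol Sinkhorn controls.
#' @return A `conditioner`.
#' @export
make_shape_conditioner <- function(point_cloud, epsilon = 4, weight = 1,
                                   max_iter = 800L, tol = 1e-8) {
  if (is.character(point_cloud)) point_cloud <- read_point_cloud(point_cloud)
  y <- as_coord_matrix(point_cloud, "point_cloud")
  if (nrow(y) < 1L) stop("empty point cloud")
  energy_fn <- function(coords, t)
    weight * entropic_ot(coords, y, epsilon, max_iter, tol)$cost
  grad_fn <- function(coords, t)
    weight * entropic_ot(coords, y, epsilon, max_iter, tol)$grad_x
  new_conditioner("shape-ot", energy = energy_fn, grad = grad_fn,
                  params = list(n_points = nrow(y), epsilon = epsilon,
                                weight = weight))
}

## --------------------------------------------------------------- classifier

#' Generic classifier-guidance conditioner
#'
#' Adds `guidance_scale * grad log p(c | x, t)` to the score, i.e. an energy
#' `-guidance_scale * log_prob_fn(coords, t)`.  The gradient is taken from
#' `grad_fn` when supplied and by central finite differences otherwise.
#'
#' @param log_prob_fn Function `(coords, t) -> scalar` log-probability
#'   (finite on finite input; a non-finite value aborts sampling).
#' @param guidance_scale Non-negative scale; 0 disables guidance.
#' @param grad_fn Optional analytic gradient `(coords, t) -> n x 3`.
#' @param fd_step Finite-difference step (A).
#' @return A `conditioner`.
#' @export
make_classifier_conditioner <- function(log_prob_fn, guidance_scale = 1,
                                        grad_fn = NULL, fd_step = 1e-4) {
  stopifnot_scalar(guidance_scale, "guidance_scale", min = 0)
  energy_fn <- function(coords, t) {
    lp <- log_prob_fn(coords, t)
    if (!is.finite(lp)) stop("classifier log-probability is non-finite")
    -guidance_scale * lp
  }
  grad_impl <- if (!is.null(grad_fn)) grad_fn else function(coords, t) {
    g <- matrix(0, nrow(coords), 3L)
    for (i in seq_len(nrow(coords))) for (d in 1:3) {
      xp <- coords; xp[i, d] <- xp[i, d] + fd_step
      xm <- coords; xm[i, d] <- xm[i, d] - fd_step
      g[i, d] <- (log_prob_fn(xp, t) - log_prob_fn(xm, t)) / (2 * fd_step)
    }
    g
  }
  grad_energy <- function(coords, t) {
    if (guidance_scale == 0) return(matrix(0, nrow(coords), 3L))
    g <- grad_impl(coords, t)
    if (!all(is.finite(g))) stop("classifier gradient is non-finite")
    -guidance_scale * g
  }
  new_conditioner("classifier", energy = energy_fn, grad = grad_energy,
                  params = list(guidance_scale = guidance_scale))
}

#' Built-in toy helix-content classifier
#'
#' Smooth proxy for helical content: the mean over residues of a Gaussian
#' bump on the i,i+4 CA distance centred at 6.2 A (width 0.8 A), the
#' signature spacing of an alpha-helix.  Returns the log-probability and its
#' analytic gradient, suitable for [make_classifier_conditioner()].
#'
#' @return List with functions `log_prob(coords, t)` and `grad(coords, t)`.
#' @export
helix_content_classifier <- function() {
  d0 <- 6.2; w <- 0.8
  log_prob <- function(coords, t) {
    n <- nrow(coords)
    if (n < 5L) return(0)
    dv <- coords[5:n, , drop = FALSE] - coords[1:(n - 4L), , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    mean(exp(-(d - d0)^2 / (2 * w^2)))
  }
  grad <- function(coords, t) {
    n <- nrow(coords)
    g <- matrix(0, n, 3L)
    if (n < 5L) return(g)
    dv <- coords[5:n, , drop = FALSE] - coords[1:(n - 4L), , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    dsd <- exp(-(d - d0)^2 / (2 * w^2)) * (-(d - d0) / w^2) / (n - 4L)
    u <- dv / pmax(d, 1e-12)
    gu <- u * dsd
    for (i in seq_len(n - 4L)) {
      g[i, ] <- g[i, ] - gu[i, ]
      g[i + 4L, ] <- g[i + 4L, ] + gu[i, ]
    }
    g
  }
  list(log_prob = log_prob, grad = grad)
}
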