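#' Sparse geometry graphs over residues
#'
#' Directed residue graph combining guaranteed chain edges, k-nearest
#' spatial neighbours and k random long-range edges drawn with probability
#' proportional to an inverse power of spatial distance (the connectivity
#' statistics of fast N-body methods).  Each node selects at most
#' `k_local + k_random` out-neighbours, so the total edge count is linear in
#' the number of residues.
#'
#' @param structure A `backbone_structure` or an n x 3 CA matrix.
#' @param k_local Number of nearest-neighbour edges per node (>= 2); chain
#'   neighbours are always included within this budget.  Clamped (with a
#'   warning) to n-1 when it exceeds it.
#' @param k_random Number of random long-range edges per node (>= 0).
#' @param exponent_p Exponent of the inverse-power sampling law.
#' @param seed Optional seed (the random edges are resampled on every call
#'   otherwise, consuming the current RNG stream).
#' @param chain Chain labels when `structure` is a bare matrix.
#' @return Object of class `geometry_graph`: `n_nodes`, `edges` (E x 2,
#'   ordered pairs i -> j), `chain`, and the construction settings.
#' @export
build_graph <- function(structure, k_local = 12L, k_random = 8L,
                        exponent_p = 2, seed = NULL, chain = NULL) {
  if (inherits(structure, "backbone_structure")) {
    ca <- ca_coords(structure); chain <- structure$chain
  } else {
    ca <- as_coord_matrix(structure, "ca")
    if (is.null(chain)) chain <- rep("A", nrow(ca))
  }
  n <- nrow(ca)
  if (k_local < 2L) stop("k_local must be >= 2")
  if (k_random < 0L) stop("k_random must be >= 0")
  if (k_local >= n) {
    warning("k_local >= n_nodes; clamping to n - 1")
    k_local <- n - 1L
  }
  D <- as.matrix(stats::dist(ca))
  sel <- with_seed(seed, lapply(seq_len(n), function(i) {
    forced <- c(if (i > 1L && chain[i - 1L] == chain[i]) i - 1L,
                if (i < n && chain[i + 1L] == chain[i]) i + 1L)
    ord <- order(D[i, ])
    ord <- ord[ord != i & !(ord %in% forced)]
    local <- c(forced, ord[seq_len(max(0L, min(k_local - length(forced),
                                               length(ord))))])
    rest <- setdiff(seq_len(n), c(i, local))
    rnd <- if (k_random > 0L && length(rest) > 0L) {
      pr <- pmax(D[i, rest], 1e-6)^(-exponent_p)
      if (length(rest) == 1L) rest
      else sample(rest, size = min(k_random, length(rest)), prob = pr)
    } else integer(0)
    cbind(i, c(local, rnd))
  }))
  edges <- do.call(rbind, sel)
  storage.mode(edges) <- "integer"
  structure(list(n_nodes = n, edges = edges, chain = chain,
                 k_local = as.integer(k_local), k_random = as.integer(k_random),
                 exponent_p = exponent_p),
            class = "geometry_graph")
}

#' @export
print.geometry_graph <- function(x, ...) {
  cat(sprintf("<geometry_graph: %d nodes, %d directed edges (k_local %d, k_random %d, p %g)>\n",
              x$n_nodes, nrow(x$edges), x$k_local, x$k_random, x$exponent_p))
  invisible(x)
}

row_unit <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)

cross_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# Gram-Schmidt frame from two direction matrices (rowwise): e1 along `a`,
# e2 the component of `b` orthogonal to e1, e3 = e1 x e2.  Returns n x 9
# (columns of the rotation stacked: e1, e2, e3), right-handed by construction.
gs_frames <- function(a, b, label = "residue") {
  e1 <- row_unit(a)
  proj <- rowSums(b * e1)
  b_perp <- b - e1 * proj
  nb <- sqrt(rowSums(b_perp^2))
  bad <- which(nb < 1e-8)
  if (length(bad))
    stop("degenerate (collinear) frame at ", label, " ", paste(bad, collapse = ", "))
  e2 <- b_perp / nb
  e3 <- cross_rows(e1, e2)
  cbind(e1, e2, e3)
}

#' Backbone residue frames
#'
#' Right-handed orthonormal frame per residue: origin at CA, first axis
#' along C-CA, second the Gram-Schmidt complement of N-CA, third their cross
#' product.  Errors on collinear N/CA/C.
#'
#' @param structure A `backbone_structure`.
#' @return List with `origin` (n x 3 CA matrix) and `rot` (n x 9 matrix,
#'   frame axes e1, e2, e3 stacked column-wise).
#' @export
residue_frames <- function(structure) {
  stopifnot(inherits(structure, "backbone_structure"))
  rot <- gs_frames(structure$c - structure$ca, structure$n - structure$ca)
  list(origin = structure$ca, rot = rot)
}

# Frames computable from the CA trace alone: identical to residue_frames()
# applied to rebuild_backbone_from_ca(), but without materializing atoms.
frames_from_ca <- function(ca, chain) {
  dirs <- ca_local_directions(ca, chain)
  c_dir <- row_unit(row_unit(dirs$u) + 0.40 * dirs$w)
  n_dir <- row_unit(row_unit(dirs$v) - 0.40 * dirs$w)
  list(origin = ca, rot = gs_frames(c_dir, n_dir))
}

# Apply the frame rotations (rows of R9) to local vectors p (E x 3 rows).
frame_apply <- function(R9, p) {
  R9[, 1:3, drop = FALSE] * p[, 1L] + R9[, 4:6, drop = FALSE] * p[, 2L] +
    R9[, 7:9, drop = FALSE] * p[, 3L]
}

# Apply the transposed rotations: express global vectors d in the frames.
frame_pullback <- function(R9, d) {
  cbind(rowSums(R9[, 1:3, drop = FALSE] * d),
        rowSums(R9[, 4:6, drop = FALSE] * d),
        rowSums(R9[, 7:9, drop = FALSE] * d))
}

# Relative rotation R_i^T R_j per edge, as rows of 9 (same column layout).
relative_rot9 <- function(Ri, Rj) {
  out <- matrix(0, nrow(Ri), 9L)
  for (col_b in 1:3) for (row_a in 1:3) {
    out[, (col_b - 1L) * 3L + row_a] <-
      rowSums(Ri[, (row_a - 1L) * 3L + 1:3] * Rj[, (col_b - 1L) * 3L + 1:3])
  }
  out
}

# Quaternion (w, x, y, z) from rotation rows (sign-canonicalized so the
# largest-magnitude component is positive; vectorized Shepperd branches).
rot9_to_quat <- function(R9) {
  r11 <- R9[, 1L]; r21 <- R9[, 2L]; r31 <- R9[, 3L]
  r12 <- R9[, 4L]; r22 <- R9[, 5L]; r32 <- R9[, 6L]
  r13 <- R9[, 7L]; r23 <- R9[, 8L]; r33 <- R9[, 9L]
  E <- length(r11)
  q <- matrix(0, E, 4L)
  tr <- r11 + r22 + r33
  c0 <- 1 + tr; c1 <- 1 + r11 - r22 - r33
  c2 <- 1 - r11 + r22 - r33; c3 <- 1 - r11 - r22 + r33
  pick <- max.col(cbind(c0, c1, c2, c3))
  i0 <- pick == 1L
  if (any(i0)) {
    s <- 2 * sqrt(pmax(c0[i0], 1e-12))
    q[i0, ] <- cbind(s / 4, (r32 - r23)[i0] / s, (r13 - r31)[i0] / s,
                     (r21 - r12)[i0] / s)
  }
  i1 <- pick == 2L
  if (any(i1)) {
    s <- 2 * sqrt(pmax(c1[i1], 1e-12))
    q[i1, ] <- cbind((r32 - r23)[i1] / s, s / 4, (r12 + r21)[i1] / s,
                     (r13 + r31)[i1] / s)
  }
  i2 <- pick == 3L
  if (any(i2)) {
    s <- 2 * sqrt(pmax(c2[i2], 1e-12))
    q[i2, ] <- cbind((r13 - r31)[i2] / s, (r12 + r21)[i2] / s, s / 4,
                     (r23 + r32)[i2] / s)
  }
  i3 <- pick == 4L
  if (any(i3)) {
    s <- 2 * sqrt(pmax(c3[i3], 1e-12))
    q[i3, ] <- cbind((r21 - r12)[i3] / s, (r13 + r31)[i3] / s,
                     (r23 + r32)[i3] / s, s / 4)
  }
  flip <- q[cbind(seq_len(E), max.col(abs(q)))] < 0
  q[flip, ] <- -q[flip, ]
  q
}

#' Relative-geometry edge features
#'
#' For every edge (i, j) the distance, direction and orientation of residue
#' j expressed in residue i's backbone frame, plus sequence-offset and
#' chain metadata.  All geometric features are invariant under global
#' rototranslation of the structure.
#'
#' @param structure A `backbone_structure`.
#' @param graph A `geometry_graph` over the same residues.
#' @return The graph with `edge_features` attached: a list holding `rel_pos`
#'   (E x 3, j's CA in i's frame), `dist` (E), `unit` (E x 3), `quat`
#'   (E x 4, relative orientation), `seq_offset` and `same_chain`.
#' @export
featurize_edges <- function(structure, graph) {
  fr <- residue_frames(structure)
  graph$edge_features <- edge_features_from_frames(fr, graph)
  graph
}

edge_features_from_frames <- function(fr, graph) {
  ed <- graph$edges
  i <- ed[, 1L]; j <- ed[, 2L]
  Ri <- fr$rot[i, , drop = FALSE]; Rj <- fr$rot[j, , drop = FALSE]
  d_glob <- fr$origin[j, , drop = FALSE] - fr$origin[i, , drop = FALSE]
  rel <- frame_pullback(Ri, d_glob)
  dist <- sqrt(rowSums(rel^2))
  u <- rel / pmax(dist, 1e-12)
  quat <- rot9_to_quat(relative_rot9(Ri, Rj))
  list(rel_pos = rel, dist = dist, unit = u, quat = quat,
       seq_offset = j - i, same_chain = as.numeric(graph$chain[i] == graph$chain[j]))
}

#' Extract true inter-residue geometries along graph edges
#'
#' The position of residue j's CA in residue i's frame for every edge:
#' the quantity the denoiser learns to predict, and the input of
#' [solve_consensus()].
#'
#' @param structure A `backbone_structure`.
#' @param graph A `geometry_graph`.
#' @param weights Optional positive per-edge confidence weights (default 1).
#' @return Object of class `edge_geometry`: `pred` (E x 3), `weights` (E).
#' @export
extract_edge_geometry <- function(structure, graph, weights = NULL) {
  fr <- residue_frames(structure)
  ed <- graph$edges
  rel <- frame_pullback(fr$rot[ed[, 1L], , drop = FALSE],
                        fr$origin[ed[, 2L], , drop = FALSE] -
                          fr$origin[ed[, 1L], , drop = FALSE])
  edge_geometry(rel, weights %||% rep(1, nrow(ed)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an edge-geometry prediction set
#' @param pred E x 3 matrix: predicted CA position of node j in node i's
#'   frame per edge.
#' @param weights Positive, finite per-edge confidence weights.
#' @return Object of class `edge_geometry`.
#' @export
edge_geometry <- function(pred, weights) {
  pred <- as_coord_matrix(pred, "pred")
  weights <- as.numeric(weights)
  if (length(weights) != nrow(pred)) stop("one weight per edge required")
  if (any(!is.finite(weights) | weights <= 0)) stop("weights must be finite and positive")
  structure(list(pred = pred, weights = weights), class = "edge_geometry")
}

#' Consensus synthesis of global coordinates from edge geometries
#'
#' Solves for global CA coordinates that best agree with per-edge predicted
#' local positions by block coordinate descent on the single objective
#' `sum_e w_e || x_j - x_i - R_i p_e ||^2`:
#'
#' 1. *Frames from current coordinates*: each node's rotation `R_i` is the
#'    weighted Procrustes fit of its predicted local point cloud to the
#'    current global positions of its targets.
#' 2. *Least-squares consensus*: all positions are updated simultaneously
#'    to the confidence-weighted least-squares consensus of the resulting
#'    absolute estimates, a sparse graph-Laplacian solve (translation gauge
#'    fixed at the running centroid).
#'
#' Both stages decrease the common objective, so the alternation is
#' monotone; cost per iteration is linear in the edge count.  Rotations are
#' initialized either by composing relative rotations along the chain
#' (`init = "sync"`, estimated from shared-neighbour Procrustes fits; on
#' self-consistent inputs this reconstructs the true structure, up to rigid
#' motion, in the first pass) or from the CA-trace frames of `init_coords`
#' (`init = "frames"`, the warm start used inside the denoiser so the
#' output stays in the gauge of the noisy input).
#'
#' @param edge_predictions An `edge_geometry`.
#' @param graph A `geometry_graph` (must be weakly connected).
#' @param init_coords n x 3 starting CA coordinates (sets the translation
#'   gauge, and the rotation gauge for `init = "frames"`).
#' @param n_iters Maximum alternation rounds.
#' @param tol Stop when the largest per-node move falls below this (A).
#' @param init Rotation initialization, `"sync"` (default) or `"frames"`.
#' @return n x 3 CA coordinate matrix.
#' @export
solve_consensus <- function(edge_predictions, graph, init_coords,
                            n_iters = 10L, tol = 1e-4,
                            init = c("sync", "frames")) {
  stopifnot(inherits(edge_predictions, "edge_geometry"))
  init <- match.arg(init)
  ed <- graph$edges
  n <- graph$n_nodes
  ca <- as_coord_matrix(init_coords, "init_coords")
  if (nrow(ca) != n) stop("init_coords does not match the graph")
  g_und <- igraph::graph_from_edgelist(ed, directed = FALSE)
  if (igraph::vcount(g_und) < n)
    g_und <- igraph::add_vertices(g_und, n - igraph::vcount(g_und))
  comp <- igraph::components(g_und)
  if (comp$no > 1L)
    stop("graph is disconnected; components of sizes ",
         paste(comp$csize, collapse = ", "))
  i <- ed[, 1L]; j <- ed[, 2L]
  w <- edge_predictions$weights
  p <- edge_predictions$pred
  L <- Matrix::sparseMatrix(
    i = c(i, j, i, j), j = c(i, j, j, i),
    x = c(w, w, -w, -w), dims = c(n, n))
  L <- L + Matrix::Diagonal(n, 1e-8 * mean(w))
  Lchol <- Matrix::Cholesky(Matrix::forceSymmetric(L), LDL = FALSE, perm = TRUE)
  solve_positions <- function(R9) {
    d <- frame_apply(R9[i, , drop = FALSE], p)
    rhs <- matrix(0, n, 3L)
    acc_j <- rowsum(d * w, j, reorder = FALSE)
    acc_i <- rowsum(d * w, i, reorder = FALSE)
    rhs[as.integer(rownames(acc_j)), ] <- rhs[as.integer(rownames(acc_j)), ] + acc_j
    rhs[as.integer(rownames(acc_i)), ] <- rhs[as.integer(rownames(acc_i)), ] - acc_i
    x <- as.matrix(Matrix::solve(Lchol, rhs))
    sweep(x, 2L, colMeans(x) - colMeans(ca), "-")
  }
  R9 <- if (init == "sync") sync_rotations(p, w, graph)
  else frames_from_ca(ca, graph$chain)$rot
  x <- solve_positions(R9)
  for (it in seq_len(n_iters)) {
    R9 <- procrustes_rotations(x, p, w, graph, R9)
    x_new <- solve_positions(R9)
    delta <- max(sqrt(rowSums((x_new - x)^2)))
    x <- x_new
    if (delta < tol) break
  }
  x
}

# Per-node weighted Procrustes: R_i maximizing sum_e w_e (x_j - x_i).(R p_e)
# over the node's out-edges; nodes with degenerate fits keep their previous
# rotation.
procrustes_rotations <- function(x, p, w, graph, R9_prev) {
  ed <- graph$edges
  i <- ed[, 1L]; j <- ed[, 2L]
  y <- (x[j, , drop = FALSE] - x[i, , drop = FALSE]) * w
  # cross-covariance entries M_ab = sum w * y_a * p_b, accumulated per node
  cols <- cbind(y[, 1L] * p, y[, 2L] * p, y[, 3L] * p)  # E x 9: (a,b) = a*3+b
  M <- rowsum(cols, i, reorder = FALSE)
  nodes <- as.integer(rownames(M))
  R9 <- R9_prev
  for (k in seq_along(nodes)) {
    Mi <- matrix(M[k, ], 3L, 3L, byrow = TRUE)  # rows a (global), cols b (local)
    sv <- tryCatch(svd(Mi), error = function(e) NULL)
    if (is.null(sv) || sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-300)) next
    s <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
    R9[nodes[k], ] <- as.numeric(R)  # column-major = e1,e2,e3 stacked
  }
  R9
}

# Deterministic rotation initialization: relative rotations between chain
# neighbours from Procrustes on the local predictions of shared targets,
# composed along each chain (gauge: first node of each chain = identity).
sync_rotations <- function(p, w, graph) {
  n <- graph$n_nodes
  ed <- graph$edges
  out_idx <- split(seq_len(nrow(ed)), ed[, 1L])
  targ <- split(ed[, 2L], ed[, 1L])
  R9 <- matrix(rep(as.numeric(diag(3)), each = n), n, 9L)
  local_cloud <- function(i) {
    ei <- out_idx[[as.character(i)]]
    m <- c(targ[[as.character(i)]], i)
    q <- rbind(p[ei, , drop = FALSE], c(0, 0, 0))
    list(m = m, q = q)
  }
  rel_rot <- function(a, b) {
    ca_ <- local_cloud(a); cb_ <- local_cloud(b)
    shared <- intersect(ca_$m, cb_$m)
    if (length(shared) < 3L) return(diag(3))
    qa <- ca_$q[match(shared, ca_$m), , drop = FALSE]
    qb <- cb_$q[match(shared, cb_$m), , drop = FALSE]
    qa <- sweep(qa, 2L, colMeans(qa)); qb <- sweep(qb, 2L, colMeans(qb))
    M <- t(qa) %*% qb
    sv <- svd(M)
    if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-300)) return(diag(3))
    s <- sign(det(sv$u %*% t(sv$v)))
    sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  }
  chain <- graph$chain
  Rabs <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1L || chain[i] != chain[i - 1L]) {
      Rabs[[i]] <- diag(3)
    } else {
      Rabs[[i]] <- Rabs[[i - 1L]] %*% rel_rot(i - 1L, i)
    }
    R9[i, ] <- as.numeric(Rabs[[i]])
  }
  R9
}
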