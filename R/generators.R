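#' Ideal alpha-helix generator
#'
#' CA atoms on an ideal helical path (rise 1.5 A per residue, 100 degree
#' twist, 2.3 A CA radius; textbook values), remaining backbone atoms placed
#' with ideal peptide geometry.  With these parameters consecutive CA-CA
#' distances are ~3.8 A and the i,i+4 CA distance is ~6.2 A, the geometric
#' signatures the secondary-structure metrics key on.
#'
#' @param n_residues Number of residues (>= 1).
#' @param seed Optional seed for the coordinate jitter.
#' @param jitter Standard deviation (A) of isotropic Gaussian jitter added to
#'   each CA; 0 gives the exact ideal path.
#' @param chain Chain label.
#' @return A `backbone_structure`.
#' @export
make_ideal_helix <- function(n_residues, seed = NULL, jitter = 0, chain = "A") {
  stopifnot_scalar(n_residues, "n_residues", min = 1)
  k <- seq_len(n_residues) - 1L
  theta <- k * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * k)
  ca <- add_jitter(ca, jitter, seed)
  backbone_structure(ca, chain = chain)
}

#' Ideal extended-strand generator
#'
#' A beta-strand-like zigzag CA trace with ~3.3 A rise per residue and a
#' pleat amplitude chosen so consecutive CA-CA distances are 3.8 A.
#'
#' @inheritParams make_ideal_helix
#' @return A `backbone_structure`.
#' @export
make_ideal_strand <- function(n_residues, seed = NULL, jitter = 0, chain = "A") {
  stopifnot_scalar(n_residues, "n_residues", min = 1)
  k <- seq_len(n_residues) - 1L
  a <- sqrt(3.8^2 - 3.3^2) / 2
  ca <- cbind(3.3 * k, a * (-1)^k, 0 * k)
  ca <- add_jitter(ca, jitter, seed)
  backbone_structure(ca, chain = chain)
}

#' Beta-hairpin generator
#'
#' Two antiparallel strands at 4.8 A sheet spacing connected by a short turn.
#'
#' @param n_residues Total residue count (>= 6).
#' @inheritParams make_ideal_helix
#' @return A `backbone_structure`.
#' @export
make_beta_hairpin <- function(n_residues, seed = NULL, jitter = 0, chain = "A") {
  stopifnot_scalar(n_residues, "n_residues", min = 8)
  m <- floor((n_residues - 2L) / 2)
  n_turn <- n_residues - 2L * m   # 2 or 3 turn residues
  a <- sqrt(3.8^2 - 3.3^2) / 2
  s1 <- cbind(3.3 * (seq_len(m) - 1L), a * (-1)^(seq_len(m) - 1L), rep(0, m))
  s2 <- cbind(3.3 * (m - seq_len(m)) + 1.65, 4.8 + a * (-1)^(seq_len(m)), rep(0, m))
  turn <- hairpin_turn(s1[m, ], s2[1L, ], n_turn)
  ca <- rbind(s1, turn, s2)
  ca <- add_jitter(ca, jitter, seed)
  backbone_structure(ca, chain = chain)
}

# Place n_turn CA atoms on the major arc of the circle through A and B on
# which every bond is a 3.8 A chord (the circle radius is solved for), in the
# sheet plane, bulging away from the strands (+x).
hairpin_turn <- function(A, B, n_turn) {
  chord <- vnorm(B - A)
  n_bond <- n_turn + 1L
  f <- function(r) n_bond * 2 * asin(pmin(1.9 / r, 1)) +
    2 * asin(pmin(chord / 2 / r, 1)) - 2 * pi
  r <- stats::uniroot(f, c(1.9001, 60))$root
  e1 <- unit(B - A)
  nrm <- c(0, 0, 1)
  perp <- pracma_cross(nrm, e1)
  mid <- (A + B) / 2
  h <- sqrt(max(r^2 - (chord / 2)^2, 0))
  theta_tot <- 2 * pi - 2 * asin(pmin(chord / 2 / r, 1))
  best <- NULL
  for (combo in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    sgn_c <- combo[1L]; sgn_a <- combo[2L]
    ctr <- mid + sgn_c * h * perp
    pts <- t(vapply(seq_len(n_turn), function(j) {
      R <- rotation_about_axis(nrm, sgn_a * j * theta_tot / n_bond)
      ctr + as.numeric(R %*% (A - ctr))
    }, numeric(3)))
    dd <- c(vnorm(pts[1L, ] - A),
            if (n_turn > 1L) sqrt(rowSums(diff(pts)^2)),
            vnorm(B - pts[n_turn, ]))
    if (all(abs(dd - 3.8) < 0.05) && mean(pts[, 1L]) > mid[1L]) {
      best <- pts; break
    }
  }
  if (is.null(best)) stop("hairpin turn construction failed")
  best
}

#' Random-coil generator
#'
#' Self-avoiding random CA walk with 3.8 A steps; each new bond direction is
#' bent by 65-135 degrees from the previous one about a random axis, and a
#' step is retried when it brings any non-bonded CA pair closer than 3.0 A.
#'
#' @inheritParams make_ideal_helix
#' @return A `backbone_structure`.
#' @export
make_random_coil <- function(n_residues, seed = NULL, chain = "A") {
  stopifnot_scalar(n_residues, "n_residues", min = 1)
  with_seed(seed, {
    ca <- matrix(0, n_residues, 3L)
    if (n_residues >= 2L) {
      dir <- unit(stats::rnorm(3))
      ca[2L, ] <- ca[1L, ] + 3.8 * dir
      i <- 3L
      while (i <= n_residues) {
        ok <- FALSE
        for (try in seq_len(80L)) {
          ax <- unit(stats::rnorm(3))
          ang <- stats::runif(1, 65, 135) * pi / 180
          cand_dir <- unit(rotation_about_axis(ax, ang) %*% dir)
          cand <- ca[i - 1L, ] + 3.8 * as.numeric(cand_dir)
          prev <- ca[seq_len(i - 2L), , drop = FALSE]
          if (nrow(prev) == 0L ||
              min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= 3.0) {
            ca[i, ] <- cand; dir <- cand_dir; ok <- TRUE; break
          }
        }
        if (!ok) { # back off and restart the tail from two residues earlier
          i <- max(3L, i - 2L)
          dir <- unit(ca[i - 1L, ] - ca[i - 2L, ])
          next
        }
        i <- i + 1L
      }
    }
    backbone_structure(ca, chain = chain)
  })
}

add_jitter <- function(ca, jitter, seed) {
  if (jitter > 0) {
    ca <- ca + with_seed(seed, matrix(stats::rnorm(length(ca), sd = jitter),
                                      nrow(ca), 3L))
  }
  ca
}

#' Generate a reproducible set of synthetic backbones
#'
#' Each structure concatenates secondary-structure primitives (helix, strand,
#' hairpin, coil segments drawn according to `composition`) joined by short
#' loop segments with randomized placement, subject to a steric filter: no
#' non-bonded CA pair closer than 2.0 A.  The set plays the role of training
#' and test data for the desk-scale denoiser.
#'
#' @param n_structures Number of structures (0 gives an empty list).
#' @param length_range Integer vector `c(min, max)` of total residue counts.
#' @param composition Named weights over `helix`, `strand`, `hairpin`, `coil`
#'   (must sum to 1).
#' @param seed Master seed; the set is byte-identical for identical seeds.
#' @return List of `backbone_structure` objects.
#' @export
make_synthetic_set <- function(n_structures,
                               length_range = c(40L, 80L),
                               composition = c(helix = 0.45, strand = 0.2,
                                               hairpin = 0.15, coil = 0.2),
                               seed = 1L) {
  stopifnot_scalar(n_structures, "n_structures", min = 0)
  if (length(length_range) < 1L || any(!is.finite(length_range)))
    stop("length_range must be a non-empty numeric range")
  lo <- min(length_range); hi <- max(length_range)
  if (lo < 8) stop("minimum structure length is 8 residues")
  req <- c("helix", "strand", "hairpin", "coil")
  if (!all(req %in% names(composition)))
    stop("composition must name helix, strand, hairpin and coil")
  composition <- composition[req]
  if (abs(sum(composition) - 1) > 1e-8) stop("composition weights must sum to 1")
  if (n_structures == 0) return(list())
  lapply(seq_len(n_structures), function(s) {
    make_one_synthetic(lo, hi, composition, derive_seed(seed, s))
  })
}

make_one_synthetic <- function(lo, hi, composition, seed) {
  with_seed(seed, {
    for (attempt in seq_len(50L)) {
      L <- if (lo == hi) as.integer(lo) else sample(seq.int(lo, hi), 1L)
      ca <- build_synthetic_ca(L, composition)
      if (!is.null(ca) && min_nonbonded_ca(ca) >= 2.0)
        return(backbone_structure(ca))
    }
    stop("failed to generate a clash-free synthetic structure")
  })
}

build_synthetic_ca <- function(L, composition) {
  seg_ca <- function(type, len) {
    switch(type,
           helix = ca_coords(make_ideal_helix(len)),
           strand = ca_coords(make_ideal_strand(len)),
           hairpin = ca_coords(make_beta_hairpin(max(len, 8L))),
           coil = ca_coords(make_random_coil(
             len, seed = sample.int(2^30, 1L))))
  }
  seg_len <- function(type) {
    switch(type, helix = sample(8:18, 1L), strand = sample(5:10, 1L),
           hairpin = sample(10:18, 1L), coil = sample(4:10, 1L))
  }
  types <- names(composition)
  assembled <- NULL
  remaining <- L
  while (remaining > 0L) {
    type <- sample(types, 1L, prob = composition)
    len <- min(seg_len(type), remaining)
    if (len < 4L) type <- "coil"
    if (type == "hairpin" && len < 8L) type <- "coil"
    seg <- seg_ca(type, len)
    seg <- seg[seq_len(min(nrow(seg), remaining)), , drop = FALSE]
    remaining <- remaining - nrow(seg)
    if (is.null(assembled)) {
      assembled <- seg
      next
    }
    loop_len <- if (remaining > 3L) sample(2:4, 1L) else 0L
    remaining <- remaining - loop_len
    assembled <- attach_segment(assembled, seg, loop_len)
    if (is.null(assembled)) return(NULL)
  }
  assembled
}

# Attach `seg` (local coordinates) to the end of `base` through a loop of
# `loop_len` residues, retrying random placements until the steric filter
# passes; falls back to an outward direction (away from the centroid) that
# rarely clashes.
attach_segment <- function(base, seg, loop_len) {
  endp <- base[nrow(base), ]
  seg0 <- sweep(seg, 2L, seg[1L, ])
  for (try in seq_len(60L)) {
    u <- if (try < 50L) unit(stats::rnorm(3)) else unit(endp - colMeans(base) + stats::rnorm(3, sd = 0.2))
    R <- random_rotation()
    gap <- 3.5 * (loop_len + 1L)
    loop <- if (loop_len > 0L) {
      t(vapply(seq_len(loop_len), function(j)
        endp + u * 3.5 * j + stats::rnorm(3, sd = 0.35), numeric(3)))
    } else NULL
    placed <- sweep(seg0 %*% t(R), 2L, endp + u * gap, "+")
    cand <- rbind(base, loop, placed)
    if (min_nonbonded_ca(cand) >= 2.1) return(cand)
  }
  NULL
}

# Minimum distance over CA pairs that are not sequence-adjacent.
min_nonbonded_ca <- function(ca) {
  n <- nrow(ca)
  if (n < 3L) return(Inf)
  D <- as.matrix(stats::dist(ca))
  D[cbind(seq_len(n), seq_len(n))] <- Inf
  D[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- Inf
  D[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- Inf
  min(D)
}
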