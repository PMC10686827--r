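#' Radius of gyration
#'
#' Root-mean-square CA distance from the CA centroid.
#'
#' @param structure A `backbone_structure` or n x 3 CA matrix.
#' @return Rg in angstroms.
#' @export
radius_of_gyration <- function(structure) {
  ca <- if (inherits(structure, "backbone_structure")) ca_coords(structure)
  else as_coord_matrix(structure, "ca")
  cc <- sweep(ca, 2L, colMeans(ca))
  sqrt(mean(rowSums(cc^2)))
}

#' Relative contact order
#'
#' `(1 / (L N_c)) sum_contacts |i - j|` over CA pairs within `cutoff` and
#' sequence separation at least `min_separation`; 0 when there are no
#' contacts.  The defaults (8 A, |i-j| >= 3) are the package's contact
#' definition and are configurable.
#'
#' @param structure A `backbone_structure` or CA matrix.
#' @param cutoff CA-CA contact cutoff (A).
#' @param min_separation Minimum sequence separation.
#' @return Dimensionless relative contact order in \[0, 1\].
#' @export
contact_order <- function(structure, cutoff = 8, min_separation = 3L) {
  ca <- if (inherits(structure, "backbone_structure")) ca_coords(structure)
  else as_coord_matrix(structure, "ca")
  n <- nrow(ca)
  if (n < 2L) stop("contact order needs at least 2 residues")
  cm <- contact_pairs(ca, cutoff, min_separation)
  if (!nrow(cm)) return(0)
  sum(cm[, 2L] - cm[, 1L]) / (n * nrow(cm))
}

contact_pairs <- function(ca, cutoff, min_separation) {
  n <- nrow(ca)
  D <- as.matrix(stats::dist(ca))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  keep <- (idx[, 2L] - idx[, 1L]) >= min_separation &
    D[idx] <= cutoff
  idx[keep, , drop = FALSE]
}

#' Contact statistics of a backbone
#'
#' @inheritParams contact_order
#' @param long_range Sequence separation from which a contact counts as
#'   long-range.
#' @return List: `n_contacts`, `contact_density` (contacts per residue),
#'   `long_range_fraction` (fraction of contacts with separation >=
#'   `long_range`; 0 when there are no contacts).
#' @export
contact_stats <- function(structure, cutoff = 8, min_separation = 3L,
                          long_range = 12L) {
  ca <- if (inherits(structure, "backbone_structure")) ca_coords(structure)
  else as_coord_matrix(structure, "ca")
  cm <- contact_pairs(ca, cutoff, min_separation)
  nc <- nrow(cm)
  list(n_contacts = nc,
       contact_density = nc / nrow(ca),
       long_range_fraction = if (nc) mean((cm[, 2L] - cm[, 1L]) >= long_range) else 0)
}

#' Secondary-structure assignment from the CA trace
#'
#' Geometric assignment using CA-only signatures: a residue is helical (H)
#' when its i,i+2 and i,i+4 CA spans sit in the alpha-helix windows
#' (~5.4 A and ~6.2 A for ideal geometry), extended (E) when both spans are
#' in the beta windows (~6.6 A and ~13 A), and coil (C) otherwise.  No
#' hydrogen-bond information is used; the rules are calibrated against the
#' package's ideal-geometry generators.  Structures shorter than 5 residues
#' are all-coil.
#'
#' @param structure A `backbone_structure` or CA matrix.
#' @return Character vector of per-residue labels in `{H, E, C}`.
#' @export
assign_secondary_structure <- function(structure) {
  ca <- if (inherits(structure, "backbone_structure")) ca_coords(structure)
  else as_coord_matrix(structure, "ca")
  chain <- if (inherits(structure, "backbone_structure")) structure$chain
  else rep("A", nrow(ca))
  n <- nrow(ca)
  lab <- rep("C", n)
  if (n < 5L) return(lab)
  span <- function(k) {
    d <- rep(NA_real_, n)
    ok <- seq_len(n - k)
    same <- chain[ok] == chain[ok + k]
    d[ok[same]] <- sqrt(rowSums((ca[ok[same] + k, , drop = FALSE] -
                                   ca[ok[same], , drop = FALSE])^2))
    d
  }
  d2 <- span(2L); d4 <- span(4L)
  # window centred at i uses the spans starting at i-2..i
  for (i in seq_len(n)) {
    ks <- (i - 2L):i
    ks <- ks[ks >= 1L & ks <= n]
    s2 <- d2[ks]; s4 <- d4[ks]
    s2 <- s2[!is.na(s2)]; s4 <- s4[!is.na(s4)]
    if (!length(s2) || !length(s4)) next
    if (all(s2 > 4.7 & s2 < 6.1) && all(s4 > 4.9 & s4 < 7.3)) lab[i] <- "H"
    else if (all(s2 > 6.1 & s2 < 7.2) && all(s4 > 11.0 & s4 < 14.5)) lab[i] <- "E"
  }
  lab
}

#' Secondary-structure fractions
#' @inheritParams assign_secondary_structure
#' @return Named numeric vector `c(helix, strand, coil)`, summing to 1.
#' @export
ss_fractions <- function(structure) {
  lab <- assign_secondary_structure(structure)
  c(helix = mean(lab == "H"), strand = mean(lab == "E"), coil = mean(lab == "C"))
}

#' Optimal rigid-superposition RMSD (Kabsch)
#'
#' Minimum RMSD between two equal-length coordinate sets over proper
#' rotations and translations (reflections excluded).
#'
#' @param coords_a,coords_b n x 3 matrices (or structures; CA atoms used).
#' @return RMSD in angstroms.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- if (inherits(coords_a, "backbone_structure")) ca_coords(coords_a)
  else as_coord_matrix(coords_a, "a")
  b <- if (inherits(coords_b, "backbone_structure")) ca_coords(coords_b)
  else as_coord_matrix(coords_b, "b")
  if (nrow(a) != nrow(b)) stop("coordinate sets must have equal length")
  ac <- sweep(a, 2L, colMeans(a)); bc <- sweep(b, 2L, colMeans(b))
  sv <- svd(crossprod(ac, bc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(mean(rowSums((bc - ac %*% R)^2)))
}

#' Structural statistics of a backbone
#'
#' The per-structure summary used to characterize samples: residue count,
#' radius of gyration, relative contact order, contact density, long-range
#' contact fraction and secondary-structure fractions.
#'
#' @inheritParams contact_stats
#' @return A one-row data frame.
#' @export
structure_stats <- function(structure, cutoff = 8, min_separation = 3L,
                            long_range = 12L) {
  ss <- ss_fractions(structure)
  cs <- contact_stats(structure, cutoff, min_separation, long_range)
  nres <- if (inherits(structure, "backbone_structure")) n_residues(structure)
  else nrow(structure)
  data.frame(n_residues = nres,
             radius_of_gyration = radius_of_gyration(structure),
             contact_order = if (nres >= 2L) contact_order(structure, cutoff, min_separation) else 0,
             contact_density = cs$contact_density,
             long_range_contact_fraction = cs$long_range_fraction,
             helix_fraction = ss[["helix"]],
             strand_fraction = ss[["strand"]],
             coil_fraction = ss[["coil"]])
}

#' Batch structural statistics over PDB files
#'
#' Reads every PDB file, computes [structure_stats()] per structure, and
#' optionally writes the table (with a summary row of means) as
#' tab-delimited text.  Unreadable files are skipped with a warning.
#'
#' @param paths Character vector of PDB paths, or a directory.
#' @param out Optional output TSV path.
#' @return Data frame (one row per readable structure plus a `mean` row),
#'   with attribute `n_skipped`.
#' @export
analyze_structures <- function(paths, out = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
  if (!length(paths)) stop("no PDB files to analyze")
  rows <- list(); skipped <- 0L
  for (p in paths) {
    st <- tryCatch(read_pdb(p), error = function(e) {
      warning("skipping unreadable file ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(st)) { skipped <- skipped + 1L; next }
    r <- structure_stats(st)
    r <- cbind(file = basename(p), r)
    rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) stop("no readable PDB files among ", length(paths))
  tab <- do.call(rbind, rows)
  means <- as.data.frame(lapply(tab[-1L], mean))
  tab <- rbind(tab, cbind(file = "mean", means))
  attr(tab, "n_skipped") <- skipped
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
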