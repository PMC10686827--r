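#' Backbone structure objects
#'
#' A `backbone_structure` holds an ordered list of residues, each with the
#' four backbone heavy atoms (N, CA, C, O) in angstroms and a chain label.
#' Residue numbering is 1-based within each chain and chain labels partition
#' the residues into contiguous blocks.  Sequence identity is out of scope:
#' every residue is treated (and written to PDB) as glycine.
#'
#' @param ca Numeric n x 3 matrix of CA coordinates (angstroms).
#' @param n,c,o Optional n x 3 matrices for the N, C and O atoms.  Any that
#'   are missing are rebuilt from the CA trace with ideal peptide geometry
#'   (see [rebuild_backbone_from_ca()]).
#' @param chain Character vector of chain labels, length 1 (recycled) or n.
#' @param resno Optional integer residue numbers; defaults to 1-based
#'   numbering within each chain.
#' @return An object of class `backbone_structure`.
#' @export
backbone_structure <- function(ca, n = NULL, c = NULL, o = NULL,
                               chain = "A", resno = NULL) {
  ca <- as_coord_matrix(ca, "ca")
  nres <- nrow(ca)
  if (nres < 1L) stop("a backbone structure needs at least one residue")
  if (length(chain) == 1L) chain <- rep(chain, nres)
  if (length(chain) != nres) stop("chain labels must have length 1 or n_residues")
  chain <- as.character(chain)
  if (any(rle(chain)$values |> duplicated()))
    stop("chain labels must partition residues into contiguous blocks")
  if (is.null(n) || is.null(c) || is.null(o)) {
    rebuilt <- rebuild_backbone_from_ca(ca, chain)
    if (is.null(n)) n <- rebuilt$n
    if (is.null(c)) c <- rebuilt$c
    if (is.null(o)) o <- rebuilt$o
  }
  n <- as_coord_matrix(n, "n"); c <- as_coord_matrix(c, "c")
  o <- as_coord_matrix(o, "o")
  if (nrow(n) != nres || nrow(c) != nres || nrow(o) != nres)
    stop("atom coordinate matrices must all have n_residues rows")
  if (is.null(resno)) {
    resno <- stats::ave(seq_len(nres), chain, FUN = seq_along)
  }
  x <- structure(list(chain = chain, resno = as.integer(resno),
                      n = n, ca = ca, c = c, o = o),
                 class = "backbone_structure")
  validate_backbone(x)
  x
}

as_coord_matrix <- function(m, what) {
  if (is.null(dim(m)) && length(m) == 3L) m <- matrix(m, 1L, 3L)
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop(sprintf("'%s' coordinates must be an n x 3 matrix", what))
  if (!all(is.finite(m))) stop(sprintf("non-finite '%s' coordinates", what))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

validate_backbone <- function(x) {
  stopifnot(inherits(x, "backbone_structure"))
  nres <- length(x$chain)
  for (at in c("n", "ca", "c", "o")) {
    if (!all(is.finite(x[[at]]))) stop("non-finite coordinates in atom ", toupper(at))
  }
  # consecutive CA-CA distances within a chain must be positive
  if (nres > 1L) {
    same <- x$chain[-1L] == x$chain[-nres]
    d <- sqrt(rowSums((x$ca[-1L, , drop = FALSE] - x$ca[-nres, , drop = FALSE])^2))
    if (any(same & d <= 0)) stop("zero-length CA-CA step within a chain")
  }
  invisible(x)
}

#' @export
print.backbone_structure <- function(x, ...) {
  ch <- rle(x$chain)
  cat(sprintf("<backbone_structure: %d residues, %d chain%s (%s)>\n",
              length(x$chain), length(ch$values),
              if (length(ch$values) > 1L) "s" else "",
              paste(sprintf("%s:%d", ch$values, ch$lengths), collapse = ", ")))
  invisible(x)
}

#' Number of residues in a structure
#' @param x A `backbone_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) length(x$chain)

#' CA coordinate matrix of a structure
#' @param x A `backbone_structure`.
#' @return Numeric n x 3 matrix.
#' @export
ca_coords <- function(x) x$ca

#' Replace the CA field of a structure by a rigid per-residue translation
#'
#' Moves every atom of residue i by `new_ca[i,] - old_ca[i,]` (rigid-residue
#' displacement, the convention under which backbone diffusion noise acts).
#' @param x A `backbone_structure`.
#' @param new_ca n x 3 matrix of new CA coordinates.
#' @return A `backbone_structure`.
#' @export
set_ca_coords <- function(x, new_ca) {
  new_ca <- as_coord_matrix(new_ca, "ca")
  if (nrow(new_ca) != n_residues(x)) stop("CA matrix has wrong number of rows")
  d <- new_ca - x$ca
  x$n <- x$n + d; x$ca <- new_ca; x$c <- x$c + d; x$o <- x$o + d
  x
}

#' Rebuild N, C and O atoms from a CA trace
#'
#' Places the remaining backbone atoms with ideal bond lengths (N-CA 1.46 A,
#' CA-C 1.52 A, C=O 1.23 A) in a local frame derived from the CA trace.  The
#' construction is deterministic and commutes with rigid motions of the
#' trace, which is what the diffusion sampler requires (the sampler state is
#' the CA field only).
#'
#' @param ca n x 3 CA coordinate matrix.
#' @param chain Chain labels (length 1 or n); atoms are placed using
#'   neighbours within the same chain only.
#' @return List with matrices `n`, `c`, `o`.
#' @export
rebuild_backbone_from_ca <- function(ca, chain = "A") {
  ca <- as_coord_matrix(ca, "ca")
  nres <- nrow(ca)
  if (length(chain) == 1L) chain <- rep(chain, nres)
  N <- C <- O <- matrix(0, nres, 3L)
  dirs <- ca_local_directions(ca, chain)
  for (i in seq_len(nres)) {
    u <- dirs$u[i, ]; v <- dirs$v[i, ]; w <- dirs$w[i, ]
    C[i, ] <- ca[i, ] + 1.52 * unit(unit(u) + 0.40 * w)
    N[i, ] <- ca[i, ] + 1.46 * unit(unit(v) - 0.40 * w)
  }
  for (i in seq_len(nres)) {
    d1 <- unit(C[i, ] - ca[i, ])
    nxt <- i + 1L
    if (nxt <= nres && chain[nxt] == chain[i]) {
      d2 <- unit(C[i, ] - N[nxt, ])
      O[i, ] <- C[i, ] + 1.23 * unit(d1 + d2)
    } else {
      O[i, ] <- C[i, ] + 1.23 * unit(d1 + 0.3 * dirs$w[i, ])
    }
  }
  list(n = N, c = C, o = O)
}

# Local direction triplet (u toward next CA, v toward previous CA, w = unit
# normal) per residue, with chain-aware boundary handling and a deterministic
# fallback for degenerate (collinear or too-short) geometry.
ca_local_directions <- function(ca, chain) {
  nres <- nrow(ca)
  u <- v <- w <- matrix(0, nres, 3L)
  for (i in seq_len(nres)) {
    has_prev <- i > 1L && chain[i - 1L] == chain[i]
    has_next <- i < nres && chain[i + 1L] == chain[i]
    has_pp <- i > 2L && chain[i - 2L] == chain[i]
    has_nn <- i + 2L <= nres && chain[i + 2L] == chain[i]
    if (has_next) uu <- ca[i + 1L, ] - ca[i, ]
    else if (has_prev) uu <- ca[i, ] - ca[i - 1L, ]
    else uu <- c(1, 0, 0)
    if (has_prev && has_next) vv <- ca[i - 1L, ] - ca[i, ]
    else if (!has_next && has_pp) vv <- ca[i - 2L, ] - ca[i, ]  # chain end
    else if (!has_prev && has_nn) vv <- ca[i + 2L, ] - ca[i, ]  # chain start
    else vv <- -uu
    if (vnorm(uu) < 1e-9) uu <- c(1, 0, 0)
    if (vnorm(vv) < 1e-9) vv <- -uu
    ww <- pracma_cross(uu, vv)
    if (vnorm(ww) < 1e-8 * vnorm(uu) * vnorm(vv)) {
      # (anti)parallel, e.g. a 2-residue chain: pick the least-aligned
      # coordinate axis as a deterministic tie-break
      ax <- diag(3)[, which.min(abs(unit(uu)))]
      ww <- pracma_cross(uu, ax)
      vv <- pracma_cross(ww, uu)
    }
    u[i, ] <- uu; v[i, ] <- vv; w[i, ] <- unit(ww)
  }
  list(u = u, v = v, w = w)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Write a backbone structure to a PDB file
#'
#' Standard ATOM records (3-decimal coordinates), `TER` between chains and a
#' final `END`.  All residues are written as glycine: sequence design is not
#' part of this package.
#'
#' @param structure A `backbone_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  validate_backbone(structure)
  atoms <- c("n", "ca", "c", "o")
  names4 <- c(n = " N  ", ca = " CA ", c = " C  ", o = " O  ")
  elem <- c(n = "N", ca = "C", c = "C", o = "O")
  for (at in atoms) {
    m <- structure[[at]]
    if (any(m > 9999.999 | m < -999.999))
      stop("coordinate out of PDB fixed-width range (|x| too large)")
  }
  lines <- character(0)
  serial <- 0L
  nres <- n_residues(structure)
  for (i in seq_len(nres)) {
    for (at in atoms) {
      serial <- serial + 1L
      xyz <- structure[[at]][i, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s GLY %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial %% 100000L, names4[[at]], substr(structure$chain[i], 1, 1),
        structure$resno[i] %% 10000L, xyz[1], xyz[2], xyz[3], elem[[at]]))
    }
    if (i == nres || structure$chain[i + 1L] != structure$chain[i])
      lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a backbone structure from a PDB file
#'
#' Parses ATOM records (via \pkg{bio3d}), keeping the N, CA, C and O backbone
#' atoms of each residue.  A residue missing its CA, N or C atom is a parse
#' error; a missing O is rebuilt from peptide geometry.  Files containing
#' insertion codes are rejected.
#'
#' @param path PDB file path.
#' @return A `backbone_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  ins <- at$insert
  if (any(!is.na(ins) & ins != "")) stop("insertion codes are not supported: ", path)
  ch <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  key <- paste(ch, at$resno)
  ids <- rle(key)$values
  nres <- length(ids)
  first_of <- match(ids, key)
  N <- CA <- C <- O <- matrix(NA_real_, nres, 3L)
  chain_out <- character(nres); resno_out <- integer(nres)
  for (r in seq_len(nres)) {
    rows <- which(key == ids[r])
    chain_out[r] <- ch[rows[1L]]
    resno_out[r] <- at$resno[rows[1L]]
    for (rr in rows) {
      ele <- at$elety[rr]
      xyz <- c(at$x[rr], at$y[rr], at$z[rr])
      if (ele == "N" && all(is.na(N[r, ]))) N[r, ] <- xyz
      if (ele == "CA" && all(is.na(CA[r, ]))) CA[r, ] <- xyz
      if (ele == "C" && all(is.na(C[r, ]))) C[r, ] <- xyz
      if (ele == "O" && all(is.na(O[r, ]))) O[r, ] <- xyz
    }
    for (need in c("CA", "N", "C")) {
      m <- switch(need, CA = CA, N = N, C = C)
      if (any(is.na(m[r, ])))
        stop(sprintf("residue %s %d lacks a %s atom", chain_out[r], resno_out[r], need))
    }
  }
  miss_o <- which(is.na(O[, 1L]))
  if (length(miss_o)) {
    for (r in miss_o) {
      d1 <- unit(C[r, ] - CA[r, ])
      nxt <- r + 1L
      if (nxt <= nres && chain_out[nxt] == chain_out[r] && !any(is.na(N[nxt, ]))) {
        d2 <- unit(C[r, ] - N[nxt, ])
        O[r, ] <- C[r, ] + 1.23 * unit(d1 + d2)
      } else {
        O[r, ] <- C[r, ] + 1.23 * d1
      }
    }
  }
  backbone_structure(ca = CA, n = N, c = C, o = O,
                     chain = chain_out, resno = resno_out)
}

#' Read a point cloud from a plain-text file
#'
#' Whitespace-separated `x y z` triples, one point per line; blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return m x 3 numeric matrix.
#' @export
read_point_cloud <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty point cloud file: ", path)
  vals <- lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
  if (any(vapply(vals, length, 1L) != 3L)) stop("each line must hold exactly 3 numbers")
  m <- do.call(rbind, vals)
  if (!all(is.finite(m))) stop("non-finite point in ", path)
  m
}
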