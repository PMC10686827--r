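test_that("PDB round trip preserves coordinates and chain order", {
  st <- make_beta_hairpin(17)
  st2 <- make_ideal_helix(9, chain = "B")
  both <- backbone_structure(
    ca = rbind(ca_coords(st), sweep(ca_coords(st2), 2, c(30, 0, 0), "+")),
    n = rbind(st$n, sweep(st2$n, 2, c(30, 0, 0), "+")),
    c = rbind(st$c, sweep(st2$c, 2, c(30, 0, 0), "+")),
    o = rbind(st$o, sweep(st2$o, 2, c(30, 0, 0), "+")),
    chain = c(st$chain, st2$chain))
  tf <- tempfile(fileext = ".pdb")
  write_pdb(both, tf)
  back <- read_pdb(tf)
  expect_identical(back$chain, both$chain)
  expect_identical(back$resno, both$resno)
  for (a in c("n", "ca", "c", "o"))
    expect_lt(max(abs(back[[a]] - both[[a]])), 1e-3)
  lines <- readLines(tf)
  expect_equal(sum(lines == "TER"), 2L)      # one TER per chain
  expect_identical(tail(lines, 1L), "END")
  expect_true(all(grepl(" GLY ", lines[startsWith(lines, "ATOM")])))
})

test_that("single-residue structure writes 4 ATOM lines + TER + END", {
  tf <- tempfile(fileext = ".pdb")
  write_pdb(make_ideal_helix(1), tf)
  lines <- readLines(tf)
  expect_equal(sum(startsWith(lines, "ATOM")), 4L)
  expect_identical(lines[5:6], c("TER", "END"))
})

test_that("PDB writer and reader enforce their contracts", {
  st <- make_ideal_helix(3)
  st$ca[2, 1] <- 12345.0
  st$n[2, 1] <- 12345.0  # keep bond finite, coordinates out of field range
  expect_error(write_pdb(st, tempfile()), "fixed-width")

  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  C   GLY A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END"), tf)
  expect_error(read_pdb(tf), "CA")

  tf2 <- tempfile(fileext = ".pdb")
  writeLines("END", tf2)
  expect_error(read_pdb(tf2), "ATOM")
  expect_error(read_pdb(tempfile(fileext = ".pdb")), "no such file")

  # insertion codes are rejected
  tf3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1A      0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1A      1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1A      2.200   1.300   0.000  1.00  0.00           C",
    "END"), tf3)
  expect_error(read_pdb(tf3), "insertion")
})

test_that("a missing O atom is rebuilt at sensible carbonyl geometry", {
  st <- make_ideal_helix(5)
  tf <- tempfile(fileext = ".pdb")
  write_pdb(st, tf)
  lines <- readLines(tf)
  lines <- lines[!grepl(" O   GLY", lines, fixed = TRUE)]
  writeLines(lines, tf)
  back <- read_pdb(tf)
  d_co <- sqrt(rowSums((back$o - back$c)^2))
  expect_true(all(abs(d_co - 1.23) < 1e-6))
})

test_that("ideal helix geometry has the canonical CA spacings", {
  h <- make_ideal_helix(30)
  ca <- ca_coords(h)
  d1 <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d1 - 3.8) < 0.1))
  d4 <- sqrt(rowSums((ca[5:30, ] - ca[1:26, ])^2))
  expect_true(all(abs(d4 - 6.2) < 0.5))
  # i,i+4 closer than i,i+3 is false for an ideal helix
  d3 <- sqrt(rowSums((ca[4:29, ] - ca[1:26, ])^2))
  expect_true(all(d4 > d3))
  expect_equal(n_residues(make_ideal_helix(1)), 1L)
  expect_error(make_ideal_helix(0))
})

test_that("synthetic sets are seeded, clash-free and validated", {
  s1 <- make_synthetic_set(8, c(40, 80), seed = 7)
  s2 <- make_synthetic_set(8, c(40, 80), seed = 7)
  expect_identical(s1, s2)
  s3 <- make_synthetic_set(8, c(40, 80), seed = 8)
  expect_false(identical(s1, s3))
  expect_identical(make_synthetic_set(0, c(40, 80), seed = 1), list())
  expect_error(make_synthetic_set(2, numeric(0), seed = 1))
  expect_error(make_synthetic_set(2, c(40, 80),
                                  composition = c(helix = 1, strand = 1,
                                                  hairpin = 0, coil = 0),
                                  seed = 1), "sum to 1")
  # steric filter: no non-bonded CA pair below 2 A across a larger batch
  big <- make_synthetic_set(100, c(30, 60), seed = 33)
  min_d <- min(vapply(big, function(st) {
    ca <- ca_coords(st)
    D <- as.matrix(dist(ca))
    n <- nrow(ca)
    D[cbind(1:n, 1:n)] <- Inf
    D[cbind(1:(n - 1), 2:n)] <- Inf
    D[cbind(2:n, 1:(n - 1))] <- Inf
    min(D)
  }, 1))
  expect_gte(min_d, 2.0)
})

test_that("point-cloud files parse and reject malformed content", {
  tf <- tempfile(fileext = ".xyz")
  writeLines(c("# a comment", "0 0 0", "1.5 -2  3e0", ""), tf)
  pc <- read_point_cloud(tf)
  expect_equal(dim(pc), c(2L, 3L))
  expect_equal(pc[2, ], c(1.5, -2, 3))
  writeLines("1 2", tf)
  expect_error(read_point_cloud(tf), "3 numbers")
})
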