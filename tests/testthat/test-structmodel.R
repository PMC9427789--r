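# PDB I/O and rigid-body geometry

make_two_chain_fixture <- function(path) {
  rows <- list(
    pdb_row(1, "N",  "GLY", "A", 1, 0.0, 0.0, 0.0, elem = "N"),
    pdb_row(2, "CA", "GLY", "A", 1, 1.5, 0.0, 0.0, elem = "C"),
    pdb_row(3, "CA", "ALA", "A", 2, 3.0, 1.0, 0.0, elem = "C"),
    pdb_row(4, "CB", "ALA", "A", 2, 3.5, 2.0, 1.0, elem = "C"),
    pdb_row(5, "CA", "SER", "A", 3, 5.0, 2.0, 0.0, elem = "C"),
    pdb_row(6, "CA", "ASP", "B", 1, 0.0, 5.0, 0.0, elem = "C"),
    pdb_row(7, "OD1", "ASP", "B", 1, 1.0, 6.0, 0.5, elem = "O"),
    pdb_row(8, "CA", "LYS", "B", 2, 2.0, 5.5, 0.0, elem = "C"))
  write_pdb_fixture(path, rows)
}

test_that("read_pdb parses chains and residues and drops waters", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_two_chain_fixture(f)
  m <- read_pdb(f)
  expect_s3_class(m, "structure_model")
  expect_equal(sort(unique(m$atoms$chain)), c("A", "B"))
  expect_equal(nrow(residues_of(m)), 5)
  expect_equal(n_atoms(m), 8)

  # waters come through HETATM in real files; they also must vanish when
  # written as ATOM records of residue HOH
  f2 <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(f)
  hoh <- sub("^ATOM  ", "HETATM", sprintf(
    "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    9L, " O  ", " ", "HOH", "A", 90L, " ", 9, 9, 9, 1, 0, " O"))
  writeLines(c(lines[lines != "END"], hoh, "END"), f2)
  m2 <- read_pdb(f2)
  expect_false(any(m2$atoms$resid == "HOH"))
  expect_equal(n_atoms(m2), 8)
})

test_that("read_pdb reports missing files, empty files and absent models", {
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_pdb(f), "ATOM|parse")
  f3 <- withr::local_tempfile(fileext = ".pdb")
  rows <- list(pdb_row(1, "CA", "GLY", "A", 1, 0, 0, 0, elem = "C"),
               pdb_row(2, "CA", "GLY", "A", 2, 3, 0, 0, elem = "C"),
               pdb_row(3, "CA", "GLY", "A", 3, 6, 0, 0, elem = "C"))
  write_pdb_fixture(f3, NULL, multi_model = list(rows, rows))
  expect_equal(n_atoms(read_pdb(f3, model_index = 2)), 3)
  expect_error(read_pdb(f3, model_index = 5), "absent")
})

test_that("altloc resolution follows the requested policy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  rows <- list(
    pdb_row(1, "CA", "SER", "A", 1, 0, 0, 0, alt = "A", occ = 0.6, elem = "C"),
    pdb_row(2, "CA", "SER", "A", 1, 0.5, 0, 0, alt = "B", occ = 0.4, elem = "C"),
    pdb_row(3, "CB", "SER", "A", 1, 1, 1, 0, elem = "C"))
  write_pdb_fixture(f, rows)
  m <- read_pdb(f, altloc_policy = "highest_occupancy")
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$alt, "A")
  expect_equal(ca$x, 0)
  m2 <- read_pdb(f, altloc_policy = "first")
  expect_equal(m2$atoms$alt[m2$atoms$elety == "CA"], "A")
})

test_that("PDB round-trip preserves structure exactly and coordinates to 3 decimals", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_two_chain_fixture(f)
  m <- read_pdb(f)
  # perturb to non-round coordinates to exercise the 3-decimal contract
  m$atoms$x <- m$atoms$x + 0.1234567
  g <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, g)
  m2 <- read_pdb(g)
  expect_equal(m2$atoms$chain, m$atoms$chain)
  expect_equal(m2$atoms$elety, m$atoms$elety)
  expect_equal(nrow(residues_of(m2)), nrow(residues_of(m)))
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_true(max(abs(m2$atoms$x - round(m$atoms$x, 3))) < 1e-9)
})

test_that("write_pdb rejects empty models and multi-character chain ids", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_two_chain_fixture(f)
  m <- read_pdb(f)
  bad <- m; bad$atoms$chain <- "AB"
  expect_error(write_pdb(bad, withr::local_tempfile(fileext = ".pdb")),
               "single character")
  empty <- structure(list(atoms = m$atoms[0, ], metadata = list()),
                     class = "structure_model")
  expect_error(write_pdb(empty, withr::local_tempfile(fileext = ".pdb")),
               "empty")
})

test_that("kabsch superposition recovers applied transforms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_two_chain_fixture(f)
  m <- read_pdb(f)

  s0 <- kabsch_superpose(m, m)
  expect_lt(s0$rmsd, 1e-8)
  expect_equal(s0$transform$rotation, diag(3), tolerance = 1e-8)

  set.seed(42)
  for (k in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    tf <- rigid_transform(R, rnorm(3, 0, 10))
    moved <- apply_transform(m, tf)
    s <- kabsch_superpose(moved, m)
    expect_lt(s$rmsd, 1e-8)
    inv <- invert_transform(tf)
    expect_equal(s$transform$rotation, inv$rotation, tolerance = 1e-6)
    expect_equal(s$transform$translation, inv$translation, tolerance = 1e-6)
  }
})

test_that("single displaced atom yields the closed-form RMSD", {
  # n points on a sphere-ish cloud; displace one by 1 A: for a spread cloud
  # the optimal alignment is near identity and RMSD ~ 1/sqrt(n)
  set.seed(7)
  n <- 200
  P <- matrix(rnorm(3 * n, 0, 20), ncol = 3)
  Q <- P; Q[1, 1] <- Q[1, 1] + 1
  s <- kabsch_superpose(P, Q)
  expect_equal(s$rmsd, 1 / sqrt(n), tolerance = 0.02)
  # the Kabsch minimum can only be at or below the identity-alignment RMSD
  expect_lte(s$rmsd, coord_rmsd(P, Q) + 1e-12)
})

test_that("kabsch rejects degenerate selections", {
  P <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  expect_error(kabsch_superpose(P, P), "at least 3")
  L <- cbind(seq_len(5), 0, 0) # collinear
  expect_error(kabsch_superpose(L, L), "collinear|degenerate")
})

test_that("rmsd is invariant under joint rigid transforms and rotations are proper", {
  set.seed(11)
  P <- matrix(rnorm(30), ncol = 3)
  Q <- P + matrix(rnorm(30, 0, 0.3), ncol = 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (k in 1:100) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    tf <- rigid_transform(R, rnorm(3, 0, 5))
    s <- kabsch_superpose(apply_transform(P, tf), apply_transform(Q, tf))
    expect_equal(s$rmsd, base, tolerance = 1e-8)
    Rk <- s$transform$rotation
    expect_equal(crossprod(Rk), diag(3), tolerance = 1e-8)
    expect_equal(det(Rk), 1, tolerance = 1e-8)
  }
})
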