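test_that("PDB round trip preserves counts, labels and coordinates", {
  h <- makeFixture(20, "helix", residueName = "GLY")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructures(path, h)
  back <- readStructures(path)
  expect_length(back, 1)
  expect_equal(nAtoms(back[[1]]), 20)
  expect_equal(back[[1]]@residueNames, rep("GLY", 20))
  expect_equal(coords(back[[1]]), coords(h), tolerance = 1e-3)

  # multi-model framing: one structure per MODEL record, matching labels
  frames <- list(h, rigidMove(h, rotZ(1), c(5, 0, 0)),
                 rigidMove(h, rotZ(2), c(0, 5, 0)))
  writeStructures(path, frames)
  back <- readStructures(path)
  expect_length(back, 3)
  for (b in back) expect_equal(b@atomLabels, h@atomLabels)
  expect_equal(coords(back[[3]]), coords(frames[[3]]), tolerance = 1e-3)
})

test_that("CA-only selection and HETATM records are handled", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  ALA A   2       4.800   0.000   0.000  1.00  0.00",
    "HETATM    4  O   HOH A   3       9.000   0.000   0.000  1.00  0.00",
    "END"), path)
  all4 <- readStructures(path)[[1]]
  expect_equal(nAtoms(all4), 4)
  ca <- readStructures(path, caOnly = TRUE)[[1]]
  expect_equal(nAtoms(ca), 2)
  expect_equal(coords(ca)[, 1], c(1, 4.8))
})

test_that("alternate locations resolve to highest occupancy, ties to A", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00",
    "ATOM      3  CA AALA A   2       5.000   0.000   0.000  0.50  0.00",
    "ATOM      4  CA BALA A   2       7.000   0.000   0.000  0.50  0.00",
    "END"), path)
  s <- readStructures(path)[[1]]
  expect_equal(nAtoms(s), 2)
  expect_equal(coords(s)[1, 1], 2)  # B wins on occupancy
  expect_equal(coords(s)[2, 1], 5)  # tie goes to A
})

test_that("malformed and empty PDB inputs raise informative errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       3.800   xxx     0.000  1.00  0.00"),
    path)
  expect_error(readStructures(path), "line 2")
  writeLines(character(0), path)
  expect_error(readStructures(path), "empty")
})

test_that("XYZ round trip preserves frames and coordinates", {
  s <- makeFixture(10, "coil", seed = 3)
  path <- withr::local_tempfile(fileext = ".xyz")
  writeStructures(path, list(s, rigidMove(s, rotZ(0.5))))
  back <- readStructures(path)
  expect_length(back, 2)
  expect_equal(coords(back[[1]]), coords(s), tolerance = 1e-5)
})

test_that("superposition recovers exact rigid transforms", {
  s <- makeFixture(15, "helix")
  fit <- superpose(s, s)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  rot <- rotZ(pi / 2)
  moved <- rigidMove(s, rot, c(3, -2, 7))
  fit <- superpose(moved, s)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation %*% rot, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD matches independent minimizers on toy sets", {
  a <- matrix(c(0, 0, 0, 3.8, 0, 0, 3.8, 3.8, 0, 0, 3.8, 2), 4, 3,
              byrow = TRUE)
  b <- matrix(c(0.3, -0.2, 0.1, 3.5, 0.4, -0.3, 4.1, 3.6, 0.5, 0.2, 4, 1.6),
              4, 3, byrow = TRUE)
  got <- superpose(a, b)$rmsd

  # independent route: numerical minimization over Euler angles
  obj <- function(p) {
    r <- rotZ(p[1]) %*%
      matrix(c(1, 0, 0, 0, cos(p[2]), sin(p[2]), 0, -sin(p[2]), cos(p[2])),
             3, 3) %*% rotZ(p[3])
    am <- sweep(a, 2, colMeans(a)) %*% t(r)
    bm <- sweep(b, 2, colMeans(b))
    sqrt(mean(rowSums((am - bm)^2)))
  }
  starts <- expand.grid(a1 = seq(0, 2 * pi, length.out = 5),
                        a2 = seq(0, pi, length.out = 4),
                        a3 = seq(0, 2 * pi, length.out = 5))
  best <- min(apply(starts, 1, function(p) optim(p, obj)$value))
  expect_equal(got, best, tolerance = 1e-3)
  expect_lte(got, best + 1e-9)  # Kabsch is the true minimum

  skip_if_not_installed("bio3d")
  oracle <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("rmsd is symmetric, translation-invariant and rigid-motion invariant", {
  a <- makeFixture(12, "coil", seed = 5)
  b <- makeFixture(12, "coil", seed = 9)
  expect_equal(rmsdAfterSuperposition(a, a), 0, tolerance = 1e-10)
  expect_equal(rmsdAfterSuperposition(a, rigidMove(a, diag(3), c(5, 5, 5))),
               0, tolerance = 1e-8)
  r1 <- rmsdAfterSuperposition(a, b)
  expect_equal(r1, rmsdAfterSuperposition(b, a), tolerance = 1e-6)
  expect_gte(r1, 0)

  for (seed in 1:5) {
    set.seed(seed)
    rot <- randomRotations(1)[[1]]
    tr <- rnorm(3, sd = 10)
    expect_equal(rmsdAfterSuperposition(rigidMove(a, rot, tr),
                                        rigidMove(b, rot, tr)),
                 r1, tolerance = 1e-6)
  }
})

test_that("superposed rmsd never exceeds raw rmsd", {
  for (seed in 1:10) {
    a <- randomChain(15, seed)
    b <- randomChain(15, seed + 100)
    expect_lte(rmsdAfterSuperposition(a, b), rawRmsd(a, b) + 1e-12)
  }
})

test_that("superpose rejects mismatched or degenerate inputs", {
  a <- makeFixture(10, "helix")
  b <- makeFixture(12, "helix")
  expect_error(superpose(a, b), "same number")
  line <- peptideStructure(cbind(1:5 * 3.8, 0, 0))
  expect_error(superpose(line, line), "collinear")
  expect_error(rmsdAfterSuperposition(coords(a)[integer(0), , drop = FALSE],
                                      coords(a)[integer(0), , drop = FALSE]))
})

test_that("rotation vectors round-trip and handle canonical cases", {
  expect_equal(rotationVector(diag(3)), c(0, 0, 0))
  expect_equal(rotationVector(rotZ(pi / 2)), c(0, 0, pi / 2),
               tolerance = 1e-10)
  expect_error(rotationVector(matrix(1, 3, 3)), "rotation")

  set.seed(11)
  for (r in randomRotations(200)) {
    v <- rotationVector(r)
    expect_lte(sqrt(sum(v^2)), pi + 1e-9)
    expect_lt(max(abs(rotationMatrix(v) - r)), 1e-8)
  }
})

test_that("rotation vectors of uniform rotations are isotropic", {
  set.seed(2024)
  vs <- t(vapply(randomRotations(1000), rotationVector, numeric(3)))
  se <- apply(vs, 2, sd) / sqrt(nrow(vs))
  expect_true(all(abs(colMeans(vs)) < 3 * se))
})
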