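test_that("distances match independent arithmetic and the trivial cases", {
  fr <- rbind(c(0, 0, 0), c(0, 0, 3.5), c(0, 0, 0))
  expect_equal(frame_distance(fr, 1, 2), 3.5)
  expect_equal(frame_distance(fr, 1, 3), 0)  # coincident atoms
  set.seed(42)
  fr2 <- matrix(rnorm(12), 4, 3)
  d <- fr2[1, ] - fr2[3, ]
  expect_equal(frame_distance(fr2, 1, 3),
               sqrt(d[1]^2 + d[2]^2 + d[3]^2))
  expect_equal(frame_distance(fr2, 1, 3), frame_distance(fr2, 3, 1))
  expect_error(frame_distance(fr2, 2, 2), "distinct")
  expect_error(frame_distance(fr2, 1, 9), "out of range")
})

test_that("angles cover collinear, right-angle and an acos oracle", {
  fr <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(frame_angle(fr, 1, 2, 3), 180)
  expect_equal(frame_angle(fr, 3, 2, 4), 90)
  set.seed(7)
  fr2 <- matrix(rnorm(9), 3, 3)
  a <- fr2[1, ] - fr2[2, ]; b <- fr2[3, ] - fr2[2, ]
  oracle <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  expect_equal(frame_angle(fr2, 1, 2, 3), oracle, tolerance = 1e-12)
  fr3 <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(frame_angle(fr3, 1, 2, 3), "degenerate")
})

test_that("dihedrals follow the IUPAC convention and two independent oracles", {
  # planar cis and trans quartets
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(frame_dihedral(cis, 1, 2, 3, 4), 0)
  trans <- rbind(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(abs(frame_dihedral(trans, 1, 2, 3, 4)), 180)

  set.seed(13)
  for (rep in 1:25) {
    fr <- matrix(rnorm(12, sd = 2), 4, 3)
    got <- frame_dihedral(fr, 1, 2, 3, 4)
    # oracle 1: acos of normal-plane cosine, sign from a triple product
    b1 <- fr[2, ] - fr[1, ]; b2 <- fr[3, ] - fr[2, ]; b3 <- fr[4, ] - fr[3, ]
    xp <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
    n1 <- xp(b1, b2); n2 <- xp(b2, b3)
    cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
    phi <- acos(pmin(1, pmax(-1, cosphi))) * 180 / pi
    if (sum(xp(n1, n2) * b2) < 0) phi <- -phi
    expect_equal(got, phi, tolerance = 1e-9)
    # oracle 2: bio3d's torsion routine
    expect_equal(got,
                 bio3d::torsion.xyz(as.vector(t(fr)), atm.inc = 4),
                 tolerance = 1e-6, ignore_attr = TRUE)
    # invariance under full reversal of the quartet (the torsion looks the
    # same from either end); negation comes from mirror reflection instead
    expect_equal(frame_dihedral(fr, 4, 3, 2, 1), got, tolerance = 1e-9)
    expect_equal(frame_dihedral(-fr, 1, 2, 3, 4), -got, tolerance = 1e-9)
  }
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(frame_dihedral(collinear, 1, 2, 3, 4), "collinear")
})

test_that("distance/angle/dihedral are invariant under rigid motion", {
  set.seed(21)
  fr <- matrix(rnorm(18, sd = 3), 6, 3)
  d0 <- frame_distance(fr, 1, 4)
  a0 <- frame_angle(fr, 1, 2, 3)
  t0 <- frame_dihedral(fr, 1, 2, 3, 4)
  for (rep in 1:10) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 10)
    fr2 <- sweep(fr %*% t(R), 2, shift, `+`)
    expect_equal(frame_distance(fr2, 1, 4), d0, tolerance = 1e-9)
    expect_equal(frame_angle(fr2, 1, 2, 3), a0, tolerance = 1e-9)
    expect_equal(frame_dihedral(fr2, 1, 2, 3, 4), t0, tolerance = 1e-9)
  }
})

test_that("Kabsch recovers planted rigid transforms and refuses mirrors", {
  set.seed(5)
  P <- matrix(rnorm(45), 15, 3)
  sp0 <- kabsch_superpose(P, P)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)

  for (rep in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 8)
    Q <- sweep(P %*% t(R), 2, shift, `+`)
    sp <- kabsch_superpose(Q, P)
    expect_lt(sp$rmsd, 1e-10)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
    expect_lt(max(abs(apply_superposition(sp, Q) - P)), 1e-9)
  }

  mirror <- P
  mirror[, 1] <- -mirror[, 1]
  expect_gt(kabsch_superpose(mirror, P)$rmsd, 0.1)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(P[1:4, ], P), "identical dimensions")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("optimal superposition never beats the identity placement", {
  set.seed(31)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P + matrix(rnorm(30, sd = 0.4), 10, 3)
  sp <- kabsch_superpose(Q, P)
  rmsd_identity <- sqrt(mean(rowSums((Q - P)^2)))
  expect_lte(sp$rmsd, rmsd_identity + 1e-12)
  # independent oracle: bio3d's fitted RMSD
  expect_equal(sp$rmsd,
               bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE),
               tolerance = 1e-3)
})

test_that("residue displacement reports planted shifts and flags absences", {
  top <- md_topology(serial = 1:8, name = rep("CA", 8),
                     resname = rep("GLY", 8), resid = 1:8, chain = "A",
                     element = "C")
  set.seed(9)
  xyz <- matrix(rnorm(24, sd = 4), 8, 3)
  a <- list(topology = top, coords = xyz)

  ident <- residue_displacement(a, a, atom_select(name = "CA"),
                                atom_select(resid = 1:5, name = "CA"))
  expect_true(all(ident$displacement < 1e-10))

  # translate residue 8 by exactly 2 Angstrom, keep the fit region fixed
  xyz_b <- xyz
  xyz_b[8, ] <- xyz_b[8, ] + c(0, 0, 2)
  b <- list(topology = top, coords = xyz_b)
  prof <- residue_displacement(a, b, atom_select(name = "CA"),
                               atom_select(resid = 1:5, name = "CA"))
  expect_equal(prof$displacement[prof$resid == 8], 2, tolerance = 1e-8)
  expect_lt(max(prof$displacement[prof$resid <= 5]), 1e-8)

  # a residue missing from b is NA, not zero
  top7 <- md_topology(serial = 1:7, name = rep("CA", 7),
                      resname = rep("GLY", 7), resid = 1:7, chain = "A",
                      element = "C")
  b7 <- list(topology = top7, coords = xyz_b[1:7, ])
  prof2 <- residue_displacement(a, b7, atom_select(name = "CA"),
                                atom_select(resid = 1:5, name = "CA"))
  expect_true(is.na(prof2$displacement[prof2$resid == 8]))
})
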