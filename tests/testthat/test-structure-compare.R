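# XYZ I/O, Kabsch superposition, dihedral angles and ensemble reports.

test_that("XYZ files round-trip and malformed input names the line", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("3", "water-ish", "O 0.0 0.0 0.0", "H 0.96 0.0 0.0",
               "H -0.24 0.93 0.0"), f)
  g <- read_xyz(f)
  expect_length(g, 1L)
  expect_identical(g[[1]]$elements, c("O", "H", "H"))
  expect_identical(g[[1]]$label, "water-ish")

  set.seed(3)
  geos <- lapply(1:5, function(i) rand_geometry(4, sprintf("frame%d", i)))
  f2 <- tempfile(fileext = ".xyz")
  write_xyz(geos, f2, digits = 10)
  back <- read_xyz(f2)
  expect_length(back, 5L)
  for (i in 1:5) {
    expect_identical(back[[i]]$label, geos[[i]]$label)
    expect_equal(back[[i]]$coords, geos[[i]]$coords, tolerance = 1e-9)
  }

  writeLines(c("4", "short frame", "C 0 0 0", "C 1 0 0"), f)
  expect_error(read_xyz(f), "line 1.*ends early")
  writeLines(c("2", "bad coord", "C 0 0 0", "C 1 zero 0"), f)
  expect_error(read_xyz(f), "line 4")
})

test_that("superposition is exact on rigid copies and symmetric", {
  set.seed(5)
  a <- rand_geometry(7, "ref")
  expect_lt(superpose_rmsd(a, a)$rmsd, 1e-14)
  for (i in 1:10) {
    b <- rigid_copy(a, label = "copy")
    fit <- superpose_rmsd(a, b)
    expect_lt(fit$rmsd, 1e-10)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    # returned transform really aligns b onto a
    aligned <- b$coords %*% t(fit$rotation) +
      rep(fit$translation, each = nrow(b$coords))
    expect_equal(aligned, a$coords, tolerance = 1e-9)
    c2 <- rand_geometry(7, "other"); c2$elements <- a$elements
    expect_equal(superpose_rmsd(a, c2)$rmsd, superpose_rmsd(c2, a)$rmsd,
                 tolerance = 1e-12)
    # invariance to pre-rotation of either input
    expect_equal(superpose_rmsd(rigid_copy(a), c2)$rmsd,
                 superpose_rmsd(a, rigid_copy(c2))$rmsd, tolerance = 1e-10)
  }
})

test_that("Kabsch equals the quaternion-grid brute-force minimum", {
  # two fixed 4-atom toys
  a <- geometry(c("C", "N", "O", "H"),
                rbind(c(0, 0, 0), c(1.4, 0, 0), c(1.9, 1.2, 0.3),
                      c(-0.5, 0.8, -0.7)), "toyA")
  b <- geometry(c("C", "N", "O", "H"),
                rbind(c(0.1, -0.2, 0), c(1.5, 0.2, 0.1), c(2.2, 1.0, 0.6),
                      c(-0.7, 0.9, -0.4)), "toyB")
  k <- superpose_rmsd(a, b)$rmsd
  expect_lt(abs(k - brute_force_rmsd(a$coords, b$coords)), 1e-9)

  set.seed(9)
  for (i in 1:4) {
    ga <- rand_geometry(6); gb <- rand_geometry(6)
    gb$elements <- ga$elements
    expect_lt(abs(superpose_rmsd(ga, gb)$rmsd -
                    brute_force_rmsd(ga$coords, gb$coords)), 1e-9)
  }
})

test_that("superposition agrees with an established reference implementation", {
  set.seed(12)
  a <- rand_geometry(8); b <- rand_geometry(8); b$elements <- a$elements
  ours <- superpose_rmsd(a, b)$rmsd
  ref <- bio3d::rmsd(as.vector(t(a$coords)), as.vector(t(b$coords)),
                     fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds its return value
})

test_that("reflections are never used and degenerate sets are flagged", {
  set.seed(21)
  a <- rand_geometry(6)
  mirror <- geometry(a$elements, a$coords %*% diag(c(1, 1, -1)), "mirror")
  expect_gt(superpose_rmsd(a, mirror)$rmsd, 1e-3)  # enantiomer stays distinct
  line <- geometry(c("C", "C", "C"), cbind(c(0, 1, 2), 0, 0), "line")
  fit <- superpose_rmsd(line, rigid_copy(line))
  expect_true("degenerate" %in% fit$flags)
  expect_lt(fit$rmsd, 1e-10)
  b <- rand_geometry(6)
  expect_error(superpose_rmsd(a, b), "element")
  # masking restricts the fit to the selected atoms
  am <- rand_geometry(6); bm <- rigid_copy(am)
  bm$coords[6, ] <- bm$coords[6, ] + 5          # one outlier atom
  expect_gt(superpose_rmsd(am, bm)$rmsd, 0.5)
  expect_lt(superpose_rmsd(am, bm, atom_mask = 1:5)$rmsd, 1e-10)
})

test_that("dihedrals follow the signed IUPAC convention", {
  # planar cis: 0 degrees; planar trans: 180 degrees
  cis <- geometry(rep("C", 4),
                  rbind(c(1, 1, 0), c(0, 1, 0), c(0, -1, 0), c(1, -1, 0)))
  expect_equal(dihedral(cis, 1, 2, 3, 4), 0)
  trans <- geometry(rep("C", 4),
                    rbind(c(1, 1, 0), c(0, 1, 0), c(0, -1, 0), c(-1, -1, 0)))
  expect_equal(dihedral(trans, 1, 2, 3, 4), 180)

  # staggered toy vs an independent plane-normal construction
  g <- geometry(rep("C", 4),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0),
                      c(3.1, 1.6, 1.2)))
  b1 <- g$coords[2, ] - g$coords[1, ]
  b2 <- g$coords[3, ] - g$coords[2, ]
  b3 <- g$coords[4, ] - g$coords[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  expected <- atan2(sum(b2 / sqrt(sum(b2^2)) * (c(
    n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
    n1[1] * n2[2] - n1[2] * n2[1]))), sum(n1 * n2)) * 180 / pi
  expect_equal(dihedral(g, 1, 2, 3, 4), expected, tolerance = 1e-10)
  # and against an established implementation
  expect_equal(dihedral(g, 1, 2, 3, 4),
               bio3d::torsion.xyz(as.vector(t(g$coords))), tolerance = 1e-6)

  # mirror reflection flips the sign, keeps the magnitude
  gm <- geometry(g$elements, g$coords %*% diag(c(1, 1, -1)))
  expect_equal(dihedral(gm, 1, 2, 3, 4), -dihedral(g, 1, 2, 3, 4))

  bad <- geometry(rep("C", 4), rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                     c(1, 1, 0)))
  expect_error(dihedral(bad, 1, 2, 3, 4), "coincide")
  expect_error(dihedral(g, 1, 2, 3, 3), "distinct")
})

test_that("ensemble reports correlate dihedral change with RMSD", {
  # identical copies: zero RMSD everywhere, correlation not applicable
  ref <- chain_with_torsion(60, "ref")
  copies <- c(list(ref), lapply(1:4, function(i)
    rigid_copy(ref, label = sprintf("c%d", i))))
  rep0 <- ensemble_structure_report(copies, "ref", c(1, 2, 3, 4))
  expect_true(all(rep0$members$rmsd < 1e-10))
  expect_true(is.na(rep0$correlation))
  expect_match(rep0$correlation_note, "not applicable")

  # progressive torsion rotation: monotone by construction
  angles <- seq(20, 110, by = 15)
  fam <- c(list(chain_with_torsion(20, "ref")),
           lapply(angles[-1], function(a) chain_with_torsion(a)))
  rep1 <- ensemble_structure_report(fam, "ref", c(1, 2, 3, 4))
  expect_equal(rep1$correlation, 1)

  # member order must not matter
  rep2 <- ensemble_structure_report(rev(fam), "ref", c(1, 2, 3, 4))
  expect_identical(rep1$members, rep2$members)
  expect_identical(rep1$correlation, rep2$correlation)

  expect_error(ensemble_structure_report(fam, "nope", c(1, 2, 3, 4)),
               "not found")

  f <- tempfile(fileext = ".csv")
  write_rmsd_csv(rep1, f)
  got <- read.csv(f)
  expect_identical(nrow(got), nrow(rep1$members))
  expect_equal(got$rmsd_angstrom, rep1$members$rmsd, tolerance = 1e-10)
})
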