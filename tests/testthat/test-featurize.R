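test_that("PDB reading echoes coordinates in nm and flags the ligand", {
  s <- readStructure(toyHoloPath())
  a <- atomTable(s)
  expect_equal(nrow(a), 19)
  expect_equal(a$x[1], 0.4)             # 4.0 Angstrom -> 0.4 nm
  expect_equal(a[a$name == "CA" & a$resno == 2, c("x", "y", "z")],
               data.frame(x = 0, y = 0.8, z = 0), ignore_attr = TRUE)
  expect_equal(sum(a$ligand), 6)        # benzene ring carbons
  expect_setequal(a$element[a$ligand], "C")
})

test_that("structures without atoms are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK   1 NOTHING HERE", "END"), f)
  expect_error(readStructure(f), "zero atoms|parse failed")
  expect_error(readStructure(file.path(tempdir(), "absent.pdb")), "no such file")
})

test_that("pocket definition matches brute-force distances (boundary inclusive)", {
  s <- readStructure(toyHoloPath())
  a <- atomTable(s)
  lig <- intersect(ligandAtoms(s), heavyAtoms(s))
  prot <- proteinHeavyAtoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # exhaustive all-pairs oracle
  dmin <- sapply(prot, function(p)
    min(sqrt(rowSums(sweep(xyz[lig, , drop = FALSE], 2, xyz[p, ])^2))))
  expect_equal(definePocket(s), prot[dmin <= 0.5])
  # synthetic boundary case: atoms at 0.3/0.49/0.51 from a ligand at origin
  b <- a[seq_len(4), ]
  b$ligand <- c(TRUE, FALSE, FALSE, FALSE)
  b$element <- "C"
  b[, c("x", "y", "z")] <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.49, 0, 0),
                                 c(0.51, 0, 0))
  sb <- new("StructureModel", atoms = b, provenance = "synthetic")
  expect_equal(definePocket(sb), c(2L, 3L))
  # cutoff 0: only exactly coincident atoms
  expect_warning(res <- definePocket(sb, cutoff = 0), "undefined")
  expect_length(res, 0)
})

test_that("contact features equal per-frame brute-force evaluation", {
  set.seed(21)
  nat <- 8
  coords <- lapply(1:100, function(i) matrix(runif(nat * 3, 0, 1.5), nat, 3))
  traj <- coordinateTrajectory(coords, frameInterval = 1)
  lig <- 1:2
  groups <- list(R1 = 3:4, R2 = 5:6, R3 = 7:8)
  ft <- contactFeatures(traj, lig, groups, cutoff = 0.5)
  ref <- t(vapply(1:100, function(f) {
    xyz <- coords[[f]]
    vapply(groups, function(g) {
      d <- sqrt(outer(rowSums(xyz[lig, ]^2), rowSums(xyz[g, ]^2), "+") -
                  2 * xyz[lig, ] %*% t(xyz[g, ]))
      as.numeric(min(d) <= 0.5)
    }, numeric(1))
  }, numeric(3)))
  expect_equal(featureMatrix(ft), ref, ignore_attr = TRUE)
  # single-frame threshold checks
  one <- coordinateTrajectory(list(rbind(c(0, 0, 0), c(0.4, 0, 0))), 1)
  expect_equal(featureMatrix(contactFeatures(one, 1, list(R = 2)))[1, 1], 1)
  one6 <- coordinateTrajectory(list(rbind(c(0, 0, 0), c(0.6, 0, 0))), 1)
  expect_equal(featureMatrix(contactFeatures(one6, 1, list(R = 2)))[1, 1], 0)
  expect_error(contactFeatures(one, 1, list(R = integer(0))), "empty residue")
})

test_that("pocket-ligand distance is a mass-weighted centroid distance", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 0))
  traj <- coordinateTrajectory(list(xyz, xyz + 0.2), frameInterval = 1)
  # same single atom for both selections -> zero
  expect_equal(pocketLigandDistance(traj, 1, 1), c(0, 0))
  # two unit-mass-like atoms (same element) centred on the third
  expect_equal(pocketLigandDistance(traj, c(1, 2), 3), c(0, 0),
               tolerance = 1e-12)
  # brute-force oracle with unequal masses
  a <- atomTable(traj)
  a$element <- c("C", "N", "O")
  traj2 <- coordinateTrajectory(traj@coords, 1, atoms = a)
  m <- c(12.011, 14.007, 15.999)
  ref <- sapply(1:2, function(f) {
    x <- traj2@coords[f, , ]
    cP <- colSums(x[1:2, ] * m[1:2]) / sum(m[1:2])
    sqrt(sum((cP - x[3, ])^2))
  })
  expect_equal(pocketLigandDistance(traj2, 1:2, 3), ref)
  aU <- a; aU$element <- c("C", "Xx", "O")
  trajU <- coordinateTrajectory(traj@coords, 1, atoms = aU)
  expect_error(pocketLigandDistance(trajU, 1:2, 3), "unknown element")
})

test_that("superposition RMSD is invariant under rigid motions", {
  ref <- readStructure(toyHoloPath())
  xyz <- as.matrix(atomTable(ref)[, c("x", "y", "z")])
  sel <- 1:12
  # identical frame -> 0
  t0 <- coordinateTrajectory(list(xyz), 1, atoms = atomTable(ref))
  expect_equal(superposeRMSD(t0, ref, sel), 0, tolerance = 1e-12)
  # random proper rotations + translations -> still 0
  set.seed(8)
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    moved <- xyz %*% t(R) + matrix(rnorm(3), nrow(xyz), 3, byrow = TRUE)
    tm <- coordinateTrajectory(list(moved), 1, atoms = atomTable(ref))
    expect_lt(superposeRMSD(tm, ref, sel), 1e-9)
  }
  expect_error(superposeRMSD(t0, ref, 1:2), "at least 3")
  collin <- xyz; collin[, 2:3] <- 0
  refC <- new("StructureModel",
              atoms = transform(atomTable(ref), y = 0, z = 0),
              provenance = "synthetic")
  expect_error(superposeRMSD(t0, refC, c(1, 2, 3)), "collinear")
})

test_that("superposition RMSD matches the bio3d fitting oracle", {
  ref <- readStructure(toyHoloPath())
  xyz <- as.matrix(atomTable(ref)[, c("x", "y", "z")])
  sel <- 1:10
  set.seed(31)
  pert <- xyz + matrix(rnorm(length(xyz), sd = 0.05), nrow(xyz))
  tm <- coordinateTrajectory(list(pert), 1, atoms = atomTable(ref))
  ours <- superposeRMSD(tm, ref, sel)
  theirs <- bio3d::rmsd(as.vector(t(xyz[sel, ])), as.vector(t(pert[sel, ])),
                        fit = TRUE)
  expect_lt(abs(ours - theirs), 5e-4)   # bio3d reports 3 decimals
})

test_that("bound-state labels honour the dwell-time criterion", {
  fi <- 1          # 1 ns frames
  n <- 1000
  rmsd <- rep(1, n); dist <- rep(1, n)
  # three sub-threshold excursions: 50, 100 and 400 ns
  rmsd[101:150] <- 0.3; dist[101:150] <- 0.1
  rmsd[301:400] <- 0.3; dist[301:400] <- 0.1
  rmsd[501:900] <- 0.3; dist[501:900] <- 0.1
  lab <- boundStateLabels(rmsd, dist, fi, dwellMin = 100)
  expect_equal(lab$firstBindingTime, 300)     # start of the 100 ns excursion
  expect_false(any(lab$bound[101:150]))
  expect_true(lab$bound[301])
  # exactly dwellMin -> bound; one frame less -> unbound
  lab99 <- boundStateLabels(rmsd, dist, fi, dwellMin = 101)
  expect_false(any(lab99$bound[301:400]))
  expect_true(lab99$bound[501])
  expect_error(boundStateLabels(rmsd[-1], dist, fi), "length")
})

test_that("increasing the dwell requirement never adds bound frames", {
  set.seed(77)
  n <- 2000
  r <- abs(stats::filter(rnorm(n), rep(1, 20), circular = TRUE)) / 6
  d <- abs(stats::filter(rnorm(n), rep(1, 20), circular = TRUE)) / 12
  prev <- rep(TRUE, n)
  for (dm in c(5, 10, 20, 50, 100)) {
    b <- boundStateLabels(r, d, 1, dwellMin = dm)$bound
    expect_true(all(b <= prev))
    prev <- b
  }
})

test_that("transition path segments count frames between threshold crossings", {
  # monotone descent 1.0 -> 0.2 over 10 frames of 1 ns:
  # first below 0.6 at frame index 3, first at/below 0.38 at frame index 8
  s <- c(1.0, 0.9, 0.7, 0.55, 0.52, 0.5, 0.45, 0.40, 0.3, 0.2)
  taus <- transitionPathSegments(s, 1)
  expect_equal(taus, 5)
  # never below 0.38 -> empty
  expect_length(transitionPathSegments(pmax(s, 0.45), 1), 0)
  # aborted dip below 0.6 then a completed crossing -> only one segment
  s2 <- c(1, 1, 0.55, 0.9, 1, 0.5, 0.45, 0.41, 0.3, 1)
  expect_equal(transitionPathSegments(s2, 1), 3)
  # unbinding direction mirrors the definition
  expect_equal(transitionPathSegments(rev(s), 1, direction = "unbinding"), 5)
  expect_error(transitionPathSegments(s, 1, boundBelow = 0.7,
                                      unboundAbove = 0.6), "inverted")
})
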