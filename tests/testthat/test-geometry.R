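# Structure parsing, bond perception and keto-enol fragment location.

test_that("read_xyz parses well-formed files and rejects malformed ones", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water", "O 0 0 0", "H 0.97 0 0", "H -0.24 0.93 0"), p)
  mol <- read_xyz(p)
  expect_s3_class(mol, "molecule3d")
  expect_equal(length(mol$elements), 3L)
  expect_equal(nrow(mol$bonds), 0L)
  expect_equal(mol$name, "water")
  expect_equal(mol$coords[2, 1], 0.97)

  writeLines(character(0), p)
  expect_error(read_xyz(p), "empty")
  writeLines(c("2", "bad count", "O 0 0 0", "H 1 0 0", "H 0 1 0"), p)
  expect_error(read_xyz(p), "declares 2 atoms")
  writeLines(c("2", "bad coord", "O 0 0 0", "H one 0 0"), p)
  expect_error(read_xyz(p), "line 4")
  writeLines(c("1", "bad element", "Xq 0 0 0"), p)
  expect_error(read_xyz(p), "unknown element")
})

test_that("read_sdf parses V2000 records and enforces the dialect", {
  p <- withr::local_tempfile(fileext = ".sdf")
  writeLines(ethanol_mol_lines(), p)
  mols <- read_sdf(p)
  expect_length(mols, 1L)
  expect_equal(length(mols[[1]]$elements), 9L)
  expect_equal(nrow(mols[[1]]$bonds), 8L)
  expect_equal(mols[[1]]$name, "ethanol")

  writeLines(c(ethanol_mol_lines(), "$$$$", ethanol_mol_lines(), "$$$$"), p)
  expect_length(read_sdf(p), 2L)

  bad <- ethanol_mol_lines()
  bad[5 + 9] <- sprintf("%3d%3d%3d  0  0  0  0", 0L, 2L, 1L)
  writeLines(bad, p)
  expect_error(read_sdf(p), "references atom 0")

  v3 <- ethanol_mol_lines()
  v3[4] <- "  0  0  0  0  0  0  0  0  0  0999 V3000"
  writeLines(v3, p)
  expect_error(read_sdf(p), "V3000")

  writeLines(ethanol_mol_lines()[1:8], p)
  expect_error(read_sdf(p), "truncated")
})

test_that("read_sdf agrees with the ChemmineR reader on atom and bond counts", {
  p <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(ethanol_mol_lines(), "$$$$"), p)
  mine <- read_sdf(p)[[1]]
  suppressWarnings(suppressMessages({
    ref <- ChemmineR::read.SDFset(p)[[1]]
    ab <- ChemmineR::atomblock(ref)
    bb <- ChemmineR::bondblock(ref)
  }))
  expect_equal(length(mine$elements), nrow(ab))
  expect_equal(nrow(mine$bonds), nrow(bb))
  expect_equal(unname(mine$coords), unname(ab[, 1:3]), tolerance = 1e-8)
})

test_that("perceive_bonds applies the covalent-radius cutoff", {
  # O-H at 0.97: cutoff 1.2 * (0.66 + 0.31) = 1.164 -> bonded
  m <- molecule3d(c("O", "H"), rbind(c(0, 0, 0), c(0.97, 0, 0)))
  expect_equal(nrow(perceive_bonds(m)$bonds), 1L)
  # two C at 2.0: cutoff 1.2 * 1.52 = 1.824 -> not bonded
  m <- molecule3d(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(nrow(perceive_bonds(m)$bonds), 0L)
  expect_error(perceive_bonds(m, tolerance = 1.6), "tolerance")
  m <- molecule3d(c("C", "Xe"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(perceive_bonds(m), "Xe")
})

test_that("perceive_bonds on ideal benzene matches a brute-force oracle", {
  mol <- benzene_molecule()
  got <- perceive_bonds(mol, 1.2)$bonds
  # independent oracle: all-pairs loop with its own radius values
  radius <- c(C = 0.76, H = 0.31)
  expected <- 0L
  for (i in 1:11) for (j in (i + 1):12) {
    d <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    if (d <= 1.2 * (radius[mol$elements[i]] + radius[mol$elements[j]]))
      expected <- expected + 1L
  }
  expect_equal(expected, 12L)
  expect_equal(nrow(got), expected)
})

test_that("bond perception is invariant under rigid motions", {
  mol <- keto_enol_fixture()
  ref <- mol$bonds
  set.seed(7)
  for (r in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    shift <- rnorm(3, sd = 10)
    mol2 <- mol
    mol2$coords <- sweep(mol$coords %*% q, 2, shift, "+")
    expect_equal(perceive_bonds(mol2)$bonds, ref)
  }
})

test_that("bond_length is the Euclidean distance with index checks", {
  m <- molecule3d(c("C", "C"), rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(bond_length(m, 1, 2), sqrt(3))
  m$coords[2, ] <- c(1, 0, 0)
  expect_equal(bond_length(m, 1, 2), 1)
  expect_error(bond_length(m, 1, 1), "distinct")
  expect_error(bond_length(m, 1, 3), "out of range")
})

test_that("fragment detection recovers the fixture and classifies conformers", {
  for (tors in c(0, 180)) {
    mol <- keto_enol_fixture(torsion = tors)
    frag <- detect_keto_enol_fragment(mol)
    expect_equal(frag$ring_size, 6L)
    expect_equal(frag$conformer, if (tors == 0) "syn" else "anti")
    expect_equal(abs(frag$torsion_deg), tors, tolerance = 1e-9)
    feats <- extract_features(mol, frag)
    expect_equal(unclass(feats), IDEAL_LENGTHS, tolerance = 1e-9)
  }
})

test_that("conformer label flips exactly when the torsion crosses 90 degrees", {
  for (tors in c(10, 45, 89.9, 90.1, 135, 179)) {
    frag <- detect_keto_enol_fragment(keto_enol_fixture(torsion = tors))
    expect_equal(frag$conformer, if (tors > 90) "anti" else "syn",
                 info = sprintf("torsion %g", tors))
  }
})

test_that("fragment detection fails informatively on unsuitable molecules", {
  expect_error(detect_keto_enol_fragment(perceive_bonds(benzene_molecule())),
               "no keto-enol fragment")
  # heavy-atom-only input: drop the hydroxyl H
  mol <- generate_fragment_geometry(IDEAL_LENGTHS, 180)
  noH <- molecule3d(mol$elements[1:8], mol$coords[1:8, ], name = "no H")
  expect_error(detect_keto_enol_fragment(perceive_bonds(noH)),
               "no hydroxyl H")
  # unbonded molecule
  expect_error(detect_keto_enol_fragment(mol), "perceive_bonds")
})

test_that("extract_features is invariant under rigid motion and reindexing", {
  mol <- keto_enol_fixture()
  frag <- detect_keto_enol_fragment(mol)
  ref <- extract_features(mol, frag)
  set.seed(11)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  mol2 <- mol
  mol2$coords <- sweep(mol$coords %*% q, 2, c(1, -2, 3), "+")
  expect_equal(extract_features(mol2, frag), ref, tolerance = 1e-12)
  # reverse the atom order and remap the fragment indices
  n <- length(mol$elements)
  perm <- rev(seq_len(n))
  mol3 <- molecule3d(mol$elements[perm], mol$coords[perm, ],
                     name = mol$name)
  mol3 <- perceive_bonds(mol3)
  frag3 <- detect_keto_enol_fragment(mol3)
  expect_equal(extract_features(mol3, frag3), ref, tolerance = 1e-12)
})

test_that("feature scaling follows similarity scaling of coordinates", {
  mol <- keto_enol_fixture()
  frag <- detect_keto_enol_fragment(mol)
  mol2 <- mol
  mol2$coords <- mol$coords * 1.01
  expect_equal(unclass(extract_features(mol2, frag)),
               unclass(extract_features(mol, frag)) * 1.01,
               tolerance = 1e-12)
  frag_bad <- frag
  frag_bad$idx_H <- 99L
  expect_error(extract_features(mol, frag_bad), "out of range")
})

test_that("feature vectors outside the physical window are rejected", {
  bad <- IDEAL_LENGTHS
  bad["r_OH"] <- 0.4
  expect_error(validate_feature_vector(bad), "window")
  swapped <- IDEAL_LENGTHS
  swapped["r_OH"] <- 1.5
  expect_error(validate_feature_vector(swapped), "shorter")
})
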