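# Structural module: parsing, contact criteria, superposition, B-factors.

test_that("PDB parsing returns exact coordinates and infers bonds", {
  atoms <- toy_atoms(c("N", "CA", "C"), c("N", "C", "C"),
                     x = c(0, 1.46, 2.40), y = c(0, 0, 1), z = c(0, 0.4, 0))
  m <- parse_structure(toy_pdb(atoms))
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x, c(0, 1.46, 2.40))
  expect_equal(m$atoms$element, c("N", "C", "C"))
  expect_equal(nrow(m$bonds), 2)      # N-CA and CA-C only
  empty <- tempfile(fileext = ".pdb"); writeLines("END", empty)
  expect_error(parse_structure(empty), "no ATOM/HETATM")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1       a.bcd   0.000   0.000  1.00 20.00           N"),
             bad)
  expect_error(parse_structure(bad), "line")
})

test_that("alternate locations resolve to the higher-occupancy conformer", {
  paths <- demo_structure_paths()
  m <- parse_structure(paths["a"])
  cb3 <- m$atoms[m$atoms$name == "CB" & m$atoms$resno == 3 & !m$atoms$het, ]
  expect_equal(nrow(cb3), 1)
  expect_equal(cb3$altloc, "A")          # occ 0.60 beats occ 0.40
  expect_equal(cb3$occ, 0.6)
  # when the later conformer has the higher occupancy it must win
  atoms <- rbind(
    transform(toy_atoms(c("N", "CA", "C"), c("N", "C", "C"),
                        x = c(0, 1.46, 2.4), y = c(0, 0, 1),
                        z = c(0, 0.4, 0)), occ = 1, altloc = ""),
    transform(toy_atoms("CB", "C", 1.46, -1.2, 1.3), occ = 0.3, altloc = "A"),
    transform(toy_atoms("CB", "C", 2.26, -1.2, 1.3), occ = 0.7, altloc = "B"))
  m2 <- parse_structure(toy_pdb(atoms))
  cb <- m2$atoms[m2$atoms$name == "CB", ]
  expect_equal(cb$altloc, "B")
  expect_equal(cb$x, 2.26)
})

test_that("hydrogen-bond candidates follow the 3.3 A distance-only rule", {
  # protein N at origin; ligand O at 3.2 (in), second O at 3.4 (out)
  atoms <- rbind(
    toy_atoms("N", "N", 0, 0, 0),
    toy_atoms(c("O1", "O2"), c("O", "O"), x = c(3.2, 3.4), y = 0, z = 0,
              resname = "LIG", chain = "L", het = TRUE))
  m <- parse_structure(toy_pdb(atoms))
  hb <- find_hbond_candidates(m, "LIG")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance_A, 3.2, tolerance = 1e-6)
  expect_equal(hb$kind, "hbond_candidate")
})

test_that("covalently bonded pairs are excluded from hydrogen-bond candidates", {
  # a cysteine-like S with a covalently attached ligand N (1.7 A, the
  # warhead adduct analogue): inside the 3.3 A cutoff but excluded as a
  # bond; a second ligand N at 3.0 A is a genuine candidate
  atoms <- rbind(
    toy_atoms("SG", "S", 0, 0, 0, resname = "CYS"),
    toy_atoms(c("N1", "N2"), c("N", "N"), x = c(1.7, 1.2), y = c(0, 2.75),
              z = 0, resname = "LIG", chain = "L", het = TRUE))
  m <- parse_structure(toy_pdb(atoms))
  hb <- find_hbond_candidates(m, "LIG")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$ligand_atom, "L/LIG1/N2")
})

test_that("nonpolar contacts require both carbons to be hydrophobic", {
  # protein: an aliphatic CB and a carbonyl C (has an O neighbour, so it is
  # not hydrophobic). ligand: a methyl C at 4.0 A from CB (in range) and
  # another methyl at 4.3 A from everything (outside the cutoff).
  atoms <- rbind(
    toy_atoms(c("CB", "C", "O"), c("C", "C", "O"),
              x = c(0, 0.8, 1.2), y = c(0, 3.1, 4.2), z = 0),
    toy_atoms(c("C1", "C2"), c("C", "C"), x = c(4.0, 4.3), y = c(0, -2),
              z = 0, resname = "LIG", chain = "L", het = TRUE))
  m <- parse_structure(toy_pdb(atoms))
  np <- find_nonpolar_contacts(m, "LIG")
  expect_equal(nrow(np), 1)
  expect_equal(np$protein_atom, "A/ALA1/CB")
  expect_equal(np$ligand_atom, "L/LIG1/C1")
  expect_equal(np$distance_A, 4.0, tolerance = 1e-6)
})

test_that("hbond candidates are a subset of the generic 4.2 A contacts", {
  paths <- demo_structure_paths()
  m <- parse_structure(paths["a"])
  hb <- find_hbond_candidates(m, "LIG")
  gc <- find_contacts(m, "LIG")
  expect_gt(nrow(hb), 0)
  key <- function(d) paste(d$protein_atom, d$ligand_atom)
  expect_true(all(key(hb) %in% key(gc)))
  np <- find_nonpolar_contacts(m, "LIG")
  expect_gt(nrow(np), 0)
  expect_true(all(np$distance_A <= 4.2))
})

test_that("contact enumeration is invariant under global rigid motion", {
  paths <- demo_structure_paths()
  m <- parse_structure(paths["a"])
  m2 <- m    # transform in memory; bonds are preserved by a rigid motion
  m2$atoms <- rigid_move(m2$atoms, angle = 1.1, axis = c(1, 2, 0.5),
                         shift = c(-3, 9, 2))
  for (fn in list(find_hbond_candidates, find_nonpolar_contacts,
                  find_contacts)) {
    a <- fn(m, "LIG"); b <- fn(m2, "LIG")
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$distance_A, b$distance_A, tolerance = 1e-6)
    expect_equal(paste(a$protein_atom, a$ligand_atom),
                 paste(b$protein_atom, b$ligand_atom))
  }
})

test_that("backbone superposition is exact for identity and rigid motions", {
  bb <- toy_backbone()
  m <- parse_structure(toy_pdb(bb))
  self <- superpose_backbone(m, m)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  m2 <- m    # exact rigid copy, transformed in memory
  m2$atoms <- rigid_move(m2$atoms, angle = 0.9, axis = c(1, 1, 1),
                         shift = c(10, -5, 3))
  sup <- superpose_backbone(m, m2)
  expect_equal(sup$rmsd, 0, tolerance = 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)
  expect_equal(sup$n_atoms_matched, 12)
})

test_that("superposition attains the global least-squares minimum", {
  bb <- toy_backbone()
  disp <- bb
  disp$x[5] <- disp$x[5] + 1.0          # one atom displaced by 1 A
  disp <- rigid_move(disp, angle = 0.4, axis = c(0, 1, 0), shift = c(1, 2, 3))
  ma <- parse_structure(toy_pdb(bb))
  mb <- parse_structure(toy_pdb(disp))
  sup <- superpose_backbone(ma, mb)
  A <- as.matrix(ma$atoms[, c("x", "y", "z")])
  B <- as.matrix(mb$atoms[, c("x", "y", "z")])
  expect_equal(sup$rmsd, brute_force_rmsd(A, B), tolerance = 1e-3)
  # independent library cross-check of the superposed rmsd
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_equal(sup$rmsd, ref, tolerance = 1e-2)
  expect_error(superpose_backbone(ma, mb, resno_range = c(1, 2)),
               "insufficient overlap")
})

test_that("ligand RMSD measures displacement in the superposed frame", {
  paths <- demo_structure_paths()
  ma <- parse_structure(paths["a"])
  mb <- parse_structure(paths["b"])
  sup <- superpose_backbone(ma, mb)
  expect_equal(sup$rmsd, 0, tolerance = 1e-3)   # backbone moved rigidly
  # ligand in model b was displaced by exactly 1.0 A within the frame
  expect_equal(ligand_rmsd(ma, mb, "LIG"), 1.0, tolerance = 1e-3)
  expect_equal(ligand_rmsd(ma, ma, "LIG"), 0, tolerance = 1e-9)
})

test_that("ligand RMSD matches a hand-computed displacement field", {
  bb <- toy_backbone()
  lig <- toy_atoms(c("C1", "C2", "N1"), c("C", "C", "N"),
                   x = c(5, 6.5, 7.2), y = c(4, 4.2, 5.5), z = c(1, 1.5, 1),
                   resname = "LIG", chain = "L", het = TRUE)
  a <- rbind(bb, lig)
  ligb <- lig
  ligb$x <- ligb$x + c(0.3, 0, -0.4)
  ligb$y <- ligb$y + c(0, 0.5, 0)
  b <- rbind(bb, ligb)
  ma <- parse_structure(toy_pdb(a)); mb <- parse_structure(toy_pdb(b))
  # backbones identical => frame transform is the identity; rms of the
  # displacement field sqrt(mean(0.09, 0.25, 0.16))
  expect_equal(ligand_rmsd(ma, mb, "LIG"),
               sqrt(mean(c(0.3, 0.5, 0.4)^2)), tolerance = 1e-6)
  ligc <- ligb; ligc$name <- c("C1", "C9", "N1")
  mc <- parse_structure(toy_pdb(rbind(bb, ligc)))
  expect_error(ligand_rmsd(ma, mc, "LIG"), "mapping error")
})

test_that("B-factor profiling flags the hottest atom and averages groups", {
  lig <- toy_atoms(c("C1", "C2", "C3", "C4"), rep("C", 4),
                   x = 1:4 * 3, y = 0, z = 0, resname = "LIG", chain = "L",
                   het = TRUE, b = c(20, 20, 80, 20))
  m <- parse_structure(toy_pdb(rbind(toy_backbone(), lig)))
  prof <- bfactor_profile(m, "LIG",
                          groups = c(C1 = "head", C2 = "head",
                                     C3 = "tail", C4 = "tail"))
  expect_equal(prof$max_atom, "C3")
  gm <- prof$group_means
  expect_equal(gm$mean_b[gm$group == "head"], 20)
  expect_equal(gm$mean_b[gm$group == "tail"], 50)
  uni <- toy_atoms(c("C2", "C1"), c("C", "C"), x = c(3, 6), y = 0, z = 0,
                   resname = "LIG", chain = "L", het = TRUE, b = 20)
  m2 <- parse_structure(toy_pdb(rbind(toy_backbone(), uni)))
  prof2 <- bfactor_profile(m2, "LIG")
  expect_equal(prof2$max_atom, "C1")    # ties resolved by atom-name order
  expect_equal(diff(range(prof2$atoms$b)), 0)
})
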