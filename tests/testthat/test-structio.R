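# Structure I/O, SASA, burial fraction, superposition, TM-score.

min_ala_pdb <- paste(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      10.674   6.719  -4.163  1.00  0.00           C",
  "ATOM      4  O   ALA A   1      10.213   7.839  -4.381  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1      11.912   4.630  -4.717  1.00  0.00           C",
  "END", sep = "\n")

test_that("minimal single-residue PDB parses with all heavy atoms", {
  s <- parse_structure(min_ala_pdb)
  expect_equal(n_residues(s), 1)
  expect_equal(nrow(s$atoms), 5)
  expect_equal(s$sequence$residues, "A")
  expect_equal(s$atoms$radius[s$atoms$atom_name == "N"], 1.55)
})

test_that("PDB writing and reparsing round-trips atoms and coordinates", {
  structures <- nf_random_structures(20, length = 15, seed = 11)
  for (s in structures) {
    s2 <- parse_structure(write_structure(s), id = s$id)
    expect_equal(s2$sequence$residues, s$sequence$residues)
    expect_equal(nrow(s2$atoms), nrow(s$atoms))
    expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
                 as.matrix(s$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    # CA-only convention survives the round trip
    expect_equal(s2$atoms$radius, s$atoms$radius)
  }
})

test_that("multi-chain and non-canonical inputs are rejected informatively", {
  two_chain <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY B   1       3.800   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  err <- expect_error(parse_structure(two_chain), "chain")
  expect_match(conditionMessage(err), "A")
  expect_match(conditionMessage(err), "B")
  bad_res <- sub("ALA", "MSE", min_ala_pdb)
  expect_error(parse_structure(bad_res), "non-canonical")
})

test_that("altloc records resolve to the highest-occupancy conformer", {
  alt_pdb <- paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END", sep = "\n")
  s <- parse_structure(alt_pdb)
  ca <- s$atoms[s$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 2.000)  # the 0.60-occupancy conformer wins
})

test_that("isolated-atom SASA matches the closed form", {
  atoms <- data.frame(res_index = 1L, atom_name = "CB", element = "C",
                      x = 0, y = 0, z = 0, radius = 1.7)
  s <- protein_structure("one", protein_sequence("one", "A"), atoms)
  res <- shrake_rupley_sasa(s, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(res$total, 4 * pi * 3.1^2, tolerance = 1e-9)
  expect_equal(res$total, sum(res$per_atom_area))
  expect_equal(sum(res$per_residue_area), res$total)
})

test_that("two overlapping spheres match the analytic spherical-cap area", {
  atoms <- data.frame(res_index = 1:2, atom_name = "CA", element = "C",
                      x = c(0, 2), y = 0, z = 0, radius = 1.7)
  s <- protein_structure("two", protein_sequence("two", "AA"), atoms)
  # radius override: spheres here are plain 1.7 A carbons, not CA pseudo
  s$atoms$radius <- 1.7
  res <- shrake_rupley_sasa(s, probe_radius = 1.4, n_sphere_points = 960)
  R <- 3.1; d <- 2.0
  analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  expect_lt(abs(res$per_atom_area[1] - analytic) / analytic, 0.02)
  expect_lt(abs(res$per_atom_area[2] - analytic) / analytic, 0.02)
})

test_that("SASA converges in the number of sphere points", {
  s <- nf_random_structures(1, length = 20, seed = 3)[[1]]
  a1 <- shrake_rupley_sasa(s, n_sphere_points = 960)$total
  a2 <- shrake_rupley_sasa(s, n_sphere_points = 3840)$total
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("SASA rejects NaN coordinates and tiny point sets", {
  s <- nf_random_structures(1, length = 5, seed = 3)[[1]]
  s$atoms$x[2] <- NaN
  expect_error(shrake_rupley_sasa(s), "coordinates")
  s2 <- nf_random_structures(1, length = 5, seed = 4)[[1]]
  expect_error(shrake_rupley_sasa(s2, n_sphere_points = 50))
})

test_that("occlusion can only reduce exposed area", {
  s <- nf_random_structures(1, length = 12, seed = 9)[[1]]
  full <- shrake_rupley_sasa(s)
  iso <- 4 * pi * (s$atoms$radius + 1.4)^2
  expect_lte(full$total, sum(iso) + 1e-9)
  expect_true(all(full$per_atom_area <= iso + 1e-9))
  # adding an atom never increases another atom's exposure
  sub <- s
  sub$atoms <- sub$atoms[-5, ]
  sub$atoms$res_index <- as.integer(seq_len(nrow(sub$atoms)))
  sub$sequence <- protein_sequence(s$id, substr(paste(rep("A", 11), collapse = ""), 1, 11))
  part <- shrake_rupley_sasa(sub)
  expect_true(all(full$per_atom_area[-5] <= part$per_atom_area + 1e-9))
})

test_that("extended chains are essentially unburied (reference regression)", {
  seq40 <- paste(rep(c("L", "S"), 20), collapse = "")
  b <- burial_fraction(extended_chain_structure(seq40))
  expect_lte(b$value, 0.15)
  # regression constant fixed by the chosen reference scale
  expect_equal(b$value, 0, tolerance = 1e-8)
  expect_gt(b$reference_sasa, 0)
})

test_that("burial clamps at zero when the fold is no more buried than the reference", {
  atoms <- data.frame(res_index = 1:2, atom_name = "CA", element = "C",
                      x = c(0, 500), y = 0, z = 0, radius = 3.0)
  s <- protein_structure("far", protein_sequence("far", "AA"), atoms)
  b <- burial_fraction(s)
  expect_equal(b$value, 0)
  expect_gte(b$folded_sasa, b$reference_sasa)
})

test_that("burial fraction is monotone non-increasing under dilation", {
  structures <- nf_random_structures(20, length = 25, seed = 21)
  for (s in structures) {
    b1 <- burial_fraction(s)$value
    s2 <- s
    s2$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] * 1.4
    expect_lte(burial_fraction(s2)$value, b1 + 1e-9)
  }
})

test_that("burial fraction needs at least two residues", {
  s <- parse_structure(min_ala_pdb)
  expect_error(burial_fraction(s), "at least 2")
})

test_that("compact hydrophobic folds clear the compactness threshold", {
  polyL <- toy_structure_predictor(paste(rep("L", 40), collapse = ""))
  expect_gt(burial_fraction(polyL)$value, 0.5)
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(31)
  P <- matrix(rnorm(30), ncol = 3)
  ident <- kabsch_superpose(P, P)
  expect_equal(ident$rmsd, 0, tolerance = 1e-9)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-9)
  R <- random_rotation()
  Q <- t(R %*% t(P)) + matrix(rep(c(3, -2, 7), each = nrow(P)), ncol = 3)
  sp <- kabsch_superpose(P, Q)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  moved <- apply_superposition(sp, P)
  expect_equal(sqrt(mean(rowSums((moved - Q)^2))), sp$rmsd, tolerance = 1e-6)
  expect_error(kabsch_superpose(P, Q[1:5, ]), "length")
})

test_that("Kabsch RMSD agrees with an independent quaternion oracle", {
  set.seed(41)
  for (i in 1:50) {
    P <- matrix(rnorm(30), ncol = 3)
    Q <- matrix(rnorm(30), ncol = 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, horn_rmsd(P, Q),
                 tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD is the minimum over brute-force rotations on 4-point toys", {
  set.seed(51)
  P <- matrix(rnorm(12), ncol = 3)
  Q <- matrix(rnorm(12), ncol = 3)
  k <- kabsch_superpose(P, Q)$rmsd
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  brute <- Inf
  for (i in 1:4000) {
    R <- random_rotation()
    brute <- min(brute, sqrt(mean(rowSums((t(R %*% t(Pc)) - Qc)^2))))
  }
  expect_gte(brute, k - 1e-9)
  expect_lt(brute - k, 0.2)
})

test_that("TM-score is 1 for self, rigid-motion invariant, and symmetric", {
  s <- nf_random_structures(2, length = 40, seed = 61)
  expect_equal(tm_score_fixed_alignment(s[[1]], s[[1]])$value, 1.0,
               tolerance = 1e-9)
  qc <- ca_coords(s[[1]])
  R <- random_rotation()
  moved <- t(R %*% t(qc)) + 5
  tm1 <- tm_score_fixed_alignment(qc, ca_coords(s[[2]]))$value
  tm2 <- tm_score_fixed_alignment(moved, ca_coords(s[[2]]))$value
  expect_equal(tm1, tm2, tolerance = 1e-9)
  tm3 <- tm_score_fixed_alignment(ca_coords(s[[2]]), qc)$value
  expect_equal(tm1, tm3, tolerance = 1e-6)
  expect_equal(tm_score_fixed_alignment(qc, ca_coords(s[[2]]))$d0,
               max(1.24 * 25^(1 / 3) - 1.8, 0.5))
})

test_that("TM-score matches the frozen reference oracle table", {
  df <- read.table(test_path("fixtures", "tm_pairs.tsv"), header = TRUE,
                   sep = "\t")
  ref <- read.table(test_path("fixtures", "tm_reference.tsv"), header = TRUE,
                    sep = "\t")
  for (i in seq_len(nrow(ref))) {
    g <- df[df$pair == ref$pair[i], ]
    tm <- tm_score_fixed_alignment(
      as.matrix(g[g$role == "query", c("x", "y", "z")]),
      as.matrix(g[g$role == "template", c("x", "y", "z")]))$value
    expect_lt(abs(tm - ref$tm_expected[i]), 0.01)
  }
})

test_that("TM-score requires CA atoms and equal lengths", {
  s <- nf_random_structures(2, length = 20, seed = 71)
  noca <- s[[1]]
  noca$atoms$atom_name <- "CB"
  expect_error(tm_score_fixed_alignment(noca, s[[2]]), "CA")
  short <- ca_coords(s[[2]])[1:10, ]
  expect_error(tm_score_fixed_alignment(ca_coords(s[[1]]), short), "length")
})

test_that("FASTA writing and reading round-trips sequences", {
  seqs <- list(protein_sequence("a1", paste(rep("ACDEFGHIKL", 8), collapse = "")),
               protein_sequence("b2", "MNPQRSTVWY"))
  tf <- tempfile(fileext = ".fasta")
  write_fasta_sequences(seqs, tf)
  lines <- readLines(tf)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta_sequences(tf)
  expect_equal(vapply(back, `[[`, character(1), "id"), c("a1", "b2"))
  expect_equal(back[[1]]$residues, seqs[[1]]$residues)
})

test_that("sequence containers reject non-canonical letters", {
  expect_error(protein_sequence("x", "ACDX"), "non-canonical")
  expect_error(protein_sequence("x", "ACDB"), "non-canonical")
})
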